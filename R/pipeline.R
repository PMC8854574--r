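# End-to-end pipeline orchestration: simulate -> select -> (classify)
# -> reconstruct -> profile -> report, with file outputs, a manifest,
# and one run-level seed fanned out to per-stage child seeds.

#' Default pipeline configuration
#'
#' @param n_histories emitted photons for the phantom simulation.
#' @param algos reconstruction algorithms to run.
#' @param preset selection preset (see [selection_criteria()]).
#' @param classifier `FALSE`, `TRUE` (train on the fly) or a path to a
#'   saved classifier.
#' @param classifier_histories training-set emissions when training.
#' @param pixels image pixels per side.
#' @param n_iter,n_max SOE iterations and AA Legendre order.
#' @return nested configuration list for [pipeline_run()].
#' @export
pipeline_config <- function(n_histories = 2e6, algos = c("bp", "soe", "aa"),
                            preset = "four_lines", classifier = FALSE,
                            classifier_histories = 2e6, pixels = 200,
                            n_iter = 1000, n_max = 70) {
  list(scene = list(layout = "phantom", f_d = 15),
       n_histories = n_histories,
       direction_bias = TRUE,
       response = list(),
       selection = list(preset = preset, tof = c(0, 10)),
       classifier = classifier,
       classifier_histories = classifier_histories,
       recon = list(algos = algos, pixels = pixels, n_iter = n_iter,
                    n_max = n_max),
       # transverse integration band: the pencil-beam envelope
       # (half-width 2 sigma of the 3 mm beam spread)
       profile = list(pitch = 2.5, band = 12))
}

# deterministic per-stage child seeds below 2^31
child_seed <- function(seed, stage) {
  (seed * 2654435761 + stage * 97561) %% 2147483647
}

#' Run the full prompt-gamma imaging pipeline
#'
#' Stages: simulate the phantom scene, apply the TOF + energy-window
#' selection, optionally train/apply the full-energy classifier,
#' reconstruct with the configured algorithms, project beam-axis
#' profiles and compare them with the generator truth. All artifacts
#' are written under `out_dir` together with a JSON manifest; every
#' stage's randomness derives from the single run seed.
#'
#' @param config list from [pipeline_config()].
#' @param seed run-level seed (integer).
#' @param out_dir output directory (created if missing).
#' @return list with `events`, `selected`, `images`, `profiles`,
#'   `truth`, `report` (deviation tables per algorithm) and
#'   `manifest`, invisibly; files under `out_dir`.
#' @export
pipeline_run <- function(config = pipeline_config(), seed = 1,
                         out_dir = tempfile("pgcam_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- run_manifest(config, seed)
  scene_cfg <- config$scene
  scene <- build_scene(scene_cfg)
  source <- default_pg_source()
  response <- do.call(response_model, config$response)

  # --- simulate ---------------------------------------------------------
  t0 <- proc.time()[3]
  set.seed(child_seed(seed, 1))
  sim <- run_simulation(scene, config$n_histories, source = source,
                        response = response,
                        direction_bias = isTRUE(config$direction_bias))
  ev_path <- file.path(out_dir, "events.tsv")
  write_events(sim$events, ev_path,
               meta = list(seed = seed, n_histories = config$n_histories,
                           scene_hash = config_hash(scene_cfg),
                           weight = sim$weight))
  manifest <- manifest_add_stage(manifest, "simulate", list(ev_path),
                                 proc.time()[3] - t0)

  # --- select -----------------------------------------------------------
  t0 <- proc.time()[3]
  crit <- selection_criteria(tof = config$selection$tof,
                             preset = config$selection$preset)
  selected <- select_events(sim$events, crit)
  sel_path <- file.path(out_dir, "selected.tsv")
  write_events(selected, sel_path)
  manifest <- manifest_add_stage(manifest, "select", list(sel_path),
                                 proc.time()[3] - t0)

  # --- classifier (optional) -------------------------------------------
  model <- NULL
  if (!identical(config$classifier, FALSE)) {
    t0 <- proc.time()[3]
    if (is.character(config$classifier)) {
      model <- load_classifier(config$classifier)
    } else {
      set.seed(child_seed(seed, 2))
      tr <- simulate_training_events(config$classifier_histories,
                                     f_d = scene$config$f_d,
                                     response = response)
      set.seed(child_seed(seed, 3))
      model <- train_classifier(tr$events, tr$scene)
    }
    cls_path <- file.path(out_dir, "classifier.rds")
    save_classifier(model, cls_path)
    selected <- apply_classifier(selected, model, scene)
    selected <- selected[selected$accepted, ]
    write_events(selected, sel_path)
    manifest <- manifest_add_stage(manifest, "classify",
                                   list(cls_path, sel_path),
                                   proc.time()[3] - t0)
  }

  # --- reconstruct + profiles ------------------------------------------
  edges <- seq(0, 200, by = config$profile$pitch)
  line_energies <- switch(config$selection$preset,
                          c12 = 4400,
                          four_lines = c(2300, 4400, 5250, 6100),
                          NULL)
  truth <- truth_profile(source, energies = line_energies, edges = edges)
  truth_path <- file.path(out_dir, "profile_truth.tsv")
  write_profile(truth, truth_path)
  images <- list(); profiles <- list(); report <- list()
  hn <- NULL
  for (algo in config$recon$algos) {
    t0 <- proc.time()[3]
    set.seed(child_seed(seed, 10 + match(algo, c("bp", "soe", "aa"))))
    rec <- switch(algo,
      bp = reconstruct(selected, scene, "bp",
                       pixels = config$recon$pixels),
      soe = reconstruct(selected, scene, "soe",
                        pixels = config$recon$pixels,
                        n_iter = config$recon$n_iter),
      aa = {
        if (is.null(hn)) hn <- precompute_hn(n_max = config$recon$n_max)
        reconstruct(selected, scene, "aa", pixels = config$recon$pixels,
                    hn = hn, n_max = config$recon$n_max)
      })
    prof <- project_profile(rec, edges = edges,
                            band = config$profile$band %||% "full")
    files <- character(0)
    for (pl in names(rec)) {
      img_path <- file.path(out_dir, sprintf("image_%s_%s.tsv", algo, pl))
      write_image(rec[[pl]], img_path,
                  meta = list(algorithm = algo, seed = seed,
                              n_events = nrow(selected)))
      files <- c(files, img_path)
    }
    prof_path <- file.path(out_dir, sprintf("profile_%s.tsv", algo))
    write_profile(prof, prof_path)
    images[[algo]] <- rec
    profiles[[algo]] <- prof
    report[[algo]] <- compare_profiles(prof, truth)
    manifest <- manifest_add_stage(manifest, paste0("recon_", algo),
                                   as.list(c(files, prof_path)),
                                   proc.time()[3] - t0)
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(events = sim$events, selected = selected, images = images,
                 profiles = profiles, truth = truth, report = report,
                 manifest = manifest, out_dir = out_dir))
}
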