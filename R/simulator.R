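# Synthetic-data generator: samples prompt-gamma emissions, transports
# photons through the phantom and crystals, applies the detector
# response and assembles truth-labelled scatter-absorber coincidences.

#' Detector response model
#'
#' Gaussian resolution parameters of the position-sensitive detectors.
#' Energy resolution scales as 1/sqrt(E) from a single anchor:
#' `FWHM(E) = fwhm_frac * anchor * sqrt(E / anchor)` (default 4.5% FWHM
#' at 500 keV, i.e. 22.5 keV there). Setting every parameter to zero
#' gives an ideal detector (identity response).
#'
#' @param energy_fwhm_frac fractional energy FWHM at the anchor.
#' @param energy_anchor anchor energy (keV).
#' @param position_fwhm per-axis position FWHM (mm).
#' @param threshold per-crystal low-energy threshold (keV), applied
#'   after smearing.
#' @param time_fwhm coincidence-time jitter FWHM (ns).
#' @return object of class `pg_response`.
#' @export
response_model <- function(energy_fwhm_frac = 0.045, energy_anchor = 500,
                           position_fwhm = 1.5, threshold = 100,
                           time_fwhm = 0.5) {
  stopifnot(energy_fwhm_frac >= 0, position_fwhm >= 0, threshold >= 0,
            time_fwhm >= 0)
  structure(list(energy_fwhm_frac = energy_fwhm_frac,
                 energy_anchor = energy_anchor,
                 position_fwhm = position_fwhm,
                 threshold = threshold, time_fwhm = time_fwhm),
            class = "pg_response")
}

#' Energy resolution FWHM at a given energy
#' @param response a [response_model()].
#' @param e energy (keV).
#' @return FWHM (keV).
#' @export
energy_fwhm <- function(response, e) {
  response$energy_fwhm_frac * response$energy_anchor *
    sqrt(e / response$energy_anchor)
}

# transport tables shared by the C++ kernel: crystals first, phantom last
scene_transport_tables <- function(scene) {
  cr <- scene$crystals
  boxes <- as.matrix(cr[, c("cx", "cy", "cz", "hx", "hy", "hz")])
  mat_names <- scene$config$crystal_material %||% "lacl3"
  box_material <- rep(1L, nrow(boxes))
  box_terminal <- rep(0L, nrow(boxes))
  if (!is.null(scene$phantom)) {
    boxes <- rbind(boxes, c(scene$phantom$center, scene$phantom$half))
    mat_names <- c(mat_names, scene$phantom$material)
    box_material <- c(box_material, 2L)
    box_terminal <- c(box_terminal, 1L)
  }
  materials <- lapply(mat_names, function(nm) {
    at <- load_attenuation(nm)
    list(energy = at$energy, photo = at$mu[, "photo"],
         compton = at$mu[, "compton"], pair = at$mu[, "pair"])
  })
  list(boxes = boxes, materials = materials,
       box_material = box_material, box_terminal = box_terminal)
}

#' Transport photons through the scene
#'
#' Tracks each emitted photon (and any annihilation secondaries) through
#' the crystal volumes with Klein-Nishina Compton scattering,
#' photoelectric absorption and pair production, and through the phantom
#' in attenuation-removal mode (an interacting photon terminates without
#' deposit, unless `max_phantom_scatter > 0` grants it Compton
#' re-emissions). Returns pre-smearing hits.
#'
#' @param scene a `pg_scene`.
#' @param emissions data.frame from [sample_emission()].
#' @param floor_kev deposits below this are ignored (keV).
#' @param e_cut photons below this energy are absorbed locally (keV).
#' @param max_phantom_scatter Compton scatters allowed inside the
#'   phantom before removal (0 = pure attenuation).
#' @return data.frame of hits: `history`, `crystal_id`, `module`,
#'   `role`, `x`, `y`, `z`, `e` (keV), `t` (ns).
#' @export
transport_photon <- function(scene, emissions, floor_kev = 1, e_cut = 1,
                             max_phantom_scatter = 0) {
  tb <- scene_transport_tables(scene)
  em <- as.matrix(emissions[, c("x", "y", "z", "dx", "dy", "dz", "e", "t")])
  hits <- cpp_transport(em, tb$boxes, tb$materials, tb$box_material,
                        tb$box_terminal, floor_kev, e_cut,
                        as.integer(max_phantom_scatter))
  hits <- as.data.frame(hits)
  idx <- as.integer(hits$box)
  data.frame(history = as.integer(hits$history),
             crystal_id = scene$crystals$crystal_id[idx],
             module = scene$crystals$module[idx],
             role = scene$crystals$role[idx],
             x = hits$x, y = hits$y, z = hits$z, e = hits$e, t = hits$t)
}

#' Apply the detector response to pre-smearing hits
#'
#' Deposits within one history and crystal are merged to their
#' energy-weighted centroid (scintillation light collection cannot
#' separate them), then energy, position and time are smeared with the
#' Gaussian resolutions of the [response_model()]; smeared positions are
#' clamped to the crystal volume and sub-threshold crystals are dropped.
#' The pre-smearing merged energy is kept in `e_true` for truth
#' bookkeeping.
#'
#' @param hits data.frame from [transport_photon()].
#' @param scene the `pg_scene` the hits were produced in.
#' @param response a [response_model()].
#' @return data.frame with one row per surviving (history, crystal):
#'   `history`, `crystal_id`, `module`, `role`, `x`, `y`, `z`, `e`,
#'   `t`, `e_true`.
#' @export
apply_response <- function(hits, scene, response = response_model()) {
  stopifnot(inherits(response, "pg_response"))
  if (nrow(hits) == 0) {
    return(cbind(hits[, c("history", "crystal_id", "module", "role",
                          "x", "y", "z", "e", "t")],
                 e_true = numeric(0)))
  }
  dt <- data.table::as.data.table(hits)
  merged <- dt[, list(e = sum(e),
                      x = sum(x * e) / sum(e),
                      y = sum(y * e) / sum(e),
                      z = sum(z * e) / sum(e),
                      t = min(t)),
               by = c("history", "crystal_id", "module", "role")]
  n <- nrow(merged)
  merged[, "e_true" := merged$e]
  if (response$energy_fwhm_frac > 0) {
    sd_e <- energy_fwhm(response, merged$e) * FWHM_TO_SD
    merged[, "e" := pmax(0, merged$e + rnorm(n, 0, sd_e))]
  }
  if (response$position_fwhm > 0) {
    sd_p <- response$position_fwhm * FWHM_TO_SD
    cr <- scene$crystals[match(merged$crystal_id, scene$crystals$crystal_id), ]
    for (ax in c("x", "y", "z")) {
      lo <- cr[[paste0("c", ax)]] - cr[[paste0("h", ax)]]
      hi <- cr[[paste0("c", ax)]] + cr[[paste0("h", ax)]]
      merged[, (ax) := pmin(pmax(merged[[ax]] + rnorm(n, 0, sd_p), lo), hi)]
    }
  }
  if (response$time_fwhm > 0) {
    merged[, "t" := merged$t + rnorm(n, 0, response$time_fwhm * FWHM_TO_SD)]
  }
  out <- as.data.frame(merged[merged$e >= response$threshold, ])
  rownames(out) <- NULL
  out
}

#' Build scatter-absorber coincidences
#'
#' Per history and module: requires the scatter crystal and at least one
#' absorber crystal above threshold. The absorber energy `ea` is the
#' add-back sum of that module's absorber deposits; the absorber
#' position is taken from the highest-energy absorber crystal, which
#' best approximates the first interaction of the scattered ray
#' (`a_position = "centroid"` instead uses the energy-weighted centroid
#' of the firing crystals; in practice it drags the position toward
#' later scatter sites and blurs the cone axis). Cross-module
#' coincidences are not formed. The truth full-energy flag is set when
#' the pre-smearing deposit total in the module matches the emitted
#' energy within 1 keV.
#'
#' @param smeared data.frame from [apply_response()].
#' @param scene the `pg_scene`.
#' @param emissions the emissions data.frame (row i = history i),
#'   supplying truth energy and emission position.
#' @param a_position `"max_crystal"` (default) or `"centroid"`.
#' @return data.frame of coincidence events with columns `history`,
#'   `module`, `xs, ys, zs`, `xa, ya, za`, `es_kev`, `ea_kev`, `t_ns`,
#'   `truth_e_kev`, `truth_x, truth_y, truth_z`, `full_energy`,
#'   `particle`.
#' @export
build_coincidences <- function(smeared, scene, emissions,
                               a_position = c("max_crystal", "centroid")) {
  a_position <- match.arg(a_position)
  empty <- data.frame(history = integer(0), module = integer(0),
                      xs = numeric(0), ys = numeric(0), zs = numeric(0),
                      xa = numeric(0), ya = numeric(0), za = numeric(0),
                      es_kev = numeric(0), ea_kev = numeric(0),
                      t_ns = numeric(0), truth_e_kev = numeric(0),
                      truth_x = numeric(0), truth_y = numeric(0),
                      truth_z = numeric(0), full_energy = logical(0),
                      particle = character(0))
  if (nrow(smeared) == 0) return(empty)
  dt <- data.table::as.data.table(smeared)
  s_part <- dt[dt$role == "scatter",
               list(xs = x, ys = y, zs = z, es_kev = e, t_ns = t,
                    e_true_s = e_true),
               by = c("history", "module")]
  a_dt <- dt[dt$role == "absorber", ]
  if (nrow(a_dt) == 0 || nrow(s_part) == 0) return(empty)
  a_part <- if (a_position == "centroid") {
    a_dt[, list(xa = sum(x * e) / sum(e), ya = sum(y * e) / sum(e),
                za = sum(z * e) / sum(e),
                ea_kev = sum(e), e_true_a = sum(e_true)),
         by = c("history", "module")]
  } else {
    a_dt[, {
      imax <- which.max(e)
      list(xa = x[imax], ya = y[imax], za = z[imax],
           ea_kev = sum(e), e_true_a = sum(e_true))
    }, by = c("history", "module")]
  }
  ev <- merge(s_part, a_part, by = c("history", "module"))
  if (nrow(ev) == 0) return(empty)
  ev <- as.data.frame(ev)
  em <- emissions[ev$history, ]
  ev$truth_e_kev <- em$e
  ev$truth_x <- em$x; ev$truth_y <- em$y; ev$truth_z <- em$z
  ev$full_energy <- abs(ev$e_true_s + ev$e_true_a - ev$truth_e_kev) <= 1
  ev$particle <- "gamma"
  ev$e_true_s <- NULL; ev$e_true_a <- NULL
  ev$history <- as.integer(ev$history)
  ev$module <- as.integer(ev$module)
  ev <- ev[order(ev$history, ev$module), EVENT_COLUMNS]
  rownames(ev) <- NULL
  ev
}

#' Run the simulation chain
#'
#' Streams histories through emission sampling, photon transport,
#' detector response and coincidence building, and summarises the
#' detection efficiency. All randomness comes from R's global RNG
#' (`set.seed()` before calling for reproducibility).
#'
#' @param scene a `pg_scene` (its `source` is used unless `source` is
#'   given).
#' @param n_histories number of emitted photons (> 0). With direction
#'   biasing these are cone-restricted emissions; efficiencies are still
#'   reported per isotropically emitted photon via the cone solid-angle
#'   weight.
#' @param source optional `pg_source` overriding the scene's.
#' @param response a [response_model()].
#' @param direction_bias if `TRUE`, emission directions are restricted
#'   to fixed cones covering the modules (exact importance sampling;
#'   valid because the phantom removes scattered photons, so directions
#'   outside the cones cannot yield hits).
#' @param max_phantom_scatter see [transport_photon()].
#' @param chunk_size histories per streamed chunk.
#' @return object of class `pg_simulation`: list with `events` (the
#'   coincidence data.frame), `n_histories`, `weight` (solid-angle
#'   fraction; 1 when unbiased) and `efficiency` (list with
#'   `per_photon`, `se_per_photon`, `per_proton`, counts).
#' @export
run_simulation <- function(scene, n_histories, source = NULL,
                           response = response_model(),
                           direction_bias = FALSE,
                           max_phantom_scatter = 0,
                           chunk_size = 1e6) {
  stopifnot(inherits(scene, "pg_scene"), n_histories > 0)
  model <- if (!is.null(source)) source else scene$source
  if (is.null(model)) stop("no source model: pass `source` or set it in the scene")
  cones <- NULL
  if (direction_bias) {
    bbox <- source_bbox(model)
    cones <- direction_cones(scene, bbox)
  }
  n_done <- 0
  chunks <- list()
  weight <- 1
  while (n_done < n_histories) {
    n_chunk <- min(chunk_size, n_histories - n_done)
    em <- sample_emission(model, n_chunk, cones = cones)
    weight <- attr(em, "weight")
    hits <- transport_photon(scene, em,
                             max_phantom_scatter = max_phantom_scatter)
    sm <- apply_response(hits, scene, response)
    ev <- build_coincidences(sm, scene, em)
    if (nrow(ev)) {
      ev$history <- as.integer(ev$history + n_done)
      chunks[[length(chunks) + 1]] <- ev
    }
    n_done <- n_done + n_chunk
  }
  events <- if (length(chunks)) {
    as.data.frame(data.table::rbindlist(chunks))
  } else {
    build_coincidences(apply_response(
      transport_photon(scene, sample_emission(model, 0)), scene, response),
      scene, sample_emission(model, 0))
  }
  n_ev <- nrow(events)
  p_biased <- n_ev / n_histories
  eff <- p_biased * weight
  se <- sqrt(max(p_biased * (1 - p_biased), 0) / n_histories) * weight
  structure(list(
    events = events, n_histories = n_histories, weight = weight,
    efficiency = list(
      n_coincidences = n_ev,
      per_photon = eff, se_per_photon = se,
      per_proton = eff * model$yield_per_proton,
      yield_per_proton = model$yield_per_proton)),
    class = "pg_simulation")
}

# emission bounding box used to build importance-sampling cones
source_bbox <- function(model) {
  switch(model$type,
         point = list(center = model$position, half = c(0, 0, 0)),
         uniform_box = model$bbox,
         lines = {
           depths <- range(unlist(lapply(model$lines,
                                         function(l) range(l$profile$depth))))
           half_tr <- 5 * model$sigma_transverse
           list(center = c(0, mean(depths) - 100, 0),
                half = c(half_tr, diff(depths) / 2, half_tr))
         })
}

#' @export
print.pg_simulation <- function(x, ...) {
  cat("<pg_simulation>", x$n_histories, "histories,",
      x$efficiency$n_coincidences, "S&A coincidences\n")
  cat(sprintf("  efficiency per emitted photon: %.3e +/- %.1e\n",
              x$efficiency$per_photon, x$efficiency$se_per_photon))
  if (x$weight < 1)
    cat(sprintf("  (direction-biased run, solid-angle weight %.4f)\n",
                x$weight))
  invisible(x)
}
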