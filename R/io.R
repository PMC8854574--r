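# Readers/writers for event lists, images and profiles, and run
# manifests. Event lists are columnar TSV with '#'-prefixed header
# metadata; numeric fields are written with 17 significant digits so
# write-then-read is the identity at full double precision.

EVENT_COLUMNS <- c("history", "module", "xs", "ys", "zs", "xa", "ya",
                   "za", "es_kev", "ea_kev", "t_ns", "truth_e_kev",
                   "truth_x", "truth_y", "truth_z", "full_energy",
                   "particle")

#' Write / read a coincidence event list (TSV)
#'
#' @param events coincidence data.frame (see [build_coincidences()];
#'   extra columns such as classifier scores are preserved).
#' @param path file path.
#' @param meta optional named list written as `# key: value` header
#'   lines (e.g. seed, scene hash, n_histories).
#' @export
write_events <- function(events, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  out <- events
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_events
#' @return `read_events` returns the event data.frame (header metadata
#'   in attribute `meta`).
#' @export
read_events <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  while (length(line <- readLines(con, n = 1)) && startsWith(line, "#"))
    hdr <- c(hdr, line)
  close(con)
  ev <- read.delim(path, comment.char = "#",
                   colClasses = c(particle = "character"))
  missing_cols <- setdiff(EVENT_COLUMNS, names(ev))
  if (length(missing_cols))
    stop("event file ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ev$full_energy <- as.logical(ev$full_energy)
  for (cl in setdiff(EVENT_COLUMNS,
                     c("history", "module", "full_energy", "particle")))
    ev[[cl]] <- as.numeric(ev[[cl]])
  ev$history <- as.integer(ev$history)
  ev$module <- as.integer(ev$module)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# *", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*: *", "", kv))
  }
  attr(ev, "meta") <- meta
  ev
}

#' Write / read a reconstructed image (text matrix + JSON sidecar)
#'
#' The pixel matrix goes to `<path>` as whitespace-separated text; the
#' plane pose, pitch and any extra metadata go to `<path>.json`.
#'
#' @param image a `pg_image`.
#' @param path file path for the matrix.
#' @param meta extra metadata stored in the sidecar (algorithm,
#'   parameters, event count, seed).
#' @export
write_image <- function(image, path, meta = list()) {
  write.table(format(image$values, digits = 10), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  side <- c(list(plane = image$plane, origin = image$origin,
                 u_axis = image$u_axis, v_axis = image$v_axis,
                 pitch = image$pitch, extent = image$extent,
                 pixels = length(image$uc)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- image_grid(plane = side$plane, origin = side$origin,
                     extent = side$extent, pixels = side$pixels)
  vals <- as.matrix(read.table(path))
  dimnames(vals) <- NULL
  grid$values <- vals
  attr(grid, "meta") <- side
  grid
}

#' Write a depth profile (two-column TSV + JSON metrics sidecar)
#'
#' @param profile a `depth_profile`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  write.table(data.frame(depth_mm = sprintf("%.17g", profile$mid),
                         value = sprintf("%.17g", profile$values)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  metrics <- tryCatch(falloff_metrics(profile), error = function(e) NULL)
  side <- list(provenance = profile$provenance, edges = profile$edges,
               metrics = metrics)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.delim(path)
  depth_profile(side$edges, tab$value, provenance = side$provenance)
}

#' Save / load a trained classifier
#'
#' Stores the binned model (bin edges, per-bin boosters as raw xgboost
#' blobs, standardization statistics and metadata) in a single RDS
#' archive.
#'
#' @param model a `pg_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(model, path) {
  ser <- model
  ser$bins <- lapply(model$bins, function(b) {
    if (!b$passthrough) b$booster <- xgboost::xgb.save.raw(b$booster)
    b
  })
  saveRDS(ser, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  ser <- readRDS(path)
  ser$bins <- lapply(ser$bins, function(b) {
    if (!b$passthrough) b$booster <- xgboost::xgb.load.raw(b$booster)
    b
  })
  ser
}

#' Run manifest
#'
#' Provenance record for a pipeline run: configuration hash, seed,
#' package version and per-stage outputs with checksums.
#'
#' @param config pipeline configuration list.
#' @param seed run seed.
#' @return list of class `pg_manifest`.
#' @export
run_manifest <- function(config, seed) {
  structure(list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("pgcam")),
    seed = seed,
    config_hash = config_hash(config),
    config = config,
    stages = list()),
    class = "pg_manifest")
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash (stays within double precision);
  # avoids a digest dependency
  bytes <- utf8ToInt(as.character(js))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

manifest_add_stage <- function(manifest, stage, files, elapsed_s) {
  manifest$stages[[stage]] <- list(
    files = lapply(files, function(f)
      list(path = f, size = file.info(f)$size,
           md5 = unname(tools::md5sum(f)))),
    elapsed_s = round(elapsed_s, 3))
  manifest
}

#' @export
print.pg_manifest <- function(x, ...) {
  cat("<pg_manifest>", x$config_hash, "seed", x$seed, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %5.1fs  %d file(s)\n", nm,
                x$stages[[nm]]$elapsed_s, length(x$stages[[nm]]$files)))
  invisible(x)
}
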