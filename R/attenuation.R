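#' Load a photon attenuation table
#'
#' Reads one of the attenuation tables shipped with the package (or a
#' user-supplied TSV in the same layout) into an `attenuation_table`
#' object. Tables give per-process linear attenuation coefficients
#' (photoelectric, incoherent/Compton, pair production) in units of
#' 1/mm on an ascending energy grid in keV.
#'
#' The shipped tables (`"lacl3"`, `"water"`) are synthetic: they are
#' computed from an analytic model (closed-form Klein-Nishina for the
#' incoherent part, a power-law photoelectric term calibrated on
#' standard lead values, and pair production scaled from standard water
#' totals by the Z-squared content of the material) rather than
#' transcribed from a tabulated compilation. Coherent scattering and
#' Doppler broadening are not included. See
#' `scripts/make_attenuation_tables.R` in the source tree.
#'
#' @param material `"lacl3"`, `"water"`, or a path to a TSV file with
#'   columns `E_keV`, `mu_photo`, `mu_compton`, `mu_pair` and a
#'   `# density_g_cm3:` header line.
#' @return an `attenuation_table`: list with `material`, `density`
#'   (g/cm^3), `energy` (keV, ascending) and `mu` (matrix with columns
#'   `photo`, `compton`, `pair`, per mm).
#' @export
load_attenuation <- function(material) {
  path <- if (file.exists(material)) {
    material
  } else {
    system.file("extdata", sprintf("attenuation_%s_synthetic.tsv", material),
                package = "pgcam", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path))
    stop("unknown attenuation material or missing file: ", material)
  hdr <- readLines(path, n = 12)
  dens_line <- grep("^# density_g_cm3:", hdr, value = TRUE)
  if (length(dens_line) != 1)
    stop("attenuation table lacks a '# density_g_cm3:' header: ", path)
  density <- as.numeric(sub("^# density_g_cm3:", "", dens_line))
  tab <- read.delim(path, comment.char = "#")
  need <- c("E_keV", "mu_photo", "mu_compton", "mu_pair")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("attenuation table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.unsorted(tab$E_keV, strictly = TRUE))
    stop("attenuation energy grid must be strictly ascending")
  if (any(tab[need[-1]] < 0)) stop("attenuation coefficients must be >= 0")
  if (any(tab$mu_pair[tab$E_keV < 1022] > 0))
    stop("pair-production coefficient must vanish below 1022 keV")
  structure(list(material = sub("\\.tsv$", "", basename(path)),
                 density = density,
                 energy = tab$E_keV,
                 mu = cbind(photo = tab$mu_photo,
                            compton = tab$mu_compton,
                            pair = tab$mu_pair)),
            class = "attenuation_table")
}

#' Interpolate attenuation coefficients at given energies
#'
#' Per-process linear attenuation coefficients at arbitrary energies
#' within the table range. Interpolation is log-log between grid nodes;
#' where a process vanishes at either bracketing node (e.g. pair
#' production near its 1022 keV threshold) linear interpolation on the
#' raw values is used instead.
#'
#' @param table an [`load_attenuation()`] object.
#' @param e energies (keV) within the table range.
#' @return data.frame with columns `mu_photo`, `mu_compton`, `mu_pair`
#'   and `mu_total` (per mm).
#' @export
lookup_attenuation <- function(table, e) {
  stopifnot(inherits(table, "attenuation_table"))
  if (any(e < min(table$energy) | e > max(table$energy)))
    stop("energy outside attenuation table range [",
         min(table$energy), ", ", max(table$energy), "] keV")
  interp_one <- function(mu) {
    pos <- mu > 0
    out <- numeric(length(e))
    if (all(pos)) {
      out <- exp(approx(log(table$energy), log(mu), xout = log(e))$y)
    } else {
      # mixed zero/positive nodes: piecewise choice per query point
      idx <- findInterval(e, table$energy, rightmost.closed = TRUE)
      lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(mu))
      both_pos <- pos[lo] & pos[hi]
      if (any(both_pos)) {
        out[both_pos] <- exp(approx(log(table$energy[pos]), log(mu[pos]),
                                    xout = log(e[both_pos]))$y)
      }
      if (any(!both_pos)) {
        out[!both_pos] <- approx(table$energy, mu, xout = e[!both_pos])$y
      }
    }
    out
  }
  res <- data.frame(mu_photo = interp_one(table$mu[, "photo"]),
                    mu_compton = interp_one(table$mu[, "compton"]),
                    mu_pair = interp_one(table$mu[, "pair"]))
  res$mu_total <- res$mu_photo + res$mu_compton + res$mu_pair
  res
}
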