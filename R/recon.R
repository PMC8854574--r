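# Compton image reconstruction on a 2-D plane: cone back-projection
# (BP), stochastic origin ensemble (SOE) and the analytical
# spherical-harmonics inversion (AA) with precomputed H_n tables.

#' Define a 2-D reconstruction image grid
#'
#' A square pixel grid on a plane given by an origin and two in-plane
#' unit axes. By convention the first (`u`) axis is the beam axis (+Y),
#' so image rows run along depth. The default 200 x 200 mm extent with
#' 200 x 200 pixels gives a 1 mm pitch.
#'
#' @param plane `"yz"` (plane x = 0; v axis = +Z, for modules facing
#'   the x surfaces) or `"xy"` (plane z = 0; v axis = +X), or `NULL`
#'   when `u_axis`/`v_axis` are given explicitly.
#' @param origin centre of the grid (lab mm).
#' @param extent side length (mm).
#' @param pixels pixels per side.
#' @param u_axis,v_axis explicit in-plane unit axes (override `plane`).
#' @return object of class `pg_image`: list with `origin`, `u_axis`,
#'   `v_axis`, `uc`, `vc` (pixel-centre in-plane coordinates), `pitch`
#'   and `values` (pixels x pixels matrix, u along rows).
#' @export
image_grid <- function(plane = "yz", origin = c(0, 0, 0), extent = 200,
                       pixels = 200, u_axis = NULL, v_axis = NULL) {
  if (is.null(u_axis)) {
    u_axis <- c(0, 1, 0)
    v_axis <- switch(plane, yz = c(0, 0, 1), xy = c(1, 0, 0),
                     stop("unknown plane: ", plane))
  }
  stopifnot(abs(sum(u_axis^2) - 1) < 1e-9, abs(sum(v_axis^2) - 1) < 1e-9,
            abs(sum(u_axis * v_axis)) < 1e-9, extent > 0, pixels >= 1)
  pitch <- extent / pixels
  cc <- (seq_len(pixels) - 0.5) * pitch - extent / 2
  structure(list(plane = if (is.null(plane)) "custom" else plane,
                 origin = origin, u_axis = u_axis, v_axis = v_axis,
                 uc = cc, vc = cc, pitch = pitch, extent = extent,
                 values = matrix(0, pixels, pixels)),
            class = "pg_image")
}

#' @export
print.pg_image <- function(x, ...) {
  cat("<pg_image>", length(x$uc), "x", length(x$vc), "pixels,",
      x$pitch, "mm pitch, plane", x$plane, "\n")
  cat("  total intensity:", sum(x$values), "\n")
  invisible(x)
}

#' Compton cone parameters from coincidence events
#'
#' For each event the cone apex is the scatter-plane hit, the axis
#' points from the absorber hit toward the scatter hit (back toward the
#' source), and the half-angle comes from the deposited energies via
#' [cos_from_energies()]. Events with kinematically invalid angles
#' (possible after resolution smearing) or coincident hit positions
#' are dropped.
#'
#' @param events coincidence data.frame.
#' @return data.frame of cones: `ax, ay, az` (apex mm), `tx, ty, tz`
#'   (unit axis), `omega` (rad), `weight`, `cos_omega`, `e` (add-back
#'   keV), `module`; attribute `n_invalid` counts dropped events.
#' @export
cones_from_events <- function(events) {
  if (nrow(events) == 0) {
    out <- data.frame(ax = numeric(0), ay = numeric(0), az = numeric(0),
                      tx = numeric(0), ty = numeric(0), tz = numeric(0),
                      omega = numeric(0), weight = numeric(0),
                      cos_omega = numeric(0), e = numeric(0),
                      module = integer(0))
    attr(out, "n_invalid") <- 0L
    return(out)
  }
  dx <- events$xs - events$xa
  dy <- events$ys - events$ya
  dz <- events$zs - events$za
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(nrm < 1e-9))
    stop("degenerate event: coincident scatter and absorber positions")
  ang <- cos_from_energies(events$es_kev, events$ea_kev)
  ok <- ang$valid
  out <- data.frame(ax = events$xs, ay = events$ys, az = events$zs,
                    tx = dx / nrm, ty = dy / nrm, tz = dz / nrm,
                    omega = ang$omega, weight = 1,
                    cos_omega = ang$cos_omega,
                    e = events$es_kev + events$ea_kev,
                    module = events$module)[ok, ]
  rownames(out) <- NULL
  attr(out, "n_invalid") <- sum(!ok)
  out
}

as_cones <- function(x) {
  if (all(c("ax", "tx", "omega") %in% names(x))) x else cones_from_events(x)
}

#' Cone back-projection reconstruction
#'
#' Each event's cone is projected onto the image plane: every pixel
#' receives weight `exp(-d^2 / (2 sigma^2))` where `d` is the angular
#' distance between the apex-to-pixel ray and the cone surface. Weights
#' are normalized to unit sum per event before accumulation, so each
#' event contributes equally. Events whose cone leaves less total
#' kernel mass on the grid than `min_total` (about one fully-hit pixel)
#' effectively miss the image plane and are dropped rather than
#' amplified by the normalization; their count is in attribute
#' `n_dropped`.
#'
#' @param events coincidence data.frame or cone data.frame from
#'   [cones_from_events()].
#' @param grid an [image_grid()].
#' @param sigma_deg Gaussian angular broadening (degrees), default 1.
#' @param min_total minimum summed kernel mass on the grid.
#' @param area_weight weight pixels by the solid angle they subtend at
#'   the cone apex (default `TRUE`), so the image is a density per unit
#'   plane area rather than per unit solid angle.
#' @return the grid with `values` filled; zero events give a zero image
#'   with a warning.
#' @export
backproject <- function(events, grid, sigma_deg = 1, min_total = 1,
                        area_weight = TRUE) {
  cones <- as_cones(events)
  if (nrow(cones) == 0) {
    warning("no valid events to back-project; returning zero image")
    return(grid)
  }
  m <- as.matrix(cones[, c("ax", "ay", "az", "tx", "ty", "tz",
                           "omega", "weight")])
  vals <- cpp_backproject(m, grid$origin, grid$u_axis, grid$v_axis,
                          grid$uc, grid$vc, sigma_deg * pi / 180,
                          min_total, area_weight)
  attr(grid, "n_dropped") <- attr(vals, "n_dropped")
  attr(vals, "n_dropped") <- NULL
  grid$values <- vals
  grid
}

#' Stochastic origin ensemble reconstruction
#'
#' Markov-chain reassignment of event origins: each event is first
#' placed uniformly on its cone band (pixels within `delta_theta_deg`
#' of the cone surface); each iteration then performs one proposed move
#' per event to a uniform pixel of its band, accepted with probability
#' `min(1, (lambda' + 1) / lambda)` where `lambda` is the occupancy of
#' the current pixel (including the moving event) and `lambda'` that of
#' the proposed pixel (excluding it). The image is the occupancy
#' averaged over the post-burn-in iterations (a single final snapshot
#' retains Markov-chain clumping noise; the running mean is the
#' ensemble's origin-density estimate). The final snapshot is kept in
#' attribute `final`.
#'
#' @inheritParams backproject
#' @param n_iter number of iterations (default 1000).
#' @param delta_theta_deg half-width of the cone band (degrees).
#' @param min_band minimum band size in pixels: events whose cone band
#'   on the grid is smaller (boundary-clipped cones that would act as
#'   spurious fixed point masses) are dropped.
#' @param burn_in iterations discarded before the occupancy average
#'   (default half of `n_iter`).
#' @return the grid with mean post-burn-in occupancy in `values`;
#'   attributes `initial` and `final` (ensemble snapshots) and
#'   `n_dropped` (events with an empty or sub-threshold band).
#' @export
soe_reconstruct <- function(events, grid, n_iter = 1000,
                            delta_theta_deg = 1.5, min_band = 25,
                            burn_in = n_iter %/% 2) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter)
  cones <- as_cones(events)
  if (nrow(cones) == 0) {
    warning("no valid events for SOE; returning zero image")
    return(grid)
  }
  m <- as.matrix(cones[, c("ax", "ay", "az", "tx", "ty", "tz",
                           "omega", "weight")])
  bands <- cpp_cone_bands(m, grid$origin, grid$u_axis, grid$v_axis,
                          grid$uc, grid$vc, delta_theta_deg * pi / 180)
  bands <- lapply(bands, function(b) if (length(b) < min_band) integer(0)
                  else b)
  res <- cpp_soe(bands, length(grid$uc) * length(grid$vc), n_iter,
                 burn_in)
  nu <- length(grid$uc)
  grid$values <- matrix(as.numeric(res$mean), nu)
  attr(grid, "initial") <- matrix(as.numeric(res$initial), nu)
  attr(grid, "final") <- matrix(as.numeric(res$final), nu)
  attr(grid, "n_dropped") <- res$n_dropped
  grid
}

#' Precompute the H_n angular moments of the Klein-Nishina cross-section
#'
#' The analytical inversion weights each Legendre order by
#' \deqn{H_n(E) = \int_{\cos\omega_{max}}^{\cos\omega_{min}}
#'   \sigma(E, \cos\omega)\, P_n^2(\cos\omega)\, d\cos\omega,}
#' evaluated by fixed-order Gauss-Legendre quadrature (order at least
#' `2 * n_max + 2`, exact for the polynomial part). The angular limits
#' are the minimum and maximum Compton scattering angles included in
#' the inversion.
#'
#' @param energies energy grid (keV), default 200-7000 keV at 50 keV
#'   pitch (H_n varies smoothly with energy; linear interpolation is
#'   used between nodes at reconstruction time).
#' @param n_max highest Legendre order (default 70).
#' @param omega_min,omega_max angular limits (rad): the minimum and
#'   maximum Compton scattering angles the two-plane system can
#'   register. The defaults (4 and 172 degrees) correspond to the
#'   100 keV per-crystal thresholds in the multi-MeV prompt-gamma
#'   range (a 4.4 MeV photon leaving 100 keV in the scatter plane
#'   scatters by about 4 degrees); narrowing them discards the
#'   forward-scattering bulk of high-energy events.
#' @param dcs differential cross-section `function(e, cos_omega)`;
#'   default [klein_nishina_dcs()]. (A constant function is a useful
#'   test hook: with `dcs = function(e, x) 1` over the full angular
#'   range, `H_n = 2 / (2n + 1)` by Legendre orthogonality.)
#' @param cache_dir optional directory: the table is stored/retrieved
#'   keyed by the parameters, so repeated reconstructions skip the
#'   quadrature.
#' @return object of class `hn_table`: list with `energy`, `n_max`,
#'   `omega_min`, `omega_max` and `values` (length(energies) x
#'   (n_max + 1) matrix).
#' @export
precompute_hn <- function(energies = seq(200, 7000, by = 50), n_max = 70,
                          omega_min = 4 * pi / 180,
                          omega_max = 172 * pi / 180,
                          dcs = klein_nishina_dcs, cache_dir = NULL) {
  stopifnot(omega_min > 0, omega_min < omega_max, omega_max < pi,
            n_max >= 0)
  key <- NULL
  if (!is.null(cache_dir)) {
    key <- file.path(cache_dir, sprintf(
      "hn_%d_%.6f_%.6f_%d_%.0f_%.0f.rds", n_max, omega_min, omega_max,
      length(energies), min(energies), max(energies)))
    if (file.exists(key)) return(readRDS(key))
  }
  lo <- cos(omega_max); hi <- cos(omega_min)
  order_q <- max(2 * n_max + 2, 64)
  gl <- pracma::gaussLegendre(order_q, lo, hi)
  pn2 <- legendre_table(n_max, gl$x)^2           # nodes x (n_max + 1)
  vals <- matrix(0, length(energies), n_max + 1)
  for (i in seq_along(energies)) {
    sig <- dcs(energies[i], gl$x)
    vals[i, ] <- colSums((gl$w * sig) * pn2)
  }
  out <- structure(list(energy = energies, n_max = n_max,
                        omega_min = omega_min, omega_max = omega_max,
                        values = vals),
                   class = "hn_table")
  if (!is.null(key)) {
    dir.create(dirname(key), showWarnings = FALSE, recursive = TRUE)
    saveRDS(out, key)
  }
  out
}

#' Analytical spherical-harmonics reconstruction
#'
#' Series inversion of the cone-projection operator: the image value at
#' a pixel `s` is
#' \deqn{f(s) = \sum_{events} \sum_{n=0}^{N_{max}}
#'   \frac{2n+1}{4\pi H_n(E_\gamma)} P_n(\cos\omega)\,
#'   P_n(\hat{s}\cdot\hat{t}),}
#' where `t` is the event's cone axis and `s` the unit vector from the
#' cone apex to the pixel. `H_n` is interpolated linearly on the energy
#' grid of the precomputed table. Raw (possibly negative) pixel values
#' are retained; use `clip_image()` for display or profile metrics.
#'
#' @inheritParams backproject
#' @param hn an [precompute_hn()] table; computed on the fly (with
#'   default parameters and `n_max`) when omitted.
#' @param n_max highest Legendre order used (must not exceed the
#'   table's).
#' @param area_weight multiply each pixel's series value by the solid
#'   angle the pixel subtends at the event apex (default `TRUE`),
#'   converting the direction-space inversion into an emission density
#'   per unit image area; set `FALSE` for the bare angular series.
#' @return the grid with raw values; attribute `n_skipped` counts
#'   events outside the table's energy range or angular limits.
#' @export
aa_reconstruct <- function(events, grid, hn = NULL, n_max = 70,
                           area_weight = TRUE) {
  cones <- as_cones(events)
  if (is.null(hn)) hn <- precompute_hn(n_max = n_max)
  stopifnot(inherits(hn, "hn_table"), n_max <= hn$n_max)
  ok <- cones$e >= min(hn$energy) & cones$e <= max(hn$energy) &
    cones$omega >= hn$omega_min & cones$omega <= hn$omega_max
  n_skipped <- sum(!ok)
  cones <- cones[ok, ]
  if (nrow(cones) == 0) {
    warning("no usable events for the analytical reconstruction")
    attr(grid, "n_skipped") <- n_skipped
    return(grid)
  }
  # per-event coefficients: (2n+1) / (4 pi H_n(E)) * P_n(cos omega)
  hmat <- apply(hn$values[, seq_len(n_max + 1), drop = FALSE], 2,
                function(col) approx(hn$energy, col, xout = cones$e)$y)
  hmat <- matrix(hmat, nrow = nrow(cones))
  pn <- legendre_table(n_max, cones$cos_omega)
  ncoef <- (2 * seq(0, n_max) + 1) / (4 * pi)
  coeff <- t(pn / hmat * rep(ncoef, each = nrow(cones)) * cones$weight)
  m <- as.matrix(cones[, c("ax", "ay", "az", "tx", "ty", "tz",
                           "omega", "weight")])
  grid$values <- cpp_aa(m, coeff, grid$origin, grid$u_axis, grid$v_axis,
                        grid$uc, grid$vc, area_weight)
  attr(grid, "n_skipped") <- n_skipped
  grid
}

#' Clip negative image values to zero
#' @param grid a `pg_image`.
#' @return the grid with `values = pmax(values, 0)`.
#' @export
clip_image <- function(grid) {
  grid$values <- pmax(grid$values, 0)
  grid
}

#' Image argmax position
#'
#' In-plane coordinates (and lab position) of the maximal pixel; ties
#' resolved by the lowest linear index.
#'
#' @param grid a `pg_image` with values.
#' @return list with `u`, `v` (in-plane mm) and `lab` (length-3).
#' @export
image_argmax <- function(grid) {
  q <- which.max(grid$values)
  i <- (q - 1) %% length(grid$uc) + 1
  j <- (q - 1) %/% length(grid$uc) + 1
  list(u = grid$uc[i], v = grid$vc[j],
       lab = grid$origin + grid$uc[i] * grid$u_axis +
         grid$vc[j] * grid$v_axis)
}

# image plane ("yz" or "xy") for a module, from its outward axis
module_plane <- function(module) {
  w <- module$rotation[, 3]
  if (abs(w[1]) > 0.99) "yz" else if (abs(w[3]) > 0.99) "xy"
  else stop("module pose has no standard image plane")
}

#' Reconstruct a full event set, combining all modules
#'
#' Routes each module's events to its image plane (the plane containing
#' the beam axis and parallel to the module's detection planes: x = 0
#' for modules facing the x surfaces, z = 0 for those facing the z
#' surfaces), reconstructs each plane with the requested algorithm, and
#' returns the per-plane images. Planes shared by two modules are
#' reconstructed from their pooled events.
#'
#' @param events coincidence data.frame.
#' @param scene the `pg_scene`.
#' @param algo `"bp"`, `"soe"` or `"aa"`.
#' @param pixels image pixels per side.
#' @param extent image extent (mm).
#' @param ... algorithm parameters passed on ([backproject()]:
#'   `sigma_deg`; [soe_reconstruct()]: `n_iter`, `delta_theta_deg`;
#'   [aa_reconstruct()]: `hn`, `n_max`).
#' @return named list of `pg_image` (by plane), class `pg_recon`.
#' @export
reconstruct <- function(events, scene, algo = c("bp", "soe", "aa"),
                        pixels = 200, extent = 200, ...) {
  algo <- match.arg(algo)
  planes <- vapply(scene$modules, module_plane, "")
  ev_plane <- planes[match(events$module,
                           vapply(scene$modules, `[[`, 0L, "module_id"))]
  out <- list()
  for (pl in unique(planes)) {
    ev <- events[ev_plane == pl, ]
    if (nrow(ev) == 0) next
    grid <- image_grid(pl, pixels = pixels, extent = extent)
    out[[pl]] <- switch(algo,
                        bp = backproject(ev, grid, ...),
                        soe = soe_reconstruct(ev, grid, ...),
                        aa = aa_reconstruct(ev, grid, ...))
  }
  structure(out, class = "pg_recon", algo = algo)
}
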