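#' Klein-Nishina differential cross-section (relative units)
#'
#' Differential cross-section for Compton scattering of an unpolarized
#' photon, in units of the classical electron radius squared
#' (`r_e^2 = 1`), so that the forward-scattering value is exactly 1 for
#' every energy:
#' \deqn{d\sigma/d\Omega = \tfrac{1}{2} P^2 (P + 1/P - \sin^2\omega),
#'       \quad P = 1/(1 + \alpha(1 - \cos\omega)),}
#' with \eqn{\alpha = E_\gamma / m_e c^2}.
#'
#' @param e_gamma incident photon energy (keV), positive; recycled
#'   against `cos_omega`.
#' @param cos_omega cosine of the scattering angle, in `[-1, 1]`.
#' @return numeric vector of relative differential cross-sections (> 0).
#' @examples
#' klein_nishina_dcs(1000, 1)    # forward limit, exactly 1
#' klein_nishina_dcs(511, -1)    # backscatter at alpha = 1: 10/54
#' @export
klein_nishina_dcs <- function(e_gamma, cos_omega) {
  if (any(!is.finite(e_gamma)) || any(e_gamma <= 0))
    stop("e_gamma must be positive and finite")
  if (any(!is.finite(cos_omega)) || any(cos_omega < -1) || any(cos_omega > 1))
    stop("cos_omega must lie in [-1, 1]")
  alpha <- e_gamma / MEC2_KEV
  p <- 1 / (1 + alpha * (1 - cos_omega))
  sin2 <- 1 - cos_omega^2
  0.5 * p^2 * (p + 1 / p - sin2)
}

#' Total Klein-Nishina cross-section (closed form)
#'
#' Integral of [klein_nishina_dcs()] over the full solid angle, in
#' `r_e^2` units. Approaches the Thomson value `8*pi/3` as the energy
#' goes to zero.
#'
#' @param e_gamma photon energy (keV).
#' @return total cross-section in `r_e^2` units.
#' @export
klein_nishina_total <- function(e_gamma) {
  a <- e_gamma / MEC2_KEV
  # series expansion below ~1 keV where the closed form loses precision
  out <- ifelse(
    a < 2e-3,
    (8 * pi / 3) * (1 - 2 * a + 26 / 5 * a^2),
    2 * pi * ((1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
                log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2)
  )
  out
}

#' Sample Compton scattering angles from the Klein-Nishina distribution
#'
#' Draws `n` values of `cos(omega)` distributed proportionally to
#' [klein_nishina_dcs()] at the given energy, by rejection sampling
#' against a uniform envelope (the relative cross-section never exceeds
#' its forward value of 1). Uses R's global random number generator.
#'
#' @param e_gamma photon energy (keV), scalar.
#' @param n number of samples.
#' @return list with components `cos_omega` and `omega` (rad).
#' @export
sample_compton_angle <- function(e_gamma, n = 1) {
  stopifnot(length(e_gamma) == 1, e_gamma > 0, n >= 0)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2 * (n - length(out)), 16)
    x <- runif(m, -1, 1)
    keep <- runif(m) < klein_nishina_dcs(e_gamma, x)
    out <- c(out, x[keep])
  }
  cw <- out[seq_len(n)]
  list(cos_omega = cw, omega = acos(cw))
}

#' Energy of a Compton-scattered photon
#'
#' Compton scattering law
#' \eqn{E' = E / (1 + \alpha (1 - \cos\omega))}.
#'
#' @param e_gamma incident photon energy (keV).
#' @param cos_omega cosine of the scattering angle.
#' @return scattered photon energy (keV), in `(0, e_gamma]`.
#' @export
scattered_energy <- function(e_gamma, cos_omega) {
  stopifnot(all(e_gamma > 0))
  e_gamma / (1 + (e_gamma / MEC2_KEV) * (1 - cos_omega))
}

#' Compton scattering angle from the two-plane energy deposits
#'
#' For a coincidence with scatter-plane deposit `e_s` and absorber-plane
#' deposit `e_a`, and assuming full absorption (add-back energy
#' `e_s + e_a` equals the incident energy), the Compton scattering angle
#' satisfies
#' \deqn{\cos\omega = 1 - m_e c^2 \left(\frac{1}{E_a} -
#'       \frac{1}{E_s + E_a}\right).}
#' Finite energy resolution can push the value below -1
#' (kinematically forbidden); such events are flagged invalid and must
#' be discarded by callers.
#'
#' @param e_s scatter-plane deposit (keV), `>= 0`.
#' @param e_a absorber-plane deposit (keV), `> 0`.
#' @return data.frame with columns `cos_omega`, `omega` (rad, `NA` when
#'   invalid) and logical `valid`.
#' @export
cos_from_energies <- function(e_s, e_a) {
  stopifnot(all(e_s >= 0), all(e_a > 0))
  cw <- 1 - MEC2_KEV * (1 / e_a - 1 / (e_s + e_a))
  valid <- cw >= -1 & cw <= 1
  data.frame(cos_omega = cw,
             omega = ifelse(valid, acos(pmin(1, pmax(-1, cw))), NA_real_),
             valid = valid)
}

#' Legendre polynomial values by the Bonnet recurrence
#'
#' @param n polynomial order (non-negative integer, scalar).
#' @param x evaluation points in `[-1, 1]`.
#' @return numeric vector `P_n(x)`.
#' @seealso [legendre_table()] for all orders `0..n` at once.
#' @export
legendre_eval <- function(n, x) {
  stopifnot(length(n) == 1, n >= 0, n == floor(n))
  stopifnot(all(x >= -1 & x <= 1))
  legendre_table(n, x)[, n + 1]
}

#' Table of Legendre polynomials P_0..P_nmax
#'
#' @param n_max highest order.
#' @param x evaluation points.
#' @return matrix with `length(x)` rows and `n_max + 1` columns; column
#'   `k` holds `P_{k-1}(x)`.
#' @export
legendre_table <- function(n_max, x) {
  out <- matrix(0, length(x), n_max + 1)
  out[, 1] <- 1
  if (n_max >= 1) out[, 2] <- x
  if (n_max >= 2) {
    for (k in 2:n_max) {
      out[, k + 1] <- ((2 * k - 1) * x * out[, k] - (k - 1) * out[, k - 1]) / k
    }
  }
  out
}
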