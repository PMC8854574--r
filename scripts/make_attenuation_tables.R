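#!/usr/bin/env Rscript
# Regenerates the synthetic photon attenuation tables shipped under
# inst/extdata/. The tables are computed from an analytic per-element
# model (see R/attenuation.R for the provenance notes):
#   - incoherent (Compton): exact closed-form Klein-Nishina total
#     cross-section times the electron density of the material;
#   - photoelectric: per-atom power law C * Z^4.5 * (E/100 keV)^-2.53,
#     calibrated against the standard photoelectric mass attenuation of
#     lead at 100 and 500 keV (5.2 and 0.086 cm^2/g);
#   - pair production: residual of standard water total attenuation
#     anchors after subtracting the Klein-Nishina part, scaled to other
#     materials by sum(Z_i^2)/M relative to water.
# Coherent (Rayleigh) scattering and Doppler broadening are omitted.
# Run from the repository root: Rscript scripts/make_attenuation_tables.R

mec2 <- 511.0
avogadro <- 6.02214076e23

kn_total <- function(e_kev) { # r_e^2 units
  a <- e_kev / mec2
  2 * pi * ((1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
              log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2)
}
re2_cm2 <- (2.8179403262e-13)^2 # classical electron radius squared, cm^2

# photoelectric per atom, cm^2 (power law through the two lead anchors)
pe_atom <- function(z, e_kev) {
  c0 <- (5.2 * 207.2 / avogadro) / 82^4.5
  c0 * z^4.5 * (e_kev / 100)^-2.53
}

# standard water total mass attenuation anchors (cm^2/g, coherent excluded)
water_total <- data.frame(
  e = c(1250, 1500, 2000, 3000, 4000, 5000, 6000, 7000, 8000, 10000),
  mu = c(0.06323, 0.05754, 0.04942, 0.03969, 0.03403, 0.03031, 0.02770,
         0.02577, 0.02429, 0.02219))

materials <- list(
  water = list(elements = data.frame(z = c(1, 8), a = c(1.008, 15.999),
                                     n = c(2, 1)),
               density = 1.0),
  lacl3 = list(elements = data.frame(z = c(57, 17), a = c(138.905, 35.453),
                                     n = c(1, 3)),
               density = 3.85))

grid <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150, 200, 300, 400, 500,
          600, 800, 1000, 1022, 1100, 1250, 1500, 2000, 3000, 4000, 5000,
          6000, 7000, 8000)

# water pair-production residual per sum(Z^2)/M unit, at the anchors
water_el <- materials$water$elements
ne_water <- avogadro * sum(water_el$n * water_el$z) / sum(water_el$n * water_el$a)
z2m_water <- sum(water_el$n * water_el$z^2) / sum(water_el$n * water_el$a)
kappa_anchor <- pmax(0, water_total$mu -
                        ne_water * kn_total(water_total$e) * re2_cm2 -
                        sapply(water_total$e, function(e) {
                          sum(water_el$n * pe_atom(water_el$z, e)) /
                            sum(water_el$n * water_el$a) * avogadro
                        }))
kappa_unit <- function(e_kev) { # per sum(Z^2)/M, cm^2/g
  out <- numeric(length(e_kev))
  above <- e_kev > 1022
  if (any(above)) {
    # interpolate linearly in E between 1022 keV (zero) and the anchors
    out[above] <- approx(c(1022, water_total$e), c(0, kappa_anchor),
                         xout = pmin(e_kev[above], 10000), rule = 2)$y
  }
  out / z2m_water
}

for (name in names(materials)) {
  mat <- materials[[name]]
  el <- mat$elements
  m_molar <- sum(el$n * el$a)
  ne <- avogadro * sum(el$n * el$z) / m_molar          # electrons per gram
  natoms <- avogadro * el$n / m_molar                  # atoms of each element per gram
  mu_compton <- ne * kn_total(grid) * re2_cm2          # cm^2/g
  mu_photo <- sapply(grid, function(e) sum(natoms * pe_atom(el$z, e)))
  z2m <- sum(el$n * el$z^2) / m_molar
  mu_pair <- z2m * kappa_unit(grid)
  tab <- data.frame(E_keV = grid,
                    mu_photo = mu_photo * mat$density / 10,   # per mm
                    mu_compton = mu_compton * mat$density / 10,
                    mu_pair = mu_pair * mat$density / 10)
  path <- file.path("inst", "extdata",
                    sprintf("attenuation_%s_synthetic.tsv", name))
  con <- file(path, "w")
  writeLines(c(
    sprintf("# synthetic photon attenuation table: %s", name),
    sprintf("# density_g_cm3: %.3f", mat$density),
    "# columns: E_keV, mu_photo, mu_compton, mu_pair (linear coefficients, per mm)",
    "# computed analytically (Klein-Nishina closed form; power-law photoelectric",
    "# calibrated on lead anchors; pair production Z^2-scaled from standard water",
    "# totals); coherent scattering omitted. See scripts/make_attenuation_tables.R"),
    con)
  write.table(format(tab, digits = 6, scientific = TRUE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  message("wrote ", path)
}
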