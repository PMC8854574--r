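# Klein-Nishina cross-section, Compton kinematics, Legendre recurrence
# and attenuation lookup.

test_that("Klein-Nishina differential cross-section matches hand values", {
  # forward scattering equals the classical limit for any energy
  expect_equal(klein_nishina_dcs(c(100, 511, 1000, 6100), 1),
               rep(1, 4))
  # backscatter at alpha = 1: P = 1/3, value = (1/18) * (1/3 + 3) = 10/54
  expect_equal(klein_nishina_dcs(511, -1), 10 / 54, tolerance = 1e-12)
  expect_error(klein_nishina_dcs(511, 1.5), "cos_omega")
  expect_error(klein_nishina_dcs(-5, 0), "e_gamma")
})

test_that("KN solid-angle integral matches the closed-form total", {
  for (e in c(100, 511, 1000, 4400, 6100)) {
    num <- 2 * pi * stats::integrate(function(x) klein_nishina_dcs(e, x),
                                     -1, 1, rel.tol = 1e-10)$value
    expect_equal(num, klein_nishina_total(e), tolerance = 1e-4)
  }
  # Thomson limit at vanishing energy
  expect_equal(klein_nishina_total(1e-4), 8 * pi / 3, tolerance = 1e-5)
})

test_that("Compton angle sampling follows the KN distribution", {
  set.seed(1)
  s <- sample_compton_angle(1000, 1e5)
  # chi-square against the normalized analytic pdf
  brk <- seq(-1, 1, length.out = 41)
  counts <- hist(s$cos_omega, breaks = brk, plot = FALSE)$counts
  dens <- vapply(seq_len(40), function(i)
    stats::integrate(function(x) klein_nishina_dcs(1000, x),
                     brk[i], brk[i + 1])$value, 0)
  expected <- dens / sum(dens) * 1e5
  chi2 <- sum((counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 39))
  expect_gt(chi2, qchisq(0.001, df = 39))
  # Thomson shape is symmetric in cos at vanishing energy
  set.seed(2)
  s0 <- sample_compton_angle(0.01, 2e4)
  expect_lt(abs(mean(s0$cos_omega)), 0.02)
  # fixed seed reproduces the sequence
  set.seed(7); a <- sample_compton_angle(500, 100)
  set.seed(7); b <- sample_compton_angle(500, 100)
  expect_identical(a, b)
})

test_that("Compton scattering law and its energy inversion round-trip", {
  expect_equal(scattered_energy(1000, 1), 1000)
  expect_equal(scattered_energy(511, -1), 511 / 3, tolerance = 1e-12)
  expect_equal(scattered_energy(1000, 0), 1000 / (1 + 1000 / 511),
               tolerance = 1e-12)
  expect_equal(cos_from_energies(0 + 1e-12, 800)$cos_omega, 1,
               tolerance = 1e-9)
  expect_equal(cos_from_energies(500, 500)$cos_omega, 1 - 511 / 1000)
  # kinematically forbidden partition is flagged invalid
  bad <- cos_from_energies(5000, 200)
  expect_false(bad$valid)
  expect_true(is.na(bad$omega))
  # round trip: sampled angle -> energies -> angle, exactly
  set.seed(3)
  for (e in c(600, 2300, 4400, 6100)) {
    cw <- sample_compton_angle(e, 50)$cos_omega
    ep <- scattered_energy(e, cw)
    back <- cos_from_energies(e - ep, ep)
    expect_true(all(back$valid))
    expect_equal(back$cos_omega, cw, tolerance = 1e-9)
  }
})

test_that("Legendre recurrence reproduces known polynomials", {
  x <- seq(-1, 1, by = 0.1)
  expect_equal(legendre_eval(0, x), rep(1, length(x)))
  expect_equal(legendre_eval(1, x), x)
  expect_equal(legendre_eval(3, 0.5), -0.4375)
  expect_true(all(abs(legendre_table(70, x)) <= 1 + 1e-12))
})

test_that("Legendre polynomials are orthogonal up to order 70", {
  gl <- pracma::gaussLegendre(160, -1, 1)
  p <- legendre_table(70, gl$x)
  gram <- t(p * gl$w) %*% p
  expected <- diag(2 / (2 * seq(0, 70) + 1))
  expect_lt(max(abs(gram - expected)), 1e-10)
})

test_that("attenuation tables load with valid structure", {
  for (mat in c("lacl3", "water")) {
    at <- load_attenuation(mat)
    expect_s3_class(at, "attenuation_table")
    expect_false(is.unsorted(at$energy, strictly = TRUE))
    expect_true(all(at$mu >= 0))
    expect_true(all(at$mu[at$energy < 1022, "pair"] == 0))
  }
  expect_error(load_attenuation("unobtainium"), "unknown")
})

test_that("attenuation lookup interpolates and range-checks", {
  at <- load_attenuation("water")
  # grid nodes are reproduced exactly
  i <- match(1000, at$energy)
  node <- lookup_attenuation(at, 1000)
  expect_equal(node$mu_compton, unname(at$mu[i, "compton"]))
  expect_equal(node$mu_photo, unname(at$mu[i, "photo"]))
  # interpolated value is bracketed by the neighboring nodes
  mid <- lookup_attenuation(at, 800)
  lo <- at$mu[match(600, at$energy), "compton"]
  hi <- at$mu[match(1000, at$energy), "compton"]
  expect_true(mid$mu_compton > min(lo, hi) && mid$mu_compton < max(lo, hi))
  expect_error(lookup_attenuation(at, 9000), "range")
  expect_error(lookup_attenuation(at, 1), "range")
})

test_that("transmission through a crystal slab matches the closed form", {
  # 1 MeV photons through the 15 mm scatter crystal, head on
  scene <- point_scene()
  at <- load_attenuation("lacl3")
  mu <- lookup_attenuation(at, 1000)$mu_total
  n <- 4e4
  em <- data.frame(x = 0, y = 0, z = 0, dx = 1, dy = 0, dz = 0,
                   e = 1000, t = 0)[rep(1, n), ]
  set.seed(4)
  hits <- transport_photon(scene, em)
  # fraction of histories whose FIRST interaction is in the S crystal
  # (a photon may cross S, interact in A and backscatter into S; that
  # is not a first-pass S interaction)
  s_ids <- scene$crystals$crystal_id[scene$crystals$role == "scatter"]
  first <- hits[order(hits$history, hits$t), ]
  first <- first[!duplicated(first$history), ]
  n_int <- sum(first$crystal_id %in% s_ids)
  p_expected <- 1 - exp(-mu * 15)
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(n_int / n - p_expected), 3 * se + 2e-3)
})
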