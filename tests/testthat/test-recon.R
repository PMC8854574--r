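# Cone construction and the three image-reconstruction algorithms.

test_that("cones are built from hits and energies as specified", {
  ev <- data.frame(history = 1L, module = 1L,
                   xs = 0, ys = 0, zs = 0, xa = 0, ya = 0, za = 30,
                   es_kev = 500, ea_kev = 500, t_ns = 0,
                   truth_e_kev = 1000, truth_x = 0, truth_y = 0,
                   truth_z = 0, full_energy = TRUE, particle = "gamma")
  cones <- cones_from_events(ev)
  expect_equal(c(cones$tx, cones$ty, cones$tz), c(0, 0, -1))
  expect_equal(cones$cos_omega, 0.489)
  expect_equal(cones$e, 1000)
  # coincident hit positions are degenerate
  ev2 <- ev; ev2$xa <- 0; ev2$za <- 0
  expect_error(cones_from_events(ev2), "degenerate")
  # invalid kinematics are dropped and counted
  ev3 <- ev; ev3$es_kev <- 5000; ev3$ea_kev <- 200
  c3 <- cones_from_events(ev3)
  expect_equal(nrow(c3), 0)
  expect_equal(attr(c3, "n_invalid"), 1L)
})

test_that("back-projection localizes a point source within 3 mm", {
  fx <- fx_point_events()
  ev <- fx$events[fx$events$full_energy, ]
  ev <- ev[seq_len(min(2000, nrow(ev))), ]
  grid <- image_grid("yz", pixels = 100)
  img <- backproject(ev, grid)
  am <- image_argmax(img)
  expect_lt(sqrt(am$u^2 + am$v^2), 3)
  # the maximal-weight band of a single noiseless cone passes the source
  one <- build_scene(list(layout = "point"))
  cone1 <- data.frame(ax = 55, ay = 0, az = 0, tx = -1, ty = 0, tz = 0,
                      omega = 20 * pi / 180, weight = 1,
                      cos_omega = cos(20 * pi / 180), e = 1000,
                      module = 1L)
  img1 <- backproject(cone1, image_grid("yz", pixels = 100))
  # ring radius on the plane x=0: 55 * tan(20 deg) from (y,z) = (0,0)
  am1 <- image_argmax(img1)
  r <- sqrt(am1$u^2 + am1$v^2)
  expect_equal(r, 55 * tan(20 * pi / 180), tolerance = 0.15)
  expect_warning(backproject(ev[0, ], grid), "no valid events")
})

test_that("SOE conserves occupancy and concentrates a point source", {
  fx <- fx_point_events()
  ev <- fx$events[fx$events$full_energy, ]
  ev <- ev[seq_len(min(2000, nrow(ev))), ]
  grid <- image_grid("yz", pixels = 100)
  set.seed(51)
  img <- soe_reconstruct(ev, grid, n_iter = 600)
  n_used <- nrow(cones_from_events(ev)) - attr(img, "n_dropped")
  # occupancy equals the number of active events, in the initial
  # ensemble, the iteration-averaged image and the final snapshot
  expect_equal(sum(attr(img, "initial")), n_used)
  expect_equal(sum(img$values), n_used, tolerance = 1e-9)
  expect_equal(sum(attr(img, "final")), n_used)
  am <- image_argmax(img)
  expect_lt(sqrt(am$u^2 + am$v^2), 3)
  # the stationary ensemble is more concentrated than the initial one
  # (snapshot vs snapshot; the iteration-averaged image is smoother by
  # construction)
  entropy <- function(v) {
    p <- v[v > 0] / sum(v)
    -sum(p * log(p))
  }
  expect_lt(entropy(attr(img, "final")), entropy(attr(img, "initial")))
})

test_that("SOE with flat proposals over the whole grid stays uniform", {
  # uniform density: acceptance ratio ~ 1 everywhere, no concentration
  n_ev <- 400; n_px <- 400
  bands <- rep(list(seq_len(n_px)), n_ev)
  set.seed(52)
  res <- pgcam:::cpp_soe(bands, n_px, 200, 100)
  expect_equal(sum(res$mean), n_ev, tolerance = 1e-9)
  # mean occupancy per pixel ~ n_ev / n_px, no pixel runs away
  expect_lt(max(res$mean), 10 * n_ev / n_px)
})

test_that("H_n reduces to Legendre orthogonality for a flat kernel", {
  hn <- precompute_hn(energies = 1000, n_max = 40,
                      omega_min = 1e-9, omega_max = pi - 1e-9,
                      dcs = function(e, x) rep(1, length(x)))
  expect_equal(as.numeric(hn$values), 2 / (2 * seq(0, 40) + 1),
               tolerance = 1e-9)
})

test_that("H_0 matches an adaptive-quadrature oracle", {
  hn <- precompute_hn(energies = 1000, n_max = 70)
  oracle <- stats::integrate(function(x) klein_nishina_dcs(1000, x),
                             cos(hn$omega_max), cos(hn$omega_min),
                             rel.tol = 1e-10)$value
  expect_equal(hn$values[1, 1], oracle, tolerance = 1e-6)
  # higher orders against the same independent quadrature
  for (n in c(10, 35, 70)) {
    on <- stats::integrate(function(x)
      klein_nishina_dcs(1000, x) * legendre_eval(n, x)^2,
      cos(hn$omega_max), cos(hn$omega_min), rel.tol = 1e-10)$value
    expect_equal(hn$values[1, n + 1], on, tolerance = 1e-6)
  }
})

test_that("H_n tables regenerate bit-identically and cache to disk", {
  a <- precompute_hn(energies = c(500, 1000), n_max = 20)
  b <- precompute_hn(energies = c(500, 1000), n_max = 20)
  expect_identical(a, b)
  cd <- tempfile("hncache")
  c1 <- precompute_hn(energies = c(500, 1000), n_max = 20, cache_dir = cd)
  expect_true(length(list.files(cd)) == 1)
  c2 <- precompute_hn(energies = c(500, 1000), n_max = 20, cache_dir = cd)
  expect_identical(c1$values, c2$values)
})

test_that("analytical inversion with N_max = 0 is flat", {
  ev <- data.frame(ax = 55, ay = 0, az = 0, tx = -1, ty = 0, tz = 0,
                   omega = 0.6, weight = 1, cos_omega = cos(0.6),
                   e = 1000, module = 1L)
  hn <- precompute_hn(energies = c(900, 1100), n_max = 0)
  img <- aa_reconstruct(ev, image_grid("yz", pixels = 40), hn = hn,
                        n_max = 0, area_weight = FALSE)
  expect_lt(diff(range(img$values)), 1e-12)
})

test_that("analytical reconstruction localizes a point source within 2 mm", {
  fx <- fx_point_events()
  ev <- fx$events[fx$events$full_energy, ]
  grid <- image_grid("yz", pixels = 100)
  hn <- fixture("hn_default", precompute_hn())
  img <- aa_reconstruct(ev, grid, hn = hn, n_max = 70)
  am <- image_argmax(img)
  expect_lt(sqrt(am$u^2 + am$v^2), 2)
})

test_that("vectorized AA equals a naive per-event double loop", {
  fx <- fx_point_events()
  ev <- fx$events[seq_len(100), ]
  grid <- image_grid("yz", pixels = 50)
  hn <- fixture("hn_default", precompute_hn())
  n_max <- 30
  img <- aa_reconstruct(ev, grid, hn = hn, n_max = n_max,
                        area_weight = FALSE)
  cones <- cones_from_events(ev)
  cones <- cones[cones$omega >= hn$omega_min & cones$omega <= hn$omega_max, ]
  naive <- matrix(0, 50, 50)
  for (e in seq_len(nrow(cones))) {
    hvals <- vapply(seq_len(n_max + 1), function(k)
      approx(hn$energy, hn$values[, k], xout = cones$e[e])$y, 0)
    pncw <- legendre_table(n_max, cones$cos_omega[e])[1, ]
    for (i in 1:50) for (j in 1:50) {
      pix <- grid$origin + grid$uc[i] * grid$u_axis + grid$vc[j] * grid$v_axis
      s <- pix - c(cones$ax[e], cones$ay[e], cones$az[e])
      s <- s / sqrt(sum(s^2))
      x <- sum(s * c(cones$tx[e], cones$ty[e], cones$tz[e]))
      pnx <- legendre_table(n_max, min(1, max(-1, x)))[1, ]
      naive[i, j] <- naive[i, j] +
        sum((2 * (0:n_max) + 1) / (4 * pi * hvals) * pncw * pnx)
    }
  }
  expect_equal(img$values, naive, tolerance = 1e-9)
})

test_that("larger N_max never widens the point-spread function", {
  fx <- fx_point_events()
  ev <- fx$events[fx$events$full_energy, ]
  grid <- image_grid("yz", pixels = 100)
  hn <- fixture("hn_default", precompute_hn())
  fwhm_of <- function(nm) {
    img <- clip_image(aa_reconstruct(ev, grid, hn = hn, n_max = nm))
    pr <- rowSums(img$values)
    pr <- pr - min(pr)
    half <- max(pr) / 2
    # contiguous above-half run containing the peak (sidelobes excluded)
    imax <- which.max(pr)
    lo <- imax; while (lo > 1 && pr[lo - 1] >= half) lo <- lo - 1
    hi <- imax; while (hi < length(pr) && pr[hi + 1] >= half) hi <- hi + 1
    (hi - lo) * grid$pitch
  }
  w <- vapply(c(10, 30, 70), fwhm_of, 0)
  expect_true(all(diff(w) <= grid$pitch))  # non-increasing up to one pixel
})

test_that("all three reconstructions are translation-covariant", {
  fx <- fx_point_events()
  ev <- fx$events[fx$events$full_energy, ]
  ev <- ev[seq_len(min(1500, nrow(ev))), ]
  shift <- c(0, 10, 0)
  ev2 <- ev
  for (cc in c("xs", "xa")) ev2[[cc]] <- ev2[[cc]] + shift[1]
  for (cc in c("ys", "ya")) ev2[[cc]] <- ev2[[cc]] + shift[2]
  for (cc in c("zs", "za")) ev2[[cc]] <- ev2[[cc]] + shift[3]
  grid <- image_grid("yz", pixels = 100)
  hn <- fixture("hn_default", precompute_hn())
  for (algo in c("bp", "soe", "aa")) {
    rec <- function(e) {
      set.seed(53)
      switch(algo,
             bp = backproject(e, grid),
             soe = soe_reconstruct(e, grid, n_iter = 300),
             aa = aa_reconstruct(e, grid, hn = hn, n_max = 40))
    }
    a1 <- image_argmax(rec(ev)); a2 <- image_argmax(rec(ev2))
    expect_lt(abs((a2$u - a1$u) - shift[2]), grid$pitch + 1e-9)
    expect_lt(abs(a2$v - a1$v), grid$pitch + 1e-9)
  }
})
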