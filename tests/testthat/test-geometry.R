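# Scene construction, poses, ray-box intersection and solid angles.

test_that("default phantom scene has four modules and twenty crystals", {
  scene <- build_scene()
  expect_equal(length(scene$modules), 4)
  expect_equal(nrow(scene$crystals), 20)
  expect_equal(sum(scene$crystals$role == "scatter"), 4)
  expect_equal(sum(scene$crystals$role == "absorber"), 16)
  # scatter faces 100 mm from the beam axis (50 mm air + half phantom)
  s1 <- scene$crystals[scene$crystals$role == "scatter" &
                         scene$crystals$module == 1, ]
  expect_equal(s1$cx - s1$hx, 100)
  # crystal dimensions
  expect_equal(unname(unlist(s1[c("hx", "hy", "hz")])), c(7.5, 25, 25))
  a1 <- scene$crystals[scene$crystals$role == "absorber" &
                         scene$crystals$module == 1, ][1, ]
  expect_equal(sort(unname(unlist(a1[c("hx", "hy", "hz")]))),
               c(12.5, 25, 25))
})

test_that("single-module point configuration puts the S face at standoff", {
  scene <- point_scene(standoff = 50)
  expect_equal(length(scene$modules), 1)
  s <- scene$crystals[scene$crystals$role == "scatter", ]
  expect_equal(s$cx - s$hx, 50)
  expect_null(scene$phantom)
})

test_that("focal distance is a pure pass-through", {
  for (fd in c(5, 15, 30)) {
    scene <- point_scene(f_d = fd)
    s <- scene$crystals[scene$crystals$role == "scatter", ]
    a <- scene$crystals[scene$crystals$role == "absorber", ][1, ]
    gap <- (a$cx - a$hx) - (s$cx + s$hx)
    expect_equal(gap, fd)
  }
  expect_error(build_scene(list(layout = "point", f_d = -1)))
})

test_that("module poses must be axis-aligned proper rotations", {
  th <- 30 * pi / 180
  tilted <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_error(build_module(1, tilted, c(100, 0, 0)), "axis permutation")
  improper <- diag(c(1, 1, -1))
  expect_error(build_module(1, improper, c(100, 0, 0)), "rotation")
})

test_that("overlapping volumes are rejected", {
  scene <- build_scene()
  scene$crystals$cx[1] <- 0  # push a crystal into the phantom
  expect_error(pgcam:::check_scene_overlaps(scene), "overlap")
})

test_that("ray-box intersection matches an independent bisection oracle", {
  box <- list(center = c(10, -5, 3), half = c(7.5, 25, 12.5))
  inside <- function(p) all(abs(p - box$center) <= box$half)
  bisect <- function(o, d, t_in, t_out, target_inside) {
    for (k in 1:60) {
      mid <- (t_in + t_out) / 2
      if (inside(o + mid * d) == target_inside) t_out <- mid else t_in <- mid
    }
    (t_in + t_out) / 2
  }
  # axis-aligned chord through the centre of a 15 mm-thick crystal
  hit <- ray_path_in_box(c(-100, -5, 3), c(1, 0, 0),
                         list(center = c(10, -5, 3), half = c(7.5, 25, 12.5)))
  expect_equal(unname(hit[2] - hit[1]), 15)
  # ray parallel to a face, outside the box
  expect_null(ray_path_in_box(c(0, -50, 3), c(1, 0, 0), box))
  expect_error(ray_path_in_box(c(0, 0, 0), c(0, 0, 0), box), "norm")
  set.seed(11)
  n_checked <- 0
  for (i in 1:200) {
    o <- runif(3, -60, 60)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    res <- ray_path_in_box(o, d, box)
    # coarse scan to bracket the crossing for the oracle
    ts <- seq(-200, 200, by = 0.05)
    ins <- vapply(ts, function(t) inside(o + t * d), TRUE)
    if (is.null(res)) {
      expect_false(any(ins))
      next
    }
    first <- which(ins)[1]
    last <- tail(which(ins), 1)
    if (is.na(first) || first == 1) next  # grazing below scan resolution
    t_entry <- bisect(o, d, ts[first - 1], ts[first], TRUE)
    t_exit <- bisect(o, d, ts[last], ts[last + 1], FALSE)
    expect_equal(unname(res[1]), t_entry, tolerance = 1e-6)
    expect_equal(unname(res[2]), t_exit, tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 20)
})

test_that("scene configuration round-trips through YAML exactly", {
  scene <- build_scene(list(f_d = 30, standoff = 40))
  path <- tempfile(fileext = ".yaml")
  write_scene_config(scene, path)
  rebuilt <- build_scene(read_scene_config(path))
  expect_identical(scene$crystals, rebuilt$crystals)
  expect_identical(scene$config, rebuilt$config)
})

test_that("S-crystal solid angle matches a surface-integral oracle", {
  scene <- build_scene()
  s <- scene$crystals[scene$crystals$role == "scatter" &
                        scene$crystals$module == 1, ]
  # Monte Carlo: fraction of isotropic rays from the origin hitting the box
  set.seed(12)
  n <- 3e6
  cw <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  sw <- sqrt(1 - cw^2)
  dirs <- cbind(sw * cos(phi), sw * sin(phi), cw)
  # the front face is the silhouette seen from the origin
  tfront <- (s$cx - s$hx) / dirs[, 1]
  hitmc <- tfront > 0 &
    abs(tfront * dirs[, 2] - s$cy) <= s$hy &
    abs(tfront * dirs[, 3] - s$cz) <= s$hz
  omega_mc <- 4 * pi * mean(hitmc)
  # numeric surface integral of cos(theta) / r^2 over the front face
  f <- function(y, z) {
    r2 <- (s$cx - s$hx)^2 + y^2 + z^2
    (s$cx - s$hx) / r2^1.5
  }
  gy <- seq(s$cy - s$hy, s$cy + s$hy, length.out = 201)
  gz <- seq(s$cz - s$hz, s$cz + s$hz, length.out = 201)
  vals <- outer(gy, gz, f)
  wy <- rep(1, 201); wy[c(1, 201)] <- 0.5
  omega_int <- sum(vals * outer(wy, wy)) * diff(gy)[1] * diff(gz)[1]
  expect_equal(omega_mc, omega_int, tolerance = 0.01)
})
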