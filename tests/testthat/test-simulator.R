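# Photon transport, detector response and coincidence building.

test_that("photons aimed away from all material leave no hits", {
  scene <- point_scene()  # module toward +x
  em <- data.frame(x = 0, y = 0, z = 0, dx = -1, dy = 0, dz = 0,
                   e = 1000, t = 0)[rep(1, 500), ]
  set.seed(31)
  hits <- transport_photon(scene, em)
  expect_equal(nrow(hits), 0)
})

test_that("a purely photoelectric crystal absorbs in one full-energy hit", {
  # synthetic material: photoelectric only, very high coefficient
  tab <- data.frame(E_keV = c(10, 8000), mu_photo = c(50, 50),
                    mu_compton = 0, mu_pair = 0)
  path <- file.path(tempdir(), "attenuation_blackbody_synthetic.tsv")
  writeLines("# density_g_cm3: 1.0", path)
  suppressWarnings(write.table(tab, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  scene <- build_scene(list(layout = "point", crystal_material = path))
  em <- data.frame(x = 0, y = 0, z = 0, dx = 1, dy = 0, dz = 0,
                   e = 1000, t = 0)[rep(1, 200), ]
  set.seed(32)
  hits <- transport_photon(scene, em)
  expect_equal(nrow(hits), 200)          # every photon absorbed
  expect_true(all(hits$e == 1000))       # full energy in one deposit
  expect_true(all(hits$role == "scatter"))
})

test_that("energy is conserved per history up to the deposit floor", {
  fx <- fx_ideal_point()
  tot <- tapply(fx$hits$e, fx$hits$history, sum)
  expect_true(all(tot <= 1000 + 1e-6))
  # full-energy flag matches the 1 keV criterion on module deposits
  ev <- fx$events
  expect_true(all(abs(ev$es_kev[ev$full_energy] + ev$ea_kev[ev$full_energy]
                      - 1000) <= 1))
  expect_true(all(ev$es_kev[!ev$full_energy] + ev$ea_kev[!ev$full_energy]
                  < 1000 - 0.5))
})

test_that("energy resolution model matches its anchor and scaling", {
  resp <- response_model()
  expect_equal(energy_fwhm(resp, 500), 22.5)
  expect_equal(energy_fwhm(resp, 1000), 22.5 * sqrt(2))
  # smearing a fixed 1000 keV deposit reproduces the model FWHM
  scene <- point_scene()
  s_id <- scene$crystals$crystal_id[scene$crystals$role == "scatter"][1]
  hits <- data.frame(history = seq_len(2e4), crystal_id = s_id,
                     module = 1L, role = "scatter",
                     x = 55, y = 0, z = 0, e = 1000, t = 0)
  set.seed(33)
  sm <- apply_response(hits, scene, response_model(position_fwhm = 0,
                                                   time_fwhm = 0))
  fwhm <- sd(sm$e) * 2 * sqrt(2 * log(2))
  expect_equal(fwhm, 22.5 * sqrt(2), tolerance = 0.05)
  expect_equal(mean(sm$e), 1000, tolerance = 0.01)
})

test_that("an all-zero response model is the identity", {
  fx <- fx_ideal_point()
  raw <- fx$hits[fx$hits$history %in% fx$hits$history[1:50], ]
  sm <- apply_response(raw, fx$scene, response_model(0, 500, 0, 0, 0))
  # merged per crystal; single-deposit crystals keep exact values
  one <- raw[!duplicated(raw[c("history", "crystal_id")]) &
               !duplicated(raw[c("history", "crystal_id")], fromLast = TRUE), ]
  merged <- merge(one, sm, by = c("history", "crystal_id"))
  expect_equal(merged$e.x, merged$e.y, tolerance = 1e-12)
  expect_equal(merged$x.x, merged$x.y, tolerance = 1e-12)
})

test_that("sub-threshold crystals are dropped and cannot seed events", {
  scene <- point_scene()
  s_id <- scene$crystals$crystal_id[scene$crystals$role == "scatter"][1]
  a_id <- scene$crystals$crystal_id[scene$crystals$role == "absorber"][1]
  a_row <- scene$crystals[scene$crystals$crystal_id == a_id, ]
  hits <- data.frame(
    history = c(1L, 1L, 2L),
    crystal_id = c(s_id, a_id, s_id),
    module = 1L, role = c("scatter", "absorber", "scatter"),
    x = c(55, a_row$cx, 55), y = 0, z = 0,
    e = c(95, 700, 300), t = 0)
  sm <- apply_response(hits, scene, response_model(0, 500, 0, 100, 0))
  expect_equal(nrow(sm), 2)          # the 95 keV crystal is gone
  expect_true(all(sm$e >= 100))
  em <- data.frame(x = 0, y = 0, z = 0, dx = 1, dy = 0, dz = 0,
                   e = 1000, t = 0)[rep(1, 2), ]
  ev <- build_coincidences(sm, scene, em)
  expect_equal(nrow(ev), 0)  # S-only histories form no coincidence
})

test_that("coincidences require S and A in the same module and history", {
  fx <- fx_ideal_point()
  ev <- fx$events
  expect_true(all(ev$es_kev >= 100 & ev$ea_kev >= 100))
  # absorber position lies inside the absorber plane
  expect_true(all(ev$xa >= 50 + 15))
  # crafted event: S 300 + A 700 from a 1 MeV photon is full-energy
  scene <- fx$scene
  s_id <- scene$crystals$crystal_id[scene$crystals$role == "scatter"][1]
  a_id <- scene$crystals$crystal_id[scene$crystals$role == "absorber"][1]
  a_row <- scene$crystals[scene$crystals$crystal_id == a_id, ]
  sm <- apply_response(data.frame(
    history = 1L, crystal_id = c(s_id, a_id), module = 1L,
    role = c("scatter", "absorber"), x = c(55, a_row$cx),
    y = c(0, a_row$cy), z = c(0, a_row$cz), e = c(300, 700), t = 0),
    scene, response_model(0, 500, 0, 100, 0))
  em <- data.frame(x = 0, y = 0, z = 0, dx = 1, dy = 0, dz = 0,
                   e = 1000, t = 0)
  ev1 <- build_coincidences(sm, scene, em)
  expect_equal(nrow(ev1), 1)
  expect_true(ev1$full_energy)
  expect_equal(ev1$ea_kev, 700)
})

test_that("run_simulation counts and errors behave at the boundaries", {
  scene <- point_scene()
  src <- source_model("point", position = c(0, 0, 0), energy = 1000)
  expect_error(run_simulation(scene, 0, source = src))
  set.seed(34)
  sim1 <- run_simulation(scene, 1, source = src)
  expect_true(sim1$efficiency$n_coincidences %in% c(0, 1))
  # per-proton efficiency is the per-photon value scaled by the yield
  fx <- fx_point_events()
  expect_equal(fx$sim$efficiency$per_proton,
               fx$sim$efficiency$per_photon * 0.081)
})

test_that("far-field efficiency scales with the inverse square distance", {
  src <- source_model("point", position = c(0, 0, 0), energy = 1000)
  effs <- vapply(c(200, 400), function(d) {
    scene <- point_scene(standoff = d)
    set.seed(35)
    run_simulation(scene, 3e5, source = src,
                   direction_bias = TRUE)$efficiency$per_photon
  }, 0)
  expect_equal(effs[1] / effs[2], 4, tolerance = 0.35)
})

test_that("kinematic angle from energies matches the geometric cone angle", {
  # zero-smearing single-Compton full-energy events
  fx <- fx_ideal_point()
  hits <- fx$hits
  s_ids <- fx$scene$crystals$crystal_id[fx$scene$crystals$role == "scatter"]
  n_s <- tapply(hits$crystal_id %in% s_ids, hits$history, sum)
  n_all <- tapply(hits$history, hits$history, length)
  # exactly one scatter-plane interaction and one absorber deposit,
  # with the scatter interaction FIRST (a photon can also traverse S,
  # Compton-scatter in A and photo-absorb back in S; the forward
  # kinematics do not apply to that sequence)
  first <- hits[order(hits$history, hits$t), ]
  first <- first[!duplicated(first$history), ]
  s_first <- first$history[first$crystal_id %in% s_ids]
  clean <- intersect(as.integer(names(n_s)[n_s == 1 & n_all == 2]),
                     s_first)
  ev <- fx$events
  ev <- ev[ev$full_energy & ev$history %in% clean, ]
  expect_gt(nrow(ev), 50)
  # geometric angle: emission -> S vs S -> A
  v1 <- cbind(ev$xs - ev$truth_x, ev$ys - ev$truth_y, ev$zs - ev$truth_z)
  v2 <- cbind(ev$xa - ev$xs, ev$ya - ev$ys, ev$za - ev$zs)
  cg <- rowSums(v1 * v2) /
    sqrt(rowSums(v1^2) * rowSums(v2^2))
  ce <- cos_from_energies(ev$es_kev, ev$ea_kev)
  ok <- ce$valid
  dang <- abs(acos(pmin(1, pmax(-1, cg[ok]))) - ce$omega[ok]) * 180 / pi
  expect_lt(median(dang), 0.5)
  expect_gt(mean(dang < 0.5), 0.95)
})
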