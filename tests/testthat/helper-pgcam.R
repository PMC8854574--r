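# Shared fixtures, computed lazily and cached for the whole test run.
# All randomness is seeded here; heavy simulations are sized for the
# statistics the assertions need, not more.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# single default module facing +x with the source at the origin
point_scene <- function(f_d = 15, standoff = 50) {
  build_scene(list(layout = "point", f_d = f_d, standoff = standoff))
}

ideal_response <- function() response_model(0, 500, 0, 100, 0)

# point-source events seen by one module (realistic response)
fx_point_events <- function() fixture("point_events", {
  set.seed(101)
  scene <- point_scene()
  src <- source_model("point", position = c(0, 0, 0), energy = 1000)
  sim <- run_simulation(scene, 3e5, source = src)
  list(scene = scene, events = sim$events, sim = sim)
})

# zero-resolution point-source run (thresholds kept), with raw hits
fx_ideal_point <- function() fixture("ideal_point", {
  set.seed(102)
  scene <- point_scene()
  src <- source_model("point", position = c(0, 0, 0), energy = 1000)
  em <- sample_emission(src, 4e5)
  hits <- transport_photon(scene, em)
  smeared <- apply_response(hits, scene, ideal_response())
  events <- build_coincidences(smeared, scene, em)
  list(scene = scene, emissions = em, hits = hits, events = events)
})

# labelled training events + a trained (reduced-size) classifier
fx_ml <- function() fixture("ml", {
  set.seed(104)
  tr <- simulate_training_events(4e7)
  ev <- tr$events
  set.seed(105)
  idx <- sample.int(nrow(ev), floor(nrow(ev) * 0.3))
  set.seed(106)
  model <- suppressWarnings(train_classifier(
    ev[-idx, ], tr$scene, n_bins = 7, min_per_class = 300,
    n_per_class = 5000))
  list(scene = tr$scene, train = ev[-idx, ], test = ev[idx, ],
       model = model)
})

# small phantom run for selection / spectrum tests
fx_phantom_small <- function() fixture("phantom_small", {
  set.seed(103)
  scene <- build_scene(list(layout = "phantom", f_d = 15))
  src <- default_pg_source()
  sim <- run_simulation(scene, 4e6, source = src, direction_bias = TRUE,
                        chunk_size = 2e6)
  list(scene = scene, source = src, events = sim$events, sim = sim)
})
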