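# Machine-learning identification of full-energy coincidences.
#
# A gradient-boosted tree classifier (binary logistic) is trained
# independently in add-back energy bins on class-balanced samples of
# full-energy vs partial-deposit events, using the ten features a real
# two-plane measurement provides: the two 3-D interaction positions in
# module-local coordinates, the two deposited energies, the Compton
# angle computed from the energies, and the Klein-Nishina probability
# of that angle at the add-back energy.

FEATURE_NAMES <- c("us", "vs", "ws", "ua", "va", "wa",
                   "es", "ea", "cos_omega", "kn_prob")

#' Extract classifier features from coincidence events
#'
#' Positions are expressed in module-local coordinates (u, v in the
#' detection plane, w along the module axis) so that the four modules
#' share one feature distribution. The Compton angle feature is present
#' only for kinematically valid events; invalid events are flagged and
#' are excluded from training and scored 0 when classifying.
#'
#' @param events coincidence data.frame.
#' @param scene the `pg_scene` (module poses).
#' @return data.frame of the 10 features plus `addback` (keV) and
#'   logical `valid`.
#' @export
extract_features <- function(events, scene) {
  n <- nrow(events)
  mod_ids <- vapply(scene$modules, `[[`, 0L, "module_id")
  us <- matrix(0, n, 3); ua <- matrix(0, n, 3)
  for (m in scene$modules) {
    sel <- events$module == m$module_id
    if (!any(sel)) next
    rot_t <- t(m$rotation)
    ps <- t(rot_t %*% (t(as.matrix(events[sel, c("xs", "ys", "zs")])) -
                         m$translation))
    pa <- t(rot_t %*% (t(as.matrix(events[sel, c("xa", "ya", "za")])) -
                         m$translation))
    us[sel, ] <- ps; ua[sel, ] <- pa
  }
  ang <- cos_from_energies(events$es_kev, events$ea_kev)
  addback <- events$es_kev + events$ea_kev
  knp <- rep(NA_real_, n)
  if (any(ang$valid))
    knp[ang$valid] <- klein_nishina_dcs(addback[ang$valid],
                                        ang$cos_omega[ang$valid])
  out <- data.frame(us = us[, 1], vs = us[, 2], ws = us[, 3],
                    ua = ua[, 1], va = ua[, 2], wa = ua[, 3],
                    es = events$es_kev, ea = events$ea_kev,
                    cos_omega = ifelse(ang$valid, ang$cos_omega, NA_real_),
                    kn_prob = knp,
                    addback = addback, valid = ang$valid)
  rownames(out) <- NULL
  out
}

#' Simulate a classifier training set
#'
#' Replicates the dedicated training geometry: a single module with the
#' scatter face 50 mm from a 200 x 200 x 200 mm emission volume in
#' which gamma rays of uniform energy (200-7000 keV by default) start
#' from uniform random positions. Returns truth-labelled coincidences.
#'
#' @param n_histories emitted photons (direction-biased toward the
#'   module; the label distribution is unaffected).
#' @param f_d focal distance (mm).
#' @param e_range emitted energy range (keV).
#' @param response a [response_model()].
#' @return list with `events` (coincidence data.frame) and `scene`.
#' @export
simulate_training_events <- function(n_histories, f_d = 15,
                                     e_range = c(200, 7000),
                                     response = response_model()) {
  scene <- build_scene(list(layout = "point", f_d = f_d, standoff = 50))
  src <- source_model("uniform_box", e_range = e_range,
                      bbox = list(center = c(-150, 0, 0),
                                  half = c(100, 100, 100)))
  sim <- run_simulation(scene, n_histories, source = src,
                        response = response, direction_bias = TRUE)
  list(events = sim$events, scene = scene)
}

#' Train the binned full-energy classifier
#'
#' Splits the labelled events into `n_bins` add-back energy intervals
#' and trains one gradient-boosted tree scorer per bin on
#' class-balanced samples (the majority class is downsampled to the
#' minority count, capped at `n_per_class`). Features are standardized
#' per bin with training-set statistics stored in the model. Bins with
#' fewer than `min_per_class` events in either class fall back to
#' pass-through with a warning.
#'
#' @param events truth-labelled coincidence data.frame (needs
#'   `full_energy`).
#' @param scene the `pg_scene` the events come from.
#' @param n_bins number of add-back bins (default 14).
#' @param e_range binned add-back range (keV), default 200-7000.
#' @param n_per_class per-bin per-class training cap (default 5e4).
#' @param min_per_class minimum per class per bin (default 2000).
#' @param threshold decision threshold on the score (default 0.5).
#' @param nrounds,max_depth,gamma boosted-tree parameters (defaults
#'   140 trees of depth 4, gamma 0.1).
#' @return object of class `pg_classifier`.
#' @export
train_classifier <- function(events, scene, n_bins = 14,
                             e_range = c(200, 7000), n_per_class = 5e4,
                             min_per_class = 2000, threshold = 0.5,
                             nrounds = 140, max_depth = 4, gamma = 0.1) {
  stopifnot(is.logical(events$full_energy))
  edges <- seq(e_range[1], e_range[2], length.out = n_bins + 1)
  feats <- extract_features(events, scene)
  usable <- feats$valid
  bin_of <- findInterval(feats$addback, edges, rightmost.closed = TRUE)
  bins <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    sel <- which(usable & bin_of == b)
    lab <- events$full_energy[sel]
    n_fe <- sum(lab); n_nfe <- sum(!lab)
    n_take <- min(n_fe, n_nfe, n_per_class)
    if (n_take < min_per_class) {
      warning(sprintf(
        "bin %d (%.0f-%.0f keV): %d/%d events per class < %d; pass-through",
        b, edges[b], edges[b + 1], n_fe, n_nfe, min_per_class))
      bins[[b]] <- list(passthrough = TRUE, n_fe = n_fe, n_nfe = n_nfe)
      next
    }
    take <- c(sample(sel[lab], n_take), sample(sel[!lab], n_take))
    x <- as.matrix(feats[take, FEATURE_NAMES])
    ctr <- colMeans(x); scl <- pmax(apply(x, 2, stats::sd), 1e-9)
    xs <- scale(x, ctr, scl)
    dtrain <- xgboost::xgb.DMatrix(
      xs, label = as.numeric(events$full_energy[take]), nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    gamma = gamma, nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0)
    bins[[b]] <- list(passthrough = FALSE, booster = booster,
                      center = ctr, scale = scl,
                      n_fe = n_fe, n_nfe = n_nfe, n_train = 2 * n_take)
  }
  structure(list(edges = edges, bins = bins, threshold = threshold,
                 params = list(nrounds = nrounds, max_depth = max_depth,
                               gamma = gamma)),
            class = "pg_classifier")
}

#' @export
print.pg_classifier <- function(x, ...) {
  n_active <- sum(!vapply(x$bins, `[[`, TRUE, "passthrough"))
  cat("<pg_classifier>", length(x$bins), "add-back bins (",
      n_active, "trained,", length(x$bins) - n_active, "pass-through ),",
      "threshold", x$threshold, "\n")
  invisible(x)
}

#' Score and filter events with the full-energy classifier
#'
#' Each event is scored by the scorer of its add-back bin (a
#' probability in `[0, 1]`) and accepted when the score reaches the
#' decision threshold. Events outside the binned range are rejected
#' with reason `"out_of_range"`; kinematically invalid events are
#' scored 0 and rejected with reason `"invalid_kinematics"`;
#' pass-through bins accept everything. Event order is preserved.
#'
#' @param events coincidence data.frame.
#' @param model a [train_classifier()] model.
#' @param scene the `pg_scene`.
#' @param threshold override the model's decision threshold.
#' @return the events with added columns `score`, `accepted` and
#'   `reason`.
#' @export
apply_classifier <- function(events, model, scene,
                             threshold = model$threshold) {
  stopifnot(inherits(model, "pg_classifier"))
  feats <- extract_features(events, scene)
  n <- nrow(events)
  score <- rep(0, n)
  reason <- rep("scored", n)
  bin_of <- findInterval(feats$addback, model$edges,
                         rightmost.closed = TRUE)
  out_range <- bin_of < 1 | bin_of > length(model$bins)
  reason[out_range] <- "out_of_range"
  reason[!feats$valid] <- "invalid_kinematics"
  for (b in seq_along(model$bins)) {
    sel <- which(!out_range & feats$valid & bin_of == b)
    if (!length(sel)) next
    bm <- model$bins[[b]]
    if (bm$passthrough) {
      score[sel] <- 1
      reason[sel] <- "passthrough"
    } else {
      xs <- scale(as.matrix(feats[sel, FEATURE_NAMES]), bm$center, bm$scale)
      score[sel] <- predict(bm$booster,
                            xgboost::xgb.DMatrix(xs, nthread = 1))
    }
  }
  events$score <- score
  events$accepted <- score >= threshold & !out_range & feats$valid
  events$reason <- reason
  events
}

#' Classifier performance and purity gain per energy bin
#'
#' Confusion-matrix summary per add-back bin: sensitivity (fraction of
#' full-energy events kept), false-positive rate (fraction of partial
#' events wrongly kept) and the purity gain factor
#' `purity(after selection) / purity(before selection)`, the figure of
#' merit for peak-to-background enhancement.
#'
#' @param events scored events from [apply_classifier()] with truth
#'   `full_energy`.
#' @param model the classifier (for the bin edges).
#' @return data.frame per bin: `e_lo`, `e_hi`, `n`, `purity_before`,
#'   `purity_after`, `gain`, `sensitivity`, `fpr` (NA where undefined,
#'   e.g. an empty selection).
#' @export
evaluate_gain <- function(events, model) {
  edges <- model$edges
  bin_of <- findInterval(events$es_kev + events$ea_kev, edges,
                         rightmost.closed = TRUE)
  out <- data.frame(e_lo = head(edges, -1), e_hi = tail(edges, -1))
  stats_list <- lapply(seq_len(nrow(out)), function(b) {
    sel <- bin_of == b
    n <- sum(sel)
    if (n == 0)
      return(c(n = 0, purity_before = NA, purity_after = NA, gain = NA,
               sensitivity = NA, fpr = NA))
    fe <- events$full_energy[sel]
    acc <- events$accepted[sel]
    before <- mean(fe)
    after <- if (any(acc)) mean(fe[acc]) else NA
    c(n = n, purity_before = before, purity_after = after,
      gain = if (before > 0 && !is.na(after)) after / before else NA,
      sensitivity = if (any(fe)) sum(acc & fe) / sum(fe) else NA,
      fpr = if (any(!fe)) sum(acc & !fe) / sum(!fe) else NA)
  })
  cbind(out, do.call(rbind, stats_list))
}
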