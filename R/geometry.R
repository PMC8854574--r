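# Scene description: water phantom plus two-plane Compton modules.
#
# Lab frame convention: right-handed, proton beam along +Y, origin at the
# phantom centre. Reported "depth" is Y + 100 mm, so that the image frame
# is centred at a depth of 100 mm. Module frames use axes (u, v, w) with
# w pointing from the scatter plane into the detector (away from the
# beam) and the origin at the centre of the scatter-crystal front face.

S_CRYSTAL_HALF <- c(25, 25, 7.5)   # 50 x 50 x 15 mm^3
A_CRYSTAL_HALF <- c(25, 25, 12.5)  # 50 x 50 x 25 mm^3

#' Build one two-plane Compton detector module
#'
#' A module holds one monolithic scatter (S) crystal of 50 x 50 x 15 mm^3
#' and a 2 x 2 array of absorber (A) crystals of 50 x 50 x 25 mm^3 each,
#' separated by the focal distance `f_d` (gap between the S back face and
#' the A front faces). The pose maps module coordinates to the lab frame.
#'
#' @param module_id integer id.
#' @param rotation 3 x 3 rotation matrix, columns are the lab directions
#'   of the module axes (u, v, w). Must be a signed axis permutation
#'   (crystal boxes stay axis-aligned in the lab frame).
#' @param translation lab position (mm) of the centre of the scatter
#'   crystal front face.
#' @param f_d focal distance (mm), the adjustable S-A gap; default 15.
#' @return list with `module_id`, `f_d`, `rotation`, `translation` and a
#'   `crystals` data.frame (lab-frame axis-aligned boxes).
#' @export
build_module <- function(module_id, rotation, translation, f_d = 15) {
  module_id <- as.integer(module_id)
  stopifnot(f_d > 0, all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("module rotation must be a proper rotation matrix")
  if (any(abs(abs(rotation) - round(abs(rotation))) > 1e-9))
    stop("module rotation must be a signed axis permutation ",
         "(crystals are modelled as axis-aligned boxes)")
  centers_local <- rbind(
    c(0, 0, S_CRYSTAL_HALF[3]),
    cbind(expand.grid(u = c(-25, 25), v = c(-25, 25)),
          w = 15 + f_d + A_CRYSTAL_HALF[3]))
  centers_local <- as.matrix(centers_local)
  halves_local <- rbind(S_CRYSTAL_HALF,
                        matrix(A_CRYSTAL_HALF, 4, 3, byrow = TRUE))
  centers_lab <- t(rotation %*% t(centers_local) + translation)
  halves_lab <- t(abs(rotation) %*% t(halves_local))
  crystals <- data.frame(
    module = module_id,
    role = c("scatter", rep("absorber", 4)),
    cx = centers_lab[, 1], cy = centers_lab[, 2], cz = centers_lab[, 3],
    hx = halves_lab[, 1], hy = halves_lab[, 2], hz = halves_lab[, 3])
  list(module_id = module_id, f_d = f_d, rotation = rotation,
       translation = translation, crystals = crystals)
}

# rotation with local w mapped to `w_lab` and local u mapped to `u_lab`
module_rotation <- function(w_lab, u_lab) {
  w <- w_lab / sqrt(sum(w_lab^2))
  u <- u_lab / sqrt(sum(u_lab^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

#' Build a simulation scene
#'
#' Constructs the phantom-plus-detectors geometry. Two layouts are
#' provided:
#' \describe{
#'   \item{`"phantom"`}{(default) a 100 x 200 x 100 mm^3 water phantom
#'     with the beam along +Y, surrounded by four modules facing the
#'     four lateral (x and z) surfaces at `standoff` mm from them, i.e.
#'     scatter planes 100 mm from the beam axis for the default sizes.}
#'   \item{`"point"`}{a single module at `standoff` mm from the origin
#'     (no phantom), for point-source efficiency studies.}
#' }
#'
#' @param config list of options: `layout` ("phantom" or "point"),
#'   `f_d` (focal distance, mm), `standoff` (air gap from phantom
#'   surface / source, mm), `n_modules` (phantom layout, 1-4),
#'   `phantom_half` (half extents c(hx, hy, hz), mm),
#'   `phantom_material`, `source` (passed to [source_model()] as-is).
#' @return object of class `pg_scene`: list with `config`, `phantom`
#'   (or NULL), `modules`, `crystals` (data.frame with global
#'   `crystal_id`) and `source`.
#' @export
build_scene <- function(config = list()) {
  defaults <- list(layout = "phantom", f_d = 15, standoff = 50,
                   n_modules = 4, phantom_half = c(50, 100, 50),
                   phantom_material = "water", crystal_material = "lacl3")
  cfg <- modifyList(defaults, config)
  stopifnot(cfg$f_d > 0, cfg$standoff > 0)
  if (cfg$layout == "phantom") {
    phantom <- list(center = c(0, 0, 0), half = cfg$phantom_half,
                    material = cfg$phantom_material)
    face <- list(
      list(w = c(1, 0, 0), d = cfg$phantom_half[1]),
      list(w = c(-1, 0, 0), d = cfg$phantom_half[1]),
      list(w = c(0, 0, 1), d = cfg$phantom_half[3]),
      list(w = c(0, 0, -1), d = cfg$phantom_half[3]))
    if (cfg$n_modules < 1 || cfg$n_modules > 4)
      stop("phantom layout supports 1 to 4 modules")
    modules <- lapply(seq_len(cfg$n_modules), function(i) {
      f <- face[[i]]
      build_module(i, module_rotation(f$w, c(0, 1, 0)),
                   f$w * (f$d + cfg$standoff), f_d = cfg$f_d)
    })
  } else if (cfg$layout == "point") {
    phantom <- NULL
    modules <- list(build_module(
      1, module_rotation(c(1, 0, 0), c(0, 1, 0)),
      c(cfg$standoff, 0, 0), f_d = cfg$f_d))
  } else stop("unknown scene layout: ", cfg$layout)
  crystals <- do.call(rbind, lapply(modules, `[[`, "crystals"))
  crystals <- cbind(crystal_id = seq_len(nrow(crystals)), crystals)
  rownames(crystals) <- NULL
  scene <- structure(list(config = cfg, phantom = phantom,
                          modules = modules, crystals = crystals,
                          source = if (!is.null(cfg$source))
                            do.call(source_model, cfg$source) else NULL),
                     class = "pg_scene")
  check_scene_overlaps(scene)
  scene
}

check_scene_overlaps <- function(scene) {
  boxes <- scene$crystals[, c("cx", "cy", "cz", "hx", "hy", "hz")]
  if (!is.null(scene$phantom)) {
    boxes <- rbind(boxes, data.frame(
      cx = scene$phantom$center[1], cy = scene$phantom$center[2],
      cz = scene$phantom$center[3], hx = scene$phantom$half[1],
      hy = scene$phantom$half[2], hz = scene$phantom$half[3]))
  }
  n <- nrow(boxes)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sep <- abs(boxes[i, 1:3] - boxes[j, 1:3]) -
      (boxes[i, 4:6] + boxes[j, 4:6])
    if (all(sep < -1e-9))
      stop("scene configuration error: overlapping volumes (boxes ",
           i, " and ", j, ")")
  }
  invisible(scene)
}

#' @export
print.pg_scene <- function(x, ...) {
  cat("<pg_scene>", x$config$layout, "layout,",
      length(x$modules), "module(s),", nrow(x$crystals), "crystals\n")
  if (!is.null(x$phantom))
    cat("  phantom:", paste(2 * x$phantom$half, collapse = " x "),
        "mm^3", x$phantom$material, "\n")
  cat("  focal distance:", x$config$f_d, "mm\n")
  invisible(x)
}

#' Ray-box intersection by the slab method
#'
#' Entry and exit distances of a ray through an axis-aligned box.
#'
#' @param origin ray origin (length-3, mm).
#' @param direction unit direction vector.
#' @param box list or one-row data.frame with `cx, cy, cz, hx, hy, hz`
#'   (or `center` / `half` components).
#' @return numeric `c(entry, exit)` distances (mm, may be negative when
#'   the origin is inside or past the box), or `NULL` when the ray
#'   misses the box.
#' @export
ray_path_in_box <- function(origin, direction, box) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("direction must have non-zero norm")
  if (abs(nrm - 1) > 1e-9) stop("direction must be unit-norm")
  if (!is.null(box$center)) {
    center <- box$center; half <- box$half
  } else {
    center <- c(box$cx, box$cy, box$cz); half <- c(box$hx, box$hy, box$hz)
  }
  tmin <- -Inf; tmax <- Inf
  for (k in 1:3) {
    if (abs(direction[k]) < 1e-12) {
      if (abs(origin[k] - center[k]) > half[k]) return(NULL)
    } else {
      t1 <- (center[k] - half[k] - origin[k]) / direction[k]
      t2 <- (center[k] + half[k] - origin[k]) / direction[k]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmax <= tmin) return(NULL)
  c(entry = tmin, exit = tmax)
}

# bounding sphere of one module's crystals (lab frame)
module_bounding_sphere <- function(module) {
  cr <- module$crystals
  corners <- do.call(rbind, lapply(seq_len(nrow(cr)), function(i) {
    as.matrix(expand.grid(cr$cx[i] + c(-1, 1) * cr$hx[i],
                          cr$cy[i] + c(-1, 1) * cr$hy[i],
                          cr$cz[i] + c(-1, 1) * cr$hz[i]))
  }))
  center <- colMeans(corners)
  radius <- sqrt(max(rowSums((corners - rep(center, each = nrow(corners)))^2)))
  list(center = center, radius = radius)
}

#' Fixed emission cones covering the detector modules
#'
#' For importance sampling of emission directions: one cone per module,
#' guaranteed to contain every crystal corner of the module as seen from
#' every point of the source bounding box. Directions sampled uniformly
#' inside the union of cones (overlaps removed by thinning in
#' [sample_emission()]) reproduce isotropic emission restricted to
#' directions that can reach a detector — exact, because the phantom
#' removes scattered photons, so discarded directions cannot produce
#' hits.
#'
#' @param scene a `pg_scene`.
#' @param source_bbox list(center, half) of the emission region (mm).
#' @return list of cones `list(axis, cos_half, solid_angle)` plus
#'   attribute `solid_angle_sum`.
#' @keywords internal
direction_cones <- function(scene, source_bbox) {
  corners <- as.matrix(expand.grid(
    source_bbox$center[1] + c(-1, 1) * source_bbox$half[1],
    source_bbox$center[2] + c(-1, 1) * source_bbox$half[2],
    source_bbox$center[3] + c(-1, 1) * source_bbox$half[3]))
  cones <- lapply(scene$modules, function(m) {
    cr <- m$crystals
    ccorners <- do.call(rbind, lapply(seq_len(nrow(cr)), function(i) {
      as.matrix(expand.grid(cr$cx[i] + c(-1, 1) * cr$hx[i],
                            cr$cy[i] + c(-1, 1) * cr$hy[i],
                            cr$cz[i] + c(-1, 1) * cr$hz[i]))
    }))
    axis0 <- colMeans(ccorners) - source_bbox$center
    axis <- axis0 / sqrt(sum(axis0^2))
    # exact coverage: widest angle from the axis to any crystal corner
    # as seen from any source-box corner
    half_angle <- 0
    for (i in seq_len(nrow(corners))) {
      d <- ccorners - rep(corners[i, ], each = nrow(ccorners))
      ct <- (d %*% axis) / sqrt(rowSums(d^2))
      half_angle <- max(half_angle, acos(min(1, max(-1, min(ct)))))
    }
    half_angle <- min(half_angle + 1e-3, pi)
    list(axis = axis, cos_half = cos(half_angle),
         solid_angle = 2 * pi * (1 - cos(half_angle)))
  })
  attr(cones, "solid_angle_sum") <-
    sum(vapply(cones, `[[`, 0, "solid_angle"))
  cones
}

#' Write / read a scene configuration as YAML
#'
#' The YAML round-trips the `config` list used by [build_scene()]
#' exactly, so `build_scene(read_scene_config(p))` reproduces the scene.
#'
#' @param scene a `pg_scene`.
#' @param path file path.
#' @export
write_scene_config <- function(scene, path) {
  yaml::write_yaml(scene$config, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @return `read_scene_config` returns the config list.
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("phantom_half"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.numeric(cfg[[nm]])
  cfg
}
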