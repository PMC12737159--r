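#' Siddon ray trace of one LOR through a voxel grid
#'
#' Exact per-voxel chord lengths of the LOR segment clipped to the grid,
#' in traversal order, with the half-open voxel convention `[low, high)`.
#' The chord lengths sum to the clipped segment length to floating-point
#' accuracy, which is what makes the forward projector count-preserving.
#'
#' @param lor an `lor` (from [lor_endpoints()]) or a list with 3-vectors
#'   `a` and `b`.
#' @param grid an `image_grid`.
#' @return data.frame with `index` (1-based linear voxel index, column-major),
#'   `i`, `j`, `k` (1-based array indices) and `length` (mm).
#' @export
siddon_trace <- function(lor, grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (sum((lor$a - lor$b)^2) == 0) stop("degenerate zero-length LOR")
  tr <- cpp_siddon(as.numeric(lor$a), as.numeric(lor$b),
                   grid$lo, grid$dims, grid$vox)
  ijk <- arrayInd(tr$index, grid$dims)
  data.frame(index = tr$index, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
             length = tr$length)
}

#' System sensitivity image
#'
#' Per-voxel total Siddon weight over the crystal-pair LORs of all allowed
#' panel pairs, the normalization denominator of the MLEM update. The full
#' LOR set (42 pairs x 900 x 900 crystals for the default scanner) is
#' Bernoulli-thinned by `keep_prob` with a fixed seed; thinning rescales the
#' sensitivity uniformly (in expectation) and cancels out of the MLEM image
#' up to a global scale. By default each LOR endpoint is jittered uniformly
#' within its crystal face, so the denominator integrates the tube response
#' over the face instead of sampling the face center — sampling at centers
#' aliases the crystal pitch against the voxel grid and imprints spurious
#' banding on the sensitivity.
#'
#' @param geom a `scanner_geometry`.
#' @param grid an `image_grid`.
#' @param keep_prob probability of keeping each crystal-pair LOR.
#' @param jitter jitter endpoints uniformly within the crystal face.
#' @param n_rays jittered samples averaged per crystal-pair LOR; more samples
#'   cut the residual Monte-Carlo speckle of the face integration, which
#'   matters most in the weakly-sensed axial-edge planes.
#' @param seed thinning/jitter seed.
#' @return a `voxel_image`; raises an error if any voxel inside the scanner
#'   field of view (cylinder of the panel aperture) has zero sensitivity.
#' @export
sensitivity_image <- function(geom, grid = image_grid(), keep_prob = 1,
                              jitter = TRUE, n_rays = 4, seed = 99) {
  stopifnot(inherits(geom, "scanner_geometry"), keep_prob > 0, keep_prob <= 1)
  cs <- geom$crystals_per_side
  per_panel <- cs * cs
  idx <- expand.grid(row = 0:(cs - 1), col = 0:(cs - 1))
  pos <- do.call(rbind, lapply(0:(geom$n_panels - 1), function(p)
    crystal_position(p, idx$row, idx$col, geom)))
  offsets <- (0:(geom$n_panels - 1)) * per_panel
  sens <- cpp_sensitivity(pos, as.integer(offsets), as.integer(per_panel),
                          geom$pairs, geom$tangent,
                          if (jitter) geom$pitch else 0, as.integer(n_rays),
                          grid$lo, grid$dims, grid$vox,
                          keep_prob, as.integer(seed))
  img <- array(sens, grid$dims)

  # every voxel well inside the imaging FOV must be seen by some LOR
  xc <- grid_centers(grid, 1)
  yc <- grid_centers(grid, 2)
  zc <- grid_centers(grid, 3)
  r_fov <- geom$front_face_r * 0.45          # conservative interior cylinder
  inside <- outer(xc^2, yc^2, `+`) < r_fov^2
  zin <- abs(zc) < geom$axial_extent / 2 - grid$vox
  for (k in which(zin)) {
    if (any(img[, , k][inside] <= 0))
      stop("zero-sensitivity voxel inside the FOV: geometry/grid mismatch")
  }
  voxel_image(img, grid)
}

#' List-mode MLEM reconstruction
#'
#' Standard list-mode maximum-likelihood EM with a Siddon line-intersection
#' system model: starting from a uniform image,
#' `x_j <- (x_j / s_j) * sum_i a_ij / (sum_k a_ik x_k)` over the measured
#' coincidences i, for exactly `n_iter` full passes. No attenuation, scatter,
#' randoms or normalization corrections enter the system model; residual
#' background manifests as image noise. The update is multiplicative, so
#' non-negativity is preserved, and each full pass cannot decrease the
#' list-mode Poisson log-likelihood.
#'
#' @param coincidences a `coincidence_stream`.
#' @param geom a `scanner_geometry`.
#' @param grid an `image_grid`.
#' @param n_iter number of full EM passes (0 returns the uniform start).
#' @param sensitivity a `voxel_image` from [sensitivity_image()]; computed on
#'   the fly when NULL.
#' @param jitter displace each event's LOR endpoints uniformly within their
#'   crystal faces (seeded), matching the face-integrated sensitivity model;
#'   with `FALSE` the endpoints are the crystal face centers, which aliases
#'   the crystal pitch against the voxel grid on both sides of the update.
#' @param n_rays jittered rays averaged per event row (a Monte-Carlo
#'   integration of the crystal-face tube response; 1 reduces to a single
#'   sampled line). Ignored when `jitter = FALSE`.
#' @param support_frac reconstruction support threshold: voxels whose
#'   sensitivity falls below this fraction of the maximum are excluded
#'   (kept at zero). Voxels at the extreme axial edge of the field of view
#'   are crossed only by a handful of oblique LORs; dividing by their
#'   near-zero sensitivity amplifies a few counts into dominant spikes, the
#'   standard edge-of-FOV instability that reconstruction packages remove by
#'   masking the outer FOV. 0 disables the mask.
#' @param seed endpoint-jitter seed.
#' @return a `voxel_image`; attributes `loglik` (per-iteration log-likelihood
#'   of the pre-update iterate), `n_dropped` (events whose LOR misses the
#'   grid) and `n_events`.
#' @export
mlem_reconstruct <- function(coincidences, geom, grid = image_grid(),
                             n_iter = 9, sensitivity = NULL, jitter = TRUE,
                             n_rays = 1, support_frac = 0, seed = 7) {
  stopifnot(nrow(coincidences) >= 1, n_iter >= 0,
            support_frac >= 0, support_frac < 1)
  if (is.null(sensitivity)) sensitivity <- sensitivity_image(geom, grid)
  stopifnot(inherits(sensitivity, "voxel_image"))
  if (support_frac > 0) {
    v <- sensitivity$values
    v[v < support_frac * max(v)] <- 0
    sensitivity <- voxel_image(v, sensitivity$grid)
  }
  pa <- crystal_position(coincidences$panel_a, coincidences$row_a,
                         coincidences$col_a, geom)
  pb <- crystal_position(coincidences$panel_b, coincidences$row_b,
                         coincidences$col_b, geom)
  fit <- cpp_mlem(pa, pb, as.integer(coincidences$panel_a),
                  as.integer(coincidences$panel_b), geom$tangent,
                  if (jitter) geom$pitch else 0, as.integer(n_rays),
                  grid$lo, grid$dims, grid$vox, as.integer(n_iter),
                  as.numeric(sensitivity$values), as.integer(seed))
  img <- voxel_image(array(fit$image, grid$dims), grid)
  attr(img, "loglik") <- fit$loglik
  attr(img, "n_dropped") <- fit$n_dropped
  attr(img, "n_events") <- fit$n_events
  img
}

#' Cylindrical region of interest
#'
#' Axis along the depth (z) direction. The default reproduces the analysis
#' ROI: 36 mm long, 40 mm diameter, centered on the FOV — wider than the
#' 28 mm phantom so the full activation column survives masking while
#' peripheral background is zeroed.
#'
#' @param length axial length, mm.
#' @param diameter diameter, mm.
#' @param center 3-vector, mm (world coordinates).
#' @return object of class `roi_cylinder`.
#' @export
roi_cylinder <- function(length = 36, diameter = 40, center = c(0, 0, 0)) {
  stopifnot(length > 0, diameter > 0)
  structure(list(length = length, diameter = diameter, center = center),
            class = "roi_cylinder")
}

#' Mask an image with a cylindrical ROI
#'
#' Voxels whose center lies inside the cylinder keep their value bit for
#' bit; all others are set to zero.
#'
#' @param image a `voxel_image`.
#' @param roi an `roi_cylinder`.
#' @return the masked `voxel_image`.
#' @export
apply_roi <- function(image, roi = roi_cylinder()) {
  stopifnot(inherits(image, "voxel_image"), inherits(roi, "roi_cylinder"))
  g <- image$grid
  xc <- grid_centers(g, 1) - roi$center[1]
  yc <- grid_centers(g, 2) - roi$center[2]
  zc <- grid_centers(g, 3) - roi$center[3]
  lat <- outer(xc^2, yc^2, `+`) <= (roi$diameter / 2)^2
  zin <- abs(zc) <= roi$length / 2
  if (!any(lat) || !any(zin)) stop("ROI does not intersect the grid")
  v <- image$values
  for (k in seq_along(zc)) {
    if (zin[k]) v[, , k][!lat] <- 0 else v[, , k] <- 0
  }
  out <- voxel_image(v, g)
  attributes(out) <- c(attributes(out), attributes(image)[c("loglik",
                                                            "n_dropped",
                                                            "n_events")])
  out
}
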