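#' Depth-summed lateral map
#'
#' Sums image intensity along the depth (z) direction, producing the 2D
#' lateral map in which the beam center appears as a peak.
#'
#' @param image a `voxel_image`.
#' @return object of class `lateral_map`: list with `values` (x by y matrix)
#'   and `grid`.
#' @export
depth_sum <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  structure(list(values = rowSums(image$values, dims = 2),
                 grid = image$grid), class = "lateral_map")
}

#' Locate the beam center in a lateral map
#'
#' Global argmax of the depth-summed map; ties resolve to the smallest
#' (column-major) index, i.e. smallest y then smallest x. Coordinates are
#' reported on the integer-mm convention of the grid: voxel-center world
#' coordinate plus half the grid extent, so a beam on the scanner axis of the
#' default 64 x 64 x 36 grid reads (32, 32).
#'
#' @param map a `lateral_map`.
#' @return named numeric `c(x, y)` in reported mm.
#' @export
find_beam_center <- function(map) {
  stopifnot(inherits(map, "lateral_map"))
  if (all(map$values == 0)) stop("all-zero lateral map")
  ij <- arrayInd(which.max(map$values), dim(map$values))
  off <- grid_report_offset(map$grid)
  c(x = grid_centers(map$grid, 1)[ij[1]] + off[1],
    y = grid_centers(map$grid, 2)[ij[2]] + off[2])
}

#' Lateral shift between two beam centers
#'
#' Componentwise difference `center_1 - center_2`, mm.
#'
#' @param center_1,center_2 centers from [find_beam_center()] (same grid
#'   convention).
#' @return named numeric `c(dx, dy)`.
#' @export
lateral_shift <- function(center_1, center_2) {
  c(dx = unname(center_1[1] - center_2[1]),
    dy = unname(center_1[2] - center_2[2]))
}

#' Depth profile through the beam center
#'
#' Intensity versus depth along the axial line through the given lateral
#' center: the single voxel column by default, or the 3 x 3 lateral average
#' with `average = TRUE` (noise suppression). Depth is
#' `z + dims[3]/2` mm.
#'
#' @param image a `voxel_image`.
#' @param center reported-mm `c(x, y)` (as from [find_beam_center()]).
#' @param average average over the 3 x 3 lateral neighborhood.
#' @return object of class `depth_profile`: data.frame with `depth` (mm,
#'   strictly increasing) and `intensity`.
#' @export
depth_profile <- function(image, center, average = FALSE) {
  stopifnot(inherits(image, "voxel_image"))
  g <- image$grid
  off <- grid_report_offset(g)
  i <- which.min(abs(grid_centers(g, 1) + off[1] - center[1]))
  j <- which.min(abs(grid_centers(g, 2) + off[2] - center[2]))
  if (abs(grid_centers(g, 1)[i] + off[1] - center[1]) > g$vox ||
      abs(grid_centers(g, 2)[j] + off[2] - center[2]) > g$vox)
    stop("center lies outside the grid")
  if (average) {
    ii <- max(1, i - 1):min(g$dims[1], i + 1)
    jj <- max(1, j - 1):min(g$dims[2], j + 1)
    intensity <- apply(image$values[ii, jj, , drop = FALSE], 3, mean)
  } else {
    intensity <- image$values[i, j, ]
  }
  out <- data.frame(depth = grid_centers(g, 3) + off[3],
                    intensity = intensity)
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' R50 distal-falloff depth
#'
#' Depth at which the profile, beyond its global peak, last falls through
#' 50% of the peak value (linear interpolation between bracketing samples).
#' The distal crossing is the activation-range surrogate; proximal crossings
#' are ignored.
#'
#' @param profile a `depth_profile` (or data.frame with `depth`,
#'   `intensity`).
#' @return R50 depth, mm.
#' @export
r50_depth <- function(profile) {
  v <- profile$intensity
  d <- profile$depth
  if (length(v) < 2 || max(v) <= 0) stop("profile needs a positive maximum")
  if (any(diff(d) <= 0)) stop("depths must be strictly increasing")
  thr <- 0.5 * max(v)
  pk <- which.max(v)
  above <- which(v >= thr)
  above <- above[above >= pk]
  i <- max(above)
  if (i == length(v))
    stop("no distal 50% crossing: profile never falls below half maximum")
  # interpolate between the last sample at/above threshold and the next
  d[i] + (v[i] - thr) / (v[i] - v[i + 1]) * (d[i + 1] - d[i])
}

#' Range shift between two irradiations
#'
#' `r50_depth(profile_2) - r50_depth(profile_1)`, mm.
#'
#' @param profile_1,profile_2 `depth_profile`s.
#' @return range shift, mm.
#' @export
range_shift <- function(profile_1, profile_2) {
  r50_depth(profile_2) - r50_depth(profile_1)
}

#' Agreement between a measured and a model profile
#'
#' The model is resampled onto the measured depths by linear interpolation
#' and the comparison is restricted to their common depth support. Two
#' metrics are returned, both normalized by the measured intensity range
#' `R = max(m) - min(m)`:
#' `pct = 100 * sqrt(mean((m - s)^2)) / R` (percentage discrepancy) and
#' `rmse_rel = mean((m - s)^2) / R^2` (relative mean square error).
#' With `normalize = "mean"` the model is first rescaled so its mean matches
#' the measurement (the convention when the model is in arbitrary units);
#' the default `"none"` compares the profiles as given.
#'
#' @param measured,model `depth_profile`s.
#' @param normalize `"none"` or `"mean"`.
#' @return list with `pct`, `rmse_rel`, `n` (depths compared).
#' @export
profile_discrepancy <- function(measured, model,
                                normalize = c("none", "mean")) {
  normalize <- match.arg(normalize)
  lo <- max(min(measured$depth), min(model$depth))
  hi <- min(max(measured$depth), max(model$depth))
  keep <- measured$depth >= lo & measured$depth <= hi
  if (sum(keep) < 2) stop("profiles share too little depth support")
  m <- measured$intensity[keep]
  s <- stats::approx(model$depth, model$intensity,
                     xout = measured$depth[keep])$y
  rng <- max(m) - min(m)
  if (rng <= 0) stop("measured profile is constant (zero intensity range)")
  if (normalize == "mean") {
    if (mean(s) <= 0) stop("model profile mean must be positive to normalize")
    s <- s * mean(m) / mean(s)
  }
  mse <- mean((m - s)^2)
  list(pct = 100 * sqrt(mse) / rng, rmse_rel = mse / rng^2, n = length(m))
}
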