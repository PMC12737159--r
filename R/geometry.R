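#' Build a multi-panel PET scanner geometry
#'
#' Constructs the dodecagonal (by default) ring of square detector panels used
#' for in-beam imaging of a proton FLASH spill. Panel centers sit at angle
#' `2*pi*k/n_panels` on a circle of radius `panel_distance_r` in the transaxial
#' (x-y) plane, with faces normal to the radial direction and the square
#' aperture centered on the scanner axis (z = 0). The radius is the *effective*
#' photon-interaction radius (front face plus mean interaction depth), the
#' convention under which the closed-form fractional solid angle matches
#' ray-sampling exactly; the physical front face lies at
#' `panel_distance_r - depth_offset`.
#'
#' Coincidences are only formed between panels separated by at least
#' `min_panel_separation` positions on the ring (near-adjacent panels cannot
#' view the field of view); with 12 panels and separation 3 this yields the
#' 42 panel pairs served by the distributed coincidence processors.
#'
#' @param n_panels even number of panels (default 12).
#' @param panel_distance_r effective center-to-panel distance in mm (default 80).
#' @param panel_side_a side of the square panel aperture in mm (default 33).
#' @param crystals_per_side crystals along each side of a panel (default 30,
#'   i.e. 2 x 2 tiled detectors of 15 x 15 LYSO crystals, modeled gapless).
#' @param min_panel_separation minimum ring separation for a coincidence pair.
#' @param depth_offset mean interaction depth inside the crystals, mm; only
#'   used to report the front-face radius.
#' @return an object of class `scanner_geometry`.
#' @examples
#' geom <- build_scanner()
#' nrow(geom$pairs)  # 42
#' fractional_solid_angle(geom)
#' @export
build_scanner <- function(n_panels = 12, panel_distance_r = 80,
                          panel_side_a = 33, crystals_per_side = 30,
                          min_panel_separation = 3, depth_offset = 10) {
  if (n_panels < 2 || n_panels %% 2 != 0)
    stop("n_panels must be an even number >= 2")
  if (panel_distance_r <= 0 || panel_side_a <= 0 || crystals_per_side < 1)
    stop("panel dimensions must be positive")
  if (panel_distance_r <= panel_side_a / 2)
    stop("panel_distance_r must exceed panel_side_a/2")
  # non-overlap as seen from the center
  if (n_panels * 2 * atan(panel_side_a / (2 * panel_distance_r)) >= 2 * pi)
    stop("panels overlap: n_panels * 2*atan(a/(2r)) must be < 2*pi")
  if (min_panel_separation < 1 || min_panel_separation > n_panels / 2)
    stop("min_panel_separation must be in [1, n_panels/2]")

  k <- 0:(n_panels - 1)
  theta <- 2 * pi * k / n_panels
  pairs <- which(outer(k, k, function(a, b) {
    d <- abs(a - b)
    b > a & pmin(d, n_panels - d) >= min_panel_separation
  }), arr.ind = TRUE)
  pairs <- cbind(panel_a = k[pairs[, 1]], panel_b = k[pairs[, 2]])
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  geom <- list(
    n_panels = n_panels,
    panel_distance_r = panel_distance_r,
    panel_side_a = panel_side_a,
    crystals_per_side = crystals_per_side,
    axial_extent = panel_side_a,
    pitch = panel_side_a / crystals_per_side,
    min_panel_separation = min_panel_separation,
    depth_offset = depth_offset,
    front_face_r = panel_distance_r - depth_offset,
    theta = theta,
    normal = cbind(cos(theta), sin(theta), 0),
    tangent = cbind(-sin(theta), cos(theta), 0),
    pairs = pairs
  )
  class(geom) <- "scanner_geometry"
  geom
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(
    "<scanner_geometry> %d square panels, a = %.1f mm, effective r = %.1f mm\n",
    x$n_panels, x$panel_side_a, x$panel_distance_r))
  cat(sprintf("  %d x %d crystals/panel (pitch %.2f mm), %d coincidence pairs\n",
              x$crystals_per_side, x$crystals_per_side, x$pitch, nrow(x$pairs)))
  cat(sprintf("  fractional solid angle f_geom = %.4f\n",
              fractional_solid_angle(x)))
  invisible(x)
}

#' Fractional solid angle subtended by the panel ring
#'
#' Closed-form geometric detection fraction for a point source at the scanner
#' center: `f_geom = (n/pi) * atan(a^2 / (4 r sqrt(r^2 + a^2/2)))`, i.e.
#' `n` times the exact solid angle of a square aperture of side `a` at
#' perpendicular distance `r`, divided by `4*pi`. For the default 12-panel
#' geometry (r = 80 mm, a = 33 mm) this evaluates to 0.156.
#'
#' @param geom a `scanner_geometry`.
#' @return the fraction of 4 pi covered by the panels, in (0, 1).
#' @export
fractional_solid_angle <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  r <- geom$panel_distance_r
  a <- geom$panel_side_a
  geom$n_panels / pi * atan(a^2 / (4 * r * sqrt(r^2 + a^2 / 2)))
}

#' Crystal face-center positions
#'
#' Maps crystal indices (0-based: panel, row, col) to 3D positions on the
#' panel's effective detection plane. `row` indexes the axial (z) direction,
#' `col` the tangential direction. Vectorized; recycles scalar arguments.
#'
#' @param panel,row,col integer vectors of 0-based crystal indices.
#' @param geom a `scanner_geometry`.
#' @return an n x 3 matrix of positions in mm.
#' @export
crystal_position <- function(panel, row, col, geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  n <- max(length(panel), length(row), length(col))
  panel <- rep_len(as.integer(panel), n)
  row <- rep_len(as.integer(row), n)
  col <- rep_len(as.integer(col), n)
  if (any(panel < 0 | panel >= geom$n_panels))
    stop("panel index out of range")
  cs <- geom$crystals_per_side
  if (any(row < 0 | row >= cs | col < 0 | col >= cs))
    stop("crystal row/col index out of range")
  half <- cs / 2
  u <- (col + 0.5 - half) * geom$pitch          # tangential
  v <- (row + 0.5 - half) * geom$pitch          # axial (z)
  nrm <- geom$normal[panel + 1, , drop = FALSE]
  tng <- geom$tangent[panel + 1, , drop = FALSE]
  pos <- geom$panel_distance_r * nrm + u * tng
  pos[, 3] <- pos[, 3] + v
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' First photon-panel intersection
#'
#' Propagates photons from `origin` along unit `direction` and returns the
#' crystal containing the first intersection with a panel detection plane, or
#' NA if the ray escapes (between panels or axially). Vectorized over rays.
#'
#' @param origin n x 3 matrix (or length-3 vector) of emission points, mm.
#' @param direction n x 3 matrix (or length-3 vector) of unit directions.
#' @param geom a `scanner_geometry`.
#' @return data.frame with columns `panel`, `row`, `col` (0-based, NA on miss)
#'   and `tpath` (path length to the detection plane, mm).
#' @export
intersect_photon <- function(origin, direction, geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  if (nrow(origin) == 1 && nrow(direction) > 1)
    origin <- origin[rep(1, nrow(direction)), , drop = FALSE]
  n <- nrow(direction)
  half <- geom$panel_side_a / 2
  cs <- geom$crystals_per_side

  best_t <- rep(Inf, n)
  best_panel <- rep(NA_integer_, n)
  best_u <- rep(NA_real_, n)
  best_v <- rep(NA_real_, n)

  for (k in seq_len(geom$n_panels)) {
    nk <- geom$normal[k, ]
    tk <- geom$tangent[k, ]
    dn <- direction[, 1] * nk[1] + direction[, 2] * nk[2]
    on <- origin[, 1] * nk[1] + origin[, 2] * nk[2]
    tt <- (geom$panel_distance_r - on) / dn
    hx <- origin[, 1] + tt * direction[, 1]
    hy <- origin[, 2] + tt * direction[, 2]
    hz <- origin[, 3] + tt * direction[, 3]
    u <- hx * tk[1] + hy * tk[2]
    hit <- dn > 0 & tt > 0 & abs(u) <= half & abs(hz) <= half & tt < best_t
    hit[is.na(hit)] <- FALSE
    if (any(hit)) {
      best_t[hit] <- tt[hit]
      best_panel[hit] <- k - 1L
      best_u[hit] <- u[hit]
      best_v[hit] <- hz[hit]
    }
  }

  col <- pmin(pmax(floor(best_u / geom$pitch + cs / 2), 0), cs - 1)
  row <- pmin(pmax(floor(best_v / geom$pitch + cs / 2), 0), cs - 1)
  data.frame(panel = best_panel,
             row = ifelse(is.na(best_panel), NA_integer_, as.integer(row)),
             col = ifelse(is.na(best_panel), NA_integer_, as.integer(col)),
             tpath = ifelse(is.na(best_panel), NA_real_, best_t))
}

#' Line of response between two crystals
#'
#' Endpoints are the crystal face centers on the effective detection planes.
#' Same-panel pairs are rejected: two photons absorbed in one panel cannot
#' form a line through the field of view.
#'
#' @param c1,c2 lists or one-row data.frames with `panel`, `row`, `col`
#'   (0-based).
#' @param geom a `scanner_geometry`.
#' @return an object of class `lor`: list with `a`, `b` (3-vectors, mm) and
#'   `length` (mm).
#' @export
lor_endpoints <- function(c1, c2, geom) {
  if (c1$panel == c2$panel) stop("LOR endpoints must lie on distinct panels")
  a <- drop(crystal_position(c1$panel, c1$row, c1$col, geom))
  b <- drop(crystal_position(c2$panel, c2$row, c2$col, geom))
  structure(list(a = a, b = b, length = sqrt(sum((a - b)^2))), class = "lor")
}

#' Nearest crystal to a point on a panel
#'
#' Inverse of [crystal_position()]: projects a point onto the panel whose
#' detection plane is nearest and returns the containing crystal.
#'
#' @param pos n x 3 matrix of positions, mm.
#' @param geom a `scanner_geometry`.
#' @return data.frame with 0-based `panel`, `row`, `col`.
#' @export
nearest_crystal <- function(pos, geom) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  # panel by angular sector
  ang <- atan2(pos[, 2], pos[, 1]) %% (2 * pi)
  panel <- as.integer(round(ang / (2 * pi / geom$n_panels))) %% geom$n_panels
  tk <- geom$tangent[panel + 1, , drop = FALSE]
  u <- pos[, 1] * tk[, 1] + pos[, 2] * tk[, 2]
  v <- pos[, 3]
  cs <- geom$crystals_per_side
  col <- pmin(pmax(floor(u / geom$pitch + cs / 2), 0), cs - 1)
  row <- pmin(pmax(floor(v / geom$pitch + cs / 2), 0), cs - 1)
  data.frame(panel = panel, row = as.integer(row), col = as.integer(col))
}

#' Monte-Carlo estimate of the geometric detection fraction
#'
#' Samples isotropic directions from a point and reports the fraction hitting
#' any panel; the brute-force check of [fractional_solid_angle()].
#'
#' @param geom a `scanner_geometry`.
#' @param n_rays number of rays.
#' @param origin emission point (default scanner center).
#' @param seed RNG seed.
#' @return list with `fraction` and its binomial `se`.
#' @export
solid_angle_mc <- function(geom, n_rays = 1e6, origin = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  dir <- isotropic_directions(n_rays)
  hit <- !is.na(intersect_photon(matrix(origin, ncol = 3), dir, geom)$panel)
  p <- mean(hit)
  list(fraction = p, se = sqrt(p * (1 - p) / n_rays))
}

#' Uniform random unit vectors
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
isotropic_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

# panel -> 0-based ids of coincidence pairs containing it (padded with -1),
# as needed by the dead-time kernel
panel_pair_matrix <- function(geom) {
  m <- nrow(geom$pairs)
  lst <- lapply(0:(geom$n_panels - 1), function(p)
    which(geom$pairs[, 1] == p | geom$pairs[, 2] == p) - 1L)
  K <- max(lengths(lst))
  t(vapply(lst, function(v) c(v, rep(-1L, K - length(v))), integer(K)))
}
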