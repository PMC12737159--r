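#' Reconstruction / activation voxel grid
#'
#' Regular isotropic grid centered on the scanner field of view, with the
#' beam (depth) direction along z. The grid is offset by half a voxel so that
#' voxel centers fall on integer multiples of `voxel_mm` in world
#' coordinates; a beam on the scanner axis then peaks in a voxel centered at
#' exactly (0, 0), which keeps reported integer-mm beam centers deterministic.
#' Reported lateral coordinates are `world + dims/2` mm (so a centered beam
#' reads (32, 32) on the default 64 x 64 x 36 grid) and depth is
#' `z + dims[3]/2` mm.
#'
#' @param dims voxel counts (x, y, z).
#' @param voxel_mm isotropic voxel size, mm.
#' @return object of class `image_grid`.
#' @export
image_grid <- function(dims = c(64, 64, 36), voxel_mm = 1) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims > 0), voxel_mm > 0)
  lo <- -(dims / 2 + 0.5) * voxel_mm
  structure(list(dims = dims, vox = voxel_mm, lo = lo), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels of %g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$vox))
  invisible(x)
}

# world coordinates of voxel centers along one axis (1 = x, 2 = y, 3 = z)
grid_centers <- function(grid, axis) {
  grid$lo[axis] + (seq_len(grid$dims[axis]) - 0.5) * grid$vox
}

# reported-coordinate offset: world + offset = paper-style mm coordinate
grid_report_offset <- function(grid) grid$dims * grid$vox / 2

#' Non-negative 3D activity image
#'
#' Container pairing a voxel array with its grid.
#'
#' @param values 3D numeric array matching `grid$dims`.
#' @param grid an `image_grid`.
#' @return object of class `voxel_image`.
#' @export
voxel_image <- function(values, grid) {
  stopifnot(inherits(grid, "image_grid"), all(dim(values) == grid$dims))
  if (any(values < 0)) stop("voxel values must be non-negative")
  structure(list(values = values, grid = grid), class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %d x %d x %d, total intensity %.4g\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values)))
  invisible(x)
}
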