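#' Phantom specification
#'
#' Solid-water cylinder irradiated along its axis (the scanner z axis).
#'
#' @param diameter cylinder diameter, mm.
#' @param length cylinder length, mm.
#' @param density mass density, g/cm^3.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(diameter = 28, length = 70, density = 1.032) {
  stopifnot(diameter > 0, length > 0, density > 0)
  structure(list(diameter = diameter, length = length, density = density),
            class = "phantom_spec")
}

#' Detector blur parameters
#'
#' @param energy_fwhm_frac energy resolution as FWHM fraction of 511 keV
#'   (default 0.15, typical for LYSO).
#' @param time_fwhm_ns per-single Gaussian timing jitter FWHM, ns. The default
#'   3.6/sqrt(2) makes the pair time-difference FWHM equal the 3.6 ns
#'   coincidence timing resolution of a panel pair.
#' @param emission_sigma_mm optional isotropic Gaussian blur of the emission
#'   point (positron range / acollinearity surrogate), off by default.
#' @return object of class `blur_params`.
#' @export
blur_params <- function(energy_fwhm_frac = 0.15, time_fwhm_ns = 3.6 / sqrt(2),
                        emission_sigma_mm = 0) {
  stopifnot(energy_fwhm_frac >= 0, time_fwhm_ns >= 0, emission_sigma_mm >= 0)
  structure(list(energy_fwhm_frac = energy_fwhm_frac,
                 time_fwhm_ns = time_fwhm_ns,
                 emission_sigma_mm = emission_sigma_mm),
            class = "blur_params")
}

FWHM_TO_SD <- 1 / (2 * sqrt(2 * log(2)))

#' Build a spatial activation map
#'
#' Probability density (over voxels) of positron-emitter production: a
#' separable product of an isotropic lateral Gaussian (the beam's intensity
#' profile) truncated to the phantom radius, and a depth profile that is flat
#' from `plateau_start` and falls off logistically through 50% of the plateau
#' at `r50_depth`. Activation ends proximal to the Bragg peak, so the distal
#' falloff is the range surrogate; `r50_depth` is free so that localization
#' experiments can impose known range shifts. Depth is measured as
#' `z + dims[3]/2` mm (0 at the upstream face of the grid).
#'
#' @param beam a `beam_spec` (supplies `lateral_sigma`).
#' @param phantom a `phantom_spec`; its radius truncates the lateral profile
#'   (use `diameter = Inf` for an untruncated beam).
#' @param grid an `image_grid`.
#' @param r50_depth depth (mm) where the profile crosses 50% of the plateau.
#' @param falloff_width mm over which the logistic falls from 80% to 20%.
#' @param plateau_start depth (mm) where the plateau begins.
#' @param beam_center lateral (x, y) of the beam axis in world mm.
#' @return object of class `activation_map` (normalized voxel weights).
#' @export
build_activation_map <- function(beam, phantom = phantom_spec(),
                                 grid = image_grid(), r50_depth = 8.3,
                                 falloff_width = 3, plateau_start = 0,
                                 beam_center = c(0, 0)) {
  stopifnot(inherits(beam, "beam_spec"), inherits(grid, "image_grid"))
  depth_max <- grid$dims[3] * grid$vox
  if (r50_depth <= 0 || r50_depth >= depth_max)
    stop("r50_depth must lie inside the grid depth range (0, ", depth_max, ")")
  sigma <- beam$lateral_sigma
  radius <- phantom$diameter / 2

  xc <- grid_centers(grid, 1) - beam_center[1]
  yc <- grid_centers(grid, 2) - beam_center[2]
  zc <- grid_centers(grid, 3)
  depth <- zc + grid$dims[3] * grid$vox / 2

  r2 <- outer(xc^2, yc^2, `+`)
  lateral <- exp(-r2 / (2 * sigma^2))
  lateral[r2 > radius^2] <- 0
  # logistic scale from the 80%-20% width
  s <- falloff_width / (2 * log(4))
  dpth <- 1 / (1 + exp((depth - r50_depth) / s))
  dpth[depth < plateau_start] <- 0

  w <- array(0, grid$dims)
  for (k in seq_along(zc)) w[, , k] <- lateral * dpth[k]
  tot <- sum(w)
  if (tot <= 0) stop("activation map has no support on the grid")
  structure(list(weights = w / tot, grid = grid, lateral_sigma = sigma,
                 radius = radius, r50_depth = r50_depth,
                 falloff_width = falloff_width, plateau_start = plateau_start,
                 beam_center = beam_center), class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> sigma = %.1f mm, r50 depth = %.1f mm, center (%g, %g)\n",
    x$lateral_sigma, x$r50_depth, x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Sample timed annihilation events
#'
#' Draws, per budgeted species, a Poisson number of decays with expectation
#' `count_scale * decays_in_interval(0, duration)`, decay times from the
#' exponential law truncated to `[0, duration]`, and positions i.i.d. from the
#' activation map (voxel draw plus uniform jitter inside the voxel). With
#' `in_spill = TRUE`, creation times are additionally spread uniformly over
#' the spill. `count_scale` scales the experiment down to desk size without
#' touching the physics (times and positions keep their true distributions).
#'
#' @param map an `activation_map`.
#' @param inventory an `isotope_table` with `initial_count` set.
#' @param duration acquisition length, s.
#' @param seed RNG seed.
#' @param count_scale expectation scale factor (1 = full experiment).
#' @param in_spill spread creation times over the spill (needs `spill_s`).
#' @param spill_s spill duration, s (used when `in_spill`).
#' @return data.frame of class `annihilation_stream`: `time_ns` (integer-valued),
#'   `x`, `y`, `z` (mm), `species`, `id`; sorted by time.
#' @export
sample_annihilations <- function(map, inventory, duration, seed = 1,
                                 count_scale = 1, in_spill = FALSE,
                                 spill_s = 0.1) {
  stopifnot(inherits(map, "activation_map"), duration > 0, count_scale > 0)
  rows <- which(inventory$budgeted & !is.na(inventory$initial_count))
  if (length(rows) == 0) stop("inventory has no budgeted species with N(0)")
  set.seed(seed)

  parts <- lapply(rows, function(i) {
    sp <- inventory[i, ]
    lam <- sp$decay_constant
    mu <- count_scale * decays_in_interval(sp, 0, duration)
    n <- stats::rpois(1, mu)
    if (n == 0) return(NULL)
    # truncated exponential via inverse CDF
    u <- stats::runif(n)
    t <- -log(1 - u * (1 - exp(-lam * duration))) / lam
    if (in_spill) t <- t + stats::runif(n, 0, spill_s)
    data.frame(time_s = t, species = sp$name, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, parts)
  if (is.null(ev)) {
    ev <- data.frame(time_ns = numeric(0), x = numeric(0), y = numeric(0),
                     z = numeric(0), species = character(0), id = integer(0))
    class(ev) <- c("annihilation_stream", "data.frame")
    return(ev)
  }

  n <- nrow(ev)
  g <- map$grid
  vi <- sample.int(length(map$weights), n, replace = TRUE, prob = map$weights)
  ijk <- arrayInd(vi, g$dims)
  pos <- sweep(ijk - 1, 2, g$lo, function(i, l) l + i * g$vox) +
    matrix(stats::runif(3 * n, 0, g$vox), ncol = 3)

  out <- data.frame(time_ns = round(ev$time_s * 1e9),
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    species = ev$species, stringsAsFactors = FALSE)
  out <- out[order(out$time_ns), ]
  out$id <- seq_len(n)
  rownames(out) <- NULL
  class(out) <- c("annihilation_stream", "data.frame")
  out
}

#' Emit annihilation photons and detect singles
#'
#' For each annihilation: with probability `f_2gamma` two photons are emitted
#' back-to-back in a uniform random direction; each photon that geometrically
#' intersects a panel is recorded with probability `eps_gamma`. Recorded
#' energy is Gaussian around 511 keV (FWHM = `energy_fwhm_frac` * 511,
#' rounded to 0.1 keV) and recorded time adds a per-single Gaussian jitter
#' (integer ns). Undetected photons are dropped silently; the returned stream
#' carries per-event provenance in `id` and a detection summary in
#' `attr(, "accounting")`.
#'
#' @param events an `annihilation_stream`.
#' @param geom a `scanner_geometry`.
#' @param eff an `efficiency_model`.
#' @param blur a `blur_params`.
#' @param seed RNG seed.
#' @return data.frame of class `singles_stream`: `time_ns`, `panel`, `row`,
#'   `col` (0-based), `energy_keV`, `id` (annihilation id, NA for background);
#'   sorted by time then (panel, row, col).
#' @export
emit_and_detect <- function(events, geom, eff, blur = blur_params(),
                            seed = 1, chunk = 200000L) {
  stopifnot(inherits(geom, "scanner_geometry"),
            inherits(eff, "efficiency_model"))
  set.seed(seed)
  n <- nrow(events)
  acc <- c(annihilations = n, pairs_emitted = 0, photons_hit = 0,
           singles_recorded = 0)
  if (n == 0) {
    out <- empty_singles()
    attr(out, "accounting") <- acc
    return(out)
  }

  esd <- blur$energy_fwhm_frac * 511 * FWHM_TO_SD
  tsd <- blur$time_fwhm_ns * FWHM_TO_SD
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  parts <- lapply(chunks, function(ix) {
    m <- length(ix)
    emit <- stats::runif(m) < eff$f_2gamma
    acc["pairs_emitted"] <<- acc["pairs_emitted"] + sum(emit)
    if (!any(emit)) return(NULL)
    ix <- ix[emit]
    m <- length(ix)
    org <- cbind(events$x[ix], events$y[ix], events$z[ix])
    if (blur$emission_sigma_mm > 0)
      org <- org + matrix(stats::rnorm(3 * m, 0, blur$emission_sigma_mm),
                          ncol = 3)
    dir <- isotropic_directions(m)
    sub <- lapply(list(dir, -dir), function(d) {
      hit <- intersect_photon(org, d, geom)
      ok <- !is.na(hit$panel)
      acc["photons_hit"] <<- acc["photons_hit"] + sum(ok)
      ok <- ok & stats::runif(m) < eff$eps_gamma
      if (!any(ok)) return(NULL)
      data.frame(time_ns = events$time_ns[ix][ok],
                 panel = hit$panel[ok], row = hit$row[ok], col = hit$col[ok],
                 energy_keV = round(511 + stats::rnorm(sum(ok), 0, esd), 1),
                 id = events$id[ix][ok])
    })
    do.call(rbind, sub)
  })
  out <- do.call(rbind, c(parts, list(empty_singles())))
  if (tsd > 0 && nrow(out) > 0)
    out$time_ns <- out$time_ns + round(stats::rnorm(nrow(out), 0, tsd))
  out <- sort_singles(out)
  acc["singles_recorded"] <- nrow(out)
  attr(out, "accounting") <- acc
  class(out) <- c("singles_stream", "data.frame")
  out
}

empty_singles <- function() {
  data.frame(time_ns = numeric(0), panel = integer(0), row = integer(0),
             col = integer(0), energy_keV = numeric(0), id = integer(0))
}

sort_singles <- function(s) {
  s <- s[order(s$time_ns, s$panel, s$row, s$col), ]
  rownames(s) <- NULL
  s
}

assert_sorted <- function(s) {
  if (nrow(s) > 1 && any(diff(s$time_ns) < 0))
    stop("singles stream must be time-sorted")
}

#' Apply per-panel-pair dead time
#'
#' Non-paralyzable model of the distributed coincidence processors' rate cap:
#' each allowed panel pair carries a frame clock; a single opens a new frame
#' on a pair only if the pair has been idle for at least
#' `1/max_rate_per_pair` since the previous frame start (inclusive boundary),
#' while singles arriving within the coincidence window of the last accepted
#' single on that pair belong to the open frame and pass — a pair processor
#' must be able to take in both photons of one coincidence. A single is
#' accepted only if every pair its panel belongs to accepts it. The frame
#' (coincidence-candidate) rate seen by each per-pair processor therefore
#' never exceeds `max_rate_per_pair`.
#'
#' @param singles a time-sorted `singles_stream`.
#' @param geom a `scanner_geometry`.
#' @param max_rate_per_pair maximum accepted event-frame rate per panel pair,
#'   1/s.
#' @param window_ns coincidence window used for frame membership, ns.
#' @return the thinned stream; dropped count in `attr(, "n_dropped")`.
#' @export
apply_dead_time <- function(singles, geom, max_rate_per_pair = 2.5e5,
                            window_ns = 10) {
  stopifnot(max_rate_per_pair > 0)
  assert_sorted(singles)
  if (nrow(singles) == 0) return(singles)
  keep <- cpp_deadtime(singles$time_ns, as.integer(singles$panel),
                       panel_pair_matrix(geom), nrow(geom$pairs),
                       1e9 / max_rate_per_pair, window_ns)
  out <- singles[keep, ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("singles_stream", "data.frame")
  out
}

#' Add uncorrelated background singles
#'
#' Prompt-gamma and other uncorrelated radiation is modeled as singles
#' uniform in time over `[0, duration]`, uniform over crystals, with energy
#' uniform on [150, 800] keV (a broad placeholder spectrum; no measured rates
#' or spectra exist for this configuration, so both are configuration
#' choices).
#'
#' @param singles a `singles_stream` to merge into (may be empty).
#' @param random_rate background singles rate, 1/s.
#' @param duration acquisition length, s.
#' @param geom a `scanner_geometry`.
#' @param seed RNG seed.
#' @return merged, time-sorted `singles_stream` (background has `id = NA`).
#' @export
add_background <- function(singles, random_rate, duration, geom, seed = 1) {
  stopifnot(random_rate >= 0, duration > 0)
  if (random_rate == 0) return(singles)
  set.seed(seed)
  n <- stats::rpois(1, random_rate * duration)
  cs <- geom$crystals_per_side
  bg <- data.frame(
    time_ns = round(stats::runif(n, 0, duration * 1e9)),
    panel = sample.int(geom$n_panels, n, replace = TRUE) - 1L,
    row = sample.int(cs, n, replace = TRUE) - 1L,
    col = sample.int(cs, n, replace = TRUE) - 1L,
    energy_keV = round(stats::runif(n, 150, 800), 1),
    id = NA_integer_)
  out <- sort_singles(rbind(as.data.frame(singles), bg))
  class(out) <- c("singles_stream", "data.frame")
  out
}

#' Simulate one irradiation end to end
#'
#' Activation map -> annihilations -> photon transport/detection ->
#' dead time -> background, with one seed fanning out to the stages.
#'
#' @param geom a `scanner_geometry`.
#' @param map an `activation_map`.
#' @param inventory an `isotope_table` with `initial_count` set.
#' @param duration acquisition length, s.
#' @param eff an `efficiency_model`.
#' @param blur a `blur_params`.
#' @param count_scale desk-size scale factor on expected decay counts.
#' @param background_rate uncorrelated singles rate, 1/s.
#' @param max_rate_per_pair dead-time cap, 1/s (NULL disables dead time).
#' @param seed master seed for this irradiation.
#' @return a `singles_stream` with an `accounting` attribute.
#' @export
simulate_irradiation <- function(geom, map, inventory, duration = 660,
                                 eff = efficiency_model(geom = geom),
                                 blur = blur_params(), count_scale = 1,
                                 background_rate = 0,
                                 max_rate_per_pair = 2.5e5, seed = 1) {
  ann <- sample_annihilations(map, inventory, duration, seed = seed,
                              count_scale = count_scale)
  s <- emit_and_detect(ann, geom, eff, blur, seed = seed + 1)
  acc <- attr(s, "accounting")
  if (!is.null(max_rate_per_pair)) {
    s <- apply_dead_time(s, geom, max_rate_per_pair)
    acc["deadtime_dropped"] <- attr(s, "n_dropped")
  } else acc["deadtime_dropped"] <- 0
  if (background_rate > 0)
    s <- add_background(s, background_rate, duration, geom, seed = seed + 2)
  acc["singles_out"] <- nrow(s)
  attr(s, "accounting") <- acc
  s
}

#' Write / read list-mode singles
#'
#' Plain-text tab-separated list-mode format: header line
#' `#flashpet-singles v1`, then columns `time_ns`, `panel`, `row`, `col`
#' (integers) and `energy_keV` (one decimal), sorted by time with ties broken
#' by (panel, row, col). Energies are generated pre-rounded to 0.1 keV, so
#' the round trip is lossless.
#'
#' @param stream a sorted `singles_stream`.
#' @param path file path.
#' @return `read_listmode` returns a `singles_stream` (without provenance ids).
#' @export
write_listmode <- function(stream, path) {
  assert_sorted(stream)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#flashpet-singles v1", con)
  writeLines("time_ns\tpanel\trow\tcol\tenergy_keV", con)
  if (nrow(stream) > 0)
    writeLines(sprintf("%.0f\t%d\t%d\t%d\t%.1f", stream$time_ns,
                       stream$panel, stream$row, stream$col,
                       stream$energy_keV), con)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != "#flashpet-singles v1")
    stop("not a flashpet singles file (bad header): ", path)
  if (lines[2] != "time_ns\tpanel\trow\tcol\tenergy_keV")
    stop("malformed column header at line 2 of ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    out <- empty_singles()
    out$id <- NULL
    class(out) <- c("singles_stream", "data.frame")
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5))
    stop("malformed record at line ", which(nf != 5)[1] + 2, " of ", path)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 5,
              byrow = TRUE)
  if (anyNA(m))
    stop("malformed record at line ",
         which(apply(is.na(m), 1, any))[1] + 2, " of ", path)
  out <- data.frame(time_ns = m[, 1], panel = as.integer(m[, 2]),
                    row = as.integer(m[, 3]), col = as.integer(m[, 4]),
                    energy_keV = m[, 5])
  class(out) <- c("singles_stream", "data.frame")
  out
}
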