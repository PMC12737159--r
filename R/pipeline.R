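#' Default run configuration
#'
#' Assembles the full configuration of a simulated irradiation-plus-analysis
#' run. Defaults reproduce the study conditions (142.4 MeV, 3.1e10 protons,
#' 100 ms spill, sigma = 7 mm beam on a 28 mm solid-water cylinder viewed by
#' the 12-panel scanner; 10 ns / 360-650 keV coincidence policy; 9 MLEM
#' iterations on a 64 x 64 x 36 mm grid with a 36 x 40 mm ROI cylinder) at a
#' desk-size event scale (`count_scale`, about 1e5 annihilations per run).
#'
#' @param master_seed master seed; per-stage seeds are derived as
#'   `master_seed * 100 + stage offset` (0 annihilations, 1 detection,
#'   2 background, 50+ second irradiation) so stages can be re-run in
#'   isolation.
#' @param ... overrides for any configuration element.
#' @return a list of class `run_config`.
#' @export
default_run_config <- function(master_seed = 1, ...) {
  cfg <- list(
    master_seed = master_seed,
    beam = beam_spec(),
    phantom = phantom_spec(),
    scanner = list(n_panels = 12, panel_distance_r = 80, panel_side_a = 33,
                   crystals_per_side = 30, min_panel_separation = 3),
    map = list(r50_depth = 8.3, falloff_width = 3, plateau_start = 0,
               beam_center = c(0, 0)),
    duration = 660,
    count_scale = 0.0026,
    background_rate = 500,
    max_rate_per_pair = 2.5e5,
    blur = blur_params(),
    policy = coincidence_policy(),
    grid = image_grid(),
    roi = roi_cylinder(),
    n_iter = 9,
    sens_keep_prob = 1,
    windows_fast = cbind(seq(0, 0.98, by = 0.02), seq(0.02, 1, by = 0.02)),
    windows_slow = cbind(seq(0, 600, by = 60), seq(60, 660, by = 60)),
    second_irradiation = NULL
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(master, k) (master %% 21470000L) * 100L + k

#' Load a run configuration from a YAML file
#'
#' Scalar fields override the defaults of [default_run_config()]; structured
#' fields (`beam`, `phantom`, `blur`, `policy`, `roi`, `grid`,
#' `second_irradiation`) are given as named sub-maps of the constructor
#' arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the yaml package")
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(master_seed = raw$master_seed %||% 1)
  build <- list(beam = beam_spec, phantom = phantom_spec, blur = blur_params,
                policy = coincidence_policy, roi = roi_cylinder,
                grid = image_grid)
  for (nm in names(raw)) {
    if (nm == "master_seed") next
    cfg[[nm]] <- if (nm %in% names(build)) do.call(build[[nm]], raw[[nm]])
    else raw[[nm]]
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_one_irradiation <- function(cfg, geom, sens, map, inventory, eff,
                                seed_off) {
  seed <- stage_seed(cfg$master_seed, seed_off)
  singles <- simulate_irradiation(
    geom, map, inventory, duration = cfg$duration, eff = eff,
    blur = cfg$blur, count_scale = cfg$count_scale,
    background_rate = cfg$background_rate,
    max_rate_per_pair = cfg$max_rate_per_pair, seed = seed)
  cc <- find_coincidences(singles, geom, cfg$policy)
  img <- mlem_reconstruct(cc, geom, cfg$grid, n_iter = cfg$n_iter,
                          sensitivity = sens)
  img <- apply_roi(img, cfg$roi)
  list(singles = singles, coincidences = cc, image = img)
}

#' Run a complete simulated experiment
#'
#' Executes simulate -> coincide -> histogram -> reconstruct -> localize ->
#' budget for one (or, with `second_irradiation`, two) irradiations, writing
#' all products and a manifest into `outdir`. With a second irradiation
#' (elements `x_shift` mm and `r50_shift` mm) the localization report also
#' contains the recovered lateral and range shifts.
#'
#' @param cfg a `run_config`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory products (`singles`,
#'   `coincidences`, `hist_fast`, `hist_slow`, `image`, `localization`,
#'   `budget`, `manifest`).
#' @export
run_experiment <- function(cfg = default_run_config(), outdir = tempfile()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sc <- cfg$scanner
  geom <- build_scanner(sc$n_panels, sc$panel_distance_r, sc$panel_side_a,
                        sc$crystals_per_side, sc$min_panel_separation)
  eff <- efficiency_model(geom = geom)
  inventory <- initial_inventory(cfg$beam)
  sens <- sensitivity_image(geom, cfg$grid, keep_prob = cfg$sens_keep_prob)

  map1 <- build_activation_map(cfg$beam, cfg$phantom, cfg$grid,
                               r50_depth = cfg$map$r50_depth,
                               falloff_width = cfg$map$falloff_width,
                               plateau_start = cfg$map$plateau_start,
                               beam_center = cfg$map$beam_center)
  run1 <- run_one_irradiation(cfg, geom, sens, map1, inventory, eff, 0L)

  hist_fast <- histogram_times(run1$coincidences,
                               bin_width = diff(cfg$windows_fast[1, ]),
                               t_start = cfg$windows_fast[1, 1],
                               t_end = cfg$windows_fast[nrow(cfg$windows_fast), 2])
  hist_slow <- histogram_times(run1$coincidences,
                               bin_width = diff(cfg$windows_slow[1, ]),
                               t_start = cfg$windows_slow[1, 1],
                               t_end = cfg$windows_slow[nrow(cfg$windows_slow), 2])

  map1_center <- find_beam_center(depth_sum(run1$image))
  prof1 <- depth_profile(run1$image, map1_center)
  loc <- list(center_1 = as.list(map1_center), r50_1 = r50_depth(prof1))

  run2 <- NULL
  if (!is.null(cfg$second_irradiation)) {
    sh <- cfg$second_irradiation
    map2 <- build_activation_map(cfg$beam, cfg$phantom, cfg$grid,
                                 r50_depth = cfg$map$r50_depth + sh$r50_shift,
                                 falloff_width = cfg$map$falloff_width,
                                 plateau_start = cfg$map$plateau_start,
                                 beam_center = cfg$map$beam_center +
                                   c(sh$x_shift, 0))
    run2 <- run_one_irradiation(cfg, geom, sens, map2, inventory, eff, 50L)
    center_2 <- find_beam_center(depth_sum(run2$image))
    prof2 <- depth_profile(run2$image, center_2)
    loc$center_2 <- as.list(center_2)
    loc$r50_2 <- r50_depth(prof2)
    loc$lateral_shift <- as.list(lateral_shift(map1_center, center_2))
    loc$range_shift <- loc$r50_2 - loc$r50_1
  }

  budget <- activation_budget(cfg$beam, eff, horizon = cfg$duration)

  # --- products on disk -------------------------------------------------
  write_listmode(run1$singles, file.path(outdir, "singles.tsv"))
  write_coincidences(run1$coincidences, file.path(outdir, "coincidences.tsv"))
  hist_df <- function(h) data.frame(t_start = h$edges[-length(h$edges)],
                                    t_end = h$edges[-1], count = h$counts)
  utils::write.csv(hist_df(hist_fast), file.path(outdir, "hist_20ms.csv"),
                   row.names = FALSE)
  utils::write.csv(hist_df(hist_slow), file.path(outdir, "hist_60s.csv"),
                   row.names = FALSE)
  img_file <- write_volume(run1$image, file.path(outdir, "image"))
  jsonlite::write_json(loc, file.path(outdir, "localization.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(species = names(budget$decays), decays = budget$decays),
    file.path(outdir, "budget.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(f_geom = budget$f_geom, horizon_s = budget$horizon,
         decays = as.list(budget$decays), n_measure = budget$n_measure),
    file.path(outdir, "budget_summary.json"), auto_unbox = TRUE, digits = NA)

  products <- c("singles.tsv", "coincidences.tsv", "hist_20ms.csv",
                "hist_60s.csv", basename(img_file), "localization.json",
                "budget.csv")
  acc_sim <- attr(run1$singles, "accounting")
  acc_cc <- attr(run1$coincidences, "accounting")
  manifest <- list(
    master_seed = cfg$master_seed,
    config_hash = config_hash(cfg),
    products = products,
    accounting = c(as.list(acc_sim), as.list(acc_cc)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(singles = run1$singles, coincidences = run1$coincidences,
                 hist_fast = hist_fast, hist_slow = hist_slow,
                 image = run1$image, second = run2, localization = loc,
                 budget = budget, manifest = manifest, outdir = outdir))
}

config_hash <- function(cfg) {
  s <- utils::capture.output(utils::str(unclass(cfg), digits.d = 12))
  sum(utf8ToInt(paste(s, collapse = "")) * (seq_along(
    utf8ToInt(paste(s, collapse = ""))) %% 997)) %% 1e9
}

# NIfTI when RNifti is installed, otherwise a plain-text voxel table
write_volume <- function(image, stem) {
  if (requireNamespace("RNifti", quietly = TRUE)) {
    f <- paste0(stem, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(image$values), f)
    f
  } else {
    f <- paste0(stem, ".csv")
    ijk <- which(image$values != 0, arr.ind = TRUE)
    utils::write.csv(data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                                value = image$values[ijk]), f,
                     row.names = FALSE)
    f
  }
}

#' Compare measured per-window counts against the decay budget
#'
#' Mean-normalizes the per-species analytic window expectations (and their
#' total) to the measured per-window coincidence counts — the stacked-bar
#' comparison of measurement against the activation model.
#'
#' @param measured a `time_histogram` whose bins match `windows`.
#' @param table an `isotope_table` with `initial_count` set.
#' @param windows two-column matrix of window bounds, s.
#' @return data.frame with `t_start`, `t_end`, `measured`, one normalized
#'   column per budgeted species, and `sim_total`.
#' @export
compare_decay <- function(measured, table, windows) {
  stopifnot(inherits(measured, "time_histogram"))
  windows <- as.matrix(windows)
  if (length(measured$counts) != nrow(windows))
    stop("window schedules do not match")
  if (any(abs(measured$edges[-length(measured$edges)] - windows[, 1]) > 1e-9))
    stop("window schedules do not match")
  exp_mat <- window_expectations(table, windows)
  sim_total <- colSums(exp_mat)
  scale <- mean(measured$counts) / mean(sim_total)
  if (!is.finite(scale) || mean(measured$counts) <= 0)
    stop("measured mean must be positive to normalize")
  out <- data.frame(t_start = windows[, 1], t_end = windows[, 2],
                    measured = measured$counts)
  for (sp in rownames(exp_mat)) out[[sp]] <- exp_mat[sp, ] * scale
  out$sim_total <- sim_total * scale
  out
}
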