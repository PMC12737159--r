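#' Beam specification
#'
#' Parameters of a single synchrotron FLASH proton spill.
#'
#' @param energy beam energy, MeV.
#' @param n_protons protons extracted during the spill.
#' @param spill_duration spill length, s.
#' @param lateral_sigma standard deviation of the lateral Gaussian intensity
#'   profile, mm.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(energy = 142.4, n_protons = 3.1e10,
                      spill_duration = 0.100, lateral_sigma = 7.0) {
  stopifnot(energy > 0, n_protons >= 0, spill_duration > 0, lateral_sigma > 0)
  structure(list(energy = energy, n_protons = n_protons,
                 spill_duration = spill_duration,
                 lateral_sigma = lateral_sigma), class = "beam_spec")
}

#' Detection-efficiency model
#'
#' Factors of the expected-coincidence chain: geometric fraction `f_geom`
#' (from [fractional_solid_angle()]), the two-photon annihilation branching
#' ratio `f_2gamma`, and the single-photon detection probability `eps_gamma`.
#'
#' @param f_geom geometric fraction in (0, 1]; computed from `geom` if NULL.
#' @param f_2gamma two-photon branch fraction.
#' @param eps_gamma single-photon detection probability.
#' @param geom optional `scanner_geometry` used when `f_geom` is NULL.
#' @return object of class `efficiency_model`.
#' @export
efficiency_model <- function(f_geom = NULL, f_2gamma = 0.998, eps_gamma = 0.8,
                             geom = NULL) {
  if (is.null(f_geom)) {
    if (is.null(geom)) stop("supply f_geom or a scanner_geometry")
    f_geom <- fractional_solid_angle(geom)
  }
  stopifnot(f_geom > 0, f_geom <= 1, f_2gamma > 0, f_2gamma <= 1,
            eps_gamma > 0, eps_gamma <= 1)
  structure(list(f_geom = f_geom, f_2gamma = f_2gamma,
                 eps_gamma = eps_gamma), class = "efficiency_model")
}

#' Default positron-emitting-nucleus inventory
#'
#' The six species produced by 142 MeV protons in solid water, with their
#' half-lives and, where established for this beam/phantom combination, the
#' per-proton production yield at the scanner field of view (11C, 15O, 13N,
#' from the major channels 12C(p,pn)11C, 16O(p,pn)15O and 16O(p,2p2n)13N).
#' 12N is flagged non-budgeted: its 11 ms half-life makes its contribution to
#' any post-spill count budget negligible. 10C and 14O carry no default yield
#' and enter budgets only if one is supplied.
#'
#' @return data.frame of class `isotope_table` with columns `name`,
#'   `half_life` (s), `decay_constant` (1/s), `yield_per_proton`,
#'   `initial_count`, `budgeted`.
#' @examples
#' tab <- default_isotope_table()
#' tab[tab$name == "11C", "half_life"]  # 1224 s
#' @export
default_isotope_table <- function() {
  tab <- data.frame(
    name = c("10C", "11C", "12N", "13N", "14O", "15O"),
    half_life = c(19.3, 1224, 0.011, 598, 70.9, 122),
    yield_per_proton = c(NA, 2.2e-3, NA, 9.2e-5, NA, 5.1e-4),
    initial_count = NA_real_,
    budgeted = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  tab$decay_constant <- log(2) / tab$half_life
  tab <- tab[, c("name", "half_life", "decay_constant", "yield_per_proton",
                 "initial_count", "budgeted")]
  class(tab) <- c("isotope_table", "data.frame")
  tab
}

#' Set initial nucleus counts from beam and yields
#'
#' `N(0) = yield_per_proton * n_protons`, production treated as instantaneous
#' at the end of the spill (t = 0): the 100 ms spill is far shorter than any
#' budgeted half-life, so in-spill decay is negligible for the analytic
#' budget. Species without a yield are skipped with a warning and excluded
#' from budgets.
#'
#' @param beam a `beam_spec`.
#' @param table an `isotope_table`.
#' @return the table with `initial_count` filled in.
#' @export
initial_inventory <- function(beam, table = default_isotope_table()) {
  stopifnot(inherits(beam, "beam_spec"))
  miss <- is.na(table$yield_per_proton) & table$budgeted
  if (any(miss)) {
    warning("no yield for budgeted species: ",
            paste(table$name[miss], collapse = ", "), "; skipped")
    table$budgeted[miss] <- FALSE
  }
  has <- !is.na(table$yield_per_proton)
  table$initial_count[has] <- table$yield_per_proton[has] * beam$n_protons
  table
}

species_row <- function(species, table = NULL) {
  if (is.character(species)) {
    if (is.null(table)) table <- default_isotope_table()
    i <- match(species, table$name)
    if (is.na(i)) stop("unknown species: ", species)
    species <- table[i, ]
  }
  if (is.null(species$decay_constant))
    species$decay_constant <- log(2) / species$half_life
  species
}

#' Activity of one species
#'
#' `A(t) = lambda * N(0) * exp(-lambda t)` in decays/s, for t >= 0 measured
#' from the end of the spill.
#'
#' @param species a row of an `isotope_table` (or a list with
#'   `decay_constant` and `initial_count`).
#' @param t time(s) since end of spill, s; vectorized.
#' @return activity in decays/s.
#' @export
activity <- function(species, t) {
  species <- species_row(species)
  if (any(t < 0)) stop("t must be >= 0")
  if (is.na(species$initial_count)) stop("initial_count not set")
  lam <- species$decay_constant
  lam * species$initial_count * exp(-lam * t)
}

#' Expected decays in a time interval
#'
#' `N(0) * (exp(-lambda t_start) - exp(-lambda t_end))`; additive over
#' abutting intervals (exact decay-budget conservation).
#'
#' @param species a row of an `isotope_table`.
#' @param t_start,t_end interval bounds, s (0 <= t_start < t_end; `t_end` may
#'   be Inf). Vectorized over intervals.
#' @return expected decay count(s).
#' @export
decays_in_interval <- function(species, t_start, t_end) {
  species <- species_row(species)
  if (any(t_start < 0)) stop("t_start must be >= 0")
  if (any(t_end <= t_start)) stop("t_end must exceed t_start")
  if (is.na(species$initial_count)) stop("initial_count not set")
  lam <- species$decay_constant
  species$initial_count * (exp(-lam * t_start) - exp(-lam * t_end))
}

#' Expected measured coincidences from per-species decay counts
#'
#' The detection-chain budget: `sum_k D_k * f_geom * f_2gamma * eps_gamma^2`.
#' The squared single-photon efficiency reflects that both annihilation
#' photons must be detected, while the geometric fraction enters once because
#' back-to-back photons are captured or lost as a pair by an even panel ring.
#'
#' @param decay_counts numeric vector of per-species decay counts `D_k`.
#' @param eff an `efficiency_model`.
#' @return expected coincidence count.
#' @export
expected_coincidences <- function(decay_counts, eff) {
  stopifnot(inherits(eff, "efficiency_model"))
  sum(decay_counts) * eff$f_geom * eff$f_2gamma * eff$eps_gamma^2
}

#' Per-window, per-species expected decay counts
#'
#' Integrates each budgeted species' activity curve over a schedule of
#' non-overlapping, ascending time windows; the analytic counterpart of the
#' measured per-window coincidence histogram (up to the detection chain).
#'
#' @param table an `isotope_table` with `initial_count` set.
#' @param windows two-column matrix or data.frame of `t_start`, `t_end` in s.
#' @param budgeted_only integrate only budgeted species (default TRUE).
#' @return matrix (species x windows) of expected decay counts.
#' @export
window_expectations <- function(table, windows, budgeted_only = TRUE) {
  windows <- as.matrix(windows)
  if (ncol(windows) != 2) stop("windows must have two columns")
  if (any(windows[, 2] <= windows[, 1])) stop("each window needs t_end > t_start")
  if (nrow(windows) > 1) {
    o <- order(windows[, 1])
    windows <- windows[o, , drop = FALSE]
    if (any(windows[-1, 1] < windows[-nrow(windows), 2]))
      stop("windows must be non-overlapping")
  }
  rows <- if (budgeted_only) which(table$budgeted) else seq_len(nrow(table))
  out <- t(vapply(rows, function(i)
    decays_in_interval(table[i, ], windows[, 1], windows[, 2]),
    numeric(nrow(windows))))
  rownames(out) <- table$name[rows]
  colnames(out) <- sprintf("[%g,%g)", windows[, 1], windows[, 2])
  out
}

#' Mean-matching normalization of simulated window totals
#'
#' Rescales simulated per-window counts so that their mean equals the mean of
#' the measured counts, the standard normalization when comparing a
#' simulation in arbitrary units against measured coincidence counts.
#'
#' @param sim_totals simulated per-window totals.
#' @param measured_totals measured per-window totals (same length).
#' @return rescaled `sim_totals`.
#' @export
normalize_mean <- function(sim_totals, measured_totals) {
  if (length(sim_totals) != length(measured_totals))
    stop("window counts differ in length")
  if (mean(measured_totals) <= 0) stop("measured mean must be positive")
  if (mean(sim_totals) <= 0) stop("simulated mean must be positive")
  sim_totals * mean(measured_totals) / mean(sim_totals)
}

#' Full activation/detection budget report
#'
#' Convenience wrapper chaining yields -> N(0) -> per-species decays in
#' `[0, horizon]` -> expected measured coincidences.
#'
#' @param beam a `beam_spec`.
#' @param eff an `efficiency_model`.
#' @param table an `isotope_table`.
#' @param horizon budget horizon, s (default 660 = 11 min).
#' @return list with the filled table, `decays` (named per-species vector),
#'   `f_geom`, and `n_measure`.
#' @export
activation_budget <- function(beam, eff, table = default_isotope_table(),
                              horizon = 660) {
  table <- initial_inventory(beam, table)
  rows <- which(table$budgeted)
  decays <- vapply(rows, function(i)
    decays_in_interval(table[i, ], 0, horizon), numeric(1))
  names(decays) <- table$name[rows]
  list(table = table, decays = decays, f_geom = eff$f_geom,
       horizon = horizon, n_measure = expected_coincidences(decays, eff))
}
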