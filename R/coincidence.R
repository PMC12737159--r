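#' Coincidence selection policy
#'
#' @param window_ns coincidence time window, ns (inclusive bound).
#' @param energy_low,energy_high energy window, keV (inclusive bounds).
#' @param multiples policy for windows holding three or more singles;
#'   only `"discard_all"` is defined (ambiguous events are dropped whole).
#' @return object of class `coincidence_policy`.
#' @export
coincidence_policy <- function(window_ns = 10, energy_low = 360,
                               energy_high = 650,
                               multiples = "discard_all") {
  stopifnot(window_ns > 0, energy_low < energy_high)
  multiples <- match.arg(multiples)
  structure(list(window_ns = window_ns, energy_low = energy_low,
                 energy_high = energy_high, multiples = multiples),
            class = "coincidence_policy")
}

#' Route singles to per-panel-pair substreams
#'
#' Mirrors the distributed coincidence processors: each allowed panel pair
#' gets the merged, still time-sorted substream of singles on its two panels.
#' A single therefore appears in every substream its panel belongs to
#' (7 substreams per panel for the 12-panel, separation-3 ring).
#'
#' @param singles a time-sorted `singles_stream`.
#' @param geom a `scanner_geometry`.
#' @return named list (one entry per pair, `"a-b"`) of substreams; each row
#'   keeps its global index in column `gid`.
#' @export
route_to_pairs <- function(singles, geom) {
  assert_sorted(singles)
  if (nrow(singles) > 0 &&
      (any(singles$panel < 0) || any(singles$panel >= geom$n_panels)))
    stop("single on unknown panel")
  singles$gid <- seq_len(nrow(singles))
  out <- lapply(seq_len(nrow(geom$pairs)), function(i) {
    pa <- geom$pairs[i, 1]
    pb <- geom$pairs[i, 2]
    sub <- singles[singles$panel == pa | singles$panel == pb, , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- sprintf("%d-%d", geom$pairs[, 1], geom$pairs[, 2])
  out
}

# transitive-closure grouping: singles chained by gaps <= window share a group
group_singles <- function(substream, window_ns) {
  n <- nrow(substream)
  if (n == 0) return(integer(0))
  cumsum(c(TRUE, diff(substream$time_ns) > window_ns))
}

#' Pair singles of one substream into coincidences
#'
#' Greedy transitive grouping at the time window followed by multiples
#' removal: singles whose successive gaps are within `window_ns` merge into
#' one group; a group is a valid coincidence only if it holds exactly two
#' singles on opposite panels of the pair. Groups of three or more are
#' ambiguous and discarded whole; same-panel doubles and orphans yield
#' nothing.
#'
#' @param substream one pair substream from [route_to_pairs()].
#' @param policy a `coincidence_policy`.
#' @return data.frame of raw coincidences (before energy filtering) with
#'   columns `time_ns` (earlier single), `panel_a`, `row_a`, `col_a`,
#'   `energy_a`, `panel_b`, ..., `gid_a`, `gid_b`, `id_a`, `id_b`.
#' @export
pair_window <- function(substream, policy = coincidence_policy()) {
  assert_sorted(substream)
  grp <- group_singles(substream, policy$window_ns)
  remove_multiples(substream, grp, policy)
}

#' Resolve grouped singles into two-photon coincidences
#'
#' @param substream the substream whose rows `groups` indexes.
#' @param groups integer group labels from the transitive time-window closure.
#' @param policy a `coincidence_policy`.
#' @return as [pair_window()]; multiples-dropped group count in
#'   `attr(, "n_multiples")`.
#' @export
remove_multiples <- function(substream, groups, policy = coincidence_policy()) {
  if (nrow(substream) == 0) {
    out <- empty_coincidences()
    attr(out, "n_multiples") <- 0L
    return(out)
  }
  sizes <- tabulate(groups)
  n_mult <- sum(sizes >= 3)
  two <- which(sizes == 2)
  first <- match(two, groups)           # groups sorted by time; members adjacent
  second <- first + 1L
  ok <- substream$panel[first] != substream$panel[second]
  first <- first[ok]
  second <- second[ok]
  has_id <- "id" %in% names(substream)
  out <- data.frame(
    time_ns = substream$time_ns[first],
    panel_a = substream$panel[first], row_a = substream$row[first],
    col_a = substream$col[first], energy_a = substream$energy_keV[first],
    panel_b = substream$panel[second], row_b = substream$row[second],
    col_b = substream$col[second], energy_b = substream$energy_keV[second],
    gid_a = if (!is.null(substream$gid)) substream$gid[first] else first,
    gid_b = if (!is.null(substream$gid)) substream$gid[second] else second,
    id_a = if (has_id) substream$id[first] else NA_integer_,
    id_b = if (has_id) substream$id[second] else NA_integer_)
  attr(out, "n_multiples") <- n_mult
  out
}

empty_coincidences <- function() {
  data.frame(time_ns = numeric(0), panel_a = integer(0), row_a = integer(0),
             col_a = integer(0), energy_a = numeric(0), panel_b = integer(0),
             row_b = integer(0), col_b = integer(0), energy_b = numeric(0),
             gid_a = integer(0), gid_b = integer(0), id_a = integer(0),
             id_b = integer(0))
}

#' Energy-window filter
#'
#' Keeps coincidences with BOTH energies inside
#' `[energy_low, energy_high]`, inclusive.
#'
#' @param coincidences a coincidence data.frame.
#' @param policy a `coincidence_policy`.
#' @return the filtered data.frame.
#' @export
energy_filter <- function(coincidences, policy = coincidence_policy()) {
  keep <- coincidences$energy_a >= policy$energy_low &
    coincidences$energy_a <= policy$energy_high &
    coincidences$energy_b >= policy$energy_low &
    coincidences$energy_b <= policy$energy_high
  out <- coincidences[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full coincidence selection chain
#'
#' Routes singles to the allowed panel-pair substreams, pairs each substream
#' independently (time-window grouping + multiples removal), enforces global
#' single use (a single claimed by coincidences on more than one pair is
#' ambiguous: all its coincidences are dropped), applies the energy window,
#' and returns the merged, time-sorted coincidence stream.
#'
#' @param singles a time-sorted `singles_stream`.
#' @param geom a `scanner_geometry`.
#' @param policy a `coincidence_policy`.
#' @return data.frame of class `coincidence_stream`; accounting (pairs
#'   formed, multiples dropped, cross-pair conflicts, energy-window dropped)
#'   in `attr(, "accounting")`.
#' @export
find_coincidences <- function(singles, geom, policy = coincidence_policy()) {
  subs <- route_to_pairs(singles, geom)
  parts <- lapply(subs, pair_window, policy = policy)
  n_mult <- sum(vapply(parts, attr, 0L, "n_multiples"))
  cc <- do.call(rbind, c(parts, list(empty_coincidences())))
  rownames(cc) <- NULL

  # global single-use: with ring separation >= min_panel_separation a true
  # photon pair satisfies exactly one panel pair, but a single can still be
  # claimed on several pairs through accidental neighbors
  used <- c(cc$gid_a, cc$gid_b)
  dup <- unique(used[duplicated(used)])
  n_conflict <- 0L
  if (length(dup) > 0) {
    bad <- cc$gid_a %in% dup | cc$gid_b %in% dup
    n_conflict <- sum(bad)
    cc <- cc[!bad, , drop = FALSE]
  }

  n_raw <- nrow(cc)
  cc <- energy_filter(cc, policy)
  cc <- cc[order(cc$time_ns, cc$panel_a, cc$panel_b), , drop = FALSE]
  rownames(cc) <- NULL
  attr(cc, "accounting") <- c(singles_in = nrow(singles),
                              multiples_dropped = n_mult,
                              crosspair_dropped = n_conflict,
                              paired = n_raw,
                              energy_dropped = n_raw - nrow(cc),
                              accepted = nrow(cc))
  class(cc) <- c("coincidence_stream", "data.frame")
  cc
}

#' Histogram event times
#'
#' Left-closed, right-open bins of fixed width on `[t_start, t_end)`; events
#' outside the range are counted in an overflow tally.
#'
#' @param events data.frame with a `time_ns` column.
#' @param bin_width bin width, s.
#' @param t_start,t_end histogram range, s.
#' @return object of class `time_histogram`: list with `edges` (s), `counts`,
#'   `overflow`.
#' @export
histogram_times <- function(events, bin_width, t_start = 0,
                            t_end = t_start + bin_width) {
  stopifnot(bin_width > 0, t_end > t_start)
  edges <- seq(t_start, t_end, by = bin_width)
  if (abs(edges[length(edges)] - t_end) > 1e-12)
    edges <- c(edges, t_end)
  t <- events$time_ns * 1e-9
  inside <- t >= t_start & t < t_end
  idx <- findInterval(t[inside], edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(list(edges = edges, counts = counts,
                 overflow = sum(!inside)), class = "time_histogram")
}

#' @export
print.time_histogram <- function(x, ...) {
  cat(sprintf("<time_histogram> %d bins on [%g, %g] s, %d events (+%d overflow)\n",
              length(x$counts), x$edges[1], x$edges[length(x$edges)],
              sum(x$counts), x$overflow))
  invisible(x)
}

#' Singles energy spectrum
#'
#' Equal-width bins on [0, cutoff] keV; events above the cutoff are tallied
#' as overflow. `peak_bin` locates the modal bin.
#'
#' @param singles a `singles_stream` (or any frame with `energy_keV`).
#' @param n_bins number of bins.
#' @param cutoff upper energy cutoff, keV.
#' @return object of class `energy_spectrum`: list with `edges`, `counts`,
#'   `overflow`, `peak_bin` (NA when empty).
#' @export
energy_spectrum <- function(singles, n_bins = 40, cutoff = 800) {
  stopifnot(n_bins > 0, cutoff > 0)
  edges <- seq(0, cutoff, length.out = n_bins + 1)
  e <- singles$energy_keV
  inside <- e >= 0 & e < cutoff
  idx <- findInterval(e[inside], edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = n_bins)
  peak <- if (sum(counts) == 0) NA_integer_ else which.max(counts)
  structure(list(edges = edges, counts = counts, overflow = sum(e >= cutoff),
                 peak_bin = peak), class = "energy_spectrum")
}

#' Write / read list-mode coincidences
#'
#' Tab-separated text with header `#flashpet-coinc v1` and columns `time_ns`,
#' `panel_a`, `row_a`, `col_a`, `energy_a`, `panel_b`, `row_b`, `col_b`,
#' `energy_b`.
#'
#' @param cc a `coincidence_stream`.
#' @param path file path.
#' @export
write_coincidences <- function(cc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#flashpet-coinc v1", con)
  hdr <- c("time_ns", "panel_a", "row_a", "col_a", "energy_a",
           "panel_b", "row_b", "col_b", "energy_b")
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(cc) > 0)
    writeLines(sprintf("%.0f\t%d\t%d\t%d\t%.1f\t%d\t%d\t%d\t%.1f",
                       cc$time_ns, cc$panel_a, cc$row_a, cc$col_a,
                       cc$energy_a, cc$panel_b, cc$row_b, cc$col_b,
                       cc$energy_b), con)
  invisible(path)
}

#' @rdname write_coincidences
#' @export
read_coincidences <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != "#flashpet-coinc v1")
    stop("not a flashpet coincidence file (bad header): ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  cols <- c("time_ns", "panel_a", "row_a", "col_a", "energy_a",
            "panel_b", "row_b", "col_b", "energy_b")
  if (length(body) == 0) {
    out <- as.data.frame(sapply(cols, function(x) numeric(0),
                                simplify = FALSE))
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9))
      stop("malformed record at line ", which(nf != 9)[1] + 2, " of ", path)
    m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 9,
                byrow = TRUE)
    if (anyNA(m))
      stop("malformed record at line ",
           which(apply(is.na(m), 1, any))[1] + 2, " of ", path)
    out <- as.data.frame(m)
    names(out) <- cols
    for (j in c(2, 3, 4, 6, 7, 8)) out[[j]] <- as.integer(out[[j]])
  }
  class(out) <- c("coincidence_stream", "data.frame")
  out
}
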