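# shared fixtures, all built in code

default_geom <- build_scanner()
default_eff <- efficiency_model(geom = default_geom)

# a stream of annihilations all at one point, evenly spaced in time
point_annihilations <- function(p, n, spacing_ns = 1e6) {
  ann <- data.frame(time_ns = seq(0, by = spacing_ns, length.out = n),
                    x = p[1], y = p[2], z = p[3], species = "11C",
                    id = seq_len(n))
  class(ann) <- c("annihilation_stream", "data.frame")
  ann
}

# hand-made singles stream (0-based crystal indices)
make_singles <- function(time_ns, panel, row = 15L, col = 15L,
                         energy = 511, id = NA_integer_) {
  n <- length(time_ns)
  s <- data.frame(time_ns = time_ns, panel = as.integer(panel),
                  row = rep_len(as.integer(row), n),
                  col = rep_len(as.integer(col), n),
                  energy_keV = rep_len(energy, n),
                  id = rep_len(id, n))
  s <- s[order(s$time_ns, s$panel, s$row, s$col), ]
  rownames(s) <- NULL
  class(s) <- c("singles_stream", "data.frame")
  s
}

# piecewise-linear depth profile with an exact distal half crossing at r50
linear_falloff_profile <- function(r50, half_width = 0.3, dmax = 20,
                                   step = 0.1) {
  d <- seq(0, dmax, by = step)
  v <- pmin(1, pmax(0, (r50 + half_width - d) / (2 * half_width)))
  structure(data.frame(depth = d, intensity = v),
            class = c("depth_profile", "data.frame"))
}

# inventory with the published initial nucleus counts
printed_inventory <- function() {
  tab <- default_isotope_table()
  tab$initial_count[match(c("11C", "13N", "15O"), tab$name)] <-
    c(6.7e7, 2.8e6, 1.6e7)
  tab
}
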