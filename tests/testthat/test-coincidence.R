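test_that("routing mirrors one processor per allowed panel pair", {
  geom <- default_geom
  s <- make_singles(1000, panel = 0L)
  subs <- route_to_pairs(s, geom)
  expect_length(subs, 42)
  expect_equal(sum(vapply(subs, nrow, 0L)), 7)  # 7 pairs contain panel 0

  empty <- route_to_pairs(make_singles(numeric(0), integer(0)), geom)
  expect_true(all(vapply(empty, nrow, 0L) == 0))

  set.seed(3)
  many <- make_singles(sort(round(runif(500, 0, 1e6))),
                       panel = sample(0:11, 500, TRUE))
  subs <- route_to_pairs(many, geom)
  for (sub in subs) expect_true(all(diff(sub$time_ns) >= 0))

  bad <- make_singles(1, panel = 99L)
  expect_error(route_to_pairs(bad, geom), "unknown panel")
})

test_that("time-window pairing keeps doubles and respects the 10 ns bound", {
  pol <- coincidence_policy()
  sub <- make_singles(c(100, 105), panel = c(0L, 6L))
  expect_equal(nrow(pair_window(sub, pol)), 1)
  expect_equal(pair_window(sub, pol)$time_ns, 100)

  # inclusive at exactly 10 ns, broken at 11
  expect_equal(nrow(pair_window(make_singles(c(100, 110), c(0L, 6L)), pol)), 1)
  expect_equal(nrow(pair_window(make_singles(c(100, 111), c(0L, 6L)), pol)), 0)

  # same-panel double is no coincidence
  expect_equal(nrow(pair_window(make_singles(c(100, 105), c(6L, 6L)), pol)), 0)
})

test_that("multiple coincidences are discarded whole", {
  pol <- coincidence_policy()
  trip <- make_singles(c(100, 104, 108), panel = c(0L, 6L, 0L))
  out <- pair_window(trip, pol)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_multiples"), 1L)

  # chained events merge transitively even when the extremes are > 10 ns apart
  chain <- make_singles(c(100, 109, 118), panel = c(0L, 6L, 0L))
  expect_equal(nrow(pair_window(chain, pol)), 0)

  # a pair plus a distant orphan
  mix <- make_singles(c(100, 105, 155), panel = c(0L, 6L, 0L))
  expect_equal(nrow(pair_window(mix, pol)), 1)

  # two well-separated pairs
  two <- make_singles(c(100, 104, 500, 503), panel = c(0L, 6L, 6L, 0L))
  expect_equal(nrow(pair_window(two, pol)), 2)
})

test_that("energy filter keeps both-in-window events, bounds inclusive", {
  pol <- coincidence_policy()
  cc <- data.frame(energy_a = c(511, 300, 360, 651, 650),
                   energy_b = c(511, 511, 650, 511, 360))
  out <- energy_filter(cc, pol)
  expect_equal(nrow(out), 3)
  expect_true(all(out$energy_a >= 360 & out$energy_a <= 650))
})

test_that("clean simulation: accepted coincidences are exactly the recorded pairs", {
  # no blur, no background, no dead time: selection must find precisely the
  # annihilations whose two photons were both recorded
  ann <- point_annihilations(c(0, 0, -5), 20000)
  s <- emit_and_detect(ann, default_geom, default_eff, blur_params(0, 0),
                       seed = 21)
  cc <- find_coincidences(s, default_geom)
  expect_equal(nrow(cc), sum(table(s$id) == 2))
  expect_true(all(cc$id_a == cc$id_b))
})

test_that("pure background yields the standard randoms rate per pair", {
  # uncorrelated singles on panels 0 and 6 only: accepted rate ~ 2 Ra Rb tau
  set.seed(31)
  Ra <- 2e4; T <- 10
  s <- make_singles(sort(round(runif(2 * Ra * T, 0, T * 1e9))),
                    panel = sample(c(0L, 6L), 2 * Ra * T, TRUE))
  cc <- find_coincidences(s, default_geom)
  expected <- 2 * Ra * Ra * 10e-9 * T
  expect_lt(abs(nrow(cc) - expected), 3 * sqrt(expected) + 0.05 * expected)
})

test_that("accepted streams never violate the time or energy contracts", {
  ann <- point_annihilations(c(0, 0, 0), 30000)
  s <- emit_and_detect(ann, default_geom, default_eff, seed = 22)
  s <- add_background(s, 5000, duration = 0.03, geom = default_geom,
                      seed = 23)
  cc <- find_coincidences(s, default_geom)
  expect_gt(nrow(cc), 100)
  expect_true(all(cc$energy_a >= 360 & cc$energy_a <= 650))
  expect_true(all(cc$energy_b >= 360 & cc$energy_b <= 650))
  # both members lie within the window (time stamp is the earlier single)
  sep <- abs(cc$panel_a - cc$panel_b)
  expect_true(all(pmin(sep, 12 - sep) >= 3))
})

test_that("per-pair processing is order-independent", {
  ann <- point_annihilations(c(0, 0, 0), 5000)
  s <- emit_and_detect(ann, default_geom, default_eff, seed = 24)
  subs <- route_to_pairs(s, default_geom)
  pol <- coincidence_policy()
  forward <- do.call(rbind, lapply(subs, pair_window, policy = pol))
  backward <- do.call(rbind, lapply(rev(subs), pair_window, policy = pol))
  key <- function(d) d[order(d$time_ns, d$gid_a), ]
  expect_equal(key(forward)[, 1:9], key(backward)[, 1:9],
               ignore_attr = TRUE)
})

test_that("time histograms use left-closed bins and count overflow", {
  ev <- data.frame(time_ns = c(0, 19.9e6, 20e6, 999e6, 1.5e9))
  h <- histogram_times(ev, 0.02, 0, 1)
  expect_length(h$counts, 50)
  expect_equal(h$counts[1], 2)   # 0 and 19.9 ms
  expect_equal(h$counts[2], 1)   # 20 ms starts bin 2
  expect_equal(h$overflow, 1)

  h11 <- histogram_times(data.frame(time_ns = 60e9 * (0:10)), 60, 0, 660)
  expect_length(h11$counts, 11)
  expect_equal(sum(h11$counts), 11)

  set.seed(41)
  u <- data.frame(time_ns = runif(5000, 0, 1e9))
  hu <- histogram_times(u, 0.02, 0, 1)
  expect_true(all(abs(hu$counts - 100) < 3 * sqrt(100) + 10))
})

test_that("energy spectrum bins, peak locator, and overflow behave", {
  s <- data.frame(energy_keV = rnorm(5000, 511, 30))
  sp <- energy_spectrum(s)
  expect_length(sp$counts, 40)
  expect_true(sp$edges[sp$peak_bin] <= 511 && 511 < sp$edges[sp$peak_bin + 1])

  zero <- energy_spectrum(data.frame(energy_keV = numeric(0)))
  expect_true(all(zero$counts == 0))
  expect_true(is.na(zero$peak_bin))

  hot <- energy_spectrum(data.frame(energy_keV = c(900, 1000)))
  expect_true(all(hot$counts == 0))
  expect_equal(hot$overflow, 2)
})

test_that("coincidence files round-trip through the text format", {
  ann <- point_annihilations(c(0, 0, 0), 5000)
  s <- emit_and_detect(ann, default_geom, default_eff, seed = 25)
  cc <- find_coincidences(s, default_geom)
  path <- tempfile(fileext = ".tsv")
  write_coincidences(cc, path)
  back <- read_coincidences(path)
  expect_equal(as.data.frame(back),
               as.data.frame(cc)[, names(back)], ignore_attr = TRUE)
})
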