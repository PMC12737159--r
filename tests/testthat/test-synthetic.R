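test_that("activation map crosses half its plateau at the requested depth", {
  beam <- beam_spec()
  map <- build_activation_map(beam, grid = image_grid(), r50_depth = 8.3)
  marg <- apply(map$weights, 3, sum)
  depth <- grid_centers(map$grid, 3) + 18
  plateau <- max(marg)
  i <- max(which(marg >= plateau / 2))
  cross <- depth[i] + (marg[i] - plateau / 2) / (marg[i] - marg[i + 1])
  expect_lt(abs(cross - 8.3), 0.5)

  expect_error(build_activation_map(beam, grid = image_grid(),
                                    r50_depth = 50), "inside the grid")
})

test_that("lateral positions reproduce the beam's Gaussian sigma", {
  # wide phantom so the Gaussian parameter itself is observable; the default
  # 28 mm phantom truncates the profile at 2 sigma and shrinks the sample sd
  map <- build_activation_map(beam_spec(), phantom_spec(diameter = Inf),
                              image_grid(), r50_depth = 8.3)
  inv <- printed_inventory()
  ann <- sample_annihilations(map, inv, 660, seed = 4, count_scale = 1e5 /
                                sum(vapply(which(inv$budgeted), function(i)
                                  decays_in_interval(inv[i, ], 0, 660),
                                  numeric(1))))
  plateau <- ann$z + 18 < 5
  expect_gt(sum(plateau), 1e4)
  expect_lt(abs(sd(ann$x[plateau]) - 7.0), 0.2)
  expect_lt(abs(sd(ann$y[plateau]) - 7.0), 0.2)
})

test_that("shifting the beam center translates the map's center of mass", {
  b <- beam_spec()
  g <- image_grid()
  m0 <- build_activation_map(b, grid = g, r50_depth = 8.3)
  m5 <- build_activation_map(b, grid = g, r50_depth = 8.3,
                             beam_center = c(5, 0))
  xc <- grid_centers(g, 1)
  com <- function(m) sum(xc * apply(m$weights, 1, sum))
  expect_equal(com(m5) - com(m0), 5, tolerance = 1e-9)
})

test_that("annihilation sampling follows Poisson counts and the decay law", {
  inv <- printed_inventory()
  inv$budgeted <- inv$name == "15O"    # isolate one species
  map <- build_activation_map(beam_spec(), grid = image_grid(),
                              r50_depth = 8.3)
  mu <- 1e4
  cs <- mu / decays_in_interval(inv[inv$name == "15O", ], 0, 660)
  ann <- sample_annihilations(map, inv, 660, seed = 10, count_scale = cs)
  expect_lt(abs(nrow(ann) - mu), 3 * sqrt(mu))

  # truncated-exponential mean over ten half-lives
  lam <- log(2) / 122
  T <- 1220
  ann2 <- sample_annihilations(map, inv, T, seed = 11, count_scale = cs)
  m_theory <- 1 / lam - T * exp(-lam * T) / (1 - exp(-lam * T))
  se <- (1 / lam) / sqrt(nrow(ann2))
  expect_lt(abs(mean(ann2$time_ns) * 1e-9 - m_theory), 3 * se)
})

test_that("the generator is byte-reproducible from its seed", {
  map <- build_activation_map(beam_spec(), grid = image_grid(),
                              r50_depth = 8.3)
  inv <- printed_inventory()
  a1 <- sample_annihilations(map, inv, 60, seed = 5, count_scale = 1e-4)
  a2 <- sample_annihilations(map, inv, 60, seed = 5, count_scale = 1e-4)
  expect_identical(a1, a2)

  s1 <- emit_and_detect(a1, default_geom, default_eff, seed = 6)
  s2 <- emit_and_detect(a2, default_geom, default_eff, seed = 6)
  expect_identical(s1, s2)
})

test_that("pair detection from a centered point source follows the chain", {
  n <- 40000
  ann <- point_annihilations(c(0, 0, 0), n)

  # epsilon = 1, no blur: a pair is captured or lost whole, so the fraction
  # of annihilations with any recorded photon equals f_geom
  eff1 <- efficiency_model(f_2gamma = 1, eps_gamma = 1, geom = default_geom)
  s1 <- emit_and_detect(ann, default_geom, eff1, blur_params(0, 0), seed = 2)
  f <- fractional_solid_angle(default_geom)
  frac_any <- length(unique(s1$id)) / n
  expect_lt(abs(frac_any - f), 3 * sqrt(f * (1 - f) / n))

  # with the study chain, both-photon capture is f_geom * f_2g * eps^2
  s2 <- emit_and_detect(ann, default_geom, default_eff, seed = 3)
  p <- f * 0.998 * 0.8^2
  frac_pair <- sum(table(s2$id) == 2) / n
  expect_lt(abs(frac_pair - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("recorded energies peak at 511 keV", {
  ann <- point_annihilations(c(0, 0, 0), 50000)
  s <- emit_and_detect(ann, default_geom, default_eff, seed = 4)
  expect_gt(nrow(s), 1e4)
  spec <- energy_spectrum(s)
  expect_true(spec$edges[spec$peak_bin] <= 511 &&
                511 < spec$edges[spec$peak_bin + 1])
})

test_that("per-pair dead time caps the accepted rate and spares slow streams", {
  geom <- default_geom
  # 1e6 singles/s alternating across one panel pair for 0.05 s
  set.seed(13)
  t <- sort(round(runif(50000, 0, 0.05) * 1e9))
  s <- make_singles(t, panel = rep(c(0L, 6L), length.out = 50000))
  out <- apply_dead_time(s, geom, 2.5e5)
  rate <- nrow(out) / 0.05
  expect_lte(rate, 2.6e5)   # cap + in-window frame partners
  # non-paralyzable throughput: lambda / (1 + lambda * tau)
  expect_lt(abs(rate - 1e6 / (1 + 1e6 * 4e-6)), 1.5e4)

  # far below the cap: untouched
  slow <- make_singles(seq(0, 1e9, by = 1e5), panel = 3L)
  expect_equal(nrow(apply_dead_time(slow, geom, 2.5e5)), nrow(slow))

  # inclusive boundary at exactly 1/max_rate
  two <- make_singles(c(0, 4000), panel = c(0L, 6L))
  expect_equal(nrow(apply_dead_time(two, geom, 2.5e5)), 2)

  unsorted <- make_singles(c(1, 5), panel = 0L)
  unsorted$time_ns <- c(5, 1)          # defeat the helper's sort
  expect_error(apply_dead_time(unsorted, geom), "sorted")
})

test_that("background singles are Poisson in count and flat in time/energy", {
  geom <- default_geom
  none <- add_background(make_singles(c(1, 2), panel = 0L), 0, 1, geom)
  expect_equal(nrow(none), 2)

  empty <- make_singles(numeric(0), panel = integer(0))
  bg <- add_background(empty, random_rate = 2000, duration = 10, geom,
                       seed = 12)
  expect_lt(abs(nrow(bg) - 20000), 3 * sqrt(20000))

  # energy-window retention of the flat 150-800 keV spectrum
  p <- (650 - 360) / (800 - 150)
  inwin <- mean(bg$energy_keV >= 360 & bg$energy_keV <= 650)
  expect_lt(abs(inwin - p), 3 * sqrt(p * (1 - p) / nrow(bg)))
})

test_that("list-mode files round-trip, and malformed input names its line", {
  ann <- point_annihilations(c(0, 0, 0), 30000)
  s <- emit_and_detect(ann, default_geom, default_eff, seed = 8)
  s$id <- NULL
  path <- tempfile(fileext = ".tsv")
  write_listmode(s, path)
  back <- read_listmode(path)
  expect_equal(as.data.frame(back), as.data.frame(s), ignore_attr = TRUE)

  # empty stream still writes a valid file
  empty <- s[0, ]
  write_listmode(empty, path)
  expect_equal(nrow(read_listmode(path)), 0)

  # corrupted record is reported with its line number
  write_listmode(s[1:5, ], path)
  lines <- readLines(path)
  lines[5] <- "12\t3\tbad\t4\t511.0"
  writeLines(lines, path)
  expect_error(read_listmode(path), "line 5")

  writeLines(c("#wrong header", lines[-1]), path)
  expect_error(read_listmode(path), "header")
})
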