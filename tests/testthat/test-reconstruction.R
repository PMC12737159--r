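grid10 <- image_grid(c(10, 10, 10))

test_that("axis-aligned Siddon trace yields unit chords through each voxel", {
  lor <- list(a = c(-20, 0.2, 0.3), b = c(20, 0.2, 0.3))
  tr <- siddon_trace(lor, grid10)
  expect_equal(nrow(tr), 10)
  expect_equal(tr$length, rep(1, 10), tolerance = 1e-9)
  expect_true(all(diff(tr$i) == 1))

  expect_error(siddon_trace(list(a = c(1, 1, 1), b = c(1, 1, 1)), grid10),
               "degenerate")
})

test_that("Siddon chords sum to the clipped segment length", {
  set.seed(51)
  box_lo <- grid10$lo
  box_hi <- grid10$lo + grid10$dims * grid10$vox
  clip_len <- function(a, b) {
    d <- b - a
    t0 <- 0; t1 <- 1
    for (ax in 1:3) {
      if (abs(d[ax]) < 1e-12) next
      tt <- sort(c((box_lo[ax] - a[ax]) / d[ax], (box_hi[ax] - a[ax]) / d[ax]))
      t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
    }
    max(0, t1 - t0) * sqrt(sum(d^2))
  }
  for (i in 1:200) {
    a <- runif(3, -30, 30); b <- runif(3, -30, 30)
    tr <- cpp_siddon(a, b, grid10$lo, grid10$dims, grid10$vox)
    expect_equal(sum(tr$length), clip_len(a, b), tolerance = 1e-9)
  }
})

test_that("Siddon agrees with a dense deterministic sampling oracle", {
  set.seed(52)
  n <- 1e4
  for (i in 1:20) {
    a <- runif(3, -15, 15); b <- runif(3, -15, 15)
    if (sum((a - b)^2) < 1) next
    tr <- siddon_trace(list(a = a, b = b), grid10)
    L <- sqrt(sum((b - a)^2))
    # midpoint-rule sampling along the full segment
    tt <- (seq_len(n) - 0.5) / n
    pts <- outer(tt, b - a) + rep(a, each = n)
    ijk <- floor(sweep(pts, 2, grid10$lo) / grid10$vox)
    ok <- apply(ijk >= 0 & sweep(ijk, 2, grid10$dims, `<`), 1, all)
    if (!any(ok)) {
      expect_equal(nrow(tr), 0)
      next
    }
    idx <- ijk[ok, 1] + grid10$dims[1] * (ijk[ok, 2] +
                                            grid10$dims[2] * ijk[ok, 3]) + 1
    sampled <- table(idx) * L / n
    for (j in seq_len(nrow(tr))) {
      s <- sampled[as.character(tr$index[j])]
      s <- if (is.na(s)) 0 else as.numeric(s)
      expect_lt(abs(tr$length[j] - s),
                pmax(0.02 * tr$length[j], 3 * L / n))
    }
  }
})

test_that("sensitivity is highest centrally and scales with LOR thinning", {
  geom <- build_scanner(crystals_per_side = 12)
  g <- image_grid(c(32, 32, 16), 2)
  s1 <- sensitivity_image(geom, g, keep_prob = 1, seed = 1)
  expect_gt(s1$values[16, 16, 8], s1$values[4, 16, 8])
  expect_gt(s1$values[16, 16, 8], s1$values[16, 16, 2])

  s2 <- sensitivity_image(geom, g, keep_prob = 0.5, seed = 2)
  core <- function(s) s$values[10:23, 10:23, 6:11]
  expect_equal(mean(core(s1)) / mean(core(s2)), 2, tolerance = 0.05)
  # and the thinned field tracks the full one voxel by voxel
  expect_gt(cor(as.numeric(core(s1)), as.numeric(core(s2))), 0.95)
})

test_that("sensitivity respects the ring's 30-degree rotational symmetry", {
  geom <- build_scanner(crystals_per_side = 10)
  g <- image_grid(c(48, 48, 12))
  s <- sensitivity_image(geom, g, keep_prob = 1, seed = 3)
  mid <- apply(s$values[, , 5:8], c(1, 2), sum)
  xc <- grid_centers(g, 1)
  yc <- grid_centers(g, 2)
  interp <- function(x, y) {
    i <- findInterval(x, xc); j <- findInterval(y, yc)
    fx <- (x - xc[i]); fy <- (y - yc[j])
    mid[i, j] * (1 - fx) * (1 - fy) + mid[i + 1, j] * fx * (1 - fy) +
      mid[i, j + 1] * (1 - fx) * fy + mid[i + 1, j + 1] * fx * fy
  }
  set.seed(3)
  th <- runif(200, 0, 2 * pi)
  rr <- sqrt(runif(200, 3^2, 12^2))
  v0 <- mapply(function(r, t) interp(r * cos(t), r * sin(t)), rr, th)
  v1 <- mapply(function(r, t) interp(r * cos(t + pi / 6), r * sin(t + pi / 6)),
               rr, th)
  expect_lt(abs(mean(v1) / mean(v0) - 1), 0.02)
  expect_lt(median(abs(v1 / v0 - 1)), 0.02)
})

test_that("MLEM recovers a point source and honors its update guarantees", {
  geom <- default_geom
  g <- image_grid()
  sens <- sensitivity_image(geom, g, keep_prob = 1 / 8, seed = 4)
  ann <- point_annihilations(c(0.2, 0.2, 0.2), 20000)
  eff1 <- efficiency_model(f_2gamma = 1, eps_gamma = 1, geom = geom)
  s <- emit_and_detect(ann, geom, eff1, blur_params(0, 0), seed = 5)
  cc <- find_coincidences(s, geom)
  expect_gt(nrow(cc), 2000)

  img <- mlem_reconstruct(cc, geom, g, n_iter = 9, sensitivity = sens)
  expect_true(all(img$values >= 0))
  ll <- attr(img, "loglik")
  expect_length(ll, 9)
  expect_true(all(diff(ll) >= -1e-7 * abs(ll[-9])))

  pk <- arrayInd(which.max(img$values), g$dims)
  expect_equal(pk, matrix(c(33, 33, 19), 1))   # world (0, 0, 0) voxel
  near <- img$values[(pk[1] - 1):(pk[1] + 1), (pk[2] - 1):(pk[2] + 1),
                     (pk[3] - 1):(pk[3] + 1)]
  expect_gt(sum(near) / sum(img$values), 0.9)

  # count consistency: total forward-projected mass equals the event count
  supp <- sens$values
  supp[supp < 0.1 * max(supp)] <- 0
  expect_equal(sum(supp * img$values), nrow(cc) - attr(img, "n_dropped"),
               tolerance = 0.05)

  # zero iterations return the uniform start on the support
  img0 <- mlem_reconstruct(cc, geom, g, n_iter = 0, sensitivity = sens)
  vals <- img0$values[sens$values > 0.1 * max(sens$values)]
  expect_true(all(vals == 1))
})

test_that("images of two beams shifted 5 mm apart peak 5 mm apart", {
  geom <- default_geom
  g <- image_grid()
  sens <- sensitivity_image(geom, g, keep_prob = 1 / 8, seed = 4)
  eff1 <- efficiency_model(f_2gamma = 1, eps_gamma = 1, geom = geom)
  recon_center <- function(x0, seed) {
    ann <- point_annihilations(c(x0, 0, 2), 12000)
    set.seed(seed)
    ann$x <- ann$x + rnorm(nrow(ann), 0, 2)   # a narrow beam spot
    ann$z <- ann$z + runif(nrow(ann), -4, 4)
    s <- emit_and_detect(ann, geom, eff1, blur_params(0, 0), seed = seed)
    cc <- find_coincidences(s, geom)
    img <- mlem_reconstruct(cc, geom, g, 9, sens)
    find_beam_center(depth_sum(img))
  }
  c0 <- recon_center(0, 61)
  c5 <- recon_center(-5, 62)
  expect_equal(unname(lateral_shift(c0, c5)), c(5, 0), tolerance = 1.01)
})

test_that("ROI masking zeroes outside the cylinder and nothing else", {
  g <- image_grid()
  ones <- voxel_image(array(1, g$dims), g)
  roi <- roi_cylinder(36, 40)
  masked <- apply_roi(ones, roi)
  xc <- grid_centers(g, 1); yc <- grid_centers(g, 2); zc <- grid_centers(g, 3)
  n_inside <- sum(outer(xc^2, yc^2, `+`) <= 20^2) * sum(abs(zc) <= 18)
  expect_equal(sum(masked$values), n_inside)
  expect_lte(sum(masked$values), sum(ones$values))

  whole <- apply_roi(ones, roi_cylinder(1000, 1000))
  expect_equal(whole$values, ones$values)
})
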