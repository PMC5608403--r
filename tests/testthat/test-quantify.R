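test_that("local background subtraction is exact on uniform backgrounds", {
  img <- draw_disk(matrix(40, 60, 60), c(30, 30), 5, 40 + 300)
  mask <- matrix(0L, 60, 60)
  mask[img > 40] <- 1L
  expect_equal(local_background_subtract(img, mask, 1L, quant_params()), 300)
  img0 <- draw_disk(matrix(0, 60, 60), c(30, 30), 5, 250)
  expect_equal(local_background_subtract(img0, mask, 1L, quant_params()), 250)
})

test_that("background gradients are absorbed by the local median", {
  # linear ramp background + disk signal: the local median tracks the
  # background at the nucleus, so the subtracted mean stays within 5%
  bg <- matrix(rep(seq(80, 160, length.out = 90), each = 90), 90, 90)
  img <- bg + draw_disk(matrix(0, 90, 90), c(45, 45), 6, 400)
  mask <- matrix(0L, 90, 90)
  mask[draw_disk(matrix(0, 90, 90), c(45, 45), 6, 1) > 0] <- 1L
  got <- local_background_subtract(img, mask, 1L, quant_params())
  expect_lt(abs(got / 400 - 1), 0.05)
})

test_that("global background is the mode of the non-masked pixels", {
  img <- matrix(100, 80, 80)
  mask <- matrix(0L, 80, 80); mask[40, 40] <- 1L
  expect_equal(global_background(img, mask, quant_params()), 100)
  set.seed(3)
  imgn <- matrix(round(stats::rnorm(80 * 80, 100, 5)), 80, 80)
  expect_lt(abs(global_background(imgn, mask, quant_params()) - 100), 1.6)
  big <- matrix(1L, 80, 80)
  expect_error(global_background(img, big, quant_params()), "fully occupied")
})

test_that("ring statistic is the mean of the brightest half of the ring", {
  # single-pixel nucleus; ring = Chebyshev shell at distance 2 (16 pixels)
  img <- matrix(0, 21, 21)
  mask <- matrix(0L, 21, 21); mask[11, 11] <- 1L
  shell <- which(pmax(abs(row(img) - 11), abs(col(img) - 11)) == 2)
  img[shell] <- rep(c(1, 2, 3, 4), 4)
  qp <- quant_params(ring_inner_offset = 1, ring_width = 1)
  # background mode of this field is 0, so no offset is subtracted
  expect_equal(cytoplasmic_ring_mean(img, mask, 1L, qp), 3.5)

  img[shell] <- 5
  img[img == 0] <- 2                      # uniform background 2
  img[11, 11] <- 50
  expect_equal(cytoplasmic_ring_mean(img, mask, 1L, qp), 3)  # 5 - 2
})

test_that("activity is the cytoplasmic to nuclear ratio with a floor guard", {
  img <- draw_disk(matrix(0, 41, 41), c(21, 21), 4, 100)   # nucleus mean 100
  mask <- matrix(0L, 41, 41); mask[img > 0] <- 1L
  ring <- draw_disk(matrix(FALSE, 41, 41), c(21, 21), 9, TRUE) & mask == 0L
  img[ring] <- 200
  qp <- quant_params()
  expect_equal(cdk2_activity(img, mask, 1L, qp), 2)
  img[ring] <- 0
  expect_equal(cdk2_activity(img, mask, 1L, qp), 0)
  dim_img <- img; dim_img[mask == 1L] <- 5  # below the nuclear floor
  act <- cdk2_activity(dim_img, mask, 1L, qp)
  expect_true(is.na(act))
  expect_equal(attr(act, "flag"), "nuclear_floor")
})

test_that("activity is invariant to intensity scaling and offsets", {
  nl <- noiseless_fixture()
  f <- render_frame(nl$cohort, 1, noise = FALSE)
  sp <- segment_params(nucleus_radius_px = nl$cfg$r_px)
  lab <- segment_frame(f$h2b, sp)
  # remove the constant background so scaling acts on pure signal
  sig <- pmax(f$sensor - nl$cfg$background_level, 0)
  q1 <- quantify_frame(f$h2b, sig, lab, quant_params())
  q2 <- quantify_frame(f$h2b, 3.7 * sig, lab, quant_params())
  expect_equal(q2$cdk2_activity, q1$cdk2_activity, tolerance = 1e-6)
  # adding a constant leaves background-subtracted means unchanged
  q3 <- quantify_frame(f$h2b + 50, f$sensor + 50, lab, quant_params())
  q0 <- quantify_frame(f$h2b, f$sensor, lab, quant_params())
  expect_equal(q3$nuclear_mean, q0$nuclear_mean, tolerance = 0.02)
  expect_equal(q3$total_h2b, q0$total_h2b, tolerance = 0.02)
})

test_that("noiseless renders are quantified to ground truth", {
  nl <- noiseless_fixture()
  co <- nl$cohort
  f <- render_frame(co, 1, noise = FALSE)
  lab <- segment_frame(f$h2b, segment_params(nucleus_radius_px = co$config$r_px))
  q <- quantify_frame(f$h2b, f$sensor, lab, quant_params())
  idx <- match_truth(co, q, 1)
  rel <- q$cdk2_activity / co$activity[idx, 1] - 1
  expect_lt(max(abs(rel)), 0.02)
  expect_equal(q$total_h2b, co$cells$h2b_mass[idx], tolerance = 0.01)
})

test_that("tracked noisy movies recover per-frame activities (RMSE < 0.1)", {
  e2e <- e2e_fixture()
  co <- e2e$cohort
  obs <- e2e$analysis$traces$obs
  err <- numeric(0)
  for (tid in unique(obs$track)) {
    o <- obs[obs$track == tid, ]
    ti <- match_truth(co, o[1, , drop = FALSE], o$frame[1])
    err <- c(err, o$cdk2_activity - co$activity[ti, o$frame])
  }
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 0.1)
})
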