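test_that("configuration validation enforces the documented invariants", {
  expect_error(sim_config(composition = c(CDK2inc = 0.5, CDK2low = 0.4)),
               "sum to 1")
  expect_error(sim_config(composition = c(CDK2inc = 1.2, CDK2low = -0.2,
                                          CDK2emerge = 0,
                                          prolonged_quiescent = 0,
                                          nondividing_emerge = 0)),
               "nonnegative")
  expect_error(sim_config(pixel_size = 0), "pixel_size")
  expect_error(sim_config(frame_interval = 13), "integer frame count")
  cfg <- sim_config()
  expect_equal(sum(cfg$composition), 1)
  expect_equal(cfg$n_frames, 121L)
})

test_that("trace law reproduces the closed-form values", {
  tt <- seq(0, 16, by = 0.2)
  low <- sample_trace(list(fate = "CDK2low", low_level = 0.3), tt)
  expect_equal(low, rep(0.3, length(tt)))

  em <- sample_trace(list(fate = "CDK2emerge", low_level = 0.3,
                          emerge_delay = 5, rise_rate = 0.25), tt)
  # 0.3 + 0.25 (t - 5) = 0.5  =>  t = 5.8 h
  cross <- tt[min(which(em >= 0.5))]
  expect_equal(cross, 5.8, tolerance = 0.21)
  expect_true(all(em[tt <= 5] == 0.3))

  inc <- sample_trace(list(fate = "CDK2inc", birth_activity = 0.6,
                           rise_rate = 0.09), tt)
  expect_equal(inc[length(inc)], 0.6 + 0.09 * 16)

  expect_error(sample_trace(list(fate = "CDK2emerge", low_level = 0.3,
                                 emerge_delay = 2, rise_rate = 0.25), tt),
               ">= 3 hours")
  expect_error(sample_trace(list(fate = "CDK2inc", birth_activity = 0.4,
                                 rise_rate = 0.1), tt), ">= 0.5")
})

test_that("degenerate composition yields a pure dividing cohort", {
  cfg <- sim_config(n_cells = 50, seed = 1,
                    composition = c(CDK2inc = 1, CDK2low = 0, CDK2emerge = 0,
                                    prolonged_quiescent = 0,
                                    nondividing_emerge = 0))
  co <- simulate_cohort(cfg)
  roots <- co$cells[co$cells$is_root, ]
  expect_equal(nrow(roots), 50L)
  expect_true(all(roots$fate == "CDK2inc"))
  expect_true(all(!is.na(roots$division_time)))
})

test_that("identical configuration and seed give identical outputs", {
  cfg <- sim_config(n_cells = 15, seed = 33)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$activity, b$activity)
  expect_identical(a$cells, b$cells)
  expect_identical(a$pos_row, b$pos_row)
  fa <- render_frame(a, 10)
  fb <- render_frame(b, 10)
  expect_identical(fa$h2b, fb$h2b)
  expect_identical(fa$sensor, fb$sensor)
  ia <- render_endpoint_if(a, c("CyclinA2", "EdU"))
  ib <- render_endpoint_if(b, c("CyclinA2", "EdU"))
  expect_identical(ia$shift, ib$shift)
  expect_identical(ia$truth, ib$truth)
  expect_identical(ia$images$CyclinA2, ib$images$CyclinA2)
})

test_that("ground-truth cohort satisfies its structural invariants", {
  cfg <- sim_config(n_cells = 120, seed = 4)
  co <- simulate_cohort(cfg)
  daughters <- co$cells[!is.na(co$cells$mother_id), ]
  # each daughter's mass within 45-55% of mother's; sisters sum to mother
  for (mo in unique(daughters$mother_id)) {
    ds <- daughters[daughters$mother_id == mo, ]
    mm <- co$cells$h2b_mass[mo]
    expect_equal(sum(ds$h2b_mass), mm, tolerance = 1e-9)
    expect_true(all(ds$h2b_mass / mm >= 0.45 & ds$h2b_mass / mm <= 0.55))
  }
  pq <- co$cells[co$cells$fate == "prolonged_quiescent", ]
  if (nrow(pq)) {
    expect_true(all(is.na(pq$anaphase_frame)))
    expect_true(all(co$activity[pq$id, ] < 0.6, na.rm = TRUE))
  }
  # nuclei never interpenetrate after the motion model
  f <- co$config$n_frames
  alive <- which(co$cells$end_frame == f)
  d <- as.matrix(dist(cbind(co$pos_row[alive, f], co$pos_col[alive, f])))
  lim <- outer(co$cells$radius[alive], co$cells$radius[alive], `+`)
  diag(d) <- Inf
  expect_true(all(d >= lim - 1e-6))
})

test_that("fate fractions converge to the configured composition", {
  cfg <- sim_config(n_cells = 1500, seed = 21)
  co <- simulate_cohort(cfg)
  tc <- true_composition(co)
  for (f in names(cfg$composition)) {
    p <- cfg$composition[[f]]
    se <- sqrt(p * (1 - p) / 1500)
    expect_lt(abs(tc[[f]] / 100 - p), 4 * se + 1e-9)
  }
})

test_that("rendered division halves the integrated H2B mass", {
  nl <- noiseless_fixture()
  co <- nl$cohort
  d <- co$cells[!is.na(co$cells$mother_id), ][1:2, ]
  f <- d$birth_frame[1]
  img <- render_frame(co, f, noise = FALSE)
  lab <- segment_frame(img$h2b, segment_params(nucleus_radius_px = co$config$r_px))
  q <- quantify_frame(img$h2b, img$sensor, lab, quant_params())
  idx <- match_truth(co, q, f)
  meas <- q$total_h2b[match(d$id, idx)]
  expect_equal(meas, d$h2b_mass, tolerance = 0.01)
  expect_equal(sum(meas), co$cells$h2b_mass[d$mother_id[1]], tolerance = 0.01)
})

test_that("endpoint IF values follow the protein profiles", {
  nl <- noiseless_fixture()
  ifs <- render_endpoint_if(nl$cohort, c("CyclinA2", "p21", "EdU"),
                            noise = FALSE)
  profs <- protein_profiles(nl$cfg$s_phase_window)
  tr <- ifs$truth
  low <- tr[tr$fate == "CDK2low", ]
  if (nrow(low)) expect_true(all(low$CyclinA2 == 50))
  pq <- tr[tr$fate == "prolonged_quiescent", ]
  if (nrow(pq)) expect_equal(pq$p21, rep(250 + 20 * 24, nrow(pq)))
  inc <- tr[tr$fate == "CDK2inc", ]
  s_win <- nl$cfg$s_phase_window
  in_s <- inc$time_since_anaphase >= s_win[1] & inc$time_since_anaphase <= s_win[2]
  expect_true(all(inc$EdU[in_s] == 600))
  expect_true(all(inc$EdU[!in_s] == 40))
})

test_that("all-CDK2low cohorts stay at IF baseline for Cyclin A2", {
  cfg <- sim_config(n_cells = 30, seed = 14, if_noise_sdlog = 0,
                    composition = c(CDK2inc = 0, CDK2low = 1, CDK2emerge = 0,
                                    prolonged_quiescent = 0,
                                    nondividing_emerge = 0))
  co <- simulate_cohort(cfg)
  ifs <- render_endpoint_if(co, "CyclinA2", noise = FALSE)
  expect_true(all(ifs$truth$CyclinA2 == 50))
})

test_that("zero jitter leaves the IF image unshifted", {
  nl <- noiseless_fixture()
  a <- render_endpoint_if(nl$cohort, "p21", shift = c(0, 0), noise = FALSE)
  b <- render_endpoint_if(nl$cohort, "p21", shift = c(5, -2), noise = FALSE)
  expect_identical(a$shift, c(0L, 0L))
  back <- shift_matrix(b$images$p21, -5, 2, fill = nl$cfg$background_level)
  ctr <- 20:(nrow(back) - 20)
  expect_equal(back[ctr, ctr], a$images$p21[ctr, ctr])
})

test_that("snapshot extremes reproduce the marker logic", {
  one <- function(ph) {
    occ <- stats::setNames(rep(0, 7), c("G0", "G1", "earlyS", "S", "lateS",
                                        "G2", "M"))
    occ[ph] <- 1
    snapshot_population(n = 300, occupancy = occ, noise_sdlog = 0, seed = 2)
  }
  g0 <- one("G0")
  expect_true(all(g0$prb == 100))          # hypo-phosphorylated Rb only
  expect_true(all(g0$edu == 30))           # EdU negative
  m <- one("M")
  expect_true(all(m$phh3 == 2000))         # pHH3 positive
  expect_true(all(m$dna == 10000))         # 4N
  expect_error(snapshot_population(occupancy = c(G0 = 1)), "all 7 phases")
})
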