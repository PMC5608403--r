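test_that("moving averages summarize scatters with suppression of thin bins", {
  sc <- data.frame(time = rep(seq(0, 10, by = 0.5), each = 12), value = 7)
  cv <- moving_average(sc, window = 2, step = 0.5, min_bin_count = 10)
  expect_true(all(cv$mean == 7))
  expect_true(all(cv$sd == 0))

  # symmetric windows on a linear signal: mean at the center equals center
  sc2 <- data.frame(time = seq(0, 10, by = 0.05), value = seq(0, 10, by = 0.05))
  cv2 <- moving_average(sc2, window = 2, step = 0.5, min_bin_count = 5)
  mid <- cv2[cv2$time > 1 & cv2$time < 9, ]
  expect_equal(mid$mean, mid$time, tolerance = 1e-9)

  sparse <- data.frame(time = c(rep(1, 12), 5), value = 1)
  cv3 <- moving_average(sparse, window = 1, step = 1, min_bin_count = 10)
  expect_true(all(abs(cv3$time - 1) <= 0.5))   # the lone far point suppressed
  expect_equal(nrow(moving_average(sc[0, ], 2, 0.5)), 0L)
})

test_that("moving average commutes with affine value transforms", {
  set.seed(4)
  sc <- data.frame(time = stats::runif(400, 0, 20),
                   value = stats::rnorm(400, 5, 2))
  a <- 3.2; b <- -1.4
  sc2 <- transform(sc, value = a * value + b)
  c1 <- moving_average(sc, 2, 0.5)
  c2 <- moving_average(sc2, 2, 0.5)
  expect_equal(c2$mean, a * c1$mean + b, tolerance = 1e-12)
  expect_equal(c2$sd, abs(a) * c1$sd, tolerance = 1e-12)
  expect_equal(c2$n, c1$n)
})

test_that("pair normalization uses one shared min-max and attains {0, 1}", {
  inc <- structure(data.frame(time = 1:2, mean = c(0, 10), sd = c(1, 1)),
                   class = c("dynamics_curve", "data.frame"))
  low <- structure(data.frame(time = 1:2, mean = c(5, 5), sd = c(1, 1)),
                   class = c("dynamics_curve", "data.frame"))
  np <- normalize_pair(inc, low)
  expect_equal(np$inc$mean, c(0, 1))
  expect_equal(np$low$mean, c(0.5, 0.5))
  expect_equal(min(c(np$inc$mean, np$low$mean)), 0)
  expect_equal(max(c(np$inc$mean, np$low$mean)), 1)
  # idempotence
  np2 <- normalize_pair(np$inc, np$low)
  expect_equal(np2$inc$mean, np$inc$mean)
  expect_equal(np2$low$mean, np$low$mean)
  # identical curves normalize identically; flat pairs are rejected
  np3 <- normalize_pair(inc, inc)
  expect_equal(np3$inc$mean, np3$low$mean)
  expect_error(normalize_pair(low, low), "flat")
})

test_that("group assignment separates off signals from dynamic ones", {
  cv <- function(m) structure(data.frame(time = seq_along(m), mean = m),
                              class = c("dynamics_curve", "data.frame"))
  expect_equal(assign_group(cv(rep(0.02, 8))), "Group1")
  expect_equal(assign_group(cv(seq(0.1, 0.9, length.out = 8))), "Group2")
  expect_equal(assign_group(cv(seq(0.8, 0.2, length.out = 8))), "Group2")
  expect_equal(assign_group(cv(rep(0.5, 8))), "Group2")   # flat but high
  expect_equal(assign_group(cv(c(0, 1))), "unassigned")   # too short
})

# Simulated endpoint scatters drawn straight from the protein profiles:
# this exercises the whole dynamics-map construction at the data level.
profile_curves <- function(protein, n = 2500, noise = 0.1, seed = 1) {
  set.seed(seed)
  profs <- protein_profiles()
  mk <- function(fate) {
    tt <- stats::runif(n, 0.5, 24)
    v <- vapply(tt, function(x) profs[[protein]](fate, x), numeric(1))
    data.frame(time = tt, value = v * exp(stats::rnorm(n, 0, noise)))
  }
  list(inc = moving_average(mk("CDK2inc"), 2, 0.5),
       low = moving_average(mk("CDK2low"), 2, 0.5))
}

test_that("the nine dynamic proteins partition into the expected groups", {
  group1 <- c("CyclinA2", "CyclinB1", "Geminin", "cMyc", "phosphoRb")
  group2 <- c("CyclinD1", "CyclinE", "p21", "Cdt1")
  for (p in c(group1, group2)) {
    cur <- profile_curves(p)
    np <- normalize_pair(cur$inc, cur$low)
    got <- assign_group(np)
    want <- if (p %in% group1) "Group1" else "Group2"
    expect_identical(got, want)
  }
})

test_that("quiescent Cyclin D1 exceeds the cycling curve from birth", {
  cur <- profile_curves("CyclinD1")
  np <- normalize_pair(cur$inc, cur$low)
  early <- np$low$time <= 4
  match_inc <- np$inc$mean[match(np$low$time[early], np$inc$time)]
  expect_true(all(np$low$mean[early] > match_inc, na.rm = TRUE))
})

test_that("the EdU moving average recovers the S-phase window", {
  cur <- profile_curves("EdU", noise = 0.05)
  win <- s_phase_window_from_edu(cur$inc)
  expect_lt(abs(win[1] - 5), 1.5)
  expect_lt(abs(win[2] - 13), 1.5)
})

test_that("dynamics reconstruction places cells on the time-since-anchor axis", {
  nl <- noiseless_fixture()
  ens <- suppressWarnings(align_ensemble(nl$analysis$traces, "anaphase",
                                         fates = nl$fates))
  last <- render_frame(nl$cohort, nl$cfg$n_frames, noise = FALSE)
  ifs <- render_endpoint_if(nl$cohort, c("CyclinA2", "p21"), noise = FALSE)
  att <- attach_if(nl$analysis, ifs, last_h2b = last$h2b, search_radius = 8)
  vals <- cdk2map:::root_if_values(nl$fates, att$values)

  sc <- reconstruct_dynamics(ens, vals, "p21",
                             c("CDK2low", "prolonged_quiescent"))
  pq <- sc[sc$fate == "prolonged_quiescent", ]
  if (nrow(pq)) expect_true(all(pq$time == 24))
  sc_inc <- reconstruct_dynamics(ens, vals, "CyclinA2", "CDK2inc")
  expect_true(all(sc_inc$time >= 0 & sc_inc$time <= 24))
  # Cyclin A2 in cycling cells: baseline in G1, increasing through S/G2
  g1 <- sc_inc$value[sc_inc$time < 4]
  g2 <- sc_inc$value[sc_inc$time > 10]
  if (length(g1) && length(g2)) expect_gt(mean(g2), mean(g1) * 2)
})
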