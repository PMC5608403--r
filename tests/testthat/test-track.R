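obs_df <- function(row, col, mass) {
  data.frame(row = row, col = col, total_h2b = mass)
}

tp <- track_params(max_displacement = 15)

test_that("identical frames link by identity", {
  o <- obs_df(c(10, 30, 50), c(10, 30, 50), c(1000, 900, 1100))
  expect_equal(link_frames(o, o, tp), 1:3)
})

test_that("conservation of mass beats raw distance in linking", {
  # the cells cross so each sits nearer the other's successor, but their
  # distinct masses force the mass-consistent assignment
  a <- obs_df(c(20, 26), c(20, 20), c(1000, 400))
  b <- obs_df(c(25, 21), c(20, 20), c(1000, 400))
  lk <- link_frames(a, b, tp)
  expect_equal(lk, c(1L, 2L))
})

test_that("a disappearing cell terminates its track without false links", {
  a <- obs_df(c(20, 60), c(20, 20), c(1000, 980))
  b <- obs_df(60, 20, 980)
  lk <- link_frames(a, b, tp)
  expect_true(is.na(lk[1]))
  expect_equal(lk[2], 1L)
})

test_that("merges and splits are flagged by conservation of mass", {
  a <- obs_df(c(20, 28), c(20, 20), c(500, 480))
  b <- obs_df(24, 20, 985)
  lk <- link_frames(a, b, tp)
  ms <- detect_merge_split(lk, a, b, tp)
  expect_equal(nrow(ms$merge), 1L)
  expect_setequal(c(ms$merge$src1, ms$merge$src2), 1:2)

  a2 <- obs_df(20, 20, 1000)
  b2 <- obs_df(c(16, 24), c(20, 20), c(500, 500))
  ms2 <- detect_merge_split(link_frames(a2, b2, tp), a2, b2, tp)
  expect_equal(nrow(ms2$split), 1L)

  # isolated constant-mass track: nothing flagged
  a3 <- obs_df(20, 20, 1000)
  b3 <- obs_df(20.5, 20, 1005)
  ms3 <- detect_merge_split(link_frames(a3, b3, tp), a3, b3, tp)
  expect_equal(nrow(ms3$merge), 0L)
  expect_equal(nrow(ms3$split), 0L)
})

test_that("anaphase band is 45-55% with inclusive endpoints", {
  mo <- obs_df(20, 20, 1000)
  d <- function(m1, m2) obs_df(c(16, 24), c(20, 20), c(m1, m2))
  expect_true(call_anaphase(mo, d(500, 500), tp))
  expect_false(call_anaphase(mo, d(449, 551), tp))
  expect_true(call_anaphase(mo, d(450, 550), tp))
  expect_false(call_anaphase(mo, d(440, 560), tp))
  expect_false(call_anaphase(mo, d(500, NA), tp))
  expect_false(call_anaphase(mo, NULL, tp))
})

test_that("anaphase rule equals the brute-force band predicate", {
  set.seed(11)
  for (k in 1:500) {
    m <- stats::runif(1, 500, 2000)
    f1 <- stats::runif(1, 0.35, 0.65)
    f2 <- stats::runif(1, 0.35, 0.65)
    mo <- obs_df(20, 20, m)
    dg <- obs_df(c(16, 24), c(20, 20), m * c(f1, f2))
    oracle <- (f1 >= 0.45 && f1 <= 0.55) && (f2 >= 0.45 && f2 <= 0.55)
    expect_identical(call_anaphase(mo, dg, tp), oracle)
  }
})

test_that("track assembly concatenates links and records lineage", {
  nfr <- 10L
  obs <- lapply(seq_len(nfr), function(f) obs_df(20 + 0.1 * f, 20, 1000))
  links <- lapply(seq_len(nfr - 1L), function(f) 1L)
  tr <- assemble_traces(obs, links, times = seq_len(nfr) * 0.2)
  expect_equal(nrow(tr$tracks), 1L)
  expect_true(all(is.na(tr$tracks$anaphase_frame)))

  # one division at frame 6: 1 mother, 2 daughters
  obs2 <- c(lapply(1:5, function(f) obs_df(20, 20, 1000)),
            lapply(6:10, function(f) obs_df(c(15, 25), c(20, 20), c(500, 500))))
  links2 <- c(lapply(1:4, function(f) 1L),
              list(c(NA_integer_)),
              lapply(6:9, function(f) 1:2))
  ana <- data.frame(frame = 5L, source = 1L, d1 = 1L, d2 = 2L)
  tr2 <- assemble_traces(obs2, links2, ana, times = (1:10) * 0.2)
  expect_equal(nrow(tr2$tracks), 3L)
  d <- tr2$tracks[!is.na(tr2$tracks$mother_id), ]
  expect_equal(nrow(d), 2L)
  expect_equal(unique(d$anaphase_frame), 6L)
  expect_equal(unique(d$mother_id), 1L)
})

test_that("single-frame gaps are re-linked into one track", {
  obs <- lapply(1:9, function(f) obs_df(20 + 0.1 * f, 20, 1000))
  obs[[5]] <- obs_df(numeric(0), numeric(0), numeric(0))
  links <- lapply(1:8, function(f) {
    if (f %in% c(4, 5)) rep(NA_integer_, nrow(obs[[f]])) else
      seq_len(nrow(obs[[f]]))
  })
  tr <- assemble_traces(obs, links, times = (1:9) * 0.2,
                        params = track_params(max_displacement = 15, max_gap = 1))
  expect_equal(nrow(tr$tracks), 1L)
  expect_equal(tr$tracks$end_frame, 9L)
})

test_that("anaphases on noiseless movies are exact (no misses, no false calls)", {
  nl <- noiseless_fixture()
  tr <- nl$analysis$traces
  det <- tr$tracks[!is.na(tr$tracks$anaphase_frame), ]
  truth <- nl$cohort$cells[!is.na(nl$cohort$cells$anaphase_frame), ]
  expect_equal(nrow(det), nrow(truth))
  expect_equal(sort(det$anaphase_frame), sort(truth$anaphase_frame))
  # conservation along links: no within-track mass jump beyond tolerance
  obs <- tr$obs
  for (tid in unique(obs$track)) {
    m <- obs$total_h2b[obs$track == tid]
    if (length(m) > 1) {
      expect_true(all(abs(diff(m)) <= 0.2 * m[-length(m)]))
    }
  }
})
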