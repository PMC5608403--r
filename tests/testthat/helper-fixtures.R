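# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# Small default-composition cohort pushed through the full pipeline
# (render -> segment -> track -> quantify). Used by the end-to-end tests.
e2e_fixture <- function() {
  if (is.null(.fixtures$e2e)) {
    cfg <- sim_config(n_cells = 150, seed = 42)
    cohort <- simulate_cohort(cfg)
    analysis <- analyze_movie(cohort)
    .fixtures$e2e <- list(cfg = cfg, cohort = cohort, analysis = analysis,
                          fates = classify_lineages(analysis$traces))
  }
  .fixtures$e2e
}

# Tiny noiseless cohort for construction-identity and exact-recovery tests.
noiseless_fixture <- function() {
  if (is.null(.fixtures$noiseless)) {
    cfg <- sim_config(n_cells = 25, seed = 9, noise_sd = 0,
                      trace_noise_sd = 0, if_noise_sdlog = 0,
                      jitter_shift = c(4, -3))
    cohort <- simulate_cohort(cfg)
    analysis <- analyze_movie(cohort)
    .fixtures$noiseless <- list(cfg = cfg, cohort = cohort,
                                analysis = analysis,
                                fates = classify_lineages(analysis$traces))
  }
  .fixtures$noiseless
}

# Match measured objects in frame `f` to ground-truth cells by position.
match_truth <- function(cohort, obs, f) {
  alive <- which(cohort$cells$birth_frame <= f & cohort$cells$end_frame >= f)
  vapply(seq_len(nrow(obs)), function(i) {
    d2 <- (cohort$pos_row[alive, f] - obs$row[i])^2 +
      (cohort$pos_col[alive, f] - obs$col[i])^2
    alive[which.min(d2)]
  }, integer(1))
}

# Draw a filled disk into a matrix.
draw_disk <- function(img, center, radius, value) {
  g <- expand.grid(r = seq_len(nrow(img)), c = seq_len(ncol(img)))
  sel <- (g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2
  img[cbind(g$r[sel], g$c[sel])] <- value
  img
}

# True composition (percent) of a cohort's starting cells.
true_composition <- function(cohort) {
  roots <- cohort$cells[cohort$cells$is_root, ]
  lv <- c("CDK2inc", "CDK2low", "CDK2emerge", "prolonged_quiescent",
          "nondividing_emerge")
  out <- 100 * as.vector(table(factor(roots$fate, levels = lv))) / nrow(roots)
  names(out) <- lv
  c(out, divided = 100 * mean(!is.na(roots$division_time)))
}
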