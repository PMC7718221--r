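# Construct a cc_sim_runs object directly (unit-level fixtures for the
# classifier and ranking machinery).
fake_runs <- function(p_by_pred, beta_by_pred = NULL, n_sim = NULL) {
  preds <- names(p_by_pred)
  n_sim <- n_sim %||% length(p_by_pred[[1]])
  out <- do.call(rbind, lapply(preds, function(t) {
    data.frame(run = seq_len(n_sim), predictor = t, p = p_by_pred[[t]],
               beta = if (is.null(beta_by_pred)) 0.1 else beta_by_pred[[t]],
               converged = TRUE, stringsAsFactors = FALSE)
  }))
  attr(out, "n_sim") <- n_sim
  attr(out, "subsample_size") <- 192
  attr(out, "predictors") <- preds
  class(out) <- c("cc_sim_runs", "data.frame")
  out
}

test_that("classification obeys the threshold exactly at the boundary", {
  n <- 1000
  p <- list(
    at_threshold = c(rep(0.01, 950), rep(0.5, 50)),   # exactly 0.95
    just_below = c(rep(0.01, 940), rep(0.5, 60)),     # 0.94 -> dynamic
    certain = rep(0.001, n),                          # 1.00 -> consistent
    null_like = c(rep(0.01, 50), rep(0.6, 950))       # not full-data sig
  )
  full_p <- c(at_threshold = 1e-4, just_below = 1e-4, certain = 1e-9,
              null_like = 0.4)
  cons <- classify_consistency(fake_runs(p), full_p = full_p)
  lab <- setNames(cons$label, cons$predictor)
  expect_equal(lab[["at_threshold"]], "consistent")
  expect_equal(lab[["just_below"]], "dynamic")
  expect_equal(lab[["certain"]], "consistent")
  expect_equal(lab[["null_like"]], "non-predictor")
  expect_equal(cons$proportion_significant[cons$predictor == "just_below"],
               0.94)
  expect_equal(cons$p_min[cons$predictor == "certain"], 0.001)
  expect_equal(cons$p_max[cons$predictor == "certain"], 0.001)
})

test_that("effect direction comes from the median beta sign", {
  p <- list(a = rep(0.01, 100), b = rep(0.01, 100))
  betas <- list(a = rnorm(100, 0.4, 0.05), b = rnorm(100, -0.3, 0.05))
  cons <- classify_consistency(fake_runs(p, betas),
                               full_p = c(a = 1e-5, b = 1e-5))
  expect_equal(cons$direction, c("+", "-"))
  # categorical predictors (all-NA beta) get NA direction
  betas$a <- rep(NA_real_, 100)
  cons2 <- classify_consistency(fake_runs(p, betas),
                                full_p = c(a = 1e-5, b = 1e-5))
  expect_true(is.na(cons2$direction[1]))
})

test_that("rank_importance proportions sum to one and handle degeneracy", {
  set.seed(4)
  betas <- list(big = rnorm(500, 1, 0.1), small = rnorm(500, 0.1, 0.05),
                mid = rnorm(500, 0.5, 0.1))
  p <- lapply(betas, function(b) rep(0.01, 500))
  runs <- fake_runs(p, betas)
  rk <- rank_importance(runs, c("big", "small", "mid"))
  expect_equal(sum(rk$rank_importance_p), 1)
  expect_equal(rk$rank_importance_p[rk$predictor == "big"], 1)
  expect_true(rk$never_most_important[rk$predictor == "small"])

  # exchangeable effects: each predictor tops roughly 1/3 of runs
  sym <- list(a = rnorm(900, 0.3, 0.1), b = rnorm(900, 0.3, 0.1),
              c = rnorm(900, 0.3, 0.1))
  rk2 <- rank_importance(fake_runs(lapply(sym, function(x) rep(0.01, 900)),
                                   sym), c("a", "b", "c"))
  expect_true(all(abs(rk2$rank_importance_p - 1 / 3) < 0.08))

  expect_message(rk3 <- rank_importance(runs, "big"), "singleton")
  expect_equal(rk3$rank_importance_p, 1)
})

test_that("beta_interval matches normal quantiles and degenerate cases", {
  set.seed(6)
  runs <- fake_runs(list(a = rep(0.01, 4000)),
                    list(a = rnorm(4000, 0.2, 0.04)))
  ci <- beta_interval(runs, "a", absolute = FALSE)
  expect_lt(abs(ci[1] - qnorm(0.025, 0.2, 0.04)), 0.01)
  expect_lt(abs(ci[2] - qnorm(0.975, 0.2, 0.04)), 0.01)

  const <- fake_runs(list(a = rep(0.01, 50)), list(a = rep(0.25, 50)))
  expect_equal(diff(beta_interval(const, "a")), 0)
  expect_equal(beta_interval(const, "a", level = 1), c(0.25, 0.25))

  few <- fake_runs(list(a = rep(0.01, 10)), list(a = rnorm(10)))
  expect_error(beta_interval(few, "a"), class = "cc_error_non_estimable")
})

test_that("subsample runs are deterministic, distinct, and degenerate correctly", {
  ds <- small_world(seed = 51, years = 2, n_per_year = 40,
                    effects = list(trophic_level = 0.5))
  su <- freq_setup(ds, fixed = c("trophic_level", "body_size"))
  runs1 <- run_subsample_simulations(su$spec, su$data, n_sim = 6,
                                     subsample_size = 50, master_seed = 5)
  runs2 <- run_subsample_simulations(su$spec, su$data, n_sim = 6,
                                     subsample_size = 50, master_seed = 5)
  expect_identical(as.data.frame(runs1), as.data.frame(runs2))
  subs <- attr(runs1, "subsamples")
  expect_true(all(vapply(subs, function(s) {
    length(s) == 50 && !anyDuplicated(s)
  }, logical(1))))
  expect_false(identical(subs[[1]], subs[[2]]))

  # subsample = full data: every run reproduces the full-data coefficients
  n_ids <- length(unique(su$data$observation_id))
  full <- fit_glmm(su$spec, su$data)
  runs_full <- run_subsample_simulations(su$spec, su$data, n_sim = 3,
                                         subsample_size = n_ids,
                                         master_seed = 9)
  expect_true(all(abs(runs_full$beta[runs_full$predictor == "trophic_level"] -
                        full$beta[["trophic_level"]]) < 1e-4))

  expect_error(run_subsample_simulations(su$spec, su$data, n_sim = 2,
                                         subsample_size = n_ids + 1),
               class = "cc_error_invalid_argument")
})

test_that("true nulls are significant in roughly alpha of the runs", {
  ds <- small_world(seed = 52, years = 2, n_per_year = 120)
  su <- freq_setup(ds, fixed = c("trophic_level", "cleaner_local_abundance"))
  runs <- run_subsample_simulations(su$spec, su$data, n_sim = 60,
                                    subsample_size = 100, master_seed = 77)
  cons <- classify_consistency(runs, fit_glmm(su$spec, su$data))
  # all-null world: proportions should sit near alpha, far below threshold
  expect_true(all(cons$proportion_significant < 0.3))
  expect_true(all(cons$label != "consistent"))
})
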