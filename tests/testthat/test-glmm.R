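test_that("standardize_predictors centres, scales, and rejects constants", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 10, 40), k = c(5, 5, 5))
  out <- standardize_predictors(d, c("a", "b"))
  expect_equal(mean(out$data$a), 0)
  expect_equal(sd(out$data$a), 1)
  expect_equal(out$center[["a"]], 2)
  # idempotence
  again <- standardize_predictors(out$data, c("a", "b"))
  expect_equal(again$data$a, out$data$a, tolerance = 1e-12)
  expect_error(standardize_predictors(d, "k"),
               class = "cc_error_degenerate_predictor")
})

test_that("transform_duration matches the folded-logit formula", {
  expect_equal(transform_duration(0.73), abs(log(0.73 / 0.27)))
  expect_equal(round(transform_duration(0.73), 5), 0.99462)
  expect_equal(round(transform_duration(1, epsilon = 1e-4), 5), 9.21024)
  # logit(0.5) = 0 is floored to keep the log-link response positive
  expect_equal(transform_duration(0.5), 1e-6)
  expect_error(transform_duration(1.2), class = "cc_error_invalid_argument")
  expect_error(transform_duration(0.4, epsilon = 0.7),
               class = "cc_error_invalid_argument")
})

test_that("transform_duration is symmetric about 0.5 and monotone in |p - 0.5|", {
  p <- seq(0.01, 0.49, by = 0.01)
  expect_equal(transform_duration(p), transform_duration(1 - p))
  y <- transform_duration(0.5 - p)  # increasing distance from 0.5
  expect_true(all(diff(y) > 0))
})

test_that("the PIRLS fitter equals glm when there is no random effect", {
  d <- direct_probit_data(n = 250, seed = 4, station_sd = 0)
  spec <- cc_model_spec("successes", fixed = c("x1", "x2"), random = NULL,
                        family = "binomial-probit")
  fit <- fit_glmm(spec, d)
  oracle <- glm(cbind(successes, trials - successes) ~ x1 + x2,
                family = binomial("probit"), data = d)
  expect_lt(max(abs(fit$beta - coef(oracle))), 1e-4)
  expect_equal(fit$deviance_resid, deviance(oracle), tolerance = 1e-6)

  # with a random intercept whose scale is pinned at zero, the penalised
  # solve degenerates to the same GLM
  spec_re <- cc_model_spec("successes", fixed = c("x1", "x2"),
                           random = "station_id",
                           family = "binomial-probit")
  prep <- cleanerclient:::cc_prepare(spec_re, d)
  fit0 <- cleanerclient:::cc_fit_from_prep(prep, theta_fix = 0)
  expect_lt(max(abs(fit0$beta - coef(oracle))), 1e-4)
})

test_that("gaussian log-link fitting equals glm at zero random-effect scale", {
  set.seed(8)
  d <- data.frame(x1 = rnorm(150), station_id = sample(letters[1:6], 150, TRUE))
  d$y <- pmax(exp(0.4 + 0.3 * d$x1) + rnorm(150, 0, 0.4), 1e-3)
  spec <- cc_model_spec("y", fixed = "x1", random = NULL,
                        family = "gaussian-log")
  fit <- fit_glmm(spec, d)
  oracle <- glm(y ~ x1, family = gaussian("log"), data = d)
  expect_lt(max(abs(fit$beta - coef(oracle))), 1e-4)
  expect_true(all(fit$fitted > 0))
})

test_that("agq0 estimates agree with the lme4 nAGQ = 0 oracle", {
  skip_if_not_installed("lme4")
  d <- direct_probit_data(n = 400, beta = c(0.5, -0.3), seed = 12)
  spec <- cc_model_spec("successes", fixed = c("x1", "x2"),
                        random = "station_id", family = "binomial-probit")
  fit <- fit_glmm(spec, d)
  d$prop <- d$successes / d$trials
  gm <- lme4::glmer(prop ~ x1 + x2 + (1 | station_id), data = d,
                    family = binomial("probit"), weights = trials, nAGQ = 0)
  expect_lt(max(abs(fit$beta - lme4::fixef(gm))), 1e-3)
  expect_equal(unname(fit$re_sd["station_id"]),
               attr(lme4::VarCorr(gm)$station_id, "stddev")[[1]],
               tolerance = 1e-3)
})

test_that("known coefficients are recovered within 2 SE on average", {
  ests <- t(vapply(1:25, function(r) {
    d <- direct_probit_data(n = 400, beta = c(0.5, -0.3), seed = 100 + r)
    spec <- cc_model_spec("successes", fixed = c("x1", "x2"),
                          random = "station_id", family = "binomial-probit")
    f <- fit_glmm(spec, d)
    c(f$beta[["x1"]], f$beta[["x2"]])
  }, numeric(2)))
  mcse <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - 0.5), 2 * mcse[1] + 1e-8)
  expect_lt(abs(mean(ests[, 2]) + 0.3), 2 * mcse[2] + 1e-8)
})

test_that("laplace mode stays close to agq0 on well-conditioned data", {
  d <- direct_probit_data(n = 500, beta = c(0.8, -0.5), seed = 31,
                          station_sd = 0.4)
  spec <- cc_model_spec("successes", fixed = c("x1", "x2"),
                        random = "station_id", family = "binomial-probit")
  f0 <- fit_glmm(spec, d, mode = "agq0")
  f1 <- fit_glmm(spec, d, mode = "laplace")
  expect_true(f1$converged)
  # documented agreement: within ~10% relative difference on slopes
  rel <- abs(f1$beta[c("x1", "x2")] - f0$beta[c("x1", "x2")]) /
    abs(f0$beta[c("x1", "x2")])
  expect_lt(max(rel), 0.1)
  expect_lte(f1$deviance, f0$deviance + 1e-6)
})

test_that("adding terms never increases the deviance (nested monotonicity)", {
  for (s in 1:4) {
    d <- direct_probit_data(n = 200, beta = c(0.4, 0), seed = 40 + s)
    spec <- cc_model_spec("successes", fixed = c("x1", "x2"),
                          random = "station_id", family = "binomial-probit")
    full <- fit_glmm(spec, d)
    red <- cleanerclient:::cc_drop_term(full, "x2")
    expect_lte(full$deviance, red$deviance + 1e-3)
  }
})

test_that("non-nested and crossed structures are rejected", {
  d <- direct_probit_data(n = 100, seed = 2)
  d$other <- sample(c("u", "v", "w"), 100, replace = TRUE)
  spec <- cc_model_spec("successes", fixed = "x1",
                        random = c("station_id", "other"),
                        family = "binomial-probit")
  expect_error(fit_glmm(spec, d),
               class = "cc_error_unsupported_random_structure")
})
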