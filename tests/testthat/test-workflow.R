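test_that("vif_screen matches the closed form and flags degeneracy", {
  set.seed(2)
  n <- 400
  z1 <- rnorm(n); z2 <- rnorm(n)
  # Gram-Schmidt so the sample correlation is exactly 0.8
  e1 <- scale(z1)[, 1]
  e2 <- scale(resid(lm(z2 ~ z1)))[, 1]
  d <- data.frame(a = e1, b = 0.8 * e1 + sqrt(1 - 0.64) * e2)
  out <- vif_screen(d, c("a", "b"))
  expect_equal(out$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-8)
  expect_equal(round(out$vif[1], 2), 2.78)

  ortho <- data.frame(a = e1, b = e2)
  expect_equal(vif_screen(ortho, c("a", "b"))$vif, c(1, 1),
               tolerance = 1e-10)

  dup <- data.frame(a = e1, b = e1)
  res <- vif_screen(dup, c("a", "b"))
  expect_true(all(is.infinite(res$vif)))
  expect_true(all(res$flagged))

  expect_error(vif_screen(d, "a"), class = "cc_error_invalid_argument")
})

strong_world_setup <- function() {
  ds <- small_world(seed = 61, years = 2, n_per_year = 100,
                    effects = list(trophic_level = 0.6,
                                   client_local_abundance = 0.5))
  tab <- build_response_table(ds, "clean_frequency")
  std <- standardize_predictors(tab, c("trophic_level",
                                       "client_local_abundance",
                                       "body_size"))
  std$data
}

test_that("backward stepwise keeps strong terms and deletes pure noise", {
  d <- strong_world_setup()
  # both true effects strong; body_size is a pure-noise candidate
  spec <- cc_model_spec("clean_frequency",
                        fixed = c("trophic_level", "client_local_abundance",
                                  "body_size"))
  trace <- backward_stepwise(spec, d)
  expect_true("body_size" %in% trace$steps$term)
  expect_setequal(trace$final_spec$fixed,
                  c("trophic_level", "client_local_abundance"))
  # invariant: every retained term is significant at alpha
  for (t in trace$final_spec$fixed) {
    red <- cleanerclient:::cc_drop_term(trace$final_fit, t)
    expect_lt(likelihood_ratio_test(trace$final_fit, red)$p_value, 0.05)
  }

  spec2 <- cc_model_spec("clean_frequency",
                         fixed = c("trophic_level",
                                   "client_local_abundance"))
  trace2 <- backward_stepwise(spec2, d)
  expect_equal(nrow(trace2$steps), 0)

  trace3 <- backward_stepwise(cc_model_spec("clean_frequency",
                                            fixed = character()), d)
  expect_equal(nrow(trace3$steps), 0)
  expect_equal(trace3$final_spec$fixed, character(0))
})

test_that("forward check agrees with backward selection here", {
  d <- strong_world_setup()
  spec <- cc_model_spec("clean_frequency",
                        fixed = c("trophic_level", "client_local_abundance",
                                  "body_size"))
  trace <- backward_stepwise(spec, d)
  fwd <- forward_check(trace, d)
  expect_true(fwd$agreement)
  expect_setequal(fwd$selected, trace$final_spec$fixed)

  single <- backward_stepwise(cc_model_spec("clean_frequency",
                                            fixed = "trophic_level"), d)
  expect_true(forward_check(single, d)$agreement)
})

test_that("added-last importance is order-invariant and sums sensibly", {
  d <- strong_world_setup()
  spec_a <- cc_model_spec("clean_frequency",
                          fixed = c("trophic_level",
                                    "client_local_abundance"))
  spec_b <- cc_model_spec("clean_frequency",
                          fixed = c("client_local_abundance",
                                    "trophic_level"))
  imp_a <- importance_added_last(fit_glmm(spec_a, d))
  imp_b <- importance_added_last(fit_glmm(spec_b, d))
  get <- function(imp, t) imp$table$r2_change[imp$table$term == t]
  for (t in spec_a$fixed) {
    expect_equal(get(imp_a, t), get(imp_b, t), tolerance = 1e-6)
  }
  expect_equal(imp_a$table$rank, order(-imp_a$table$r2_change))

  # single-predictor model: its added-last change is the whole R2
  fit1 <- fit_glmm(cc_model_spec("clean_frequency",
                                 fixed = "trophic_level"), d)
  imp1 <- importance_added_last(fit1)
  expect_equal(imp1$table$r2_change[1], imp1$r2_final, tolerance = 1e-10)
})

test_that("group means satisfy the weighted-mean identity over the 3/4/5 split", {
  ds <- small_world(seed = 71, years = 2, n_per_year = 60)
  su <- freq_setup(ds)
  fit <- fit_glmm(su$spec, su$data)
  imp <- importance_added_last(fit, terms = contextual_factors()$factor)
  tab <- imp$table[!is.na(imp$table$group), ]
  sizes <- table(tab$group)[names(imp$group_means)]
  overall <- mean(tab$r2_change)
  weighted <- sum(imp$group_means * as.numeric(sizes)) / sum(sizes)
  expect_equal(overall, weighted, tolerance = 1e-12)
  expect_equal(as.numeric(sizes[c("PI", "PA", "TP")]), c(3, 4, 5))
})

test_that("within_year_nested reports per-year slopes and NA for constants", {
  ds <- small_world(seed = 81, years = 3, n_per_year = 70,
                    effects = list(trophic_level = 0.7))
  tab <- build_response_table(ds, "clean_frequency")
  std <- standardize_predictors(tab, c("trophic_level", "body_size"))
  d <- std$data
  spec <- cc_model_spec("clean_frequency", fixed = c("trophic_level", "year"))
  res <- within_year_nested("trophic_level", spec, d)
  expect_equal(res$n_years, 3)
  expect_gte(res$n_years_significant, 2)

  # make the predictor constant within the first year
  d2 <- d
  d2$body_size[d2$year == "2010"] <- 0
  spec2 <- cc_model_spec("clean_frequency", fixed = c("body_size", "year"))
  res2 <- within_year_nested("body_size", spec2, d2)
  expect_true(is.na(res2$per_year$p[res2$per_year$year == "2010"]))

  expect_error(within_year_nested("nope", spec, d),
               class = "cc_error_invalid_argument")
})

test_that("within_year_nested handles categorical predictors by yearly LRT", {
  ds <- small_world(seed = 91, years = 2, n_per_year = 80,
                    functional_group_effects = c(0, 0.8, -0.8, 0))
  su <- freq_setup(ds, fixed = c("functional_group", "trophic_level"))
  res <- within_year_nested("functional_group", su$spec, su$data)
  expect_equal(nrow(res$per_year), 2)
  expect_gte(res$n_years_significant, 1)
})

test_that("observer_sensitivity flags and notices behave", {
  ds <- small_world(seed = 101, years = 2, n_per_year = 60,
                    effects = list(trophic_level = 0.6))
  su <- freq_setup(ds, fixed = c("trophic_level", "observer_type"))
  std <- standardize_predictors(su$data, character(0))  # no-op
  out <- observer_sensitivity(su$spec, su$data)
  expect_true(out$flag)
  expect_true("trophic_level" %in% out$with_observer)

  no_obs <- su$data
  no_obs$observer_type <- NULL
  res <- observer_sensitivity(su$spec, no_obs)
  expect_true(is.na(res$flag))
  expect_match(res$notice, "skipped")
})
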