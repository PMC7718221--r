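#' Temporal models: year and time-of-day effects for the four behaviours
#'
#' Fits, for each of the four responses (clean/pose x frequency/duration),
#' a GLMM with year and (standardized) time of day as fixed effects, plus a
#' companion model with time of day nested within year (year-specific
#' slopes) to assess within-year diel patterns. Year significance is a
#' likelihood-ratio test of dropping `year`; between-year contrasts use
#' Tukey-adjusted pairwise comparisons.
#'
#' @param dataset a `cc_dataset`.
#' @param responses subset of the four response names (default all).
#' @param mode fitting mode.
#' @return named list of class `cc_temporal_set`; each element holds `fit`
#'   (year + time_of_day), `nested_fit` (year + year:time_of_day),
#'   `year_lrt`, `tod_lrt`, `tukey_year` (NULL when < 3 years),
#'   `within_year` (data.frame year, slope, z, p), `notice`.
#' @export
temporal_models <- function(dataset,
                            responses = c("clean_frequency", "pose_frequency",
                                          "clean_duration", "pose_duration"),
                            mode = "agq0") {
  if (!inherits(dataset, "cc_dataset")) cc_abort("`dataset` must be a cc_dataset")
  out <- lapply(responses, function(resp) {
    tab <- build_response_table(dataset, resp)
    tab <- standardize_predictors(tab, "time_of_day")$data
    n_years <- length(unique(tab$year))
    if (n_years < 2) {
      return(list(response = resp, notice = "single year: temporal contrast skipped",
                  fit = NULL))
    }
    spec <- cc_model_spec(resp, fixed = c("year", "time_of_day"))
    fit <- fit_glmm(spec, tab, mode = mode)
    red_year <- cc_drop_term(fit, "year")
    red_tod <- cc_drop_term(fit, "time_of_day")
    year_lrt <- likelihood_ratio_test(fit, red_year)
    tod_lrt <- likelihood_ratio_test(fit, red_tod)
    tukey_year <- if (n_years >= 3 && fit$converged) {
      tukey_posthoc(fit, "year")
    } else {
      NULL
    }
    nspec <- cc_model_spec(resp, fixed = c("year", "year:time_of_day"))
    nfit <- fit_glmm(nspec, tab, mode = mode)
    within <- cc_nested_slopes(nfit, "year", "time_of_day")
    list(response = resp, fit = fit, nested_fit = nfit,
         year_lrt = year_lrt, tod_lrt = tod_lrt, tukey_year = tukey_year,
         within_year = within, notice = NULL)
  })
  names(out) <- responses
  class(out) <- "cc_temporal_set"
  out
}

# Extract year-specific slopes (Wald z and p) for `pred` from a fit whose
# fixed part contains `year_term:pred` interaction columns.
cc_nested_slopes <- function(fit, year_term, pred) {
  co <- fit$coefficients
  lev <- fit$prep$xlevels[[year_term]]
  rows <- lapply(lev, function(y) {
    cn <- paste0(year_term, y, ":", pred)
    cn2 <- paste0(pred, ":", year_term, y)
    hit <- co[co$column %in% c(cn, cn2), , drop = FALSE]
    if (nrow(hit) == 0 || !is.finite(hit$se[1]) || hit$se[1] == 0) {
      # aliased (e.g. predictor constant within the year) or dropped
      return(data.frame(year = y, slope = NA_real_, z = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(year = y, slope = hit$estimate[1], z = hit$z[1], p = hit$p[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Within-year significance of a predictor, nested in year
#'
#' For a continuous predictor retained by the across-years model, refits the
#' model with the predictor nested within the categorical year factor
#' (`year + year:predictor`) and reports the per-year Wald z and p. For a
#' categorical predictor, the data are subset by year and a per-year
#' likelihood-ratio test of the whole factor is computed. Years in which the
#' predictor does not vary are reported as NA.
#'
#' @param predictor term name (must appear in `final_spec$fixed`).
#' @param final_spec the final across-years `cc_model_spec`.
#' @param data model-ready (standardized) data.frame with a `year` column.
#' @param alpha significance level used for the `n_years_significant` count.
#' @param mode fitting mode.
#' @return list with `per_year` (data.frame), `n_years_significant`,
#'   `n_years`.
#' @export
within_year_nested <- function(predictor, final_spec, data, alpha = 0.05,
                               mode = "agq0") {
  if (!predictor %in% final_spec$fixed) {
    cc_abort(paste0("`", predictor, "` is not in the final model"))
  }
  if (!"year" %in% names(data)) cc_abort("data has no `year` column")
  categorical <- !is.numeric(data[[predictor]])
  years <- sort(unique(as.character(data$year)))

  if (!categorical) {
    varies <- tapply(data[[predictor]], data$year, function(v) {
      length(unique(v)) > 1
    })
    spec <- final_spec
    spec$fixed <- unique(c("year", setdiff(final_spec$fixed, predictor),
                           paste0("year:", predictor)))
    fit <- fit_glmm(spec, data, mode = mode)
    per_year <- cc_nested_slopes(fit, "year", predictor)
    per_year$slope[!varies[per_year$year]] <- NA
    per_year$z[!varies[per_year$year]] <- NA
    per_year$p[!varies[per_year$year]] <- NA
  } else {
    per_year <- do.call(rbind, lapply(years, function(y) {
      sub <- data[data$year == y, , drop = FALSE]
      if (length(unique(sub[[predictor]])) < 2) {
        return(data.frame(year = y, slope = NA_real_, z = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      spec <- final_spec
      spec$fixed <- setdiff(final_spec$fixed, "year")
      full <- fit_glmm(spec, sub, mode = mode)
      red <- tryCatch(cc_drop_term(full, predictor), error = function(e) NULL)
      if (is.null(red) || !full$converged || !red$converged) {
        return(data.frame(year = y, slope = NA_real_, z = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      lrt <- likelihood_ratio_test(full, red)
      data.frame(year = y, slope = NA_real_, z = sqrt(max(lrt$chi_square, 0)),
                 p = lrt$p_value, stringsAsFactors = FALSE)
    }))
  }
  list(per_year = per_year,
       n_years_significant = sum(per_year$p < alpha, na.rm = TRUE),
       n_years = length(years))
}

#' Observer-type sensitivity check
#'
#' Refits the final model with and without the observer-type covariate and
#' reports whether the set of significant fixed effects (LRT p < alpha) is
#' unchanged. A `FALSE` flag is a reported outcome, typically indicating
#' confounding between observer identity and another predictor.
#'
#' @param final_spec final `cc_model_spec` (with or without
#'   `observer_type` in its fixed terms).
#' @param data model-ready data.frame.
#' @param alpha significance level.
#' @param mode fitting mode.
#' @return list with `flag`, `with_observer`, `without_observer` (character
#'   vectors of significant terms), or a `notice` when no observer column
#'   exists.
#' @export
observer_sensitivity <- function(final_spec, data, alpha = 0.05,
                                 mode = "agq0") {
  if (!"observer_type" %in% names(data)) {
    return(list(notice = "no observer_type column: check skipped",
                flag = NA))
  }
  sig_terms <- function(fit) {
    terms <- setdiff(fit$spec$fixed, "observer_type")
    keep <- vapply(terms, function(t) {
      red <- tryCatch(cc_drop_term(fit, t), error = function(e) NULL)
      if (is.null(red) || !red$converged || !fit$converged) return(NA)
      likelihood_ratio_test(fit, red)$p_value < alpha
    }, logical(1))
    terms[which(keep)]
  }
  spec_with <- final_spec
  spec_with$fixed <- unique(c(final_spec$fixed, "observer_type"))
  spec_without <- final_spec
  spec_without$fixed <- setdiff(final_spec$fixed, "observer_type")
  fit_with <- fit_glmm(spec_with, data, mode = mode)
  fit_without <- fit_glmm(spec_without, data, mode = mode)
  s_with <- sig_terms(fit_with)
  s_without <- sig_terms(fit_without)
  list(flag = setequal(s_with, s_without),
       with_observer = s_with, without_observer = s_without)
}
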