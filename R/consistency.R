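# The consistency classifier: the package's core procedure. A model is
# refitted on many random subsamples of observations; a predictor whose
# likelihood-ratio test is significant in at least `threshold` of the
# converged refits is a consistent predictor, one that is significant in
# the full-data model but falls below the threshold is dynamic.

#' Re-run a model on random observation subsamples
#'
#' Draws `n_sim` subsamples of `subsample_size` distinct observation IDs
#' (without replacement within a run; simple random sampling, ignoring year
#' structure unless `stratify_by_year`), refits the model on each subsample,
#' and records, per predictor, the likelihood-ratio p-value and the
#' standardized coefficient. All rows (species rows, or all events for
#' duration models) belonging to a selected observation enter the refit.
#' Standardization is expected to have been performed once on the full data
#' beforehand, so coefficients are comparable across runs.
#'
#' The random-effect scale is profiled once per subsample on the full model
#' and held fixed for the per-predictor reduced fits (`refit_theta = TRUE`
#' re-profiles each reduced fit). Run `i` is seeded `master_seed + i`, so
#' any contiguous prefix of runs is reproducible independently of `n_sim`.
#'
#' @param final_spec the `cc_model_spec` to re-run.
#' @param data model-ready (standardized) data.frame with `observation_id`.
#' @param n_sim number of simulations (the headline procedure uses 1000).
#' @param subsample_size observations per subsample (default 192, the mean
#'   yearly observation count of the emulated study design).
#' @param master_seed integer master seed.
#' @param predictors terms whose significance is recorded (default: all
#'   fixed terms except `observer_type`).
#' @param refit_theta logical; re-profile the variance for reduced fits.
#' @param stratify_by_year draw the subsample proportionally within years
#'   instead of simple random sampling (off by default).
#' @param mode fitting mode.
#' @return object of class `cc_sim_runs`: a long data.frame (`run`,
#'   `predictor`, `p`, `beta`, `converged`) with metadata attributes.
#' @export
run_subsample_simulations <- function(final_spec, data, n_sim = 1000,
                                      subsample_size = 192,
                                      master_seed = 1L,
                                      predictors = NULL,
                                      refit_theta = FALSE,
                                      stratify_by_year = FALSE,
                                      mode = "agq0") {
  stopifnot_count(n_sim, "n_sim", min = 1)
  stopifnot_count(subsample_size, "subsample_size", min = 2)
  if (!"observation_id" %in% names(data)) {
    cc_abort("data has no `observation_id` column")
  }
  ids <- unique(data$observation_id)
  if (length(ids) < subsample_size) {
    cc_abort(sprintf("only %d distinct observations; need >= %d",
                     length(ids), subsample_size))
  }
  predictors <- predictors %||% setdiff(final_spec$fixed, "observer_type")
  id_year <- if (stratify_by_year) {
    tapply(as.character(data$year), data$observation_id, function(v) v[1])
  } else {
    NULL
  }

  prep_full <- cc_prepare(final_spec, data)
  runs <- vector("list", n_sim)
  theta_warm <- NULL
  for (i in seq_len(n_sim)) {
    sub_ids <- with_seed(master_seed + i, {
      if (stratify_by_year) {
        yrs <- id_year[ids]
        per <- round(subsample_size * table(yrs) / length(ids))
        unlist(lapply(names(per), function(y) {
          sample(ids[yrs == y], min(per[[y]], sum(yrs == y)))
        }))
      } else {
        sample(ids, subsample_size)
      }
    })
    rows <- which(data$observation_id %in% sub_ids)
    full <- tryCatch(
      cc_fit_from_prep(cc_subset_prep(prep_full, rows), mode = mode,
                       theta_init = theta_warm),
      error = function(e) NULL)
    conv <- !is.null(full) && full$converged
    if (conv) theta_warm <- unname(full$theta)
    rec <- if (!conv) {
      data.frame(run = i, predictor = predictors, p = NA_real_,
                 beta = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      theta_fix <- if (refit_theta) NULL else unname(full$theta)
      do.call(rbind, lapply(predictors, function(t) {
        red <- tryCatch(cc_drop_term(full, t, theta_fix = theta_fix,
                                     lite = TRUE),
                        error = function(e) NULL)
        p <- if (!is.null(red) && red$converged) {
          likelihood_ratio_test(full, red)$p_value
        } else {
          NA_real_
        }
        data.frame(run = i, predictor = t, p = p,
                   beta = cc_term_beta(full, t), converged = TRUE,
                   stringsAsFactors = FALSE)
      }))
    }
    attr(rec, "ids") <- sub_ids
    runs[[i]] <- rec
  }
  out <- do.call(rbind, runs)
  attr(out, "subsamples") <- lapply(runs, attr, "ids")
  attr(out, "n_sim") <- n_sim
  attr(out, "subsample_size") <- subsample_size
  attr(out, "master_seed") <- master_seed
  attr(out, "predictors") <- predictors
  attr(out, "spec") <- final_spec
  class(out) <- c("cc_sim_runs", "data.frame")
  out
}

#' Classify predictors as consistent, dynamic or non-predictors
#'
#' From the subsample runs: the proportion of converged runs in which each
#' predictor's LRT was significant at `alpha`. Predictors at or above
#' `threshold` are labelled `consistent`; those below the threshold but
#' significant in the full-data model are `dynamic`; the rest are
#' `non-predictor`. The effect direction is the sign of the median
#' standardized coefficient across runs (NA for categorical predictors such
#' as the client functional group). Non-converged runs are excluded from
#' numerator and denominator; a warning fires if fewer than 95% of runs
#' converged.
#'
#' @param runs a `cc_sim_runs` object.
#' @param full_fit the converged full-data `cc_fit` of the same spec (may be
#'   omitted when `full_p` is supplied).
#' @param alpha per-run significance level (default 0.05).
#' @param threshold consistency proportion threshold (default 0.95).
#' @param full_p optional named vector of precomputed full-data LRT
#'   p-values per predictor.
#' @param refit_theta re-profile the random-effect scale for the full-data
#'   reduced fits (default TRUE; FALSE reuses the full fit's scale, much
#'   faster and adequate at full-data sizes).
#' @return data.frame of class `cc_consistency`: per predictor, `group`,
#'   `proportion_significant`, `p_min`, `p_max`, `direction`, `label`,
#'   `full_data_p`, `n_converged`.
#' @export
classify_consistency <- function(runs, full_fit = NULL, alpha = 0.05,
                                 threshold = 0.95, full_p = NULL,
                                 refit_theta = TRUE) {
  if (!inherits(runs, "cc_sim_runs")) {
    cc_abort("`runs` must come from run_subsample_simulations()")
  }
  predictors <- attr(runs, "predictors")
  conv <- runs[runs$converged & !is.na(runs$p), , drop = FALSE]
  if (nrow(conv) == 0) {
    cc_abort("no converged simulation runs", class = "non_estimable")
  }
  n_runs <- attr(runs, "n_sim")
  n_conv <- length(unique(conv$run))
  if (n_conv < 0.95 * n_runs) {
    warning(sprintf("only %d of %d simulation runs converged", n_conv, n_runs))
  }
  if (is.null(full_p)) {
    if (is.null(full_fit)) {
      cc_abort("need either `full_fit` or `full_p`")
    }
    theta_fix <- if (refit_theta) NULL else unname(full_fit$theta)
    full_p <- vapply(predictors, function(t) {
      red <- tryCatch(cc_drop_term(full_fit, t, theta_fix = theta_fix),
                      error = function(e) NULL)
      if (is.null(red) || !red$converged || !full_fit$converged) {
        return(NA_real_)
      }
      likelihood_ratio_test(full_fit, red)$p_value
    }, numeric(1))
  } else {
    full_p <- full_p[predictors]
    names(full_p) <- predictors
  }
  fmap <- contextual_factors()
  rows <- lapply(predictors, function(t) {
    sub <- conv[conv$predictor == t, , drop = FALSE]
    prop <- mean(sub$p < alpha)
    dir <- if (all(is.na(sub$beta))) {
      NA_character_
    } else {
      s <- sign(stats::median(sub$beta, na.rm = TRUE))
      c("-", "0", "+")[s + 2]
    }
    label <- if (prop >= threshold) {
      "consistent"
    } else if (!is.na(full_p[t]) && full_p[t] < alpha) {
      "dynamic"
    } else {
      "non-predictor"
    }
    data.frame(predictor = t,
               group = fmap$group[match(t, fmap$factor)],
               proportion_significant = prop,
               p_min = min(sub$p), p_max = max(sub$p),
               direction = dir, label = label,
               full_data_p = unname(full_p[t]),
               n_converged = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- threshold
  class(out) <- c("cc_consistency", "data.frame")
  out
}

#' Rank-importance p-values for consistent predictors
#'
#' Within each converged run, the consistent predictors are ranked by
#' absolute standardized coefficient; `rank_importance_p` for a predictor is
#' the proportion of runs in which it is ranked most important. A value
#' below `alpha` indicates the predictor was (almost) never the most
#' important one. The values sum to one across the consistent set.
#'
#' @param runs a `cc_sim_runs` object.
#' @param consistent_set character vector of consistent predictor names
#'   (continuous terms; categorical terms carry no single coefficient and
#'   are dropped with a warning).
#' @param alpha interpretation threshold.
#' @return data.frame `predictor`, `rank_importance_p`,
#'   `never_most_important`.
#' @export
rank_importance <- function(runs, consistent_set, alpha = 0.05) {
  if (!inherits(runs, "cc_sim_runs")) {
    cc_abort("`runs` must come from run_subsample_simulations()")
  }
  conv <- runs[runs$converged & runs$predictor %in% consistent_set, ,
               drop = FALSE]
  has_beta <- tapply(!is.na(conv$beta), conv$predictor, all)
  bad <- names(has_beta)[!has_beta]
  if (length(bad)) {
    warning(paste0("dropping categorical predictor(s) without a single ",
                   "coefficient: ", paste(bad, collapse = ", ")))
    consistent_set <- setdiff(consistent_set, bad)
    conv <- conv[conv$predictor %in% consistent_set, , drop = FALSE]
  }
  if (length(consistent_set) == 0) {
    cc_abort("no rankable consistent predictors")
  }
  if (length(consistent_set) == 1) {
    message("singleton consistent set: trivially most important (p = 1)")
    return(data.frame(predictor = consistent_set, rank_importance_p = 1,
                      never_most_important = FALSE,
                      stringsAsFactors = FALSE))
  }
  top_by_run <- tapply(seq_len(nrow(conv)), conv$run, function(ix) {
    sub <- conv[ix, ]
    sub$predictor[which.max(abs(sub$beta))]
  })
  props <- table(factor(unlist(top_by_run), levels = consistent_set))
  props <- as.numeric(props) / length(top_by_run)
  data.frame(predictor = consistent_set, rank_importance_p = props,
             never_most_important = props < alpha,
             stringsAsFactors = FALSE)
}

#' Empirical coefficient interval across simulation runs
#'
#' Percentile interval of the (absolute, by default) standardized
#' coefficient of one predictor across converged simulation runs.
#'
#' @param runs a `cc_sim_runs` object.
#' @param predictor predictor name.
#' @param level interval level (default 0.95; `level = 1` returns the full
#'   observed range).
#' @param absolute use `|beta|` (the ranking scale) rather than signed beta.
#' @param min_runs minimum converged runs required (default 40).
#' @return numeric `c(lo, hi)`.
#' @export
beta_interval <- function(runs, predictor, level = 0.95, absolute = TRUE,
                          min_runs = 40L) {
  if (!inherits(runs, "cc_sim_runs")) {
    cc_abort("`runs` must come from run_subsample_simulations()")
  }
  b <- runs$beta[runs$predictor == predictor & runs$converged]
  b <- b[!is.na(b)]
  if (length(b) < min_runs) {
    cc_abort(sprintf("only %d converged runs for `%s`; need >= %d",
                     length(b), predictor, min_runs),
             class = "non_estimable")
  }
  if (absolute) b <- abs(b)
  lo <- (1 - level) / 2
  unname(stats::quantile(b, c(lo, 1 - lo)))
}
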