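#' Backward stepwise refinement by likelihood-ratio deletion
#'
#' Starting from the full model, repeatedly drops the single fixed-effect
#' term with the largest likelihood-ratio p-value at or above `alpha` until
#' every remaining term tests below `alpha`. Ties (equal p) are broken by the
#' smaller absolute standardized coefficient, then by specification order.
#' Random effects and `protected` terms are never dropped.
#'
#' @param spec starting `cc_model_spec`.
#' @param data model-ready data.frame.
#' @param alpha retention threshold (default 0.05).
#' @param protected fixed-effect terms never considered for deletion
#'   (default `"observer_type"` when present, mirroring the convention of
#'   keeping the observer covariate until a final sensitivity check).
#' @param mode fitting mode passed to [fit_glmm()].
#' @return object of class `cc_trace`: list with `steps` (data.frame: step,
#'   term, chi_square, df, p), `final_spec`, `final_fit`, `start_spec`.
#' @export
backward_stepwise <- function(spec, data, alpha = 0.05,
                              protected = intersect("observer_type",
                                                    spec$fixed),
                              mode = "agq0") {
  fit <- fit_glmm(spec, data, mode = mode)
  steps <- data.frame(step = integer(), term = character(),
                      chi_square = numeric(), df = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    droppable <- setdiff(fit$spec$fixed, protected)
    if (!length(droppable)) break
    if (!fit$converged) {
      attr(steps, "non_estimable_at") <- step_i + 1L
      break
    }
    cand <- lapply(droppable, function(t) {
      red <- cc_drop_term(fit, t)
      if (!red$converged) return(list(term = t, p = NA_real_))
      lrt <- likelihood_ratio_test(fit, red)
      list(term = t, p = lrt$p_value, chisq = lrt$chi_square, df = lrt$df,
           beta = abs(cc_term_beta(fit, t)), fit = red)
    })
    ps <- vapply(cand, function(x) x$p %||% NA_real_, numeric(1))
    worst <- which(!is.na(ps) & ps >= alpha)
    if (!length(worst)) break
    # largest p first; ties by smaller |beta|, then input order
    betas <- vapply(cand, function(x) x$beta %||% Inf, numeric(1))
    betas[is.na(betas)] <- Inf
    ord <- worst[order(-ps[worst], betas[worst], worst)]
    pick <- cand[[ord[1]]]
    step_i <- step_i + 1L
    steps <- rbind(steps, data.frame(
      step = step_i, term = pick$term, chi_square = pick$chisq,
      df = pick$df, p = pick$p, stringsAsFactors = FALSE))
    fit <- pick$fit
  }
  out <- list(steps = steps, start_spec = spec, final_spec = fit$spec,
              final_fit = fit, alpha = alpha, protected = protected,
              data_name = deparse(substitute(data)))
  class(out) <- "cc_trace"
  out
}

#' @export
print.cc_trace <- function(x, ...) {
  cat("<cc_trace> backward stepwise refinement\n")
  if (nrow(x$steps) == 0) {
    cat("  no deletions: all terms significant at alpha =", x$alpha, "\n")
  } else {
    print(transform(x$steps, p = signif(p, 3)), row.names = FALSE)
  }
  cat("  final fixed terms:", paste(x$final_spec$fixed, collapse = " + "),
      "\n")
  invisible(x)
}

#' Forward stepwise cross-check of a backward refinement
#'
#' Greedy forward selection from the intercept (+ protected terms): at each
#' step the candidate term with the smallest LRT p-value below `alpha` is
#' added. Returns whether the forward route reaches the same final term set
#' as the backward trace; disagreement is a reported outcome, not an error,
#' and typically signals collinear predictors.
#'
#' @param trace a `cc_trace` from [backward_stepwise()].
#' @param data the same data used for the backward pass.
#' @return list with `agreement` (logical), `selected` (character) and
#'   `backward` (character).
#' @export
forward_check <- function(trace, data) {
  if (!inherits(trace, "cc_trace")) cc_abort("`trace` must be a cc_trace")
  alpha <- trace$alpha
  candidates <- setdiff(trace$start_spec$fixed, trace$protected)
  selected <- character()
  base_spec <- trace$start_spec
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    cur_spec <- base_spec
    cur_spec$fixed <- c(trace$protected, selected)
    cur <- fit_glmm(cur_spec, data, mode = trace$final_fit$mode)
    ps <- vapply(remaining, function(t) {
      sp <- base_spec
      sp$fixed <- c(trace$protected, selected, t)
      f <- fit_glmm(sp, data, mode = trace$final_fit$mode)
      if (!f$converged || !cur$converged) return(NA_real_)
      likelihood_ratio_test(f, cur)$p_value
    }, numeric(1))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= alpha) break
    selected <- c(selected, remaining[which.min(ps)])
  }
  backward_set <- setdiff(trace$final_spec$fixed, trace$protected)
  list(agreement = setequal(selected, backward_set),
       selected = selected, backward = backward_set)
}

#' Variance inflation factors
#'
#' Screens continuous predictors for multicollinearity: `VIF_j = 1 / (1 -
#' R2_j)` where `R2_j` is from the least-squares regression of predictor `j`
#' on the others. Perfect collinearity yields an infinite VIF, flagged rather
#' than thrown.
#'
#' @param data data.frame with the predictor columns.
#' @param terms at least two continuous column names.
#' @param threshold flag level for reporting (default 5).
#' @return data.frame with `term`, `vif`, `flagged`.
#' @export
vif_screen <- function(data, terms, threshold = 5) {
  if (length(terms) < 2) cc_abort("need at least 2 continuous terms")
  X <- as.matrix(data[, terms, drop = FALSE])
  if (!is.numeric(X)) cc_abort("all VIF terms must be numeric")
  vifs <- vapply(seq_along(terms), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = terms, vif = vifs, flagged = vifs > threshold,
             stringsAsFactors = FALSE)
}

#' Added-last importance of retained predictors
#'
#' For each fixed-effect term of the final model, the change in adjusted
#' deviance pseudo-R-squared when that term is added last: `delta_R2 =
#' adjR2(final) - adjR2(final minus term)`. Group means are reported over
#' the partner-identity / partner-abundance / third-party partition of the
#' contextual factors (terms outside that partition contribute to no group).
#' Both absolute differences (percentage points, used for ranking) and
#' differences relative to the final model's R-squared are returned.
#'
#' @param final_fit converged `cc_fit` of the final model.
#' @param terms terms to evaluate (default: all non-protected fixed terms).
#' @return list of class `cc_importance`: `table` (term, group, r2_change,
#'   r2_change_relative, rank), `group_means`, `r2_final`.
#' @export
importance_added_last <- function(final_fit, terms = NULL) {
  if (!inherits(final_fit, "cc_fit")) cc_abort("`final_fit` must be a cc_fit")
  if (!final_fit$converged) {
    cc_abort("final fit did not converge", class = "non_estimable")
  }
  terms <- terms %||% final_fit$spec$fixed
  # intercept(+random)-only baseline, obtained by peeling terms off the fit
  null_fit <- local({
    f <- final_fit
    for (t in final_fit$spec$fixed) f <- cc_drop_term(f, t)
    f
  })
  r2_full <- pseudo_r2_adjusted(final_fit, null_fit)
  rows <- lapply(terms, function(t) {
    red <- cc_drop_term(final_fit, t)
    if (!red$converged) {
      return(data.frame(term = t, r2_change = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(term = t, r2_change = r2_full - pseudo_r2_adjusted(red, null_fit),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fmap <- contextual_factors()
  tab$group <- fmap$group[match(tab$term, fmap$factor)]
  tab$r2_change_relative <- tab$r2_change / r2_full
  tab <- tab[order(-tab$r2_change), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  gm <- tapply(tab$r2_change, tab$group, mean, na.rm = TRUE)
  out <- list(table = tab[, c("term", "group", "r2_change",
                              "r2_change_relative", "rank")],
              group_means = gm, r2_final = r2_full)
  class(out) <- "cc_importance"
  out
}

#' @export
print.cc_importance <- function(x, ...) {
  cat(sprintf("<cc_importance> final adjusted pseudo-R2 = %.3f\n", x$r2_final))
  tab <- x$table
  tab$r2_change <- round(tab$r2_change, 4)
  tab$r2_change_relative <- round(tab$r2_change_relative, 3)
  print(tab, row.names = FALSE)
  cat("group means (added-last delta R2):\n")
  print(round(x$group_means, 4))
  invisible(x)
}
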