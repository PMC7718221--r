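#' Likelihood-ratio test between nested GLMM fits
#'
#' Compares two fits of the same family and mode on the same data. The
#' statistic is `2 * (logLik(full) - logLik(reduced))`; small negative values
#' arising from the approximate objective are clamped to zero with a warning.
#' Degrees of freedom are the difference in parameter count (fixed-effect
#' columns plus variance components); tests of a single random intercept use
#' df = 1 without a boundary correction, mirroring the conventional
#' chi-squared(1) reporting of station-effect tests.
#'
#' @param full,reduced `cc_fit` objects, `reduced` nested in `full`.
#' @param df optional degrees-of-freedom override.
#' @return list of class `cc_lrt` with `chi_square`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, df = NULL) {
  if (!inherits(full, "cc_fit") || !inherits(reduced, "cc_fit")) {
    cc_abort("both arguments must be cc_fit objects")
  }
  if (!full$converged || !reduced$converged) {
    cc_abort("cannot compare non-converged fits", class = "non_estimable")
  }
  if (full$family != reduced$family || full$mode != reduced$mode ||
      full$n != reduced$n) {
    cc_abort("fits are not comparable (family, mode or data differ)",
             class = "invalid_comparison")
  }
  full_cols <- full$columns %||% full$coefficients$column
  red_cols <- reduced$columns %||% reduced$coefficients$column
  if (!all(red_cols %in% full_cols) ||
      !all(names(reduced$theta) %in% c(names(full$theta), character(0)))) {
    cc_abort("`reduced` is not nested in `full`",
             class = "invalid_comparison")
  }
  k_full <- full$p + length(full$theta)
  k_red <- reduced$p + length(reduced$theta)
  if (k_full < k_red) {
    cc_abort("`reduced` has more parameters than `full`",
             class = "invalid_comparison")
  }
  chisq <- 2 * (full$loglik - reduced$loglik)
  if (chisq < 0) {
    # magnitudes within the variance-profiling tolerance (the two-factor
    # coordinate search resolves theta to ~2e-3) are silently clamped;
    # anything larger is worth a warning
    if (chisq < -0.05) {
      warning(sprintf(
        "negative LRT statistic (%.3g) clamped to 0; approximate likelihoods",
        chisq))
    }
    chisq <- 0
  }
  df_used <- df %||% max(1L, k_full - k_red)
  out <- list(chi_square = chisq, df = df_used,
              p_value = if (k_full == k_red && chisq == 0) 1 else
                stats::pchisq(chisq, df_used, lower.tail = FALSE))
  class(out) <- "cc_lrt"
  out
}

#' @export
print.cc_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-square(%d) = %.3f, p = %.4g\n",
              x$df, x$chi_square, x$p_value))
  invisible(x)
}

#' Pearson overdispersion ratio of a binomial fit
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom (`n` minus fixed-effect parameters minus variance components).
#' Values above 2 are conventionally flagged as excessive overdispersion.
#'
#' @param fit a converged binomial `cc_fit`.
#' @return list with `ratio`, `df_resid`, `excessive` (ratio > 2).
#' @export
overdispersion_ratio <- function(fit) {
  if (!inherits(fit, "cc_fit")) cc_abort("`fit` must be a cc_fit")
  if (fit$family != "binomial-probit") {
    cc_abort("overdispersion ratio is defined for binomial fits only",
             class = "not_applicable")
  }
  y <- fit$prep$y; mu <- fit$fitted; pw <- fit$prep$pw
  pearson <- (y - mu) * sqrt(pw / pmax(mu * (1 - mu), 1e-12))
  df_resid <- fit$n - fit$p - length(fit$theta)
  ratio <- sum(pearson^2) / df_resid
  list(ratio = ratio, df_resid = df_resid, excessive = ratio > 2)
}

#' Adjusted deviance pseudo-R-squared
#'
#' `R2_dev = 1 - deviance(fit) / deviance(null)`, computed on the summed
#' family deviance residuals (so it is bounded and family-agnostic), with the
#' classical small-sample adjustment
#' `1 - (1 - R2_dev) * (n - 1) / (n - k - 1)` where `k` counts fixed-effect
#' parameters excluding the intercept.
#'
#' @param fit a `cc_fit`.
#' @param null_fit the intercept(+random terms)-only fit on the same data.
#' @return adjusted pseudo-R-squared (a single number, at most 1).
#' @export
pseudo_r2_adjusted <- function(fit, null_fit) {
  if (!inherits(fit, "cc_fit") || !inherits(null_fit, "cc_fit")) {
    cc_abort("both arguments must be cc_fit objects")
  }
  if (fit$family != null_fit$family || fit$n != null_fit$n) {
    cc_abort("fits are not on the same data", class = "invalid_comparison")
  }
  r2 <- 1 - fit$deviance_resid / null_fit$deviance_resid
  k <- fit$p - 1L
  1 - (1 - r2) * (fit$n - 1) / (fit$n - k - 1)
}

#' Tukey all-pairs post-hoc contrasts for a categorical term
#'
#' Computes all pairwise contrasts between the levels of a fitted categorical
#' fixed effect, with p-values adjusted by the studentized range distribution
#' (the large-df Tukey HSD analogue appropriate for z-based mixed-model
#' inference).
#'
#' @param fit a converged `cc_fit`.
#' @param factor_name name of a categorical fixed-effect term with at least
#'   three levels.
#' @return data.frame with columns `contrast`, `estimate`, `se`, `z`,
#'   `p_adj`.
#' @export
tukey_posthoc <- function(fit, factor_name) {
  if (!inherits(fit, "cc_fit")) cc_abort("`fit` must be a cc_fit")
  lev <- fit$prep$xlevels[[factor_name]]
  if (is.null(lev)) {
    cc_abort(paste0("`", factor_name, "` is not a categorical term of the fit"))
  }
  if (length(lev) < 3) {
    cc_abort(paste0("`", factor_name, "` has fewer than 3 levels; ",
                    "use a plain likelihood-ratio test instead"))
  }
  cols <- paste0(factor_name, lev[-1])
  present <- cols %in% colnames(fit$vcov)
  if (!all(present)) {
    cc_abort(paste0("level columns missing from fit (aliased?): ",
                    paste(cols[!present], collapse = ", ")))
  }
  k <- length(lev)
  # effect of each level relative to the reference, reference = 0
  est <- c(0, fit$beta[cols])
  V <- matrix(0, k, k)
  V[-1, -1] <- fit$vcov[cols, cols]
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    contrast = apply(pairs, 2, function(ij) {
      paste(lev[ij[2]], "-", lev[ij[1]])
    }),
    estimate = apply(pairs, 2, function(ij) est[ij[2]] - est[ij[1]]),
    se = apply(pairs, 2, function(ij) {
      sqrt(V[ij[1], ij[1]] + V[ij[2], ij[2]] - 2 * V[ij[1], ij[2]])
    }),
    stringsAsFactors = FALSE
  )
  out$z <- out$estimate / out$se
  out$p_adj <- stats::ptukey(sqrt(2) * abs(out$z), nmeans = k, df = Inf,
                             lower.tail = FALSE)
  out
}
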