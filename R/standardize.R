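#' Scale and centre continuous predictors
#'
#' Centres each listed column to mean zero and scales it to unit standard
#' deviation (sample convention, denominator n - 1). Standardization is done
#' once on the full analysis table and frozen, so that coefficients from
#' subsample refits remain on a common scale.
#'
#' @param data data.frame.
#' @param terms character vector of continuous column names.
#' @return list with `data` (transformed), `center` and `scale` (named
#'   numeric vectors allowing back-transformation).
#' @export
standardize_predictors <- function(data, terms) {
  miss <- setdiff(terms, names(data))
  if (length(miss)) {
    cc_abort(paste0("columns not in data: ", paste(miss, collapse = ", ")))
  }
  center <- scale <- stats::setNames(numeric(length(terms)), terms)
  for (t in terms) {
    x <- data[[t]]
    if (!is.numeric(x)) cc_abort(paste0("`", t, "` is not numeric"))
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      cc_abort(paste0("predictor `", t, "` has zero variance"),
               class = "degenerate_predictor", term = t)
    }
    center[t] <- mean(x)
    scale[t] <- s
    data[[t]] <- (x - center[t]) / s
  }
  list(data = data, center = center, scale = scale)
}

#' Absolute-logit transform for interaction-duration proportions
#'
#' Durations are analysed as the proportion `p` of observation time spent
#' interacting, mapped to `|logit(p')|` with `p' = clamp(p, epsilon,
#' 1 - epsilon)`. The absolute value folds the scale so that both very short
#' and very long interactions are "extreme"; a small positive floor keeps the
#' response strictly positive, as required by the Gaussian log-link model.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param epsilon clamp distance from 0/1 (default 1e-4), in `(0, 0.5)`.
#' @param floor value substituted for exact zeros (`p = 0.5`), default 1e-6.
#' @return nonnegative numeric vector.
#' @export
transform_duration <- function(p, epsilon = 1e-4, floor = 1e-6) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    cc_abort("`p` must lie in [0, 1]")
  }
  if (epsilon <= 0 || epsilon >= 0.5) cc_abort("`epsilon` must be in (0, 0.5)")
  pc <- pmin(pmax(p, epsilon), 1 - epsilon)
  y <- abs(log(pc / (1 - pc)))
  pmax(y, floor)
}
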