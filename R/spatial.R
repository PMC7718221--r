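#' Station-level predicted means and relative standard errors
#'
#' Aggregates a fitted model's response-scale predictions per station:
#' the mean prediction, and the relative standard error `RSE = 100 *
#' SE(predictions) / |mean|`, a variability measure comparable across
#' stations with different sample sizes. Stations with fewer than two
#' predictions, or a zero mean, get `NA` with a notice.
#'
#' @param fit a converged `cc_fit` whose data contained `station_id`.
#' @param include_re include the station random intercept in the predictions
#'   (default TRUE: the station differences are the object of interest).
#' @return data.frame of class `cc_spatial`: `station_id`, `n`,
#'   `predicted_mean`, `rse_percent`.
#' @export
station_predicted_summary <- function(fit, include_re = TRUE) {
  if (!inherits(fit, "cc_fit")) cc_abort("`fit` must be a cc_fit")
  if (!fit$converged) cc_abort("fit did not converge", class = "non_estimable")
  gr <- fit$prep$groups[["station_id"]]
  if (is.null(gr)) cc_abort("fit has no station_id grouping")
  mu <- if (include_re) {
    fit$fitted
  } else {
    k <- match("station_id", names(fit$prep$groups))
    eta_re <- fit$theta[[k]] * fit$u[[k]][gr$idx]
    fit$prep$fam$linkinv(fit$eta - eta_re)
  }
  rows <- lapply(seq_len(gr$q), function(i) {
    v <- mu[gr$idx == i]
    m <- mean(v)
    rse <- if (length(v) < 2 || m == 0) {
      NA_real_
    } else {
      100 * (stats::sd(v) / sqrt(length(v))) / abs(m)
    }
    data.frame(station_id = gr$levels[i], n = length(v), predicted_mean = m,
               rse_percent = rse, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cc_spatial", "data.frame")
  out
}

#' Mantel permutation test of matrix association
#'
#' Pearson correlation between the upper triangles of two symmetric distance
#' (or dissimilarity) matrices, with significance from joint row/column
#' permutations of the second matrix. One-sided upper tail with the add-one
#' permutation p-value `(1 + #(r_perm >= r_obs)) / (1 + n_perm)`. With
#' `exhaustive = TRUE` all `n!` relabellings are enumerated (n <= 8) and the
#' p-value is the exact fraction of relabellings (identity included) with
#' `r_perm >= r_obs`.
#'
#' @param dist_a,dist_b square symmetric matrices with zero diagonal, same
#'   dimension >= 3.
#' @param n_perm number of random permutations (default 9999).
#' @param seed optional seed for the permutation draw.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list of class `cc_mantel`: `statistic` (r), `p_value`,
#'   `n_permutations`, `exhaustive`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 9999, seed = NULL,
                        exhaustive = FALSE) {
  a <- as.matrix(dist_a); b <- as.matrix(dist_b)
  if (!all(dim(a) == dim(b)) || nrow(a) != ncol(a)) {
    cc_abort("matrices must be square and of equal dimension")
  }
  n <- nrow(a)
  if (n < 3) cc_abort("need at least 3 stations")
  if (max(abs(a - t(a))) > 1e-8 || max(abs(b - t(b))) > 1e-8 ||
      any(abs(diag(a)) > 1e-8) || any(abs(diag(b)) > 1e-8)) {
    cc_abort("matrices must be symmetric with zero diagonal")
  }
  ut <- upper.tri(a)
  va <- a[ut]
  if (stats::sd(va) == 0 || stats::sd(b[ut]) == 0) {
    cc_abort("distance matrix has zero variance in its upper triangle",
             class = "undefined_statistic")
  }
  r_obs <- stats::cor(va, b[ut])
  stat_perm <- function(perm) stats::cor(va, b[perm, perm][ut])
  eps <- 1e-12
  if (exhaustive) {
    if (n > 8) cc_abort("exhaustive enumeration limited to n <= 8")
    perms <- cc_permutations(n)
    rs <- vapply(perms, stat_perm, numeric(1))
    p <- mean(rs >= r_obs - eps)
    n_used <- length(perms)
  } else {
    rs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      stat_perm(sample.int(n))
    }, numeric(1)))
    p <- (1 + sum(rs >= r_obs - eps)) / (1 + n_perm)
    n_used <- n_perm
  }
  out <- list(statistic = r_obs, p_value = p, n_permutations = n_used,
              exhaustive = exhaustive)
  class(out) <- "cc_mantel"
  out
}

#' @export
print.cc_mantel <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s%d permutations)\n",
              x$statistic, x$p_value,
              if (x$exhaustive) "exhaustive " else "", x$n_permutations))
  invisible(x)
}

# All permutations of 1..n (recursive; n <= 8 guard upstream).
cc_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- cc_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}

#' Aggregation PC1 score per station
#'
#' Summarises how clustered each station is with the first principal
#' component of three features: nearest-neighbour distance, the number of
#' stations within `radius_small` (default 3 m, typical cleaner swimming
#' range) and within `radius_large` (default 5 m, maximum observed swimming
#' distance). Radius counts use closed boundaries and exclude the focal
#' station. Features are standardized; zero-variance features are dropped
#' with a warning (all features degenerate, e.g. a regular grid, yields all
#' zero scores). The sign is oriented so that higher scores mean more
#' aggregated (positive loadings on the counts; nearest-neighbour distance
#' then loads negatively).
#'
#' @param stations data.frame with `station_id`, `x`, `y` (planar metres).
#' @param radius_small,radius_large aggregation radii in metres.
#' @return data.frame `station_id`, `nn_dist`, `n_within_small`,
#'   `n_within_large`, `pc1_score`.
#' @export
aggregation_pc1 <- function(stations, radius_small = 3, radius_large = 5) {
  if (nrow(stations) < 3) cc_abort("need at least 3 stations")
  D <- as.matrix(stats::dist(stations[, c("x", "y")]))
  diag(D) <- Inf
  feats <- cbind(
    nn_dist = apply(D, 1, min),
    n_within_small = rowSums(D <= radius_small),
    n_within_large = rowSums(D <= radius_large)
  )
  sds <- apply(feats, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(paste0("dropping zero-variance aggregation feature(s): ",
                   paste(colnames(feats)[!keep], collapse = ", ")))
  }
  scores <- if (!any(keep)) {
    rep(0, nrow(feats))
  } else {
    pc <- stats::prcomp(feats[, keep, drop = FALSE], center = TRUE,
                        scale. = TRUE)
    s <- pc$x[, 1]
    rot <- stats::setNames(pc$rotation[, 1], rownames(pc$rotation))
    counts <- intersect(names(rot), c("n_within_small", "n_within_large"))
    flip <- if (length(counts)) {
      sum(rot[counts]) < 0
    } else {
      rot["nn_dist"] > 0
    }
    if (flip) s <- -s
    s
  }
  data.frame(station_id = stations$station_id,
             nn_dist = feats[, "nn_dist"],
             n_within_small = feats[, "n_within_small"],
             n_within_large = feats[, "n_within_large"],
             pc1_score = unname(scores), stringsAsFactors = FALSE)
}

#' Correlation between station behaviour and aggregation
#'
#' Two-sided Pearson correlation test between per-station predicted
#' behaviour values and aggregation PC1 scores.
#'
#' @param behaviour numeric vector of per-station values (e.g.
#'   `predicted_mean` from [station_predicted_summary()]).
#' @param pc1 numeric vector of matching PC1 scores.
#' @return list with `r`, `p_value`, `n`.
#' @export
aggregation_correlation <- function(behaviour, pc1) {
  ok <- is.finite(behaviour) & is.finite(pc1)
  behaviour <- behaviour[ok]; pc1 <- pc1[ok]
  if (length(behaviour) < 3) cc_abort("need at least 3 stations")
  if (stats::sd(behaviour) == 0 || stats::sd(pc1) == 0) {
    cc_abort("zero variance in behaviour or aggregation scores",
             class = "undefined_statistic")
  }
  ct <- stats::cor.test(behaviour, pc1, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(behaviour))
}

#' Likelihood-ratio test for the station random intercept
#'
#' Compares the model with and without the station random intercept
#' (df = 1, the conventional reporting; no boundary correction, so the test
#' is mildly conservative).
#'
#' @param spec a `cc_model_spec` whose `random` includes `station_id`.
#' @param data model-ready data.frame.
#' @param mode fitting mode.
#' @return a `cc_lrt`.
#' @export
station_random_effect_test <- function(spec, data, mode = "agq0") {
  if (!"station_id" %in% (spec$random %||% character())) {
    cc_abort("spec does not include a station random intercept")
  }
  full <- fit_glmm(spec, data, mode = mode)
  red <- cc_drop_random(full, "station_id")
  likelihood_ratio_test(full, red, df = 1)
}
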