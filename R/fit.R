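# Random-intercept GLMM fitting by penalised iteratively reweighted least
# squares (PIRLS). The fast default mode ("agq0") jointly updates fixed
# effects and random-intercept modes inside PIRLS and profiles the
# relative random-effect standard deviation(s) on the Laplace objective;
# "laplace" additionally moves the fixed effects into the outer
# maximisation of the Laplace-approximated marginal likelihood.
#
# The solver is specialised to independent random intercepts with at most
# two grouping factors, the inner one nested in the outer (observation
# within station). This lets the penalised working system be solved by
# profiling the random effects out per outer-level block, so a fit costs
# O(n p^2) per PIRLS iteration instead of a dense (p + q)^3 solve - the
# property that makes thousand-fold subsample refits affordable.

cc_family <- function(name) {
  switch(name,
    "binomial-probit" = stats::binomial(link = "probit"),
    "gaussian-log" = stats::gaussian(link = "log"),
    cc_abort(paste0("unsupported family: ", name))
  )
}

# Build the numeric ingredients of a fit from a spec and a data.frame.
cc_prepare <- function(spec, data) {
  if (!inherits(spec, "cc_model_spec")) {
    cc_abort("`spec` must be a cc_model_spec")
  }
  if (!is.data.frame(data) || nrow(data) == 0) {
    cc_abort("`data` must be a nonempty data.frame")
  }
  fam <- cc_family(spec$family)
  n <- nrow(data)

  if (spec$family == "binomial-probit") {
    if (!spec$trials %in% names(data)) {
      cc_abort(paste0("binomial spec needs a trials column `", spec$trials,
                      "`"))
    }
    trials <- as.numeric(data[[spec$trials]])
    succ <- as.numeric(data[[spec$response_col]])
    if (any(trials <= 0) || any(succ < 0)) {
      cc_abort("binomial rows need trials > 0 and successes >= 0")
    }
    succ <- pmin(succ, trials)
    y <- succ / trials
    pw <- trials
    if (spec$weight_mode == "prior") {
      if (is.null(spec$weights) || !spec$weights %in% names(data)) {
        cc_abort("weight_mode = 'prior' needs a `weights` column")
      }
      w <- as.numeric(data[[spec$weights]])
      pw <- trials * w / mean(w)
    }
  } else {
    y <- as.numeric(data[[spec$response_col]])
    if (any(!is.finite(y))) cc_abort("response contains non-finite values")
    pw <- if (!is.null(spec$weights)) {
      as.numeric(data[[spec$weights]])
    } else {
      rep(1, n)
    }
  }

  # fixed-effect design: character columns become alphabetically-levelled
  # factors (treatment contrasts, reference = first level)
  vars <- unique(unlist(lapply(spec$fixed, function(t) all.vars(
    stats::reformulate(t)))))
  mf_data <- data
  xlevels <- list()
  for (v in intersect(vars, names(mf_data))) {
    if (is.character(mf_data[[v]]) || is.factor(mf_data[[v]])) {
      mf_data[[v]] <- factor(mf_data[[v]])
      xlevels[[v]] <- levels(mf_data[[v]])
    }
  }
  form <- if (length(spec$fixed)) {
    stats::reformulate(spec$fixed, intercept = TRUE)
  } else {
    ~1
  }
  X <- stats::model.matrix(form, mf_data)
  if (nrow(X) != n) {
    cc_abort("model frame dropped rows (missing values in predictors?)")
  }
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(form), "term.labels")
  # alias detection / removal
  dropped <- character()
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[-keep]
    assign <- assign[keep]
    X <- X[, keep, drop = FALSE]
  }

  groups <- list()
  for (r in spec$random %||% character()) {
    if (!r %in% names(data)) {
      cc_abort(paste0("random-effect column `", r, "` not in data"))
    }
    f <- factor(data[[r]])
    groups[[r]] <- list(idx = as.integer(f), q = nlevels(f),
                        levels = levels(f))
  }
  inner_by_outer <- NULL
  if (length(groups) == 2) {
    nest <- function(out, inn) {
      all(tapply(out$idx, inn$idx, function(v) length(unique(v))) == 1L)
    }
    if (nest(groups[[1]], groups[[2]])) {
      # groups[[2]] nested in groups[[1]]: keep order (outer first)
    } else if (nest(groups[[2]], groups[[1]])) {
      groups <- groups[c(2, 1)]
    } else {
      cc_abort("crossed random factors are not supported; random intercepts must be nested",
               class = "unsupported_random_structure")
    }
    outer_of_inner <- as.integer(tapply(groups[[1]]$idx, groups[[2]]$idx,
                                        function(v) v[1]))
    inner_by_outer <- split(seq_len(groups[[2]]$q), outer_of_inner)
    # outer levels with no inner rows cannot occur (same rows define both)
  }

  list(X = X, y = y, pw = pw, fam = fam, family = spec$family, n = n,
       groups = groups, inner_by_outer = inner_by_outer,
       assign = assign, term_labels = term_labels, xlevels = xlevels,
       dropped = dropped, spec = spec)
}

# Restrict a prepared design to a subset of rows (subsample refits reuse
# the full-data model matrix instead of rebuilding it). Aliasing introduced
# by the subset is left to surface as a flagged non-converged fit.
cc_subset_prep <- function(prep, rows) {
  out <- prep
  out$X <- prep$X[rows, , drop = FALSE]
  out$y <- prep$y[rows]
  out$pw <- prep$pw[rows]
  out$n <- length(rows)
  out$groups <- lapply(prep$groups, function(g) {
    f <- factor(g$idx[rows])
    list(idx = as.integer(f), q = nlevels(f),
         levels = g$levels[as.integer(levels(f))])
  })
  if (length(out$groups) == 2) {
    outer_of_inner <- as.integer(tapply(out$groups[[1]]$idx,
                                        out$groups[[2]]$idx,
                                        function(v) v[1]))
    out$inner_by_outer <- split(seq_len(out$groups[[2]]$q), outer_of_inner)
  }
  out
}

# Solve [B11 B12'; B12 diag(B22)] x = Rm via the scalar Schur complement
# S = B11 - sum(B12^2 / B22). Rm is (1+k) x m; B22 is the diagonal of the
# inner (observation-level) block.
cc_block_solve <- function(B12, B22, S, Rm) {
  r1 <- Rm[1, , drop = FALSE]
  r2 <- Rm[-1, , drop = FALSE]
  x1 <- (r1 - (B12 / B22) %*% r2) / S
  x2 <- (r2 - outer(B12, drop(x1))) / B22
  rbind(x1, x2)
}

# One PIRLS solve at fixed theta. `state` carries warm-start values across
# calls. If `beta_fix` is given the fixed effects are held at that value and
# only the random-effect modes are updated (used by the Laplace outer loop).
cc_pirls <- function(prep, theta, state = NULL, beta_fix = NULL,
                     maxit = 200L, tol = 1e-10) {
  X <- prep$X; y <- prep$y; pw <- prep$pw; fam <- prep$fam
  n <- prep$n; p <- ncol(X)
  K <- length(prep$groups)
  est_beta <- is.null(beta_fix)
  q1 <- if (K >= 1) prep$groups[[1]]$q else 0L
  q2 <- if (K >= 2) prep$groups[[2]]$q else 0L
  g1 <- if (K >= 1) prep$groups[[1]]$idx else NULL
  g2 <- if (K >= 2) prep$groups[[2]]$idx else NULL
  t1 <- if (K >= 1) theta[1] else 0
  t2 <- if (K >= 2) theta[2] else 0

  beta <- state$beta %||% if (est_beta) numeric(p) else beta_fix
  if (!est_beta) beta <- beta_fix
  u1 <- state$u1 %||% numeric(q1)
  u2 <- state$u2 %||% numeric(q2)
  eta <- state$eta %||% {
    if (prep$family == "binomial-probit") {
      fam$linkfun((pw * y + 0.5) / (pw + 1))
    } else {
      log(pmax(y, 0.05 * mean(pmax(y, 1e-8))))
    }
  }

  logdet <- 0
  Mp <- NULL
  conv <- FALSE
  it <- 0L

  repeat {
    it <- it + 1L
    mu <- fam$linkinv(eta)
    d <- pmax(fam$mu.eta(eta), 1e-7)
    v <- pmax(fam$variance(mu), 1e-10)
    W <- pw * d^2 / v
    # cap the working residual: saturated probit rows (|eta| >> 0) would
    # otherwise inject astronomically large pseudo-observations
    z <- eta + pmin(pmax((y - mu) / d, -1e3), 1e3)

    # pre-step penalised working RSS under the CURRENT weights, evaluated
    # at the current coefficients' model-space predictor (the raw
    # initialisation eta lies outside the model space, so using it as the
    # baseline would make the first exact solve look like an ascent). Both
    # the damping check and the convergence test compare against this, so
    # the comparison is never made across different weight matrices.
    eta_model <- if (it == 1L) {
      drop(X %*% beta) +
        (if (K >= 1) t1 * u1[g1] else 0) +
        (if (K >= 2) t2 * u2[g2] else 0)
    } else {
      eta
    }
    pwrss0 <- sum(W * (z - eta_model)^2) + sum(u1^2) + sum(u2^2)

    ok <- TRUE
    if (K == 0) {
      WX <- X * W
      Mp <- crossprod(X, WX)
      rhs <- crossprod(X, W * z)
      bnew <- tryCatch(drop(solve(Mp, rhs)), error = function(e) NULL)
      if (is.null(bnew)) { ok <- FALSE } else {
        beta_new <- if (est_beta) bnew else beta_fix
        u1_new <- u1; u2_new <- u2
        eta_new <- drop(X %*% beta_new)
        logdet <- 0
      }
      if (!est_beta) { beta_new <- beta_fix; eta_new <- drop(X %*% beta_fix) }
    } else if (K == 1) {
      WX <- X * W
      agg <- rowsum(cbind(W, W * z, WX), g1)
      sw <- agg[, 1]; sz <- agg[, 2]; sa <- agg[, -(1:2), drop = FALSE]
      den <- 1 + t1^2 * sw
      cvec <- t1^2 / den
      logdet <- sum(log(den))
      if (est_beta) {
        Mp <- crossprod(X, WX) - crossprod(sa, cvec * sa)
        rhs <- crossprod(X, W * z) - crossprod(sa, cvec * sz)
        beta_new <- tryCatch(drop(solve(Mp, rhs)), error = function(e) NULL)
        if (is.null(beta_new)) ok <- FALSE
      } else {
        beta_new <- beta_fix
      }
      if (ok) {
        resid_g <- sz - drop(sa %*% beta_new)
        u1_new <- t1 * resid_g / den
        u2_new <- u2
        eta_new <- drop(X %*% beta_new) + t1 * u1_new[g1]
      }
    } else {
      WX <- X * W
      agg2 <- rowsum(cbind(W, W * z, WX), g2)
      sw2 <- agg2[, 1]; sz2 <- agg2[, 2]; sa2 <- agg2[, -(1:2), drop = FALSE]
      agg1 <- rowsum(cbind(W, W * z, WX), g1)
      sw1 <- agg1[, 1]; sz1 <- agg1[, 2]; sa1 <- agg1[, -(1:2), drop = FALSE]
      XtWX <- crossprod(X, WX)
      XtWz <- crossprod(X, W * z)
      corrM <- matrix(0, p, p)
      corrv <- numeric(p)
      logdet <- 0
      blocks <- prep$inner_by_outer
      # per-station block: scalar station mode + diagonal observation modes
      pre <- vector("list", q1)
      for (i in seq_len(q1)) {
        J <- blocks[[i]]
        B11 <- 1 + t1^2 * sw1[i]
        B12 <- t1 * t2 * sw2[J]
        B22 <- 1 + t2^2 * sw2[J]
        S <- B11 - sum(B12^2 / B22)
        if (S <= 0) { ok <- FALSE; break }
        logdet <- logdet + log(S) + sum(log(B22))
        A <- rbind(t1 * sa1[i, , drop = FALSE],
                   t2 * sa2[J, , drop = FALSE])
        h <- c(t1 * sz1[i], t2 * sz2[J])
        BA <- cc_block_solve(B12, B22, S, A)
        Bh <- cc_block_solve(B12, B22, S, matrix(h, ncol = 1))
        corrM <- corrM + crossprod(A, BA)
        corrv <- corrv + drop(crossprod(A, Bh))
        pre[[i]] <- list(J = J, A = A, h = h, B12 = B12, B22 = B22, S = S)
      }
      if (ok) {
        if (est_beta) {
          Mp <- XtWX - corrM
          rhs <- XtWz - corrv
          beta_new <- tryCatch(drop(solve(Mp, rhs)), error = function(e) NULL)
          if (is.null(beta_new)) ok <- FALSE
        } else {
          beta_new <- beta_fix
        }
      }
      if (ok) {
        u1_new <- numeric(q1); u2_new <- numeric(q2)
        for (i in seq_len(q1)) {
          bl <- pre[[i]]
          vstar <- cc_block_solve(bl$B12, bl$B22, bl$S,
                                  matrix(bl$h - drop(bl$A %*% beta_new),
                                         ncol = 1))
          u1_new[i] <- vstar[1]
          u2_new[bl$J] <- vstar[-1]
        }
        eta_new <- drop(X %*% beta_new) + t1 * u1_new[g1] + t2 * u2_new[g2]
      }
    }

    if (!ok) {
      return(list(conv = FALSE, failed = TRUE, dev = Inf, iters = it))
    }

    # damped step on the working-scale penalised RSS (current weights):
    # halve the joint increment while it increases, guarding the Gaussian
    # log-link fits against overshoot without extra family evaluations
    pwrss_of <- function(eta_, u1_, u2_) {
      sum(W * (z - eta_)^2) + sum(u1_^2) + sum(u2_^2)
    }
    step <- 1
    stalled <- FALSE
    eta_old <- eta
    repeat {
      b_try <- beta + step * (beta_new - beta)
      u1_try <- u1 + step * (u1_new - u1)
      u2_try <- u2 + step * (u2_new - u2)
      eta_try <- if (step == 1) eta_new else {
        drop(X %*% b_try) +
          (if (K >= 1) t1 * u1_try[g1] else 0) +
          (if (K >= 2) t2 * u2_try[g2] else 0)
      }
      pwrss_new <- pwrss_of(eta_try, u1_try, u2_try)
      if (is.finite(pwrss_new) &&
          pwrss_new <= pwrss0 * (1 + 1e-9) + 1e-12) break
      if (step < 1e-4) { stalled <- TRUE; break }
      step <- step / 2
    }
    if (stalled) {
      # no acceptable step: stop here rather than walking away from the
      # optimum; the caller sees a non-converged (or boundary) fit
      conv <- FALSE
      break
    }
    beta <- b_try; u1 <- u1_try; u2 <- u2_try; eta <- eta_try

    done <- it >= 2L &&
      (abs(pwrss_new - pwrss0) < tol * (pwrss_new + 0.1) ||
         max(abs(eta - eta_old)) < 1e-9 * (stats::sd(eta) + 0.1))
    if (done) { conv <- TRUE; break }
    if (it >= maxit) break
  }

  mu <- fam$linkinv(eta)
  dev_resid <- sum(fam$dev.resids(y, mu, pw))
  pwrss <- dev_resid + sum(u1^2) + sum(u2^2)
  dev <- if (prep$family == "gaussian-log") {
    logdet + n * (1 + log(2 * pi * pwrss / n))
  } else {
    dev_resid + sum(u1^2) + sum(u2^2) + logdet
  }
  list(conv = conv, failed = FALSE, beta = beta, u1 = u1, u2 = u2,
       eta = eta, mu = mu, W = NULL, Mp = Mp, logdet = logdet,
       dev_resid = dev_resid, pwrss = pwrss, dev = dev, iters = it)
}

# Profile the relative random-effect standard deviation(s) over the
# objective, warm-starting PIRLS across evaluations.
cc_profile <- function(prep, theta_init = NULL, theta_fix = NULL,
                       beta_fix = NULL, control = list()) {
  K <- length(prep$groups)
  maxit <- control$maxit %||% 200L
  tol <- control$tol %||% 1e-10
  theta_max <- control$theta_max %||% 5
  state <- new.env(parent = emptyenv())
  state$warm <- NULL
  state$best <- NULL
  state$best_dev <- Inf

  run <- function(theta) {
    res <- cc_pirls(prep, theta, state = state$warm, beta_fix = beta_fix,
                    maxit = maxit, tol = tol)
    if (!res$failed) {
      st <- list(beta = res$beta, u1 = res$u1, u2 = res$u2, eta = res$eta)
      state$warm <- st
      if (res$conv && res$dev < state$best_dev) {
        state$best <- st
        state$best_dev <- res$dev
      }
    }
    res
  }

  if (K == 0) {
    theta <- numeric(0)
  } else if (!is.null(theta_fix)) {
    theta <- theta_fix
  } else if (K == 1) {
    f <- function(t) {
      r <- run(t)
      if (r$failed || !is.finite(r$dev)) 1e10 else r$dev
    }
    upper <- if (!is.null(theta_init) && is.finite(theta_init[1])) {
      min(theta_max, max(0.5, 3 * theta_init[1]))
    } else {
      theta_max
    }
    opt <- stats::optimize(f, interval = c(0, upper), tol = 1e-4)
    if (upper < theta_max && opt$minimum > 0.95 * upper) {
      opt <- stats::optimize(f, interval = c(0.8 * upper, theta_max),
                             tol = 1e-4)
    }
    theta <- opt$minimum
    if (f(0) <= opt$objective) theta <- 0
  } else {
    f2 <- function(tt) {
      r <- run(tt)
      if (r$failed || !is.finite(r$dev)) 1e10 else r$dev
    }
    # coordinate-wise Brent search with warm-started PIRLS: cheap and robust
    # for two independent nested intercepts, whose profiles are close to
    # separable
    th <- pmax(pmin(theta_init %||% c(0.3, 0.3), theta_max), 0)
    for (sweep in seq_len(control$sweeps %||% 2L)) {
      for (k in 1:2) {
        th[k] <- stats::optimize(function(t) {
          tt <- th; tt[k] <- t; f2(tt)
        }, interval = c(0, theta_max), tol = 2e-3)$minimum
      }
    }
    if (f2(c(0, 0)) <= f2(th)) th <- c(0, 0)
    theta <- th
  }
  # final solve from the best converged state seen during profiling (the
  # last evaluation may have been a probe, e.g. the theta = 0 boundary,
  # whose state is a poor start for the optimum)
  if (!is.null(state$best)) state$warm <- state$best
  final <- run(theta)
  list(theta = theta, res = final)
}

#' Fit a random-intercept GLMM
#'
#' Fits the model described by a [cc_model_spec()] using penalised
#' iteratively reweighted least squares with the random-effect scale(s)
#' profiled on the Laplace objective. `mode = "agq0"` (the default, and the
#' mode used throughout the analysis pipeline) keeps the fixed effects inside
#' the penalised working problem; `mode = "laplace"` additionally maximises
#' the Laplace-approximated marginal likelihood over the fixed effects,
#' starting from the agq0 solution. Non-convergence is a recorded outcome
#' (`converged = FALSE`), never an error.
#'
#' @param spec a `cc_model_spec`.
#' @param data model-ready data.frame (see [build_response_table()]);
#'   continuous predictors are expected to be standardized already so that
#'   coefficients are comparable (see [standardize_predictors()]).
#' @param mode `"agq0"` or `"laplace"`.
#' @param control list: `maxit` (PIRLS cap, default 200), `tol` (relative
#'   penalised-deviance tolerance, default 1e-8), `theta_max` (upper bound of
#'   the profiled relative standard deviation, default 10).
#' @return object of class `cc_fit`; see package vignette for the fields.
#' @export
fit_glmm <- function(spec, data, mode = c("agq0", "laplace"),
                     control = list()) {
  mode <- match.arg(mode)
  prep <- cc_prepare(spec, data)
  cc_fit_from_prep(prep, mode = mode, control = control)
}

# Core fit on a prepared design; shared by fit_glmm and all refit paths.
cc_fit_from_prep <- function(prep, mode = "agq0", control = list(),
                             theta_fix = NULL, theta_init = NULL,
                             lite = FALSE) {
  pr <- cc_profile(prep, theta_init = theta_init, theta_fix = theta_fix,
                   control = control)
  theta <- pr$theta
  res <- pr$res

  if (mode == "laplace" && length(prep$groups) > 0 && !res$failed) {
    p <- ncol(prep$X)
    K <- length(prep$groups)
    obj <- function(par) {
      th <- pmax(par[seq_len(K)], 0)
      bf <- par[-seq_len(K)]
      r <- cc_pirls(prep, th, state = list(beta = bf, u1 = res$u1,
                                           u2 = res$u2, eta = res$eta),
                    beta_fix = bf, maxit = control$maxit %||% 200L,
                    tol = control$tol %||% 1e-10)
      if (r$failed || !is.finite(r$dev)) 1e10 else r$dev
    }
    start <- c(theta, res$beta)
    opt <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = c(rep(0, K), rep(-Inf, p)),
                   control = list(maxit = 100L, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value <= res$dev + 1e-6) {
      theta <- pmax(opt$par[seq_len(K)], 0)
      # final joint solve at the refined theta for modes and vcov
      res <- cc_pirls(prep, theta, state = list(beta = opt$par[-seq_len(K)],
                                                u1 = res$u1, u2 = res$u2,
                                                eta = res$eta),
                      maxit = control$maxit %||% 200L,
                      tol = control$tol %||% 1e-10)
    }
  }

  n <- prep$n
  p <- ncol(prep$X)
  K <- length(prep$groups)
  converged <- !res$failed && res$conv
  sigma <- if (prep$family == "gaussian-log") sqrt(res$pwrss / n) else 1
  theta_named <- if (K) stats::setNames(theta, names(prep$groups)) else numeric(0)
  if (lite) {
    # deviance-only refit (used for the thousands of LRT reduced fits)
    out <- list(
      spec = prep$spec, mode = mode, family = prep$family, n = n, p = p,
      columns = colnames(prep$X), theta = theta_named,
      deviance = res$dev, loglik = -res$dev / 2,
      deviance_resid = res$dev_resid, converged = converged,
      singular = K > 0 && any(theta < 1e-4), iters = res$iters, lite = TRUE
    )
    class(out) <- "cc_fit"
    return(out)
  }
  vcov <- if (!res$failed && !is.null(res$Mp)) {
    tryCatch(solve(res$Mp) * sigma^2, error = function(e) {
      matrix(NA_real_, p, p)
    })
  } else {
    matrix(NA_real_, p, p)
  }
  dimnames(vcov) <- list(colnames(prep$X), colnames(prep$X))
  se <- sqrt(pmax(diag(vcov), 0))
  beta <- if (res$failed) rep(NA_real_, p) else res$beta
  names(beta) <- colnames(prep$X)
  zval <- beta / se
  coefs <- data.frame(
    column = colnames(prep$X),
    term = c("(Intercept)", prep$term_labels)[prep$assign + 1L],
    estimate = beta, se = se, z = zval,
    p = 2 * stats::pnorm(-abs(zval)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # gaussian deviance is -2 logLik (includes constants); binomial Laplace
  # deviance likewise plays the role of -2 logLik for nested comparisons
  out <- list(
    spec = prep$spec, mode = mode, family = prep$family,
    n = n, p = p, columns = colnames(prep$X),
    coefficients = coefs, beta = beta, vcov = vcov,
    theta = theta_named,
    re_sd = theta_named * sigma,
    sigma = sigma,
    deviance = res$dev, loglik = -res$dev / 2,
    deviance_resid = res$dev_resid,
    logdet = res$logdet, pwrss = res$pwrss,
    converged = converged,
    singular = K > 0 && any(theta < 1e-4),
    iters = res$iters,
    fitted = res$mu, eta = res$eta,
    u = if (K >= 1) {
      us <- list(res$u1)
      if (K >= 2) us <- c(us, list(res$u2))
      stats::setNames(us, names(prep$groups))
    } else {
      list()
    },
    dropped = prep$dropped,
    prep = prep
  )
  class(out) <- "cc_fit"
  out
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("<cc_fit> %s [%s, %s]%s\n", x$spec$response, x$family, x$mode,
              if (!x$converged) "  ** NOT CONVERGED **" else ""))
  cat(sprintf("  n = %d, deviance = %.3f, logLik = %.3f\n",
              x$n, x$deviance, x$loglik))
  if (length(x$re_sd)) {
    cat("  random-intercept sd: ",
        paste(sprintf("%s = %.3f", names(x$re_sd), x$re_sd), collapse = ", "),
        if (x$singular) " (singular fit: variance at boundary 0)", "\n",
        sep = "")
  }
  stats::printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "z",
                                                   "p")]),
                      P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

# Refit a cc_fit with a fixed-effect term removed (or with a different set
# of random terms), reusing the prepared design. `theta_fix` short-circuits
# the variance profiling (used inside subsample simulations where theta is
# profiled once per subsample on the full model).
cc_drop_term <- function(fit, term, theta_fix = NULL, control = list(),
                         lite = FALSE) {
  prep <- fit$prep
  if (!term %in% prep$spec$fixed) {
    cc_abort(paste0("term `", term, "` not in the model"),
             class = "invalid_comparison")
  }
  lab <- c("(Intercept)", prep$term_labels)[prep$assign + 1L]
  keep <- lab != term
  if (all(keep)) {
    # the term was aliased away entirely (e.g. a year-level covariate made
    # collinear by few years): dropping it changes nothing but the spec
    prep2 <- prep
    prep2$term_labels <- setdiff(prep$term_labels, term)
    prep2$assign <- match(lab, c("(Intercept)", prep2$term_labels)) - 1L
    spec2 <- prep$spec
    spec2$fixed <- setdiff(spec2$fixed, term)
    prep2$spec <- spec2
    return(cc_fit_from_prep(prep2, mode = fit$mode, control = control,
                            theta_fix = theta_fix,
                            theta_init = unname(fit$theta), lite = lite))
  }
  prep2 <- prep
  prep2$X <- prep$X[, keep, drop = FALSE]
  prep2$assign <- prep$assign[keep]
  prep2$term_labels <- setdiff(prep$term_labels, term)
  # reindex assign to the reduced term list
  old_terms <- c("(Intercept)", prep$term_labels)
  new_terms <- c("(Intercept)", prep2$term_labels)
  prep2$assign <- match(old_terms[prep$assign[keep] + 1L], new_terms) - 1L
  spec2 <- prep$spec
  spec2$fixed <- setdiff(spec2$fixed, term)
  prep2$spec <- spec2
  cc_fit_from_prep(prep2, mode = fit$mode, control = control,
                   theta_fix = theta_fix, theta_init = unname(fit$theta),
                   lite = lite)
}

cc_drop_random <- function(fit, random_term, control = list()) {
  prep <- fit$prep
  if (!random_term %in% names(prep$groups)) {
    cc_abort(paste0("random term `", random_term, "` not in the model"))
  }
  prep2 <- prep
  prep2$groups <- prep$groups[setdiff(names(prep$groups), random_term)]
  prep2$inner_by_outer <- NULL
  spec2 <- prep$spec
  spec2$random <- setdiff(spec2$random, random_term)
  prep2$spec <- spec2
  cc_fit_from_prep(prep2, mode = fit$mode, control = control)
}

# Single-number coefficient for a term: the estimate for one-column
# (continuous) terms, NA for multi-column categorical terms.
cc_term_beta <- function(fit, term) {
  rows <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (nrow(rows) == 1) rows$estimate else NA_real_
}
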