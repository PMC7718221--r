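#' Configure the true effect architecture of the generator
#'
#' Builds the coefficient trajectories that [generate_observations()] feeds
#' into its probit linear predictors. Each continuous contextual factor gets a
#' trajectory over years that is either
#' \itemize{
#'   \item \strong{constant}: a single coefficient repeated across years (the
#'     archetype of a consistent predictor),
#'   \item \strong{dynamic}: year-varying coefficients, modelled as a
#'     balanced +/- amplitude pattern over years (default amplitude 0.15)
#'     plus a small persistent component (`base`, default one tenth of the
#'     amplitude). The persistent component keeps the factor a genuine
#'     full-data predictor while the sign-alternating part destroys its
#'     subsample consistency, which is exactly how a dynamic predictor
#'     behaves. The default amplitude is deliberately moderate: with the
#'     low event baseline, the convexity of the probit mean converts large
#'     sign-alternating slopes into a strong pooled effect, which would turn
#'     a dynamic factor into a consistent one;
#'   \item \strong{random}: year coefficients drawn i.i.d. Normal(0, sd);
#'   \item \strong{null}: zero in every year.
#' }
#' A trajectory may also be supplied directly as a numeric vector of length
#' `years` (a scalar is recycled as a constant effect).
#'
#' @param years number of study years.
#' @param effects named list over continuous factor names (see
#'   [contextual_factors()]); each element is a numeric scalar/vector or a
#'   list such as `list(type = "dynamic", amplitude = 0.4)`. These
#'   trajectories drive the cleaning linear predictor.
#' @param pose_effects like `effects`, but for the posing linear predictor
#'   (default: all null). Posing gets its own architecture because
#'   pose-derived covariates (the client's local abundance under the
#'   cleaning-mode definition) would otherwise carry the cleaning model's
#'   own year-varying signal and act as a proxy regressor.
#' @param functional_group_effects numeric length-4 vector of level effects
#'   for the categorical factor (probit scale), default all zero.
#' @param station_sd standard deviation of the station random intercept on the
#'   probit scale (default 0.5).
#' @param obs_noise_sd row-level latent heterogeneity on the probit scale.
#'   With the default 0 the analysis model is exactly the generating model
#'   (pure binomial counts), which parameter-recovery checks require;
#'   positive values attenuate marginal probit coefficients by
#'   `1/sqrt(1 + obs_noise_sd^2)` and produce binomial overdispersion, and
#'   are the knob for overdispersion studies.
#' @param intercepts named vector with elements `clean`, `pose` (probit scale)
#'   and `duration` (log scale of the absolute-logit response).
#' @param duration_effects optional named list of trajectories for the
#'   duration linear predictor (defaults to all-null).
#' @param duration_station_sd,duration_obs_sd,duration_resid_sd variance
#'   components of the Gaussian log-link duration model.
#' @param seed seed used to materialise stochastic trajectories (dynamic sign
#'   patterns, random draws); part of the configuration, so that a config is a
#'   pure value.
#' @return object of class `cc_effects`.
#' @export
true_effect_config <- function(years,
                               effects = list(),
                               pose_effects = list(),
                               functional_group_effects = c(0, 0, 0, 0),
                               station_sd = 0.5,
                               obs_noise_sd = 0,
                               intercepts = c(clean = -1.8, pose = -1.6,
                                              duration = log(3)),
                               duration_effects = list(),
                               duration_station_sd = 0.3,
                               duration_obs_sd = 0.3,
                               duration_resid_sd = 0.8,
                               seed = 1L) {
  stopifnot_count(years, "years", min = 1)
  cont <- continuous_factors()
  bad <- setdiff(c(names(effects), names(pose_effects)), cont)
  if (length(bad)) {
    cc_abort(paste0("unknown factor(s) in `effects`: ",
                    paste(bad, collapse = ", ")))
  }
  if (length(functional_group_effects) != 4) {
    cc_abort("`functional_group_effects` must have length 4")
  }

  materialise <- function(spec, rng_offset) {
    if (is.numeric(spec)) {
      if (length(spec) == 1) return(rep(spec, years))
      if (length(spec) != years) {
        cc_abort(sprintf(
          "effect trajectory of length %d does not match years = %d",
          length(spec), years))
      }
      return(as.numeric(spec))
    }
    type <- spec$type %||% "constant"
    switch(type,
      constant = rep(spec$beta %||% 0, years),
      null = rep(0, years),
      dynamic = {
        amplitude <- spec$amplitude %||% 0.15
        base <- spec$base %||% (0.1 * amplitude)
        signs <- with_seed(seed + rng_offset,
                           sample(rep(c(1, -1), length.out = years)))
        base + amplitude * signs
      },
      random = {
        sd <- spec$sd %||% (spec$amplitude %||% 0.4)
        with_seed(seed + rng_offset, stats::rnorm(years, 0, sd))
      },
      cc_abort(paste0("unknown trajectory type: ", type))
    )
  }

  beta <- matrix(0, nrow = years, ncol = length(cont),
                 dimnames = list(NULL, cont))
  for (f in names(effects)) {
    beta[, f] <- materialise(effects[[f]], rng_offset = match(f, cont))
  }
  beta_pose <- matrix(0, nrow = years, ncol = length(cont),
                      dimnames = list(NULL, cont))
  for (f in names(pose_effects)) {
    beta_pose[, f] <- materialise(pose_effects[[f]],
                                  rng_offset = 200L + match(f, cont))
  }
  beta_dur <- matrix(0, nrow = years, ncol = length(cont),
                     dimnames = list(NULL, cont))
  for (f in names(duration_effects)) {
    if (!f %in% cont) cc_abort(paste0("unknown duration factor: ", f))
    beta_dur[, f] <- materialise(duration_effects[[f]],
                                 rng_offset = 100L + match(f, cont))
  }

  structure(list(
    years = years,
    beta = beta,
    beta_pose = beta_pose,
    beta_duration = beta_dur,
    functional_group_effects = functional_group_effects,
    station_sd = station_sd,
    obs_noise_sd = obs_noise_sd,
    intercepts = intercepts,
    duration_station_sd = duration_station_sd,
    duration_obs_sd = duration_obs_sd,
    duration_resid_sd = duration_resid_sd,
    seed = seed
  ), class = "cc_effects")
}
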