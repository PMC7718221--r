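fg_levels <- function() {
  c("solitary/sedentary", "solitary/free-ranging",
    "gregarious/sedentary", "gregarious/free-ranging")
}

#' Generate a synthetic multi-year cleaner-client observation dataset
#'
#' Emulates the structure of a long-term focal-observation study: `years`
#' study years, a configurable number of occupied cleaning stations per year,
#' and exactly `n_per_year` ten-minute focal observations per year. Each
#' observation records, per client species present, swim-by/pose/clean event
#' counts plus per-event durations. Counts are drawn by inverting the
#' analysis model: a probit linear predictor built from the standardized
#' contextual factors and the year-specific coefficient trajectories in
#' `effects`, a station random intercept, and row-level latent heterogeneity;
#' the binomial denominator is `round(observed_minutes * k_trials_per_min)`
#' so that event opportunity scales with the time the cleaner was in view.
#' Event durations are drawn so that the absolute-logit-transformed
#' proportion of observation time follows the Gaussian log-link duration
#' model.
#'
#' Swim-by counts, latent per-observation species pools and the wider
#' environment survey are generated first; posing counts are then drawn using
#' the posing-mode factor set (local abundance = swim-bys only), and cleaning
#' counts are drawn last using the cleaning-mode factor set (local abundance
#' = poses + swim-bys). All factors entering the linear predictors are hence
#' exactly recoverable by [derive_contextual_factors()], with one exception:
#' `n_species_cleaned` enters as a latent per-observation draw because the
#' realised value only exists after cleaning counts are drawn.
#'
#' @param community client community from [generate_community()].
#' @param stations station table from [generate_stations()].
#' @param effects a `cc_effects` configuration from [true_effect_config()].
#' @param n_per_year observations per year (default 192).
#' @param seed integer seed; fully determines the output.
#' @param k_trials_per_min binomial opportunity rate per minute (default 6,
#'   i.e. one opportunity per 10 s of observation).
#' @param occupancy optional integer vector (length `years`) of occupied
#'   stations per year; the default mimics the 15-60 station range observed
#'   across an 8-year study.
#' @return object of class `cc_dataset`: a list with elements `records`,
#'   `events`, `traits`, `survey`, `stations` and `params`. The generating
#'   truth (coefficients on the standardized scale, station effects) is
#'   attached as `attr(, "truth")`.
#' @export
generate_observations <- function(community, stations, effects,
                                  n_per_year = 192, seed = 1L,
                                  k_trials_per_min = 6,
                                  occupancy = NULL) {
  if (!inherits(effects, "cc_effects")) {
    cc_abort("`effects` must be created by true_effect_config()")
  }
  stopifnot_count(n_per_year, "n_per_year", min = 1)
  years <- effects$years
  n_st <- nrow(stations)
  year_labels <- as.character(2010 + seq_len(years) - 1L)

  if (is.null(occupancy)) {
    occupancy <- if (years == 8L && n_st >= 60L) {
      c(15L, 32L, 31L, 21L, 24L, 22L, 60L, 59L)
    } else {
      NA  # drawn below under the seed
    }
  } else if (length(occupancy) != years) {
    cc_abort("`occupancy` length must equal the number of years")
  }

  with_seed(seed, {
    if (anyNA(occupancy)) {
      occupancy <- sample(15:60, years, replace = TRUE)
    }
    occupancy <- pmin(occupancy, n_st, n_per_year)

    ## ---- observation-level frame -------------------------------------
    obs_list <- vector("list", years)
    counter <- 0L
    for (yi in seq_len(years)) {
      occ <- sample(stations$station_id, occupancy[yi])
      # every occupied station gets at least one observation
      st_assign <- c(occ, sample(occ, n_per_year - length(occ),
                                 replace = TRUE))
      st_assign <- sample(st_assign)
      obs_list[[yi]] <- data.frame(
        observation_id = sprintf("obs%05d", counter + seq_len(n_per_year)),
        station_id = st_assign,
        year = year_labels[yi],
        time_of_day = round(stats::runif(n_per_year, 7.5, 17.0), 2),
        observer_type = sample(c("multi-year", "single-year"), n_per_year,
                               replace = TRUE, prob = c(0.6, 0.4)),
        observed_minutes = round(10 - stats::runif(n_per_year, 0, 2), 2),
        stringsAsFactors = FALSE
      )
      counter <- counter + n_per_year
    }
    obs <- do.call(rbind, obs_list)
    obs$trials <- pmax(1L, as.integer(round(obs$observed_minutes *
                                              k_trials_per_min)))

    ## ---- yearly wider-environment survey -----------------------------
    yr <- data.frame(
      year = year_labels,
      cleaner_wider_abundance = round(stats::runif(years, 0.6, 1.28), 3),
      n_species_wider = sample(45:78, years, replace = TRUE),
      other_cleaner_abundance = round(stats::runif(years, 0.72, 3.19), 3),
      stringsAsFactors = FALSE
    )
    survey <- expand.grid(species_id = community$species_id,
                          year = year_labels,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    survey$median_per_min <- round(pmin(pmax(
      stats::rlnorm(nrow(survey), meanlog = -1, sdlog = 0.8), 0.01), 10), 3)
    survey <- merge(survey, yr, by = "year", sort = FALSE)

    ## ---- species rows per observation --------------------------------
    n_obs <- nrow(obs)
    pool <- pmin(1L + stats::rpois(n_obs, 1.6), 7L, nrow(community))
    n_cleaned_latent <- stats::rbinom(n_obs, size = pool, prob = 0.6)
    sp_idx <- unlist(lapply(seq_len(n_obs), function(i) {
      sample.int(nrow(community), pool[i], prob = community$commonness)
    }))
    row_obs <- rep(seq_len(n_obs), pool)

    rec <- obs[row_obs, , drop = FALSE]
    rownames(rec) <- NULL
    rec$species_id <- community$species_id[sp_idx]
    rec$swimby_count <- 1L + stats::rpois(nrow(rec), 2)
    rec$cleaner_local_abundance <- pmin(1L + stats::rpois(n_obs, 0.4),
                                        9L)[row_obs]
    # recorded as exogenous observation context (see vignette): recomputing
    # this from realized clean counts would make it a collider of the
    # response and bias every other coefficient
    rec$n_species_cleaned <- n_cleaned_latent[row_obs]

    ## ---- station effects and row noise -------------------------------
    # independent station effects per behaviour: a shared intercept would
    # correlate pose-derived covariates (client local abundance) with the
    # cleaning model's random effect and bias every coefficient
    b_st_pose <- stats::rnorm(n_st, 0, effects$station_sd)
    b_st_clean <- stats::rnorm(n_st, 0, effects$station_sd)
    b_st_dur <- stats::rnorm(n_st, 0, effects$duration_station_sd)
    names(b_st_pose) <- names(b_st_clean) <- names(b_st_dur) <-
      stations$station_id
    st_i <- match(rec$station_id, stations$station_id)
    yr_i <- match(rec$year, year_labels)
    fg <- paste(community$sociality[sp_idx], community$mobility[sp_idx],
                sep = "/")
    fg_eff <- effects$functional_group_effects[match(fg, fg_levels())]

    latent_cleaned <- n_cleaned_latent[row_obs]

    factor_matrix <- function(local_ab) {
      tot <- stats::ave(local_ab, rec$observation_id, FUN = sum)
      cbind(
        trophic_level = community$trophic_level[sp_idx],
        body_size = community$body_size[sp_idx],
        client_local_abundance = local_ab,
        cleaner_local_abundance = rec$cleaner_local_abundance,
        client_wider_abundance = survey$median_per_min[
          match(paste(rec$year, rec$species_id),
                paste(survey$year, survey$species_id))],
        cleaner_wider_abundance = yr$cleaner_wider_abundance[yr_i],
        n_species_cleaned = latent_cleaned,
        n_species_local = pool[row_obs],
        client_local_relative_abundance = ifelse(tot > 0, local_ab / tot, 0),
        n_species_wider = yr$n_species_wider[yr_i],
        other_cleaner_abundance = yr$other_cleaner_abundance[yr_i]
      )
    }
    standardize <- function(M) {
      mu <- colMeans(M)
      sd <- apply(M, 2, stats::sd)
      sd[sd == 0] <- 1
      sweep(sweep(M, 2, mu), 2, sd, "/")
    }
    linpred <- function(Fstd, beta, intercept, b_st) {
      intercept + rowSums(Fstd * beta[yr_i, colnames(Fstd), drop = FALSE]) +
        fg_eff + b_st[st_i] +
        stats::rnorm(nrow(rec), 0, effects$obs_noise_sd)
    }

    ## posing drawn first (posing-mode factors use swim-bys only)
    F_pose <- standardize(factor_matrix(rec$swimby_count))
    eta_pose <- linpred(F_pose, effects$beta_pose,
                        effects$intercepts[["pose"]], b_st_pose)
    rec$pose_count <- stats::rbinom(nrow(rec), rec$trials,
                                    stats::pnorm(eta_pose))

    ## cleaning drawn second (cleaning-mode local abundance = pose + swimby)
    F_clean <- standardize(factor_matrix(rec$pose_count + rec$swimby_count))
    eta_clean <- linpred(F_clean, effects$beta, effects$intercepts[["clean"]],
                         b_st_clean)
    rec$clean_count <- stats::rbinom(nrow(rec), rec$trials,
                                     stats::pnorm(eta_clean))

    ## ---- per-event durations ----------------------------------------
    make_events <- function(counts, Fstd, type) {
      keep <- counts > 0
      if (!any(keep)) {
        return(data.frame(observation_id = character(), species_id = character(),
                          event_type = character(), duration_s = numeric(),
                          stringsAsFactors = FALSE))
      }
      ridx <- rep(which(keep), counts[keep])
      eta_d <- effects$intercepts[["duration"]] +
        rowSums(Fstd[ridx, , drop = FALSE] *
                  effects$beta_duration[yr_i[ridx], colnames(Fstd),
                                        drop = FALSE]) +
        b_st_dur[st_i[ridx]]
      obs_re <- stats::rnorm(n_obs, 0, effects$duration_obs_sd)
      mu <- exp(eta_d + obs_re[row_obs[ridx]])
      w <- rec$observed_minutes[ridx]
      y <- pmax(stats::rnorm(length(ridx), mu,
                             effects$duration_resid_sd / sqrt(w / 10)),
                1e-3)
      # invert the absolute-logit transform on the p < 0.5 branch
      p <- stats::plogis(-y)
      data.frame(
        observation_id = rec$observation_id[ridx],
        species_id = rec$species_id[ridx],
        event_type = type,
        duration_s = round(p * rec$observed_minutes[ridx] * 60, 2),
        stringsAsFactors = FALSE
      )
    }
    events <- rbind(make_events(rec$clean_count, F_clean, "clean"),
                    make_events(rec$pose_count, F_pose, "pose"))

    out <- structure(list(
      records = rec,
      events = events,
      traits = as.data.frame(community),
      survey = survey,
      stations = as.data.frame(stations),
      params = list(n_per_year = n_per_year, years = years,
                    year_labels = year_labels, occupancy = occupancy,
                    k_trials_per_min = k_trials_per_min, seed = seed)
    ), class = "cc_dataset")
    attr(out, "truth") <- list(
      beta = effects$beta, beta_pose = effects$beta_pose,
      beta_duration = effects$beta_duration,
      functional_group_effects = effects$functional_group_effects,
      station_effects = list(pose = b_st_pose, clean = b_st_clean,
                             duration = b_st_dur),
      effects = effects,
      latent_n_species_cleaned = n_cleaned_latent
    )
    out
  })
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat("<cc_dataset>\n")
  cat(sprintf("  %d observations (%d species rows) across %d years, %d stations occupied\n",
              length(unique(x$records$observation_id)), nrow(x$records),
              x$params$years, length(unique(x$records$station_id))))
  cat(sprintf("  %d cleaning/posing events with durations\n", nrow(x$events)))
  invisible(x)
}
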