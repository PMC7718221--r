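#' Declarative GLMM specification
#'
#' Describes one of the four behavioural response models (or an arbitrary
#' custom response). Frequency responses are binomial with a probit link and
#' are weighted by observation length through the binomial denominator
#' (`trials = round(observed_minutes * k)`); duration responses are Gaussian
#' with a log link on the absolute-logit-transformed proportion of
#' observation time, with `observation_id` as an extra random intercept
#' because several events share an observation.
#'
#' @param response one of `"clean_frequency"`, `"pose_frequency"`,
#'   `"clean_duration"`, `"pose_duration"`, or the name of a response column
#'   in the data (in which case `family` must be given).
#' @param fixed ordered character vector of fixed-effect term labels
#'   (formula syntax, so interaction/nested terms like `"year:time_of_day"`
#'   are allowed).
#' @param random character vector of random-intercept grouping columns,
#'   subset of `c("station_id", "observation_id")` for the built-in
#'   responses.
#' @param family `"binomial-probit"` or `"gaussian-log"`; filled in
#'   automatically for the built-in responses.
#' @param trials column holding the binomial denominator (binomial only).
#' @param weights optional prior-weight column (used by duration models,
#'   default `"observed_minutes"` there; for frequency models weighting by
#'   observation length is already carried by the denominator, but a prior
#'   weight column may be supplied via `weight_mode = "prior"`).
#' @param weight_mode `"denominator"` (default) or `"prior"`; how observation
#'   length enters the binomial likelihood.
#' @return object of class `cc_model_spec`.
#' @export
cc_model_spec <- function(response,
                          fixed = character(),
                          random = NULL,
                          family = NULL,
                          trials = "trials",
                          weights = NULL,
                          weight_mode = c("denominator", "prior")) {
  weight_mode <- match.arg(weight_mode)
  builtin <- c("clean_frequency", "pose_frequency",
               "clean_duration", "pose_duration")
  if (response %in% builtin) {
    is_freq <- grepl("frequency$", response)
    family <- if (is_freq) "binomial-probit" else "gaussian-log"
    response_col <- switch(response,
      clean_frequency = "clean_count", pose_frequency = "pose_count",
      clean_duration = "duration_y", pose_duration = "duration_y")
    if (is.null(random)) {
      random <- if (is_freq) "station_id" else c("station_id", "observation_id")
    }
    if (!is_freq && is.null(weights)) weights <- "observed_minutes"
  } else {
    if (is.null(family)) {
      cc_abort("`family` must be supplied for a custom response column")
    }
    response_col <- response
    if (missing(random)) random <- "station_id"
  }
  if (!family %in% c("binomial-probit", "gaussian-log")) {
    cc_abort("`family` must be 'binomial-probit' or 'gaussian-log'")
  }
  if (length(random) > 2) {
    cc_abort("at most two random-intercept terms are supported")
  }
  structure(list(
    response = response, response_col = response_col, family = family,
    fixed = fixed, random = random, trials = trials, weights = weights,
    weight_mode = weight_mode
  ), class = "cc_model_spec")
}

#' @export
print.cc_model_spec <- function(x, ...) {
  cat(sprintf("<cc_model_spec> %s [%s]\n", x$response, x$family))
  cat("  fixed:  ", if (length(x$fixed)) paste(x$fixed, collapse = " + ")
      else "(intercept only)", "\n")
  cat("  random: ", paste(x$random, collapse = " + "), "\n")
  invisible(x)
}

#' Build the analysis table for one behavioural response
#'
#' Assembles the model-ready table from a `cc_dataset`: attaches the twelve
#' contextual factors in the response-appropriate mode (cleaning vs posing),
#' and for duration responses expands to one row per individual event with
#' the absolute-logit response `duration_y`.
#'
#' @param dataset a `cc_dataset`.
#' @param response one of the four built-in response names.
#' @param epsilon clamp parameter passed to [transform_duration()].
#' @return data.frame ready for [fit_glmm()].
#' @export
build_response_table <- function(dataset, response, epsilon = 1e-4) {
  if (!inherits(dataset, "cc_dataset")) {
    cc_abort("`dataset` must be a cc_dataset")
  }
  mode <- if (grepl("^clean", response)) "cleaning" else "posing"
  rec <- derive_contextual_factors(dataset$records, dataset$traits,
                                   dataset$survey, response_mode = mode)
  if (grepl("frequency$", response)) {
    return(rec)
  }
  type <- if (grepl("^clean", response)) "clean" else "pose"
  ev <- dataset$events[dataset$events$event_type == type, , drop = FALSE]
  if (nrow(ev) == 0) cc_abort(paste0("no ", type, " events in dataset"))
  key_ev <- paste(ev$observation_id, ev$species_id)
  key_rec <- paste(rec$observation_id, rec$species_id)
  tab <- rec[match(key_ev, key_rec), , drop = FALSE]
  rownames(tab) <- NULL
  tab$duration_s <- ev$duration_s
  prop <- ev$duration_s / (tab$observed_minutes * 60)
  tab$duration_y <- transform_duration(prop, epsilon = epsilon)
  tab
}
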