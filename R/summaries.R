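#' Per-year sampling-effort summary of an observation table
#'
#' Computes, per year: the number of occupied stations, the total number of
#' distinct focal observations, and the mean (+/- standard error over
#' per-station counts) number of observations per station. Also returns the
#' grand total of observations, the mean yearly observation count and the
#' total observation time assuming 10-minute focal watches.
#'
#' @param records a data.frame with at least `observation_id`, `station_id`
#'   and `year` (species rows may be repeated per observation; observations
#'   are counted as distinct `observation_id` values), or a `cc_dataset`.
#' @return list of class `cc_summary` with elements `per_year` (data.frame),
#'   `total_observations`, `mean_observations_per_year`, `total_minutes`,
#'   `total_hours`, `remaining_minutes`.
#' @export
summarize_dataset <- function(records) {
  if (inherits(records, "cc_dataset")) records <- records$records
  if (!is.data.frame(records) || nrow(records) == 0) {
    cc_abort("`records` must be a nonempty data.frame")
  }
  need <- c("observation_id", "station_id", "year")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    cc_abort(paste0("records are missing columns: ",
                    paste(miss, collapse = ", ")))
  }
  obs <- unique(records[, need])
  years <- sort(unique(obs$year))
  per_year <- do.call(rbind, lapply(years, function(y) {
    oy <- obs[obs$year == y, ]
    counts <- table(oy$station_id)
    m <- mean(counts)
    se <- if (length(counts) > 1) {
      stats::sd(counts) / sqrt(length(counts))
    } else {
      0
    }
    data.frame(year = y, n_stations = length(counts), n_observations = nrow(oy),
               mean_obs_per_station = m, se_obs_per_station = se,
               stringsAsFactors = FALSE)
  }))
  total <- sum(per_year$n_observations)
  total_minutes <- total * 10
  out <- list(
    per_year = per_year,
    total_observations = total,
    mean_observations_per_year = total / nrow(per_year),
    total_minutes = total_minutes,
    total_hours = total_minutes %/% 60,
    remaining_minutes = total_minutes %% 60
  )
  class(out) <- "cc_summary"
  out
}

#' @export
print.cc_summary <- function(x, ...) {
  cat("<cc_summary>\n")
  print(transform(x$per_year,
                  mean_obs_per_station = round(mean_obs_per_station, 2),
                  se_obs_per_station = round(se_obs_per_station, 2)),
        row.names = FALSE)
  cat(sprintf("total: %d observations (%d h %d min); mean %.1f per year\n",
              x$total_observations, x$total_hours, x$remaining_minutes,
              x$mean_observations_per_year))
  invisible(x)
}
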