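#' The twelve contextual factors and their groups
#'
#' Returns the canonical table of contextual factors used throughout the
#' package: three partner-identity (PI) factors, four partner-abundance (PA)
#' factors and five third-party (TP) factors. `functional_group` is the only
#' categorical factor (four levels: sociality x mobility).
#'
#' @return data.frame with columns `factor` and `group`.
#' @export
contextual_factors <- function() {
  data.frame(
    factor = c(
      "functional_group", "trophic_level", "body_size",
      "client_local_abundance", "cleaner_local_abundance",
      "client_wider_abundance", "cleaner_wider_abundance",
      "n_species_cleaned", "n_species_local",
      "client_local_relative_abundance", "n_species_wider",
      "other_cleaner_abundance"
    ),
    group = c(rep("PI", 3), rep("PA", 4), rep("TP", 5)),
    stringsAsFactors = FALSE
  )
}

#' @rdname contextual_factors
#' @export
continuous_factors <- function() {
  setdiff(contextual_factors()$factor, "functional_group")
}

#' Attach the twelve contextual factors to observation records
#'
#' Derives, for each focal-observation x client-species record, the full
#' contextual-factor set from raw event counts, a species trait table and the
#' yearly wider-environment survey. The client's local abundance combines
#' posing and swim-by counts when the response being modelled is cleaning,
#' but uses only swim-bys when the response is posing (posing cannot predict
#' itself). Per-observation species counts (`n_species_cleaned`,
#' `n_species_local`) and the local relative abundance are recomputed from the
#' records, so the function can be applied to real field tables as well as to
#' synthetic ones.
#'
#' @param records observation records (one row per observation x species) with
#'   at least `observation_id`, `year`, `species_id`, `pose_count`,
#'   `swimby_count`, `clean_count`, `cleaner_local_abundance`.
#' @param traits species trait table as returned by [generate_community()].
#' @param survey wider-environment survey table with one row per
#'   `(year, species_id)` and columns `median_per_min`, `n_species_wider`,
#'   `other_cleaner_abundance`, `cleaner_wider_abundance`.
#' @param response_mode `"cleaning"` or `"posing"`; controls how local client
#'   abundance and local species availability are computed.
#' @return `records` augmented with the twelve factor columns.
#' @export
derive_contextual_factors <- function(records, traits, survey,
                                      response_mode = c("cleaning", "posing")) {
  response_mode <- match.arg(response_mode)
  need <- c("observation_id", "year", "species_id", "pose_count",
            "swimby_count", "clean_count", "cleaner_local_abundance")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    cc_abort(paste0("records are missing columns: ",
                    paste(miss, collapse = ", ")), class = "missing_data")
  }

  sp_missing <- setdiff(unique(records$species_id), traits$species_id)
  if (length(sp_missing)) {
    cc_abort(paste0("no trait entry for species: ",
                    paste(sp_missing, collapse = ", ")),
             class = "missing_data")
  }
  key_rec <- paste(records$year, records$species_id, sep = "\r")
  key_sur <- paste(survey$year, survey$species_id, sep = "\r")
  sur_missing <- setdiff(unique(key_rec), key_sur)
  if (length(sur_missing)) {
    cc_abort(paste0("no survey entry for (year, species): ",
                    paste(gsub("\r", "/", sur_missing), collapse = ", ")),
             class = "missing_data")
  }

  out <- records
  ti <- match(records$species_id, traits$species_id)
  out$functional_group <- paste(traits$sociality[ti], traits$mobility[ti],
                                sep = "/")
  out$trophic_level <- traits$trophic_level[ti]
  out$body_size <- traits$body_size[ti]

  si <- match(key_rec, key_sur)
  out$client_wider_abundance <- survey$median_per_min[si]
  out$cleaner_wider_abundance <- survey$cleaner_wider_abundance[si]
  out$n_species_wider <- survey$n_species_wider[si]
  out$other_cleaner_abundance <- survey$other_cleaner_abundance[si]

  la <- if (response_mode == "cleaning") {
    records$pose_count + records$swimby_count
  } else {
    records$swimby_count
  }
  out$client_local_abundance <- la
  tot <- stats::ave(la, records$observation_id, FUN = sum)
  out$client_local_relative_abundance <- ifelse(tot > 0, la / tot, 0)

  present <- if (response_mode == "cleaning") {
    (records$pose_count + records$swimby_count) > 0
  } else {
    records$swimby_count > 0
  }
  out$n_species_local <- stats::ave(as.numeric(present),
                                    records$observation_id, FUN = sum)
  # If the records already carry a per-observation species-cleaned tally
  # (synthetic datasets record it as exogenous context), respect it;
  # otherwise compute it from the realized cleaning counts (field tables).
  if (!"n_species_cleaned" %in% names(records)) {
    out$n_species_cleaned <- stats::ave(as.numeric(records$clean_count > 0),
                                        records$observation_id, FUN = sum)
  }
  out
}
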