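#' Simulate a client-species community
#'
#' Draws a set of client fish species with the traits used as partner-identity
#' predictors: trophic level (2-4.4), body size (9-150 cm, log-uniform so that
#' small-bodied species dominate, as in reef assemblages), and a functional
#' group formed by crossing sociality (solitary vs gregarious) with mobility
#' (sedentary vs free-ranging). A relative "commonness" weight (log-normal) is
#' attached per species and used by [generate_observations()] to make some
#' clients frequent visitors and others rare, mimicking reef abundance skew.
#'
#' @param n_species number of client species (>= 2); all four functional
#'   groups are represented whenever `n_species >= 4`.
#' @param seed optional integer seed; the same `(n_species, seed)` pair always
#'   returns an identical community.
#' @return a data.frame of class `cc_community` with columns `species_id`,
#'   `trophic_level`, `body_size`, `sociality`, `mobility`,
#'   `functional_group`, `commonness`.
#' @export
generate_community <- function(n_species, seed = NULL) {
  stopifnot_count(n_species, "n_species", min = 0)
  if (n_species < 2) {
    cc_abort("`n_species` must be at least 2 to form a client community")
  }
  with_seed(seed, {
    soc <- c("solitary", "gregarious")
    mob <- c("sedentary", "free-ranging")
    combos <- expand.grid(sociality = soc, mobility = mob,
                          stringsAsFactors = FALSE)
    if (n_species >= 4) {
      idx <- c(seq_len(4), sample.int(4, n_species - 4, replace = TRUE))
    } else {
      idx <- sample.int(4, n_species, replace = TRUE)
    }
    out <- data.frame(
      species_id = sprintf("sp%03d", seq_len(n_species)),
      trophic_level = round(stats::runif(n_species, 2, 4.4), 2),
      body_size = round(exp(stats::runif(n_species, log(9), log(150)))),
      sociality = combos$sociality[idx],
      mobility = combos$mobility[idx],
      stringsAsFactors = FALSE
    )
    out$functional_group <- paste(out$sociality, out$mobility, sep = "/")
    out$commonness <- stats::rlnorm(n_species, meanlog = 0, sdlog = 1)
    class(out) <- c("cc_community", "data.frame")
    out
  })
}

#' Place cleaning stations on a rectangular reef area
#'
#' Stations are placed by sequential rejection sampling: uniform proposals in
#' the area, accepted when at least `min_sep` metres from every previously
#' accepted station. Coordinates are planar metres; latitude/longitude input
#' must be projected before use (at a 70 x 60 m site a local tangent plane is
#' adequate).
#'
#' @param n_stations number of stations to place.
#' @param area `c(width, height)` in metres (default the 70 x 60 study area).
#' @param min_sep minimum pairwise separation in metres (default 1).
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling cap per station before the placement is
#'   declared infeasible.
#' @return data.frame of class `cc_stations` with `station_id`, `x`, `y`.
#' @export
generate_stations <- function(n_stations, area = c(70, 60), min_sep = 1,
                              seed = NULL, max_tries = 5000L) {
  stopifnot_count(n_stations, "n_stations", min = 1)
  if (length(area) != 2 || any(!is.finite(area)) || any(area <= 0)) {
    cc_abort("`area` must be c(width, height) with positive entries")
  }
  with_seed(seed, {
    xs <- numeric(n_stations)
    ys <- numeric(n_stations)
    for (i in seq_len(n_stations)) {
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        px <- stats::runif(1, 0, area[1])
        py <- stats::runif(1, 0, area[2])
        if (i == 1L ||
            min((xs[seq_len(i - 1)] - px)^2 + (ys[seq_len(i - 1)] - py)^2) >=
              min_sep^2) {
          xs[i] <- px
          ys[i] <- py
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        cc_abort(
          sprintf(paste0(
            "could not place station %d of %d at min_sep = %g m in a ",
            "%g x %g m area after %d tries"),
            i, n_stations, min_sep, area[1], area[2], max_tries),
          class = "placement_failure", placed = i - 1L
        )
      }
    }
    out <- data.frame(
      station_id = sprintf("st%03d", seq_len(n_stations)),
      x = xs, y = ys, stringsAsFactors = FALSE
    )
    class(out) <- c("cc_stations", "data.frame")
    out
  })
}
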