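test_that("generate_community respects trait ranges and determinism", {
  com <- generate_community(25, seed = 7)
  expect_equal(nrow(com), 25)
  expect_true(all(com$trophic_level >= 2 & com$trophic_level <= 4.4))
  expect_true(all(com$body_size >= 9 & com$body_size <= 150))
  expect_setequal(unique(com$functional_group),
                  c("solitary/sedentary", "solitary/free-ranging",
                    "gregarious/sedentary", "gregarious/free-ranging"))
  expect_identical(com, generate_community(25, seed = 7))
  expect_error(generate_community(1), class = "cc_error_invalid_argument")
})

test_that("generate_stations enforces separation and detects infeasible packing", {
  st <- generate_stations(82, area = c(70, 60), min_sep = 1, seed = 3)
  expect_equal(nrow(st), 82)
  D <- as.matrix(dist(st[, c("x", "y")]))
  diag(D) <- Inf
  expect_gte(min(D), 1)
  expect_true(all(st$x >= 0 & st$x <= 70 & st$y >= 0 & st$y <= 60))

  two <- generate_stations(2, seed = 1)
  expect_gte(dist(two[, c("x", "y")])[1], 1)

  expect_error(generate_stations(10000, area = c(2, 2), min_sep = 1,
                                 seed = 1, max_tries = 200),
               class = "cc_error_placement_failure")
})

test_that("generate_observations keeps exact per-year bookkeeping and invariants", {
  ds <- small_world(seed = 5, years = 3, n_per_year = 40)
  rec <- ds$records
  obs <- unique(rec[, c("observation_id", "year")])
  expect_equal(nrow(obs), 3 * 40)
  expect_true(all(table(obs$year) == 40))
  expect_true(all(rec$observed_minutes > 0 & rec$observed_minutes <= 10))
  expect_true(all(rec$time_of_day >= 7.5 & rec$time_of_day <= 17))
  expect_true(all(rec$clean_count >= 0 & rec$pose_count >= 0 &
                    rec$swimby_count >= 0))
  expect_true(all(rec$clean_count <= rec$trials))
  # event durations positive and bounded by observed time
  ev <- ds$events
  m <- rec$observed_minutes[match(ev$observation_id, rec$observation_id)]
  expect_true(all(ev$duration_s > 0))
  expect_true(all(ev$duration_s <= m * 60))
})

test_that("generator output is byte-identical under the same seed", {
  a <- small_world(seed = 11)
  b <- small_world(seed = 11)
  expect_identical(a$records, b$records)
  expect_identical(a$events, b$events)
  expect_identical(a$survey, b$survey)
  c <- small_world(seed = 12)
  expect_false(identical(a$records$clean_count, c$records$clean_count))
})

test_that("trajectory length mismatch is rejected", {
  expect_error(true_effect_config(years = 4,
                                  effects = list(trophic_level = c(0.1, 0.2))),
               class = "cc_error_invalid_argument")
  expect_error(true_effect_config(years = 3, effects = list(nope = 1)),
               class = "cc_error_invalid_argument")
})

test_that("derive_contextual_factors implements the mode-dependent definitions", {
  traits <- data.frame(species_id = c("a", "b"),
                       trophic_level = c(2.5, 4.0), body_size = c(12, 80),
                       sociality = c("solitary", "gregarious"),
                       mobility = c("sedentary", "free-ranging"),
                       stringsAsFactors = FALSE)
  survey <- data.frame(year = "2010", species_id = c("a", "b"),
                       median_per_min = c(0.5, 1.2), n_species_wider = 50,
                       other_cleaner_abundance = 1.1,
                       cleaner_wider_abundance = 0.9,
                       stringsAsFactors = FALSE)
  rec <- data.frame(observation_id = c("o1", "o1", "o2"),
                    station_id = "s1", year = "2010",
                    species_id = c("a", "b", "a"),
                    pose_count = c(3L, 1L, 0L),
                    swimby_count = c(2L, 0L, 4L),
                    clean_count = c(2L, 0L, 1L),
                    cleaner_local_abundance = 2L,
                    stringsAsFactors = FALSE)

  cl <- derive_contextual_factors(rec, traits, survey, "cleaning")
  expect_equal(cl$client_local_abundance, c(5, 1, 4))
  expect_equal(cl$client_local_relative_abundance, c(5 / 6, 1 / 6, 1))
  expect_equal(cl$n_species_local, c(2, 2, 1))
  expect_equal(cl$n_species_cleaned, c(1, 1, 1))  # computed from counts here
  expect_true(all(contextual_factors()$factor %in% names(cl)))

  po <- derive_contextual_factors(rec, traits, survey, "posing")
  expect_equal(po$client_local_abundance, c(2, 0, 4))
  expect_equal(po$n_species_local, c(1, 1, 1))

  # a generator-provided species-cleaned tally is respected
  rec2 <- rec
  rec2$n_species_cleaned <- 7L
  cl2 <- derive_contextual_factors(rec2, traits, survey, "cleaning")
  expect_equal(cl2$n_species_cleaned, rep(7L, 3))

  # missing trait / survey entries name the offender
  expect_error(derive_contextual_factors(
    transform(rec, species_id = c("a", "zz", "a")), traits, survey),
    "zz", class = "cc_error_missing_data")
  expect_error(derive_contextual_factors(
    transform(rec, year = "2099"), traits, survey),
    "2099", class = "cc_error_missing_data")
})

test_that("generated factors stay within their documented ranges", {
  ds <- small_world(seed = 21, years = 2, n_per_year = 60, n_species = 15)
  tab <- build_response_table(ds, "clean_frequency")
  expect_true(all(tab$trophic_level >= 2 & tab$trophic_level <= 4.4))
  expect_true(all(tab$body_size >= 9 & tab$body_size <= 150))
  expect_true(all(tab$cleaner_local_abundance >= 0 &
                    tab$cleaner_local_abundance <= 9))
  expect_true(all(tab$cleaner_wider_abundance >= 0.6 &
                    tab$cleaner_wider_abundance <= 1.28))
  expect_true(all(tab$n_species_cleaned >= 0 & tab$n_species_cleaned <= 7))
  expect_true(all(tab$n_species_local >= 0 & tab$n_species_local <= 14))
  expect_true(all(tab$client_local_relative_abundance >= 0 &
                    tab$client_local_relative_abundance <= 1))
  expect_true(all(tab$n_species_wider >= 45 & tab$n_species_wider <= 78))
  expect_true(all(tab$other_cleaner_abundance >= 0.72 &
                    tab$other_cleaner_abundance <= 3.19))
})

test_that("summarize_dataset computes per-year means, SEs and totals", {
  # encode two study years with known arithmetic: 61 obs over 15 stations
  # and 271 over 32
  mk <- function(year, n_obs, n_st, off) {
    data.frame(
      observation_id = sprintf("o%s_%03d", year, seq_len(n_obs)),
      station_id = sprintf("s%03d", off + rep_len(seq_len(n_st), n_obs)),
      year = year, stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("2010", 61, 15, 0), mk("2011", 271, 32, 100))
  s <- summarize_dataset(rec)
  expect_equal(round(s$per_year$mean_obs_per_station, 2), c(4.07, 8.47))
  expect_equal(s$per_year$n_stations, c(15, 32))
  expect_equal(s$total_observations, 332)

  one <- summarize_dataset(mk("2012", 5, 1, 0))
  expect_equal(one$per_year$mean_obs_per_station, 5)
  expect_equal(one$per_year$se_obs_per_station, 0)

  expect_error(summarize_dataset(rec[0, ]),
               class = "cc_error_invalid_argument")
})
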