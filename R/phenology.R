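#' Generate flowering phenology under synchronous protogyny
#'
#' Gives every ramet one inflorescence and schedules its flowers so that
#' the inflorescence is functionally unisexual on any day: all female
#' flowers open (near-simultaneously) during the first
#' `female_phase_days` of the inflorescence's flowering span, and male
#' flowers open on the following `male_stagger_days` days (staggered).
#' Every flower is open for exactly one day. Start dates follow the
#' season-scaled Beta law of the config, so few inflorescences flower in
#' the opening days of the season and flowering peaks in its second half.
#' Flower counts are Poisson-lognormal; the female law's `day_effect`
#' raises female flower production over the season while male production
#' stays flat, shifting inflorescence sex ratios from male- to
#' female-biased as the season progresses.
#'
#' @param population A `floral_population` from [generate_population()].
#' @param config The [population_config()] used to generate it.
#' @return A list with `phenology`, a daily record table
#'   (`day`, `ramet_id`, `inflorescence_id`, `n_open_female`,
#'   `n_open_male`; one row per inflorescence-day with at least one open
#'   flower), and `inflorescences`, a summary table (`inflorescence_id`,
#'   `ramet_id`, `first_day`, `n_female`, `n_male`).
#' @examples
#' cfg <- population_config(n_genets = 10, rng_seed = 3)
#' ph <- generate_phenology(generate_population(cfg), cfg)
#' head(ph$phenology)
#' @export
generate_phenology <- function(population, config) {
  stopifnot(inherits(population, "floral_population"))
  validate_population_config(config)
  set.seed(stage_seed(config$rng_seed, 2L))

  ramets <- population$ramets
  n <- nrow(ramets)
  first_day <- config$season[1]
  last_day <- config$season[2]
  span <- config$female_phase_days + config$male_stagger_days

  # start day: Beta over the feasible start window so the full female+male
  # span fits inside the season
  window <- last_day - first_day + 1L - span
  b <- stats::rbeta(n, config$flowering_start_law$shape1,
                    config$flowering_start_law$shape2)
  start <- first_day + as.integer(floor(b * (window + 1L)))

  # season position in [0, 1] (by start date) drives the day effects
  tfrac <- (start - first_day) / max(1L, last_day - first_day)
  n_female <- draw_flower_counts(n, config$n_female_law, tfrac)
  n_male <- draw_flower_counts(n, config$n_male_law, tfrac)
  empty <- which(n_female + n_male == 0L)
  while (length(empty) > 0L) {  # an inflorescence has at least one flower
    n_female[empty] <- draw_flower_counts(length(empty), config$n_female_law,
                                          tfrac[empty])
    n_male[empty] <- draw_flower_counts(length(empty), config$n_male_law,
                                        tfrac[empty])
    empty <- empty[n_female[empty] + n_male[empty] == 0L]
  }

  infl_id <- sprintf("I%04d", seq_len(n))
  fem <- spread_flowers(infl_id, n_female, start, config$female_phase_days)
  mal <- spread_flowers(infl_id, n_male, start + config$female_phase_days,
                        config$male_stagger_days)

  daily <- merge(fem, mal, by = c("inflorescence_id", "day"), all = TRUE)
  names(daily)[names(daily) == "n.x"] <- "n_open_female"
  names(daily)[names(daily) == "n.y"] <- "n_open_male"
  daily$n_open_female[is.na(daily$n_open_female)] <- 0L
  daily$n_open_male[is.na(daily$n_open_male)] <- 0L
  daily$ramet_id <- ramets$ramet_id[match(daily$inflorescence_id, infl_id)]
  daily <- daily[order(daily$day, daily$ramet_id),
                 c("day", "ramet_id", "inflorescence_id",
                   "n_open_female", "n_open_male")]
  rownames(daily) <- NULL

  inflorescences <- data.frame(inflorescence_id = infl_id,
                               ramet_id = ramets$ramet_id,
                               first_day = start,
                               n_female = n_female,
                               n_male = n_male,
                               stringsAsFactors = FALSE)
  list(phenology = daily, inflorescences = inflorescences)
}

# Poisson counts with a lognormal rate whose log-median shifts linearly
# with season position (centred at mid season).
draw_flower_counts <- function(n, law, tfrac) {
  meanlog <- law$meanlog + law$day_effect * (tfrac - 0.5)
  rate <- stats::rlnorm(n, meanlog = meanlog, sdlog = law$sdlog)
  stats::rpois(n, rate)
}

# Assign each flower of each inflorescence to one open day inside its
# phase window (uniform multinomial); returns long (inflorescence, day, n).
spread_flowers <- function(infl_id, counts, phase_start, phase_len) {
  keep <- counts > 0L
  if (!any(keep)) {
    return(data.frame(inflorescence_id = character(0), day = integer(0),
                      n = integer(0), stringsAsFactors = FALSE))
  }
  id <- rep(infl_id[keep], counts[keep])
  offset <- sample.int(phase_len, sum(counts[keep]), replace = TRUE) - 1L
  day <- rep(phase_start[keep], counts[keep]) + offset
  agg <- stats::aggregate(list(n = rep(1L, length(id))),
                          by = list(inflorescence_id = id, day = day), FUN = sum)
  agg
}
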