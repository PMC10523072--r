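#' Configuration for a synthetic monoecious population
#'
#' Builds the parameter set that drives the synthetic-population simulator:
#' clonal structure, spatial layout, flowering phenology, per-inflorescence
#' flower production, microsatellite genotypes, and the mating model. The
#' defaults describe a dense riverside population of a clonal, synchronously
#' protogynous aquatic plant: roughly 169 genets comprising on the order of
#' 940 flowering ramets (about 40% of genets are single ramets, the largest
#' reach ~35 ramets) on a 25 x 60 m arena, flowering over Julian days
#' 199-240, genotyped at 7 codominant microsatellite loci.
#'
#' @param n_genets Number of genets (genetic individuals). Default 169.
#' @param ramet_count_law Parameters of the genet-size law, a list with
#'   `singleton_prob` (probability a genet is a single ramet), `size` and
#'   `mu` (negative-binomial dispersion and mean of the non-singleton
#'   component, conditioned on `2..max`), and `max` (largest genet size).
#'   The default gives ~40% singletons, a maximum of 35 ramets and a mean
#'   genet size of ~5.6 ramets.
#' @param arena Rectangle extent in metres, `c(width, height)`. Default
#'   `c(25, 60)`.
#' @param season Integer Julian days `c(first_day, last_day)` bounding the
#'   flowering season. Default `c(199L, 240L)` (mid July to late August).
#' @param flowering_start_law Beta shape parameters (`shape1`, `shape2`)
#'   for the distribution of inflorescence start dates across the season
#'   (rescaled to the feasible start window). The default `Beta(6, 2.4)`
#'   puts about 1% of inflorescences in the first 12 days of the season
#'   and peak flowering roughly three quarters of the way through it.
#' @param n_female_law,n_male_law Per-inflorescence flower-count laws:
#'   Poisson-lognormal with `meanlog` (log median count), `sdlog`
#'   (between-inflorescence heterogeneity) and `day_effect`, a log-linear
#'   effect of season position (0 at mid season, so the median count is
#'   multiplied by `exp(day_effect/2)` at the season end). The defaults
#'   hold male flower production constant while female production rises
#'   over the season, calibrated so that median female production equals
#'   median male production at peak flowering: inflorescences are
#'   male-biased before the flowering peak and female-biased after it.
#' @param female_phase_days Maximum number of days over which an
#'   inflorescence's female flowers open (near-simultaneous; default 2).
#' @param male_stagger_days Number of days over which male flowers open
#'   (staggered; default 5).
#' @param n_loci Number of codominant loci. Default 7.
#' @param alleles_per_locus Number of possible alleles per locus. Default 15.
#' @param allele_freq_concentration Dirichlet concentration for population
#'   allele frequencies (1 = uniform over the simplex).
#' @param somatic_mlg_rate Probability that a ramet's true genotype differs
#'   from its genet genotype by exactly one allele at one locus (somatic
#'   mutation / scoring drift that splits a genet into several multilocus
#'   genotypes). Default 0.05.
#' @param genotyping_error Per-allele mistyping probability applied to the
#'   observed genotype tables (ramets and seeds). Default 0.01.
#' @param kernel_scale Scale (metres) of the negative-exponential pollen
#'   dispersal kernel; `Inf` means spatially uniform mating. Default 5.
#' @param genet_scatter_sd Standard deviation (metres) of ramet positions
#'   around their genet centre (stolon spread). Default 1.5.
#' @param seed_sample_fraction Fraction of pollinated female flowers from
#'   which a seed is sampled and genotyped (one seed per fruit). The
#'   default 0.075 yields on the order of 350-400 genotyped seeds under
#'   the default population.
#' @param rng_seed Integer seed; every simulator stage derives its stream
#'   from this value, so a config fully determines its outputs.
#'
#' @return A list of class `population_config`.
#' @seealso [simulate_study()], [generate_population()]
#' @export
population_config <- function(n_genets = 169L,
                              ramet_count_law = list(singleton_prob = 0.40,
                                                     size = 0.8,
                                                     mu = 6.637,
                                                     max = 35L),
                              arena = c(25, 60),
                              season = c(199L, 240L),
                              flowering_start_law = list(shape1 = 6, shape2 = 2.4),
                              n_female_law = list(meanlog = log(4),
                                                  sdlog = 0.45,
                                                  day_effect = 3.5),
                              n_male_law = list(meanlog = log(9),
                                                sdlog = 0.45,
                                                day_effect = 0),
                              female_phase_days = 2L,
                              male_stagger_days = 5L,
                              n_loci = 7L,
                              alleles_per_locus = 15L,
                              allele_freq_concentration = 1,
                              somatic_mlg_rate = 0.05,
                              genotyping_error = 0.01,
                              kernel_scale = 5,
                              genet_scatter_sd = 1.5,
                              seed_sample_fraction = 0.075,
                              rng_seed = 1L) {
  cfg <- list(n_genets = as.integer(n_genets),
              ramet_count_law = ramet_count_law,
              arena = as.numeric(arena),
              season = as.integer(season),
              flowering_start_law = flowering_start_law,
              n_female_law = n_female_law,
              n_male_law = n_male_law,
              female_phase_days = as.integer(female_phase_days),
              male_stagger_days = as.integer(male_stagger_days),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              allele_freq_concentration = allele_freq_concentration,
              somatic_mlg_rate = somatic_mlg_rate,
              genotyping_error = genotyping_error,
              kernel_scale = kernel_scale,
              genet_scatter_sd = genet_scatter_sd,
              seed_sample_fraction = seed_sample_fraction,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "population_config"
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  err <- function(...) stop("invalid population_config: ", ..., call. = FALSE)
  if (is.na(cfg$n_genets) || cfg$n_genets < 1L) err("n_genets must be >= 1")
  law <- cfg$ramet_count_law
  if (!all(c("singleton_prob", "size", "mu", "max") %in% names(law)))
    err("ramet_count_law needs singleton_prob, size, mu, max")
  if (law$singleton_prob < 0 || law$singleton_prob > 1)
    err("ramet_count_law$singleton_prob must be in [0,1]")
  if (law$max < 1L) err("ramet_count_law$max must be >= 1")
  if (law$max > 1L && (law$size <= 0 || law$mu <= 0))
    err("ramet_count_law size and mu must be positive")
  if (length(cfg$arena) != 2L || any(cfg$arena <= 0)) err("arena must be two positive extents")
  if (length(cfg$season) != 2L || cfg$season[1] >= cfg$season[2])
    err("season must satisfy first_day < last_day")
  if (any(unlist(cfg$flowering_start_law) <= 0)) err("flowering_start_law shapes must be positive")
  for (nm in c("n_female_law", "n_male_law")) {
    l <- cfg[[nm]]
    if (!all(c("meanlog", "sdlog", "day_effect") %in% names(l)))
      err(nm, " needs meanlog, sdlog, day_effect")
    if (l$sdlog < 0) err(nm, "$sdlog must be >= 0")
  }
  if (cfg$female_phase_days < 1L) err("female_phase_days must be >= 1")
  if (cfg$male_stagger_days < 1L) err("male_stagger_days must be >= 1")
  span <- cfg$female_phase_days + cfg$male_stagger_days
  if (span > diff(cfg$season) + 1L)
    err("female_phase_days + male_stagger_days exceeds the season length")
  if (cfg$n_loci < 1L) err("n_loci must be >= 1")
  if (cfg$alleles_per_locus < 2L) err("alleles_per_locus must be >= 2")
  if (cfg$allele_freq_concentration <= 0) err("allele_freq_concentration must be positive")
  for (nm in c("somatic_mlg_rate", "genotyping_error", "seed_sample_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) err(nm, " must be a probability in [0,1]")
  }
  if (!(is.infinite(cfg$kernel_scale) || cfg$kernel_scale > 0))
    err("kernel_scale must be positive or Inf")
  if (cfg$genet_scatter_sd < 0) err("genet_scatter_sd must be >= 0")
  invisible(cfg)
}

#' Configuration for fractional paternity assignment
#'
#' @param error_rate Per-locus mistyping probability used in the
#'   error-tolerant likelihood (mixture weight on the Hardy-Weinberg
#'   background). Default 0.01.
#' @param include_unsampled If `TRUE`, an `UNSAMPLED` father class is added
#'   whose per-locus likelihood integrates the paternal allele over the
#'   population allele frequencies. Default `FALSE`: the study population is
#'   treated as closed (isolated from other populations), so every candidate
#'   father is assumed sampled.
#' @param unsampled_prior Prior mass on the unsampled class, in `[0, 1)`.
#'   The remaining mass is spread uniformly over sampled candidates.
#'
#' @return A list of class `paternity_config`.
#' @seealso [assign_paternity()], [fractional_paternity()]
#' @export
paternity_config <- function(error_rate = 0.01,
                             include_unsampled = FALSE,
                             unsampled_prior = 0) {
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must be in [0,1]", call. = FALSE)
  if (unsampled_prior < 0 || unsampled_prior >= 1)
    stop("unsampled_prior must be in [0,1)", call. = FALSE)
  if (include_unsampled && unsampled_prior == 0)
    stop("include_unsampled = TRUE requires a positive unsampled_prior",
         call. = FALSE)
  structure(list(error_rate = error_rate,
                 include_unsampled = include_unsampled,
                 unsampled_prior = unsampled_prior),
            class = "paternity_config")
}

# Derive a stage-specific RNG seed from the config seed. Offsets keep the
# stages' streams distinct while the whole pipeline stays a deterministic
# function of rng_seed.
stage_seed <- function(rng_seed, offset) {
  as.integer((as.numeric(rng_seed) + offset) %% 2147483647)
}
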