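#' Simulate mating, seed set and seed genotypes
#'
#' For every day of the season, each open female flower on a sampled
#' ramet receives pollen from one sire ramet drawn among the ramets with
#' open male flowers that day, with probability proportional to
#' `N_male * exp(-distance / kernel_scale)` (spatially uniform mating when
#' `kernel_scale = Inf`). Because inflorescences are functionally
#' unisexual each day, a ramet can never pollinate itself, but
#' geitonogamous selfing between ramets of the same genet can and does
#' occur. One seed is sampled (genotyped) per pollinated flower with
#' probability `seed_sample_fraction`; its genotype is Mendelian (one
#' maternal and one paternal allele per locus from the *true* parental
#' genotypes) with per-allele genotyping error applied afterwards.
#' Female flowers open on days with no male flowers anywhere remain
#' unpollinated and produce no seed; they are tallied in the
#' `unpollinated` element.
#'
#' @param phenology Daily floral record table from [generate_phenology()].
#' @param genotypes Genotype bundle from [generate_genotypes()].
#' @param population The `floral_population` (for coordinates and genet
#'   membership).
#' @param config The matching [population_config()].
#' @return A list with `seeds` (observed seed table: `seed_id`,
#'   `mother_ramet_id`, `pollination_day`, allele columns), `truth`
#'   (per-seed ground truth: `seed_id`, `mother_ramet_id`, `mother_genet`,
#'   `true_sire_ramet`, `true_sire_genet`, `pollination_day`, `is_selfed`)
#'   and `unpollinated` (data frame of day, n_flowers with no available
#'   sires).
#' @examples
#' cfg <- population_config(n_genets = 15, rng_seed = 5,
#'                          seed_sample_fraction = 0.5)
#' pop <- generate_population(cfg)
#' ph <- generate_phenology(pop, cfg)
#' gt <- generate_genotypes(pop, cfg)
#' mt <- simulate_mating(ph$phenology, gt, pop, cfg)
#' head(mt$truth)
#' @export
simulate_mating <- function(phenology, genotypes, population, config) {
  stopifnot(inherits(population, "floral_population"))
  validate_population_config(config)
  set.seed(stage_seed(config$rng_seed, 4L))

  ramets <- population$ramets
  true_mat <- genotype_matrix(genotypes$true_genotypes)
  n_loci <- ncol(true_mat) / 2L

  mother_rows <- list(); sire_rows <- list(); day_rows <- list()
  unpoll <- list()

  for (day in sort(unique(phenology$day))) {
    ph_day <- phenology[phenology$day == day, , drop = FALSE]
    mothers <- ph_day[ph_day$n_open_female > 0L, , drop = FALSE]
    donors <- ph_day[ph_day$n_open_male > 0L, , drop = FALSE]
    if (nrow(mothers) == 0L) next

    # one genotyped seed per sampled (pollinated) flower
    n_seed <- stats::rbinom(nrow(mothers), mothers$n_open_female,
                            config$seed_sample_fraction)
    if (nrow(donors) == 0L) {
      if (sum(mothers$n_open_female) > 0L) {
        unpoll[[length(unpoll) + 1L]] <-
          data.frame(day = day, n_flowers = sum(mothers$n_open_female))
      }
      next
    }
    keep <- which(n_seed > 0L)
    if (length(keep) == 0L) next

    didx <- match(donors$ramet_id, ramets$ramet_id)
    for (i in keep) {
      midx <- match(mothers$ramet_id[i], ramets$ramet_id)
      if (is.infinite(config$kernel_scale)) {
        w <- donors$n_open_male
      } else {
        d <- sqrt((ramets$x_m[didx] - ramets$x_m[midx])^2 +
                  (ramets$y_m[didx] - ramets$y_m[midx])^2)
        w <- donors$n_open_male * exp(-d / config$kernel_scale)
      }
      sires <- donors$ramet_id[sample.int(nrow(donors), n_seed[i],
                                          replace = TRUE, prob = w)]
      mother_rows[[length(mother_rows) + 1L]] <-
        rep(mothers$ramet_id[i], n_seed[i])
      sire_rows[[length(sire_rows) + 1L]] <- sires
      day_rows[[length(day_rows) + 1L]] <- rep(day, n_seed[i])
    }
  }

  mother_id <- unlist(mother_rows)
  sire_id <- unlist(sire_rows)
  poll_day <- unlist(day_rows)
  n_seeds <- length(mother_id)
  unpollinated <- if (length(unpoll)) do.call(rbind, unpoll) else
    data.frame(day = integer(0), n_flowers = integer(0))

  cols <- genotype_colnames(n_loci)
  if (n_seeds == 0L) {
    seeds <- cbind(data.frame(seed_id = character(0),
                              mother_ramet_id = character(0),
                              pollination_day = integer(0),
                              stringsAsFactors = FALSE),
                   stats::setNames(as.data.frame(matrix(integer(0), 0, 2L * n_loci)),
                                   cols))
    truth <- data.frame(seed_id = character(0), mother_ramet_id = character(0),
                        mother_genet = character(0),
                        true_sire_ramet = character(0),
                        true_sire_genet = character(0),
                        pollination_day = integer(0), is_selfed = logical(0),
                        stringsAsFactors = FALSE)
    return(list(seeds = seeds, truth = truth, unpollinated = unpollinated))
  }

  # Mendelian transmission: one uniformly chosen allele from each parent
  mrows <- match(mother_id, rownames(true_mat))
  srows <- match(sire_id, rownames(true_mat))
  seed_mat <- matrix(0L, n_seeds, 2L * n_loci)
  for (l in seq_len(n_loci)) {
    mslot <- 2L * l - 2L + sample.int(2L, n_seeds, replace = TRUE)
    fslot <- 2L * l - 2L + sample.int(2L, n_seeds, replace = TRUE)
    seed_mat[, 2L * l - 1L] <- true_mat[cbind(mrows, mslot)]
    seed_mat[, 2L * l] <- true_mat[cbind(srows, fslot)]
  }
  seed_mat <- apply_genotyping_error(seed_mat, genotypes$allele_freqs,
                                     config$genotyping_error)

  seed_id <- sprintf("S%05d", seq_len(n_seeds))
  seeds <- data.frame(seed_id = seed_id, mother_ramet_id = mother_id,
                      pollination_day = poll_day, seed_mat,
                      stringsAsFactors = FALSE)
  names(seeds) <- c("seed_id", "mother_ramet_id", "pollination_day", cols)

  mgenet <- ramets$genet_id[match(mother_id, ramets$ramet_id)]
  sgenet <- ramets$genet_id[match(sire_id, ramets$ramet_id)]
  truth <- data.frame(seed_id = seed_id,
                      mother_ramet_id = mother_id,
                      mother_genet = mgenet,
                      true_sire_ramet = sire_id,
                      true_sire_genet = sgenet,
                      pollination_day = poll_day,
                      is_selfed = mgenet == sgenet,
                      stringsAsFactors = FALSE)
  list(seeds = seeds, truth = truth, unpollinated = unpollinated)
}
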