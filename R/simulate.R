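#' Run the full synthetic-population simulator
#'
#' Chains [generate_population()], [generate_phenology()],
#' [generate_genotypes()] and [simulate_mating()] into one deterministic
#' study bundle: population layout, daily phenology, observed genotype
#' tables, genotyped seeds and the ground-truth paternity table. Running
#' the same config twice yields identical results.
#'
#' @param config A [population_config()].
#' @return A list of class `floral_study` with elements `population`,
#'   `phenology`, `inflorescences`, `genotypes` (the full genotype
#'   bundle), `seeds`, `truth`, `unpollinated` and `config`.
#' @examples
#' study <- simulate_study(population_config(n_genets = 12, rng_seed = 7))
#' nrow(study$seeds)
#' @export
simulate_study <- function(config = population_config()) {
  validate_population_config(config)
  population <- generate_population(config)
  ph <- generate_phenology(population, config)
  genotypes <- generate_genotypes(population, config)
  mating <- simulate_mating(ph$phenology, genotypes, population, config)
  structure(list(population = population,
                 phenology = ph$phenology,
                 inflorescences = ph$inflorescences,
                 genotypes = genotypes,
                 seeds = mating$seeds,
                 truth = mating$truth,
                 unpollinated = mating$unpollinated,
                 config = config),
            class = "floral_study")
}

#' @export
print.floral_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$population$ramets), "ramets /",
      nrow(x$population$genets), "genets;",
      nrow(x$phenology), "inflorescence-day records; ",
      nrow(x$seeds), "genotyped seeds",
      sprintf("(%.0f%% selfed)\n", 100 * mean(x$truth$is_selfed)))
  invisible(x)
}

#' Write a simulated study to CSV files
#'
#' Emits the pipeline's plain-text input files into `dir`:
#' `phenology.csv`, `ramet_genotypes.csv`, `coordinates.csv`, `seeds.csv`
#' and `truth.csv`. Days are integer Julian days; coordinates are metres
#' from the arena corner; allele calls are integers with 0 = missing.
#'
#' @param study A `floral_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "floral_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    phenology = file.path(dir, "phenology.csv"),
    ramet_genotypes = file.path(dir, "ramet_genotypes.csv"),
    coordinates = file.path(dir, "coordinates.csv"),
    seeds = file.path(dir, "seeds.csv"),
    truth = file.path(dir, "truth.csv")
  )
  coords <- study$population$ramets[, c("ramet_id", "x_m", "y_m")]
  write_csv_atomic(study$phenology, paths[["phenology"]])
  write_csv_atomic(study$genotypes$ramet_genotypes, paths[["ramet_genotypes"]])
  write_csv_atomic(coords, paths[["coordinates"]])
  write_csv_atomic(study$seeds, paths[["seeds"]])
  write_csv_atomic(study$truth, paths[["truth"]])
  invisible(paths)
}
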