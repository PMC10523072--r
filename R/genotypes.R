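#' Generate microsatellite genotypes for a clonal population
#'
#' Draws population allele frequencies per locus from a symmetric
#' Dirichlet, assigns each genet a Hardy-Weinberg multilocus genotype,
#' copies it to the genet's ramets, and then perturbs it at two levels:
#' with probability `somatic_mlg_rate` a *daughter* ramet's true genotype
#' differs from its genet genotype by exactly one allele at one locus
#' (somatic variation, which splits genets into several multilocus
#' genotypes; the genet's first ramet always keeps the founding
#' genotype), and
#' each allele call of the *observed* table is independently mistyped with
#' probability `genotyping_error` (replaced by a draw from the locus
#' allele frequencies).
#'
#' @param population A `floral_population`.
#' @param config The matching [population_config()].
#' @return A list with `ramet_genotypes` (observed table: `ramet_id` plus
#'   `L<k>_a1`/`L<k>_a2` integer allele columns, 0 = missing),
#'   `true_genotypes` (same layout, before genotyping error),
#'   `genet_genotypes` (`genet_id` plus allele columns), `allele_freqs`
#'   (list of named frequency vectors per locus) and `somatic_ramets`
#'   (ids of ramets carrying a somatic variant).
#' @examples
#' cfg <- population_config(n_genets = 5, rng_seed = 9)
#' gt <- generate_genotypes(generate_population(cfg), cfg)
#' head(gt$ramet_genotypes)
#' @export
generate_genotypes <- function(population, config) {
  stopifnot(inherits(population, "floral_population"))
  validate_population_config(config)
  set.seed(stage_seed(config$rng_seed, 3L))

  n_loci <- config$n_loci
  n_all <- config$alleles_per_locus
  loci <- locus_names(n_loci)

  # microsatellite-style integer allele labels, distinct across loci
  allele_freqs <- vector("list", n_loci)
  names(allele_freqs) <- loci
  for (l in seq_len(n_loci)) {
    labels <- 100L * l + 2L * seq_len(n_all) + 1L
    w <- stats::rgamma(n_all, shape = config$allele_freq_concentration)
    allele_freqs[[l]] <- stats::setNames(w / sum(w), labels)
  }

  ng <- nrow(population$genets)
  genet_mat <- matrix(0L, nrow = ng, ncol = 2L * n_loci)
  for (l in seq_len(n_loci)) {
    f <- allele_freqs[[l]]
    labels <- as.integer(names(f))
    genet_mat[, 2L * l - 1L] <- sample(labels, ng, replace = TRUE, prob = f)
    genet_mat[, 2L * l] <- sample(labels, ng, replace = TRUE, prob = f)
  }

  ramets <- population$ramets
  gidx <- match(ramets$genet_id, population$genets$genet_id)
  true_mat <- genet_mat[gidx, , drop = FALSE]

  # somatic variants: one allele at one locus replaced by a different
  # allele, arising in daughter ramets only - the genet's first ramet
  # always carries the unmutated genet genotype, so every variant sits at
  # allelic distance 1 from an observed member of its lineage
  founder <- !duplicated(ramets$genet_id)
  somatic <- which(!founder & stats::runif(nrow(ramets)) < config$somatic_mlg_rate)
  for (i in somatic) {
    l <- sample.int(n_loci, 1L)
    slot <- 2L * l - 2L + sample.int(2L, 1L)
    labels <- as.integer(names(allele_freqs[[l]]))
    true_mat[i, slot] <- sample(setdiff(labels, true_mat[i, slot]), 1L)
  }

  obs_mat <- apply_genotyping_error(true_mat, allele_freqs,
                                    config$genotyping_error)

  cols <- genotype_colnames(n_loci)
  genet_df <- data.frame(genet_id = population$genets$genet_id, genet_mat,
                         stringsAsFactors = FALSE)
  names(genet_df) <- c("genet_id", cols)
  true_df <- data.frame(ramet_id = ramets$ramet_id, true_mat,
                        stringsAsFactors = FALSE)
  names(true_df) <- c("ramet_id", cols)
  obs_df <- data.frame(ramet_id = ramets$ramet_id, obs_mat,
                       stringsAsFactors = FALSE)
  names(obs_df) <- c("ramet_id", cols)

  list(ramet_genotypes = obs_df,
       true_genotypes = true_df,
       genet_genotypes = genet_df,
       allele_freqs = allele_freqs,
       somatic_ramets = ramets$ramet_id[somatic])
}

# Per-allele mistyping: each call is replaced, with probability error_rate,
# by a random draw from the locus allele frequencies. Missing calls (0)
# are left untouched.
apply_genotyping_error <- function(mat, allele_freqs, error_rate) {
  if (error_rate <= 0) return(mat)
  n_loci <- length(allele_freqs)
  for (l in seq_len(n_loci)) {
    f <- allele_freqs[[l]]
    labels <- as.integer(names(f))
    for (slot in c(2L * l - 1L, 2L * l)) {
      hit <- which(mat[, slot] != 0L & stats::runif(nrow(mat)) < error_rate)
      if (length(hit)) {
        mat[hit, slot] <- sample(labels, length(hit), replace = TRUE, prob = f)
      }
    }
  }
  mat
}

locus_names <- function(n_loci) sprintf("L%d", seq_len(n_loci))

genotype_colnames <- function(n_loci) {
  as.vector(t(outer(locus_names(n_loci), c("a1", "a2"), paste, sep = "_")))
}

# Extract the allele matrix (2 columns per locus) from a genotype table
# whose first column is an id. Validates codominant arity: at every locus
# either both or neither allele call is present.
genotype_matrix <- function(df, id_col = 1L) {
  mat <- as.matrix(df[, -id_col, drop = FALSE])
  storage.mode(mat) <- "integer"
  if (ncol(mat) %% 2L != 0L)
    stop("genotype table must have two allele columns per locus", call. = FALSE)
  mat[is.na(mat)] <- 0L
  n_loci <- ncol(mat) / 2L
  for (l in seq_len(n_loci)) {
    a <- mat[, 2L * l - 1L] == 0L
    b <- mat[, 2L * l] == 0L
    if (any(a != b)) {
      bad <- which(a != b)[1]
      stop(sprintf("locus %d of row %d has exactly one allele call; loci must have 0 or 2 calls",
                   l, bad), call. = FALSE)
    }
  }
  rownames(mat) <- as.character(df[[id_col]])
  mat
}
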