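#' Mendelian transmission probability at one codominant locus
#'
#' Probability that a given mother x father pair produces the offspring
#' genotype at one locus under Mendelian segregation: the average over the
#' four equally likely gamete pairs, 0 when the trio is incompatible.
#'
#' @param offspring,mother,father Length-2 integer vectors of allele
#'   calls at one locus.
#' @return A probability in `{0, 0.25, 0.5, 1}`.
#' @examples
#' transmission_prob(c(1, 2), c(1, 1), c(2, 2))  # 1
#' transmission_prob(c(1, 1), c(1, 2), c(1, 2))  # 0.25
#' @export
transmission_prob <- function(offspring, mother, father) {
  o <- sort(as.integer(offspring))
  hits <- 0L
  for (gm in as.integer(mother)) {
    for (gf in as.integer(father)) {
      if (identical(sort(c(gm, gf)), o)) hits <- hits + 1L
    }
  }
  hits / 4
}

# Hardy-Weinberg probability of an offspring locus genotype.
hw_prob <- function(offspring, freqs) {
  p1 <- unname(freqs[as.character(offspring[1])])
  p2 <- unname(freqs[as.character(offspring[2])])
  p1 <- ifelse(is.na(p1), 0, p1); p2 <- ifelse(is.na(p2), 0, p2)
  if (offspring[1] == offspring[2]) p1 * p2 else 2 * p1 * p2
}

#' Error-tolerant single-locus paternity likelihood
#'
#' Mixture likelihood for one locus of a mother/candidate-father/offspring
#' trio: with probability `1 - error_rate` the locus was scored correctly
#' and the likelihood is the Mendelian [transmission_prob()]; with
#' probability `error_rate` the genotype is an erroneous read and the
#' likelihood falls back to the Hardy-Weinberg probability of the
#' offspring genotype. This keeps a single mistyped locus (including an
#' apparent mother-offspring mismatch) from vetoing an otherwise
#' compatible candidate. A locus missing in any of the three genotypes is
#' uninformative and contributes likelihood 1.
#'
#' @param offspring,mother,candidate Length-2 allele vectors at one locus
#'   (0 or `NA` = missing).
#' @param freqs Named vector of population allele frequencies at the
#'   locus (names are allele labels).
#' @param error_rate Per-locus mistyping probability in `[0, 1]`.
#' @return The locus likelihood.
#' @examples
#' f <- c("1" = 0.5, "2" = 0.5)
#' locus_likelihood(c(1, 2), c(1, 1), c(2, 2), f, 0.02)  # 0.99
#' @export
locus_likelihood <- function(offspring, mother, candidate, freqs, error_rate) {
  if (missing_locus(offspring) || missing_locus(mother) ||
      missing_locus(candidate)) return(1)
  (1 - error_rate) * transmission_prob(offspring, mother, candidate) +
    error_rate * hw_prob(offspring, freqs)
}

missing_locus <- function(g) any(is.na(g)) || any(g == 0L)

# P(offspring | mother, father drawn from the allele pool): the paternal
# allele is integrated over the population frequencies.
unsampled_transmission <- function(offspring, mother, freqs) {
  pm <- function(a) mean(mother == a)  # P(mother transmits allele a)
  f <- function(a) {
    p <- unname(freqs[as.character(a)])
    ifelse(is.na(p), 0, p)
  }
  o1 <- offspring[1]; o2 <- offspring[2]
  if (o1 == o2) pm(o1) * f(o1) else pm(o1) * f(o2) + pm(o2) * f(o1)
}

#' Fractional paternity for one seed
#'
#' Computes the posterior probability `pi` that each candidate father
#' genotype sired the seed: the product over loci of the error-tolerant
#' [locus_likelihood()], times the candidate prior, normalized over
#' candidates. With `include_unsampled`, an extra class absorbs fathers
#' missing from the candidate table (per-locus likelihood integrates the
#' paternal allele over the population frequencies).
#'
#' @param seed_genotype,mother_genotype Integer allele vectors of length
#'   `2 * n_loci` (0 = missing).
#' @param candidates Matrix of candidate genotypes (rows named by
#'   candidate id, `2 * n_loci` columns).
#' @param allele_freqs List of named per-locus allele frequency vectors.
#' @param config A [paternity_config()].
#' @return Data frame (`candidate_id`, `pi`) summing to 1, or `NULL` when
#'   every candidate (and no unsampled class) has zero likelihood, in
#'   which case the seed is unassignable.
#' @examples
#' freqs <- list(L1 = c("1" = 0.5, "2" = 0.5))
#' cand <- rbind(c1 = c(2L, 2L), c2 = c(1L, 2L))
#' fractional_paternity(c(1L, 2L), c(1L, 1L), cand, freqs,
#'                      paternity_config(error_rate = 0))
#' @export
fractional_paternity <- function(seed_genotype, mother_genotype, candidates,
                                 allele_freqs, config = paternity_config()) {
  stopifnot(inherits(config, "paternity_config"))
  n_loci <- length(allele_freqs)
  lik <- candidate_likelihoods(as.integer(seed_genotype),
                               as.integer(mother_genotype),
                               candidates, allele_freqs, config$error_rate)
  n_cand <- nrow(candidates)
  if (config$include_unsampled) {
    lu <- 1
    for (l in seq_len(n_loci)) {
      i <- c(2L * l - 1L, 2L * l)
      o <- seed_genotype[i]; m <- mother_genotype[i]
      if (missing_locus(o) || missing_locus(m)) next
      lu <- lu * ((1 - config$error_rate) *
                    unsampled_transmission(o, m, allele_freqs[[l]]) +
                  config$error_rate * hw_prob(o, allele_freqs[[l]]))
    }
    prior <- c(rep((1 - config$unsampled_prior) / n_cand, n_cand),
               config$unsampled_prior)
    w <- c(lik, lu) * prior
    ids <- c(rownames(candidates), "UNSAMPLED")
  } else {
    w <- lik / n_cand
    ids <- rownames(candidates)
  }
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  data.frame(candidate_id = ids, pi = w / tot, stringsAsFactors = FALSE)
}

# Vectorized over candidates: product over loci of the mixture likelihood.
candidate_likelihoods <- function(seed, mother, candidates, allele_freqs,
                                  error_rate) {
  n_cand <- nrow(candidates)
  lik <- rep(1, n_cand)
  for (l in seq_along(allele_freqs)) {
    i1 <- 2L * l - 1L; i2 <- 2L * l
    o <- seed[c(i1, i2)]; m <- mother[c(i1, i2)]
    if (missing_locus(o) || missing_locus(m)) next
    ca <- candidates[, i1]; cb <- candidates[, i2]
    scored <- ca != 0L & cb != 0L
    # P(father transmits allele a), vectorized over candidates
    pf <- function(a) ((ca == a) + (cb == a)) / 2
    pm <- function(a) mean(m == a)
    o1 <- o[1]; o2 <- o[2]
    trans <- if (o1 == o2) pm(o1) * pf(o1) else pm(o1) * pf(o2) + pm(o2) * pf(o1)
    loc <- (1 - error_rate) * trans + error_rate * hw_prob(o, allele_freqs[[l]])
    loc[!scored] <- 1  # missing candidate locus is uninformative
    lik <- lik * loc
  }
  unname(lik)
}

#' Assign fractional paternity to all genotyped seeds
#'
#' For every seed, candidate fathers are the distinct MLGs of the
#' population (one representative genotype each); posterior paternity
#' probabilities `pi` are computed with [fractional_paternity()] and then
#' summed into MLL-level (genet-level) assignments. A candidate MLL equal
#' to the seed's maternal MLL marks geitonogamous selfing.
#'
#' @param seeds Seed table (`seed_id`, `mother_ramet_id`,
#'   `pollination_day`, allele columns).
#' @param ramet_genotypes Observed ramet genotype table.
#' @param clones Clonal assignment from [assign_clones()] /
#'   [build_mlls()].
#' @param config A [paternity_config()].
#' @param allele_freqs Optional list of per-locus allele frequency
#'   vectors; when `NULL` they are estimated by counting alleles over MLG
#'   representative genotypes (one per clone, so large clones do not
#'   dominate the frequencies).
#' @param min_pi Candidates whose posterior mass falls below this floor
#'   are dropped and the remainder renormalized (default 0.001). The
#'   error-tolerant likelihood gives every candidate a strictly positive
#'   but usually negligible posterior; the floor keeps assignment tables
#'   to the candidates that genuinely compete.
#' @return A list of class `floral_paternity`: `assignments` (data frame
#'   `seed_id`, `mll_id`, `pi`, `selfed`, `pollination_day`, `mother_mll`;
#'   zero-probability candidates omitted), `unassigned` (seed ids with no
#'   compatible candidate), `allele_freqs`, and `config`.
#' @examples
#' study <- simulate_study(population_config(n_genets = 12, rng_seed = 11,
#'                                           seed_sample_fraction = 0.3))
#' cl <- assign_clones(study$genotypes$ramet_genotypes)
#' pat <- assign_paternity(study$seeds, study$genotypes$ramet_genotypes, cl)
#' head(pat$assignments)
#' @export
assign_paternity <- function(seeds, ramet_genotypes, clones,
                             config = paternity_config(),
                             allele_freqs = NULL, min_pi = 0.001) {
  stopifnot(inherits(config, "paternity_config"))
  mlg_geno <- attr(clones, "mlg_genotypes")
  if (is.null(mlg_geno))
    stop("clones must carry the mlg_genotypes attribute (use assign_clones)",
         call. = FALSE)
  n_loci <- ncol(mlg_geno) / 2L
  if (is.null(allele_freqs)) allele_freqs <- estimate_allele_freqs(mlg_geno)

  mll_of_mlg <- unique(clones[, c("mlg_id", "mll_id")])
  mll_by_rep <- mll_of_mlg$mll_id[match(rownames(mlg_geno), mll_of_mlg$mlg_id)]
  ramet_mll <- stats::setNames(clones$mll_id, clones$ramet_id)

  obs_mat <- genotype_matrix(ramet_genotypes)
  seed_mat <- genotype_matrix(seeds[, c(1L, seq(4L, 3L + 2L * n_loci)), drop = FALSE])

  rows <- vector("list", nrow(seeds))
  unassigned <- character(0)
  for (s in seq_len(nrow(seeds))) {
    mother <- seeds$mother_ramet_id[s]
    mrow <- match(mother, rownames(obs_mat))
    if (is.na(mrow))
      stop("seed ", seeds$seed_id[s], " references unknown mother ", mother,
           call. = FALSE)
    pp <- fractional_paternity(seed_mat[s, ], obs_mat[mrow, ], mlg_geno,
                               allele_freqs, config)
    if (is.null(pp)) {
      unassigned <- c(unassigned, seeds$seed_id[s])
      next
    }
    mll <- c(mll_by_rep, "UNSAMPLED")[match(pp$candidate_id,
                                            c(rownames(mlg_geno), "UNSAMPLED"))]
    pi_mll <- rowsum(pp$pi, mll)
    keep <- pi_mll[, 1L] >= min_pi
    if (!any(keep)) keep <- pi_mll[, 1L] == max(pi_mll[, 1L])
    pi_mll[, 1L] <- pi_mll[, 1L] / sum(pi_mll[keep, 1L])
    mother_mll <- unname(ramet_mll[mother])
    rows[[s]] <- data.frame(seed_id = seeds$seed_id[s],
                            mll_id = rownames(pi_mll)[keep],
                            pi = unname(pi_mll[keep, 1L]),
                            selfed = rownames(pi_mll)[keep] == mother_mll,
                            pollination_day = seeds$pollination_day[s],
                            mother_mll = mother_mll,
                            stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(assignments)) {
    assignments <- data.frame(seed_id = character(0), mll_id = character(0),
                              pi = numeric(0), selfed = logical(0),
                              pollination_day = integer(0),
                              mother_mll = character(0),
                              stringsAsFactors = FALSE)
  }
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, unassigned = unassigned,
                 allele_freqs = allele_freqs, config = config),
            class = "floral_paternity")
}

#' @export
print.floral_paternity <- function(x, ...) {
  n <- length(unique(x$assignments$seed_id))
  cat("Fractional paternity:", n, "seeds assigned,",
      length(x$unassigned), "unassignable;",
      length(unique(x$assignments$mll_id)), "candidate MLLs received mass\n")
  invisible(x)
}

# Allele frequencies counted over MLG representative genotypes.
estimate_allele_freqs <- function(mlg_geno) {
  n_loci <- ncol(mlg_geno) / 2L
  out <- vector("list", n_loci)
  names(out) <- locus_names(n_loci)
  for (l in seq_len(n_loci)) {
    a <- c(mlg_geno[, 2L * l - 1L], mlg_geno[, 2L * l])
    a <- a[a != 0L]
    if (length(a) == 0L)
      stop("locus ", l, " has no scored alleles; cannot estimate frequencies",
           call. = FALSE)
    tab <- table(a)
    out[[l]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  out
}

#' Per-seed selfing probability
#'
#' The probability that a seed is geitonogamously selfed is the paternity
#' mass `pi` its assignment puts on the maternal MLL (0 when the maternal
#' MLL is not among the candidates).
#'
#' @param paternity A `floral_paternity` object or its `assignments`
#'   data frame.
#' @return Data frame (`seed_id`, `p_self`, `pollination_day`,
#'   `mother_mll`), one row per assigned seed.
#' @export
classify_selfed <- function(paternity) {
  df <- paternity_table(paternity)
  if (nrow(df) == 0L) {
    return(data.frame(seed_id = character(0), p_self = numeric(0),
                      pollination_day = integer(0), mother_mll = character(0),
                      stringsAsFactors = FALSE))
  }
  self_mass <- rowsum(df$pi * df$selfed, df$seed_id)
  first <- !duplicated(df$seed_id)
  meta <- df[first, c("seed_id", "pollination_day", "mother_mll")]
  out <- data.frame(seed_id = meta$seed_id,
                    p_self = self_mass[match(meta$seed_id, rownames(self_mass)), 1L],
                    pollination_day = meta$pollination_day,
                    mother_mll = meta$mother_mll,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

paternity_table <- function(paternity) {
  if (inherits(paternity, "floral_paternity")) paternity$assignments
  else as.data.frame(paternity)
}
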