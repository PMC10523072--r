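test_that("Mendelian transmission probabilities are exact", {
  expect_identical(transmission_prob(c(1, 2), c(1, 1), c(2, 2)), 1)
  expect_identical(transmission_prob(c(1, 1), c(1, 2), c(1, 2)), 0.25)
  expect_identical(transmission_prob(c(1, 2), c(1, 1), c(1, 1)), 0)
  # a few more enumerable cases
  expect_identical(transmission_prob(c(1, 2), c(1, 2), c(1, 2)), 0.5)
  expect_identical(transmission_prob(c(2, 1), c(1, 1), c(2, 3)), 0.5)
  expect_identical(transmission_prob(c(3, 3), c(1, 3), c(2, 3)), 0.25)
})

test_that("locus likelihood blends Mendelian and Hardy-Weinberg terms", {
  f <- c("1" = 0.5, "2" = 0.5)
  # epsilon = 0 reduces to the transmission probability
  expect_identical(locus_likelihood(c(1, 2), c(1, 1), c(2, 2), f, 0), 1)
  expect_identical(locus_likelihood(c(1, 1), c(1, 2), c(1, 2), f, 0), 0.25)
  # epsilon = 1 is pure Hardy-Weinberg, parents ignored
  expect_equal(locus_likelihood(c(1, 2), c(1, 1), c(1, 1), f, 1), 0.5)
  expect_equal(locus_likelihood(c(1, 1), c(2, 2), c(2, 2), f, 1), 0.25)
  # hand-computed mixture: 0.98 * 1 + 0.02 * 0.5
  expect_equal(locus_likelihood(c(1, 2), c(1, 1), c(2, 2), f, 0.02), 0.99)
  # missing data in any party is uninformative
  expect_identical(locus_likelihood(c(0, 0), c(1, 1), c(2, 2), f, 0.02), 1)
  expect_identical(locus_likelihood(c(1, 2), c(0, 0), c(2, 2), f, 0.02), 1)
})

test_that("fractional paternity normalizes correctly on hand examples", {
  freqs <- list(L1 = c("1" = 0.5, "2" = 0.5))
  cand <- rbind(c1 = c(2L, 2L), c2 = c(1L, 2L))
  # likelihoods 1 and 0.5 normalize to 2/3 and 1/3
  pp <- fractional_paternity(c(1L, 2L), c(1L, 1L), cand, freqs,
                             paternity_config(error_rate = 0))
  expect_equal(pp$pi[pp$candidate_id == "c1"], 2 / 3)
  expect_equal(pp$pi[pp$candidate_id == "c2"], 1 / 3)
  # one compatible candidate takes everything
  cand2 <- rbind(c1 = c(2L, 2L), c2 = c(1L, 1L))
  pp2 <- fractional_paternity(c(1L, 2L), c(1L, 1L), cand2, freqs,
                              paternity_config(error_rate = 0))
  expect_equal(pp2$pi[pp2$candidate_id == "c1"], 1)
  # nothing compatible and no unsampled class: unassignable
  cand3 <- rbind(c1 = c(1L, 1L), c2 = c(1L, 1L))
  expect_null(fractional_paternity(c(2L, 2L), c(2L, 2L), cand3, freqs,
                                   paternity_config(error_rate = 0)))
  # candidate order never matters
  pp_r <- fractional_paternity(c(1L, 2L), c(1L, 1L), cand[2:1, ], freqs,
                               paternity_config(error_rate = 0))
  expect_equal(pp_r$pi[match(pp$candidate_id, pp_r$candidate_id)], pp$pi)
})

test_that("the unsampled father class absorbs orphan seeds", {
  freqs <- list(L1 = c("1" = 0.25, "2" = 0.75))
  cand <- rbind(c1 = c(1L, 1L))
  cfg <- paternity_config(error_rate = 0, include_unsampled = TRUE,
                          unsampled_prior = 0.1)
  # candidate incompatible: all mass on UNSAMPLED
  pp <- fractional_paternity(c(2L, 2L), c(1L, 2L), cand, freqs, cfg)
  expect_equal(pp$pi[pp$candidate_id == "UNSAMPLED"], 1)
  # compatible candidate competes with the allele-frequency father
  pp2 <- fractional_paternity(c(1L, 1L), c(1L, 1L), cand, freqs, cfg)
  # candidate: prior 0.9, lik 1; unsampled: prior 0.1, lik P(pool -> 1) = 0.25
  expect_equal(pp2$pi[pp2$candidate_id == "c1"], 0.9 / (0.9 + 0.1 * 0.25))
  expect_equal(sum(pp2$pi), 1)
})

test_that("assignment recovers simulated sires at study-like settings", {
  # 7 loci x 15 alleles, epsilon = 0.01, 300 seeds, all sires sampled
  set.seed(2024)
  n_loci <- 7L; n_alleles <- 15L; n_cand <- 60L; n_seeds <- 300L
  freqs <- lapply(seq_len(n_loci), function(l) {
    w <- stats::rgamma(n_alleles, 1)
    stats::setNames(w / sum(w), 100L * l + 2L * seq_len(n_alleles) + 1L)
  })
  names(freqs) <- sprintf("L%d", seq_len(n_loci))
  draw_geno <- function(n) {
    mat <- matrix(0L, n, 2L * n_loci)
    for (l in seq_len(n_loci)) {
      lab <- as.integer(names(freqs[[l]]))
      mat[, 2L * l - 1L] <- sample(lab, n, TRUE, prob = freqs[[l]])
      mat[, 2L * l] <- sample(lab, n, TRUE, prob = freqs[[l]])
    }
    mat
  }
  mistype <- function(mat, eps) {
    for (l in seq_len(n_loci)) {
      lab <- as.integer(names(freqs[[l]]))
      for (slot in c(2L * l - 1L, 2L * l)) {
        hit <- stats::runif(nrow(mat)) < eps
        mat[hit, slot] <- sample(lab, sum(hit), TRUE, prob = freqs[[l]])
      }
    }
    mat
  }
  fathers <- draw_geno(n_cand)
  rownames(fathers) <- sprintf("F%02d", seq_len(n_cand))
  mothers <- draw_geno(n_seeds)
  sire <- sample.int(n_cand, n_seeds, replace = TRUE)
  seeds <- matrix(0L, n_seeds, 2L * n_loci)
  for (l in seq_len(n_loci)) {
    ms <- 2L * l - 2L + sample.int(2L, n_seeds, TRUE)
    fs <- 2L * l - 2L + sample.int(2L, n_seeds, TRUE)
    seeds[, 2L * l - 1L] <- mothers[cbind(seq_len(n_seeds), ms)]
    seeds[, 2L * l] <- fathers[cbind(sire, fs)]
  }
  obs_fathers <- mistype(fathers, 0.01)
  obs_mothers <- mistype(mothers, 0.01)
  obs_seeds <- mistype(seeds, 0.01)
  cfg <- paternity_config(error_rate = 0.01)
  pi_true <- numeric(n_seeds)
  top_hit <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    pp <- fractional_paternity(obs_seeds[s, ], obs_mothers[s, ], obs_fathers,
                               freqs, cfg)
    expect_equal(sum(pp$pi), 1, tolerance = 1e-9)
    id <- rownames(fathers)[sire[s]]
    pi_true[s] <- sum(pp$pi[pp$candidate_id == id])
    top_hit[s] <- pp$candidate_id[which.max(pp$pi)] == id
  }
  expect_gte(mean(pi_true), 0.8)
  expect_gte(mean(top_hit), 0.9)
})

test_that("more loci concentrate paternity on the true sire", {
  run_mean_pi <- function(n_loci_use) {
    set.seed(515)
    cfg <- test_config(9, n_genets = 30, genotyping_error = 0.01,
                       seed_sample_fraction = 0.3)
    study <- simulate_study(cfg)
    keep <- c("ramet_id", genotype_colnames_for_test(n_loci_use))
    geno <- study$genotypes$ramet_genotypes[, keep]
    seeds <- study$seeds[, c("seed_id", "mother_ramet_id", "pollination_day",
                             genotype_colnames_for_test(n_loci_use))]
    cl <- assign_clones(geno)
    pat <- assign_paternity(seeds, geno, cl,
                            paternity_config(error_rate = 0.01))
    truth_mll <- cl$mll_id[match(study$truth$true_sire_ramet, cl$ramet_id)]
    a <- pat$assignments
    pi_true <- mapply(function(sid, mll) {
      sum(a$pi[a$seed_id == sid & a$mll_id == mll])
    }, study$truth$seed_id, truth_mll)
    mean(pi_true)
  }
  expect_gte(run_mean_pi(7L), run_mean_pi(3L))
})

test_that("selfing probabilities are the paternity mass on the maternal MLL", {
  a <- data.frame(seed_id = c("s1", "s1", "s2"),
                  mll_id = c("M1", "M2", "M3"),
                  pi = c(0.9, 0.1, 1.0),
                  selfed = c(TRUE, FALSE, FALSE),
                  pollination_day = c(210L, 210L, 211L),
                  mother_mll = c("M1", "M1", "M9"))
  cs <- classify_selfed(a)
  expect_equal(cs$p_self[cs$seed_id == "s1"], 0.9)
  # maternal MLL absent from candidates: selfing probability 0
  expect_equal(cs$p_self[cs$seed_id == "s2"], 0)
})

test_that("inferred selfing sits in the reported band for clone-rich stands", {
  # few, large genets mating uniformly: geitonogamy alone drives selfing
  rates <- sapply(1:5, function(seed) {
    cfg <- population_config(
      n_genets = 6, rng_seed = seed, kernel_scale = Inf,
      ramet_count_law = list(singleton_prob = 0, size = 5, mu = 20, max = 35L),
      seed_sample_fraction = 0.3)
    study <- simulate_study(cfg)
    cl <- assign_clones(study$genotypes$ramet_genotypes)
    pat <- assign_paternity(study$seeds, study$genotypes$ramet_genotypes, cl)
    mean(classify_selfed(pat)$p_self)
  })
  expect_gte(mean(rates), 0.13)
  expect_lte(mean(rates), 0.63)
})
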