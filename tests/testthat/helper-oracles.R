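# Independent brute-force oracles. These deliberately use plain loops and
# explicit multiset counting so they share no code path with the package.

# Multiset-intersection allelic distance, counting copies explicitly.
oracle_allelic_distance <- function(g1, g2) {
  n_loci <- length(g1) / 2L
  total <- 0L
  any_shared <- FALSE
  for (l in seq_len(n_loci)) {
    p1 <- g1[c(2L * l - 1L, 2L * l)]
    p2 <- g2[c(2L * l - 1L, 2L * l)]
    if (any(p1 == 0L) || any(p2 == 0L)) next
    any_shared <- TRUE
    inter <- 0L
    remaining <- p2
    for (a in p1) {
      hit <- match(a, remaining)
      if (!is.na(hit)) {
        inter <- inter + 1L
        remaining <- remaining[-hit]
      }
    }
    total <- total + (2L - inter)
  }
  if (!any_shared) return(NA_integer_)
  total
}

# Naive connected-component search over the <= max_diff threshold graph,
# using the full all-pairs distance matrix and breadth-first traversal.
oracle_mll_partition <- function(mat, max_diff = 1L) {
  n <- nrow(mat)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- oracle_allelic_distance(mat[i, ], mat[j, ])
        adj[i, j] <- adj[j, i] <- !is.na(d) && d <= max_diff
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# Triple-loop male fraction and pollen-transfer opportunity.
oracle_pto <- function(floral) {
  n <- nrow(floral)
  f <- numeric(n)
  K <- numeric(n)
  for (r in seq_len(n)) {
    other_male <- 0
    fem_other <- 0
    for (s in seq_len(n)) {
      if (floral$day[s] != floral$day[r]) next
      if (s != r) other_male <- other_male + floral$n_open_male[s]
      if (floral$mll_id[s] != floral$mll_id[r])
        fem_other <- fem_other + floral$n_open_female[s]
    }
    f[r] <- if (floral$n_open_male[r] == 0) 0
            else if (other_male == 0) 1
            else floral$n_open_male[r] / other_male
    K[r] <- f[r] * fem_other
  }
  list(f = f, K = K)
}

# Loop aggregation of per-ramet K into genet-day and genet totals.
oracle_pto_genet <- function(floral, K) {
  keys <- unique(data.frame(mll_id = floral$mll_id, day = floral$day))
  out <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    for (r in seq_len(nrow(floral))) {
      if (floral$mll_id[r] == keys$mll_id[i] && floral$day[r] == keys$day[i])
        out[i] <- out[i] + K[r]
    }
  }
  keys$K_day <- out
  keys
}

# Random genotype tables with few alleles so distance-0/1 pairs are common.
random_genotype_table <- function(n, n_loci = 7L, n_alleles = 4L,
                                  miss_rate = 0.05) {
  mat <- matrix(sample(seq_len(n_alleles) * 2L + 99L, 2L * n_loci * n,
                       replace = TRUE), nrow = n)
  for (l in seq_len(n_loci)) {
    miss <- stats::runif(n) < miss_rate
    mat[miss, 2L * l - 1L] <- 0L
    mat[miss, 2L * l] <- 0L
  }
  # guarantee every row keeps at least one scored locus
  none <- rowSums(mat != 0L) == 0L
  mat[none, 1L] <- 101L
  mat[none, 2L] <- 103L
  df <- data.frame(ramet_id = sprintf("r%03d", seq_len(n)), mat,
                   stringsAsFactors = FALSE)
  names(df) <- c("ramet_id", genotype_colnames_for_test(n_loci))
  df
}

# Allele matrix from a genotype table (id column first).
genotype_matrix_for_test <- function(df) {
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- as.character(df[[1L]])
  mat
}

genotype_colnames_for_test <- function(n_loci) {
  as.vector(t(outer(sprintf("L%d", seq_len(n_loci)), c("a1", "a2"),
                    paste, sep = "_")))
}

# Random daily floral tables for the PTO oracle checks.
random_floral_table <- function(max_ramets = 30L, max_days = 10L) {
  n_ramets <- sample(2:max_ramets, 1L)
  n_days <- sample(2:max_days, 1L)
  n_genets <- sample(1:max(1L, n_ramets %/% 2L), 1L)
  genet <- sprintf("g%02d", sample(n_genets, n_ramets, replace = TRUE))
  rows <- expand.grid(ramet = seq_len(n_ramets), day = seq_len(n_days))
  rows <- rows[stats::runif(nrow(rows)) < 0.6, , drop = FALSE]
  if (nrow(rows) == 0L) rows <- data.frame(ramet = 1L, day = 1L)
  data.frame(day = rows$day + 198L,
             ramet_id = sprintf("r%03d", rows$ramet),
             mll_id = genet[rows$ramet],
             n_open_male = stats::rpois(nrow(rows), 1.2),
             n_open_female = stats::rpois(nrow(rows), 1.0),
             stringsAsFactors = FALSE)
}

# Small fast simulator config for tests.
test_config <- function(seed, n_genets = 40L, ...) {
  population_config(n_genets = n_genets, rng_seed = seed, ...)
}

# Map each ramet's true genet through a clonal assignment table.
true_genet_of <- function(study) {
  stats::setNames(study$population$ramets$genet_id,
                  study$population$ramets$ramet_id)
}

# Are two partitions of the same elements identical (up to label names)?
same_partition <- function(a, b) {
  ta <- as.integer(factor(a, levels = unique(a)))
  tb <- as.integer(factor(b, levels = unique(b)))
  all(tapply(tb, ta, function(x) length(unique(x))) == 1L) &&
    all(tapply(ta, tb, function(x) length(unique(x))) == 1L)
}
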