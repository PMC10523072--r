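#' Allelic distance between two multilocus genotypes
#'
#' The per-locus distance between two codominant genotypes is
#' `2 - |multiset intersection of the two allele pairs|`, i.e. 0 for
#' identical pairs, 1 when exactly one allele is shared (counting copies),
#' and 2 when no allele is shared. The total distance sums the per-locus
#' distances over loci scored in *both* genotypes; loci missing in either
#' genotype are skipped.
#'
#' @param g1,g2 Integer vectors of length `2 * n_loci` holding the allele
#'   pairs locus by locus (`a1, a2` per locus), with 0 (or `NA`) marking
#'   missing calls. Both alleles of a locus must be present or absent
#'   together.
#' @return A non-negative integer distance. Errors if the two genotypes
#'   share no scored locus.
#' @examples
#' allelic_distance(c(101, 103, 205, 205), c(101, 105, 205, 205))  # 1
#' @export
allelic_distance <- function(g1, g2) {
  g1 <- as.integer(ifelse(is.na(g1), 0L, g1))
  g2 <- as.integer(ifelse(is.na(g2), 0L, g2))
  if (length(g1) != length(g2) || length(g1) %% 2L != 0L)
    stop("genotypes must have the same even length (a1,a2 per locus)",
         call. = FALSE)
  n_loci <- length(g1) / 2L
  i1 <- 2L * seq_len(n_loci) - 1L
  a1 <- g1[i1]; b1 <- g1[i1 + 1L]
  a2 <- g2[i1]; b2 <- g2[i1 + 1L]
  if (any((a1 == 0L) != (b1 == 0L)) || any((a2 == 0L) != (b2 == 0L)))
    stop("each locus must have 0 or 2 allele calls", call. = FALSE)
  shared <- (a1 != 0L) & (a2 != 0L)
  if (!any(shared))
    stop("genotypes share no scored locus; allelic distance undefined",
         call. = FALSE)
  # sort each pair, then the multiset intersection size is the larger of
  # the two slot-wise pairings
  lo1 <- pmin(a1, b1); hi1 <- pmax(a1, b1)
  lo2 <- pmin(a2, b2); hi2 <- pmax(a2, b2)
  m <- pmax((lo1 == lo2) + (hi1 == hi2), (lo1 == hi2) + (hi1 == lo2))
  sum((2L - m)[shared])
}

# All-pairs allelic distance matrix for an n x (2*n_loci) allele matrix.
# Entries where two genotypes share no scored locus are NA.
allelic_dist_matrix <- function(mat) {
  n <- nrow(mat)
  n_loci <- ncol(mat) / 2L
  dist <- matrix(0L, n, n)
  nshared <- matrix(0L, n, n)
  for (l in seq_len(n_loci)) {
    a <- mat[, 2L * l - 1L]; b <- mat[, 2L * l]
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- a != 0L
    p1 <- outer(lo, lo, "==") + outer(hi, hi, "==")
    p2 <- outer(lo, hi, "==") + outer(hi, lo, "==")
    d <- 2L - pmax(p1, p2)
    both <- outer(ok, ok, "&")
    d[!both] <- 0L
    dist <- dist + d
    nshared <- nshared + both
  }
  dist[nshared == 0L] <- NA_integer_
  dimnames(dist) <- list(rownames(mat), rownames(mat))
  dist
}

#' Group ramets into multilocus genotypes (MLGs)
#'
#' Two ramets share an MLG when their genotypes are identical as
#' unordered allele pairs at every locus *and* have the same missing-data
#' pattern (so uninformative genotypes cannot absorb informative ones).
#' MLG labels are canonical - ordered by the lexicographically smallest
#' ramet id they contain - so permuting input rows never changes the
#' partition.
#'
#' @param genotypes Data frame with `ramet_id` followed by two integer
#'   allele columns per locus (0 = missing).
#' @return A data frame (`ramet_id`, `mlg_id`) with attributes
#'   `mlg_genotypes` (one representative allele row per MLG, canonically
#'   ordered within each locus) used by [build_mlls()].
#' @examples
#' g <- data.frame(ramet_id = c("r1", "r2"),
#'                 L1_a1 = c(101, 103), L1_a2 = c(103, 101))
#' group_mlgs(g)  # one MLG: the pairs are the same multiset
#' @export
group_mlgs <- function(genotypes) {
  if (nrow(genotypes) < 1L) stop("need at least one ramet", call. = FALSE)
  mat <- genotype_matrix(genotypes)
  n_loci <- ncol(mat) / 2L
  # canonical within-locus order
  for (l in seq_len(n_loci)) {
    i <- 2L * l - 1L
    lo <- pmin(mat[, i], mat[, i + 1L]); hi <- pmax(mat[, i], mat[, i + 1L])
    mat[, i] <- lo; mat[, i + 1L] <- hi
  }
  key <- apply(mat, 1L, paste, collapse = "/")
  ramet_id <- as.character(genotypes[[1L]])
  min_ramet <- tapply(ramet_id, key, min)
  keys <- names(sort(min_ramet))
  width <- max(3L, nchar(length(keys)))
  mlg_id <- sprintf(paste0("MLG%0", width, "d"), match(key, keys))

  rep_rows <- mat[match(keys, key), , drop = FALSE]
  rownames(rep_rows) <- sprintf(paste0("MLG%0", width, "d"), seq_along(keys))
  out <- data.frame(ramet_id = ramet_id, mlg_id = mlg_id,
                    stringsAsFactors = FALSE)
  attr(out, "mlg_genotypes") <- rep_rows
  attr(out, "mlg_min_ramet") <- stats::setNames(as.character(min_ramet[keys]),
                                                rownames(rep_rows))
  out
}

#' Cluster MLGs into multilocus lineages (MLLs)
#'
#' MLLs (taken to be genets) are the connected components of the graph
#' joining every pair of MLGs whose allelic distance is at most
#' `max_diff` (default 1, i.e. a single allele difference at a single
#' locus). The transitive closure means a chain of single-step variants
#' collapses into one lineage even if its extremes differ by more. MLL
#' labels are canonical by smallest member ramet id.
#'
#' @param mlgs Output of [group_mlgs()].
#' @param max_diff Maximum total allelic distance joining two MLGs into
#'   one lineage; must be a non-negative integer.
#' @return A data frame (`ramet_id`, `mlg_id`, `mll_id`) with attribute
#'   `mll_members` (list of MLG ids per MLL).
#' @examples
#' cfg <- population_config(n_genets = 8, rng_seed = 2)
#' gt <- generate_genotypes(generate_population(cfg), cfg)
#' cl <- build_mlls(group_mlgs(gt$ramet_genotypes))
#' table(cl$mll_id)
#' @export
build_mlls <- function(mlgs, max_diff = 1L) {
  if (length(max_diff) != 1L || is.na(max_diff) || max_diff < 0)
    stop("max_diff must be a non-negative integer", call. = FALSE)
  rep_rows <- attr(mlgs, "mlg_genotypes")
  if (is.null(rep_rows))
    stop("mlgs must be the output of group_mlgs()", call. = FALSE)
  n <- nrow(rep_rows)
  dmat <- allelic_dist_matrix(rep_rows)
  adj <- !is.na(dmat) & dmat <= max_diff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  # canonical MLL ids: order components by their smallest member ramet id
  min_ramet <- attr(mlgs, "mlg_min_ramet")[rownames(rep_rows)]
  comp_min <- tapply(min_ramet, comp, min)
  ord <- rank(comp_min, ties.method = "first")
  width <- max(3L, nchar(n))
  mll_of_mlg <- stats::setNames(sprintf(paste0("MLL%0", width, "d"), ord[as.character(comp)]),
                                rownames(rep_rows))

  out <- data.frame(ramet_id = mlgs$ramet_id,
                    mlg_id = mlgs$mlg_id,
                    mll_id = unname(mll_of_mlg[mlgs$mlg_id]),
                    stringsAsFactors = FALSE)
  attr(out, "mll_members") <- split(names(mll_of_mlg), mll_of_mlg)
  attr(out, "mlg_genotypes") <- rep_rows
  out
}

#' Assign ramets to clones (MLGs and MLLs) in one step
#'
#' Convenience wrapper: [group_mlgs()] followed by [build_mlls()].
#'
#' @inheritParams group_mlgs
#' @inheritParams build_mlls
#' @return See [build_mlls()].
#' @export
assign_clones <- function(genotypes, max_diff = 1L) {
  build_mlls(group_mlgs(genotypes), max_diff = max_diff)
}
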