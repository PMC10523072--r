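#' Inflorescence sex ratio
#'
#' The proportion of male flowers among all flowers of an inflorescence,
#' the unit at which a monoecious plant expresses sex allocation.
#'
#' @param n_male,n_total Integer counts (vectorized); `n_total` must be
#'   at least 1 and at least `n_male`.
#' @return `n_male / n_total` in `[0, 1]`.
#' @examples
#' inflorescence_sex_ratio(6, 9)
#' @export
inflorescence_sex_ratio <- function(n_male, n_total) {
  if (any(n_total < 1L)) stop("n_total must be >= 1", call. = FALSE)
  if (any(n_male < 0L | n_male > n_total))
    stop("n_male must lie in [0, n_total]", call. = FALSE)
  n_male / n_total
}

#' Build the inflorescence sex-ratio table
#'
#' One record per inflorescence: its first flowering day, male and total
#' flower counts, sex ratio, and the ramet/MLL it belongs to. This is the
#' input for [fit_sexratio_trend()].
#'
#' @param inflorescences Inflorescence summary (`inflorescence_id`,
#'   `ramet_id`, `first_day`, `n_female`, `n_male`), e.g. from
#'   [generate_phenology()] or [derive_inflorescences()].
#' @param clones Clonal assignment (`ramet_id`, `mll_id`). Ramets without
#'   an assignment are dropped with a warning.
#' @return Data frame (`inflorescence_id`, `ramet_id`, `mll_id`,
#'   `first_day`, `n_male`, `n_total`, `sex_ratio`).
#' @export
sex_ratio_table <- function(inflorescences, clones) {
  cl <- paternity_clone_cols(clones)
  mll <- cl$mll_id[match(inflorescences$ramet_id, cl$ramet_id)]
  if (anyNA(mll)) {
    warning(sum(is.na(mll)), " inflorescence(s) on ramets without a clonal ",
            "assignment were dropped")
    inflorescences <- inflorescences[!is.na(mll), , drop = FALSE]
    mll <- mll[!is.na(mll)]
  }
  n_total <- inflorescences$n_female + inflorescences$n_male
  keep <- n_total >= 1L
  out <- data.frame(inflorescence_id = inflorescences$inflorescence_id[keep],
                    ramet_id = inflorescences$ramet_id[keep],
                    mll_id = mll[keep],
                    first_day = inflorescences$first_day[keep],
                    n_male = inflorescences$n_male[keep],
                    n_total = n_total[keep],
                    stringsAsFactors = FALSE)
  out$sex_ratio <- inflorescence_sex_ratio(out$n_male, out$n_total)
  out
}

#' Summarize daily phenology records into inflorescence totals
#'
#' Recovers the per-inflorescence summary (first flowering day and total
#' female/male flower counts) from the daily record table; because every
#' flower is open exactly one day, summing daily open counts gives the
#' totals.
#'
#' @param phenology Daily record table (`day`, `ramet_id`,
#'   `inflorescence_id`, `n_open_female`, `n_open_male`).
#' @return Data frame (`inflorescence_id`, `ramet_id`, `first_day`,
#'   `n_female`, `n_male`).
#' @export
derive_inflorescences <- function(phenology) {
  sp <- split(seq_len(nrow(phenology)), phenology$inflorescence_id)
  out <- data.frame(
    inflorescence_id = names(sp),
    ramet_id = vapply(sp, function(i) phenology$ramet_id[i[1L]], character(1)),
    first_day = vapply(sp, function(i) min(phenology$day[i]), numeric(1)),
    n_female = vapply(sp, function(i) sum(phenology$n_open_female[i]), numeric(1)),
    n_male = vapply(sp, function(i) sum(phenology$n_open_male[i]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$inflorescence_id), , drop = FALSE]
}

#' Daily male-flower fraction and pollen-transfer opportunity per ramet
#'
#' For each ramet-day record, computes the daily fraction of open male
#' flowers `f_m = N_m(j) / sum_{l != j} N_m(l)` - the ramet's share of
#' pollen relative to all *other* ramets that day - and the
#' pollen-transfer opportunity `K = f_m * F_other`, where `F_other` is
#' the number of female flowers open that day on ramets *outside* the
#' focal ramet's genet (geitonogamous partners do not count as mating
#' opportunities). Conventions for degenerate days: a ramet with no open
#' male flowers has `f_m = 0`; a sole pollen donor (positive `N_m`, no
#' male flowers on any other ramet) takes `f_m = 1`, the monopoly limit,
#' and is flagged in `sole_donor`. `K` can exceed 1: it is an
#' opportunity index, not a probability.
#'
#' @param phenology Daily record table (see [generate_phenology()]).
#' @param clones Clonal assignment (`ramet_id`, `mll_id`).
#' @return Data frame (`day`, `ramet_id`, `mll_id`, `n_open_male`,
#'   `n_open_female`, `f_m`, `sole_donor`, `K`), one row per phenology
#'   record.
#' @examples
#' cfg <- population_config(n_genets = 10, rng_seed = 4)
#' study <- simulate_study(cfg)
#' cl <- assign_clones(study$genotypes$ramet_genotypes)
#' head(pto_ramet_day(study$phenology, cl))
#' @export
pto_ramet_day <- function(phenology, clones) {
  cl <- paternity_clone_cols(clones)
  mll <- cl$mll_id[match(phenology$ramet_id, cl$ramet_id)]
  if (anyNA(mll))
    stop("phenology contains ramets without a clonal assignment: ",
         paste(utils::head(unique(phenology$ramet_id[is.na(mll)]), 3L),
               collapse = ", "), call. = FALSE)
  if (any(phenology$n_open_male < 0L | phenology$n_open_female < 0L))
    stop("flower counts must be non-negative", call. = FALSE)

  out <- data.frame(day = phenology$day,
                    ramet_id = phenology$ramet_id,
                    mll_id = mll,
                    n_open_male = phenology$n_open_male,
                    n_open_female = phenology$n_open_female,
                    stringsAsFactors = FALSE)
  day_f <- factor(out$day)
  total_m <- tapply(out$n_open_male, day_f, sum)[day_f]
  total_f <- tapply(out$n_open_female, day_f, sum)[day_f]
  genet_day <- interaction(out$mll_id, day_f, drop = TRUE)
  fem_genet <- tapply(out$n_open_female, genet_day, sum)[genet_day]

  denom <- total_m - out$n_open_male
  f_m <- ifelse(out$n_open_male == 0L, 0,
                ifelse(denom == 0, 1, out$n_open_male / denom))
  out$f_m <- as.numeric(f_m)
  out$sole_donor <- out$n_open_male > 0L & denom == 0
  out$K <- out$f_m * as.numeric(total_f - fem_genet)
  rownames(out) <- NULL
  out
}

#' Pollen-transfer opportunity per genet
#'
#' Sums the per-ramet daily opportunities `K` over the flowering ramets
#' of each genet (MLL), giving the genet's daily pollen-transfer
#' opportunity `K_day`, and totals those over the season into `K_g`.
#' By default only male-phase genet-days are kept (days on which the
#' genet had at least one open male flower): the index describes siring
#' opportunity, which a genet without pollen does not have.
#'
#' @param pto_ramet Output of [pto_ramet_day()].
#' @param male_phase_only Keep only genet-days with at least one open
#'   male flower in the genet (default `TRUE`).
#' @return Data frame (`mll_id`, `day`, `K_day`) with attribute `totals`,
#'   a data frame (`mll_id`, `K_g`) of season totals (also retrievable
#'   with [pto_totals()]).
#' @export
pto_genet <- function(pto_ramet, male_phase_only = TRUE) {
  agg <- stats::aggregate(
    list(K_day = pto_ramet$K, n_male = pto_ramet$n_open_male),
    by = list(mll_id = pto_ramet$mll_id, day = pto_ramet$day), FUN = sum)
  if (male_phase_only) agg <- agg[agg$n_male > 0L, , drop = FALSE]
  agg <- agg[order(agg$mll_id, agg$day), c("mll_id", "day", "K_day")]
  rownames(agg) <- NULL
  totals <- stats::aggregate(list(K_g = agg$K_day),
                             by = list(mll_id = agg$mll_id), FUN = sum)
  attr(agg, "totals") <- totals
  agg
}

#' Season-total pollen-transfer opportunity per genet
#'
#' @param pto_daily Output of [pto_genet()].
#' @return Data frame (`mll_id`, `K_g`).
#' @export
pto_totals <- function(pto_daily) {
  tot <- attr(pto_daily, "totals")
  if (!is.null(tot)) return(tot)
  stats::aggregate(list(K_g = pto_daily$K_day),
                   by = list(mll_id = pto_daily$mll_id), FUN = sum)
}

#' Realized siring success per genet
#'
#' Aggregates per-seed paternity probabilities into the realized siring
#' success `RS` of each MLL per pollination day, and into season totals.
#' With `method = "assigned"` (the default) each seed contributes its
#' paternity probability `pi` to the single MLL assigned as its most
#' probable sire; with `method = "fractional"` every candidate MLL
#' receives its full fractional mass. Self-fertilized seeds - those whose
#' assigned sire is the maternal MLL (`"assigned"`), or the selfed mass
#' itself (`"fractional"`) - are excluded by default, as is mass on the
#' `UNSAMPLED` father class.
#'
#' @param paternity A `floral_paternity` object or its `assignments`
#'   table.
#' @param exclude_selfed Exclude self-fertilization (default `TRUE`).
#' @param method `"assigned"` (most-probable-sire, the default) or
#'   `"fractional"`.
#' @return Data frame (`mll_id`, `day`, `RS`) restricted to positive
#'   entries, with attribute `totals` (`mll_id`, `RS_total`), retrievable
#'   with [siring_totals()].
#' @export
siring_success <- function(paternity, exclude_selfed = TRUE,
                           method = c("assigned", "fractional")) {
  method <- match.arg(method)
  df <- paternity_table(paternity)
  if (method == "assigned" && nrow(df) > 0L) {
    # keep each seed's most probable candidate (ties broken by mll id)
    df <- df[order(df$seed_id, -df$pi, df$mll_id), , drop = FALSE]
    df <- df[!duplicated(df$seed_id), , drop = FALSE]
  }
  df <- df[df$mll_id != "UNSAMPLED", , drop = FALSE]
  if (exclude_selfed) df <- df[!df$selfed, , drop = FALSE]
  if (nrow(df) == 0L) {
    out <- data.frame(mll_id = character(0), day = integer(0), RS = numeric(0))
    attr(out, "totals") <- data.frame(mll_id = character(0),
                                      RS_total = numeric(0))
    return(out)
  }
  agg <- stats::aggregate(list(RS = df$pi),
                          by = list(mll_id = df$mll_id,
                                    day = df$pollination_day), FUN = sum)
  agg <- agg[agg$RS > 0, , drop = FALSE]
  agg <- agg[order(agg$mll_id, agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  totals <- stats::aggregate(list(RS_total = agg$RS),
                             by = list(mll_id = agg$mll_id), FUN = sum)
  attr(agg, "totals") <- totals
  agg
}

#' Season-total siring success per genet
#'
#' @param siring Output of [siring_success()].
#' @return Data frame (`mll_id`, `RS_total`).
#' @export
siring_totals <- function(siring) {
  tot <- attr(siring, "totals")
  if (!is.null(tot)) return(tot)
  stats::aggregate(list(RS_total = siring$RS),
                   by = list(mll_id = siring$mll_id), FUN = sum)
}

#' Daily male-flower fraction per ramet
#'
#' Convenience accessor for the `f_m` component of [pto_ramet_day()]: each
#' ramet-day's share of open male flowers relative to all other ramets that
#' day, with the sole-donor convention (`f = 1` when no other ramet has
#' pollen) flagged.
#'
#' @inheritParams pto_ramet_day
#' @return Data frame (`day`, `ramet_id`, `mll_id`, `n_open_male`, `f_m`,
#'   `sole_donor`).
#' @export
male_fraction <- function(phenology, clones) {
  pt <- pto_ramet_day(phenology, clones)
  pt[, c("day", "ramet_id", "mll_id", "n_open_male", "f_m", "sole_donor")]
}

#' Day of peak flowering
#'
#' The day with the greatest number of open inflorescences (inflorescences
#' with at least one open flower of either sex).
#'
#' @param phenology Daily floral record table.
#' @return The Julian day (integer); ties go to the earliest day.
#' @export
peak_flowering_day <- function(phenology) {
  open <- phenology$n_open_female + phenology$n_open_male > 0L
  counts <- table(phenology$day[open])
  as.integer(names(counts)[which.max(counts)])
}

# Accept either an assign_clones() result or any data frame carrying
# ramet_id and mll_id.
paternity_clone_cols <- function(clones) {
  if (!all(c("ramet_id", "mll_id") %in% names(clones)))
    stop("clones must contain ramet_id and mll_id columns", call. = FALSE)
  clones
}
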