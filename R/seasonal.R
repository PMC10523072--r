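#' Seasonal trend in inflorescence sex allocation
#'
#' Fits a binomial (logit-link) penalized-spline mixed model of the
#' number of male flowers out of the inflorescence total against first
#' flowering date: a thin-plate regression spline of date plus random
#' intercepts for MLL and, nested within it, inflorescence (an
#' observation-level term absorbing extra-binomial variation). A linear
#' logit mixed counterpart with the same random effects is fitted
#' alongside and both AICs are reported, so a nonlinear seasonal trend
#' can be judged both by the significance of the smooth term and by the
#' AIC comparison. If the inflorescence-level term makes the linear-model
#' random structure singular, that model is refitted without it and the
#' result flagged (`dropped_inner`).
#'
#' @param sex_ratios Output of [sex_ratio_table()]: needs `n_male`,
#'   `n_total`, `first_day`, `mll_id`, `inflorescence_id`.
#' @param k Spline basis dimension (default 10).
#' @param inflorescence_re Include the nested inflorescence random
#'   intercept (default `TRUE`).
#' @return A `floral_trend` object: intercept estimate and s.e. (logit
#'   scale), smooth-term `edf`, test statistic and p-value, the smooth
#'   and linear model AICs, random-effect standard deviations, the fitted
#'   population-level trend over a day grid (`trend`: `day`, `fit`, `se`,
#'   response scale), sample sizes and convergence flags. The underlying
#'   fits are kept in `$model` and `$linear_model`.
#' @examples
#' \donttest{
#' study <- simulate_study(population_config(n_genets = 60, rng_seed = 21))
#' cl <- assign_clones(study$genotypes$ramet_genotypes)
#' sr <- sex_ratio_table(study$inflorescences, cl)
#' fit_sexratio_trend(sr)
#' }
#' @export
fit_sexratio_trend <- function(sex_ratios, k = 10, inflorescence_re = TRUE) {
  d <- data.frame(n_male = sex_ratios$n_male,
                  n_fem = sex_ratios$n_total - sex_ratios$n_male,
                  day = as.numeric(sex_ratios$first_day),
                  mll = factor(sex_ratios$mll_id),
                  infl = factor(sex_ratios$inflorescence_id))
  if (nrow(d) < 20L || length(unique(d$day)) < 10L)
    stop("need at least 20 inflorescences spanning at least 10 distinct days",
         call. = FALSE)
  k <- min(k, length(unique(d$day)) - 1L)

  form <- if (inflorescence_re) {
    cbind(n_male, n_fem) ~ s(day, bs = "tp", k = k) + s(mll, bs = "re") +
      s(infl, bs = "re")
  } else {
    cbind(n_male, n_fem) ~ s(day, bs = "tp", k = k) + s(mll, bs = "re")
  }
  gam_fit <- fit_gam_engine(form, d, stats::binomial())

  # linear-logit mixed counterpart for the AIC comparison
  d$day_c <- as.numeric(scale(d$day))
  dropped_inner <- FALSE
  lin <- NULL
  if (inflorescence_re) {
    lin <- suppressMessages(suppressWarnings(try(
      lme4::glmer(cbind(n_male, n_fem) ~ day_c + (1 | mll/infl),
                  data = d, family = stats::binomial()), silent = TRUE)))
    if (inherits(lin, "try-error") || lme4::isSingular(lin)) {
      dropped_inner <- TRUE
      lin <- NULL
    }
  }
  if (is.null(lin)) {
    lin <- suppressMessages(suppressWarnings(
      lme4::glmer(cbind(n_male, n_fem) ~ day_c + (1 | mll),
                  data = d, family = stats::binomial())))
  }

  build_trend_result(gam_fit, lin, d, response = "sex_ratio",
                     dropped_inner = dropped_inner)
}

#' Seasonal trend in pollen-transfer opportunity
#'
#' Fits a Gaussian (identity-link) penalized-spline mixed model of daily
#' genet-level pollen-transfer opportunity `K_day` against date: a
#' thin-plate spline of day plus an MLL random intercept, with a linear
#' mixed counterpart fitted for the AIC comparison.
#'
#' @param pto_daily Output of [pto_genet()] (`mll_id`, `day`, `K_day`).
#' @param k Spline basis dimension (default 10).
#' @return A `floral_trend` object (see [fit_sexratio_trend()]); its
#'   `trend` element carries the fitted population-level curve, and
#'   `peak_day` the day at which it is highest.
#' @export
fit_pto_trend <- function(pto_daily, k = 10) {
  d <- data.frame(K = pto_daily$K_day,
                  day = as.numeric(pto_daily$day),
                  mll = factor(pto_daily$mll_id))
  if (nrow(d) < 20L || length(unique(d$day)) < 10L)
    stop("need at least 20 genet-day records spanning at least 10 distinct days",
         call. = FALSE)
  k <- min(k, length(unique(d$day)) - 1L)
  gam_fit <- fit_gam_engine(K ~ s(day, bs = "tp", k = k) + s(mll, bs = "re"),
                            d, stats::gaussian())
  d$day_c <- as.numeric(scale(d$day))
  lin <- suppressMessages(suppressWarnings(
    lmerTest::lmer(K ~ day_c + (1 | mll), data = d, REML = FALSE)))
  build_trend_result(gam_fit, lin, d, response = "pto", dropped_inner = FALSE)
}

# Shared GAM engine: mgcv::gam with REML for moderate data, switching to
# mgcv::bam (fast REML, discretized covariates) when the random-effect
# structure gets large.
fit_gam_engine <- function(form, d, family) {
  big <- nrow(d) > 500L
  if (big) {
    mgcv::bam(form, data = d, family = family, method = "fREML",
              discrete = TRUE)
  } else {
    mgcv::gam(form, data = d, family = family, method = "REML")
  }
}

build_trend_result <- function(gam_fit, lin, d, response, dropped_inner) {
  # re.test = FALSE skips significance tests of the random-effect smooths,
  # which dominate runtime when the inflorescence term has many levels
  sm <- summary(gam_fit, re.test = FALSE)
  s1 <- 1L  # first smooth is s(day)
  stat_name <- intersect(c("Chi.sq", "F"), colnames(sm$s.table))[1L]
  stat <- sm$s.table[s1, stat_name]
  grid <- data.frame(day = seq(min(d$day), max(d$day), by = 0.5))
  grid$mll <- d$mll[1L]
  if ("infl" %in% names(d)) grid$infl <- d$infl[1L]
  excl <- grep("^s\\((mll|infl)\\)$",
               vapply(gam_fit$smooth, function(s) s$label, character(1)),
               value = TRUE)
  pr <- stats::predict(gam_fit, newdata = grid, type = "link",
                       se.fit = TRUE, exclude = excl, discrete = FALSE)
  inv <- gam_fit$family$linkinv
  trend <- data.frame(day = grid$day, fit = inv(as.numeric(pr$fit)),
                      se = as.numeric(pr$se.fit))
  re_sd <- tryCatch({
    utils::capture.output(vc <- mgcv::gam.vcomp(gam_fit))
    if (is.matrix(vc)) stats::setNames(vc[, "std.dev"], rownames(vc))
    else vc
  }, error = function(e) NULL)

  res <- list(
    response = response,
    intercept = unname(sm$p.table["(Intercept)", "Estimate"]),
    intercept_se = unname(sm$p.table["(Intercept)", "Std. Error"]),
    edf = unname(sm$s.table[s1, "edf"]),
    statistic = unname(stat),
    statistic_name = stat_name,
    p_value = unname(sm$s.table[s1, "p-value"]),
    aic_smooth = stats::AIC(gam_fit),
    aic_linear = stats::AIC(lin),
    re_sd = re_sd,
    trend = trend,
    peak_day = trend$day[which.max(trend$fit)],
    n = nrow(d),
    n_mll = length(unique(d$mll)),
    dropped_inner = dropped_inner,
    converged = isTRUE(gam_fit$converged),
    model = gam_fit,
    linear_model = lin
  )
  class(res) <- "floral_trend"
  res
}

#' @export
print.floral_trend <- function(x, ...) {
  cat(sprintf("Seasonal trend (%s): n = %d (%d MLLs)\n", x$response, x$n, x$n_mll))
  cat(sprintf("  intercept %.3f +/- %.3f | s(day): edf = %.2f, %s = %.2f, p = %.3g\n",
              x$intercept, x$intercept_se, x$edf, x$statistic_name,
              x$statistic, x$p_value))
  cat(sprintf("  AIC smooth = %.1f vs linear = %.1f | trend peak at day %.1f\n",
              x$aic_smooth, x$aic_linear, x$peak_day))
  if (x$dropped_inner)
    cat("  note: inner (inflorescence) random term dropped as singular in the linear model\n")
  invisible(x)
}

#' Siring success against date and pollen-transfer opportunity
#'
#' Linear mixed models of log10 daily siring success per genet on siring
#' date and on that genet's pollen-transfer opportunity for the day, with
#' an MLL random intercept. Follows a stepwise protocol: the two
#' single-predictor models and the joint model are fitted, each term is
#' tested with Satterthwaite denominator degrees of freedom, and the
#' model with the lowest (ML) AIC is selected. Only genet-days with
#' positive (outcross) siring success enter, unless `offset_const` adds a
#' constant inside the log so zero rows can be kept.
#'
#' @param siring Output of [siring_success()] (`mll_id`, `day`, `RS`).
#' @param pto_daily Output of [pto_genet()]; genet-days the sire was not
#'   in male phase get `K_day = 0`.
#' @param offset_const Optional constant `c` for `log10(RS + c)`; default
#'   `NULL` (zero rows excluded, the default analysis).
#' @return A `floral_siring` object: per-model coefficient tables
#'   (estimate, s.e., Satterthwaite df, t, p), per-term F tests, AICs (ML),
#'   the selected model name, sample sizes, and the fitted `lmerTest`
#'   models in `$models`.
#' @export
fit_siring_model <- function(siring, pto_daily, offset_const = NULL) {
  d <- merge(siring, pto_daily, by = c("mll_id", "day"), all.x = TRUE)
  d$K_day[is.na(d$K_day)] <- 0
  if (!is.null(offset_const)) {
    d$y <- log10(d$RS + offset_const)
  } else {
    d <- d[d$RS > 0, , drop = FALSE]
    d$y <- log10(d$RS)
  }
  d$mll <- factor(d$mll_id)
  n_sires <- length(unique(d$mll))
  if (n_sires < 5L)
    stop("fewer than 5 sire genets with positive siring success; ",
         "cannot fit the siring model", call. = FALSE)
  d$day <- as.numeric(d$day)

  forms <- list(date = y ~ day + (1 | mll),
                pto = y ~ K_day + (1 | mll),
                joint = y ~ day + K_day + (1 | mll))
  models <- lapply(forms, function(f)
    suppressMessages(suppressWarnings(
      do.call(lmerTest::lmer, list(formula = f, data = d)))))

  coef_tables <- lapply(models, function(m) {
    ct <- stats::coef(summary(m))
    data.frame(term = rownames(ct),
               estimate = ct[, "Estimate"], se = ct[, "Std. Error"],
               df = ct[, "df"], t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  f_tables <- lapply(models, function(m) {
    an <- suppressMessages(stats::anova(m))  # lmerTest: Satterthwaite F tests
    data.frame(term = rownames(an), F = an[, "F value"],
               df_num = an[, "NumDF"], df_den = an[, "DenDF"],
               p = an[, "Pr(>F)"], row.names = NULL, stringsAsFactors = FALSE)
  })
  aics <- vapply(models, function(m)
    stats::AIC(suppressMessages(suppressWarnings(lme4::refitML(m)))),
    numeric(1))

  res <- list(models = models,
              coefficients = coef_tables,
              f_tests = f_tables,
              aic = aics,
              selected = names(which.min(aics)),
              n_obs = nrow(d),
              n_sire_mlls = n_sires,
              offset_const = offset_const,
              data = d)
  class(res) <- "floral_siring"
  res
}

#' @export
print.floral_siring <- function(x, ...) {
  cat(sprintf("Siring-success mixed models: n = %d genet-days, %d sire MLLs\n",
              x$n_obs, x$n_sire_mlls))
  for (nm in names(x$models)) {
    ft <- x$f_tests[[nm]]
    cat(sprintf("  %-5s AIC = %7.2f |", nm, x$aic[[nm]]))
    for (i in seq_len(nrow(ft))) {
      cat(sprintf(" %s: F(%d, %.1f) = %.3g, p = %.3g;", ft$term[i],
                  ft$df_num[i], ft$df_den[i], ft$F[i], ft$p[i]))
    }
    cat("\n")
  }
  cat("  selected (lowest AIC):", x$selected, "\n")
  invisible(x)
}
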