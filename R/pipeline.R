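#' Pipeline run configuration
#'
#' Reads (or builds) the configuration driving [run_stage()] /
#' [run_pipeline()]: a working directory for the CSV tables, the
#' simulator block, the paternity block, and analysis flags. Accepts a
#' YAML file or a named list; unspecified entries take their defaults.
#'
#' YAML layout (all blocks optional):
#' \preformatted{
#' dir: path/to/workdir
#' population:            # arguments to population_config()
#'   n_genets: 169
#'   rng_seed: 1
#' paternity:             # arguments to paternity_config()
#'   error_rate: 0.01
#' analysis:
#'   exclude_selfed: true
#'   male_phase_only: true
#'   max_diff: 1
#'   offset_const: null
#' }
#'
#' @param config Path to a YAML file, a named list, or `NULL` for pure
#'   defaults.
#' @param dir Working directory override.
#' @param rng_seed Seed override (takes precedence over the file).
#' @return A list of class `run_config`.
#' @export
run_config <- function(config = NULL, dir = NULL, rng_seed = NULL) {
  raw <- if (is.null(config)) list()
         else if (is.character(config)) yaml::read_yaml(config)
         else as.list(config)
  if (!is.null(dir)) raw$dir <- dir
  if (is.null(raw$dir)) raw$dir <- "."
  pop_args <- if (is.null(raw$population)) list() else raw$population
  if (!is.null(rng_seed)) pop_args$rng_seed <- rng_seed
  if (!is.null(pop_args$kernel_scale) &&
      identical(pop_args$kernel_scale, "Inf"))
    pop_args$kernel_scale <- Inf
  pat_args <- if (is.null(raw$paternity)) list() else raw$paternity
  analysis <- utils::modifyList(
    list(exclude_selfed = TRUE, male_phase_only = TRUE, max_diff = 1L,
         offset_const = NULL),
    if (is.null(raw$analysis)) list() else raw$analysis)
  cfg <- list(dir = raw$dir,
              population = do.call(population_config, pop_args),
              paternity = do.call(paternity_config, pat_args),
              analysis = analysis)
  class(cfg) <- "run_config"
  cfg
}

pipeline_paths <- function(cfg) {
  file.path(cfg$dir, c(
    phenology = "phenology.csv", ramet_genotypes = "ramet_genotypes.csv",
    coordinates = "coordinates.csv", seeds = "seeds.csv", truth = "truth.csv",
    mll_assignments = "mll_assignments.csv", paternity = "paternity.csv",
    pto_daily = "pto_daily.csv", pto_totals = "pto_totals.csv",
    sex_ratios = "sex_ratios.csv", siring = "siring.csv",
    models_summary = "models_summary.json")) |>
    stats::setNames(c("phenology", "ramet_genotypes", "coordinates", "seeds",
                      "truth", "mll_assignments", "paternity", "pto_daily",
                      "pto_totals", "sex_ratios", "siring", "models_summary"))
}

#' Validate pipeline input files
#'
#' Checks the CSV contract of the pipeline inputs: required columns,
#' integer days inside a plausible range, non-negative flower counts,
#' genotype arity (0 or 2 allele calls per locus) and referential
#' integrity (seed mothers must be genotyped ramets; phenology ramets
#' lacking a genotype are flagged, not fatal).
#'
#' @param paths Named character vector or list with any of `phenology`,
#'   `ramet_genotypes`, `seeds`; missing names are skipped.
#' @return A data frame report (`file`, `check`, `status`, `detail`) with
#'   attribute `ok`. `status` is one of `"pass"`, `"flag"`, `"fail"`.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  rep <- list()
  add <- function(file, check, status, detail = "") {
    rep[[length(rep) + 1L]] <<- data.frame(file = file, check = check,
                                           status = status, detail = detail,
                                           stringsAsFactors = FALSE)
  }
  geno <- NULL
  if (!is.null(paths$ramet_genotypes)) {
    geno <- read_table_checked(paths$ramet_genotypes, "ramet_id",
                               "ramet genotype")
    ok <- tryCatch({genotype_matrix(geno); TRUE},
                   error = function(e) {add(paths$ramet_genotypes, "arity",
                                            "fail", conditionMessage(e)); FALSE})
    if (ok) add(paths$ramet_genotypes, "arity", "pass")
    if (anyDuplicated(geno$ramet_id))
      add(paths$ramet_genotypes, "unique ramet_id", "fail",
          "duplicated ramet ids")
    else add(paths$ramet_genotypes, "unique ramet_id", "pass")
  }
  if (!is.null(paths$phenology)) {
    ph <- read_table_checked(paths$phenology,
                             c("day", "ramet_id", "inflorescence_id",
                               "n_open_female", "n_open_male"), "phenology")
    bad_day <- which(ph$day != as.integer(ph$day) | ph$day < 1 | ph$day > 366)
    if (length(bad_day))
      add(paths$phenology, "day range", "fail",
          paste("row(s)", paste(utils::head(bad_day, 5L), collapse = ", "),
                "have non-integer or out-of-range Julian days"))
    else add(paths$phenology, "day range", "pass")
    bad_n <- which(ph$n_open_female < 0 | ph$n_open_male < 0 |
                   ph$n_open_female != as.integer(ph$n_open_female) |
                   ph$n_open_male != as.integer(ph$n_open_male))
    if (length(bad_n))
      add(paths$phenology, "flower counts", "fail",
          paste("row(s)", paste(utils::head(bad_n, 5L), collapse = ", "),
                "have negative or non-integer counts"))
    else add(paths$phenology, "flower counts", "pass")
    if (!is.null(geno)) {
      orphans <- setdiff(unique(ph$ramet_id), geno$ramet_id)
      if (length(orphans))
        add(paths$phenology, "ramets genotyped", "flag",
            paste(length(orphans), "phenology ramet(s) lack genotypes, e.g.",
                  paste(utils::head(orphans, 3L), collapse = ", ")))
      else add(paths$phenology, "ramets genotyped", "pass")
    }
  }
  if (!is.null(paths$seeds)) {
    sd <- read_table_checked(paths$seeds,
                             c("seed_id", "mother_ramet_id", "pollination_day"),
                             "seeds")
    ok <- tryCatch({
      genotype_matrix(sd[, c(1L, seq(4L, ncol(sd))), drop = FALSE]); TRUE
    }, error = function(e) {add(paths$seeds, "arity", "fail",
                                conditionMessage(e)); FALSE})
    if (ok) add(paths$seeds, "arity", "pass")
    if (!is.null(geno)) {
      orphans <- setdiff(unique(sd$mother_ramet_id), geno$ramet_id)
      if (length(orphans))
        add(paths$seeds, "mothers exist", "fail",
            paste("unknown mother(s):",
                  paste(utils::head(orphans, 3L), collapse = ", ")))
      else add(paths$seeds, "mothers exist", "pass")
    }
  }
  report <- do.call(rbind, rep)
  attr(report, "ok") <- !any(report$status == "fail")
  report
}

#' Run one pipeline stage
#'
#' Executes one stage of the analysis pipeline against the CSV tables in
#' the config's working directory, writing its outputs atomically and a
#' provenance JSON (`<stage>_provenance.json`: config hash, seed, input
#' checksums, package and R versions, timestamp) alongside them.
#'
#' Stages and their files:
#' \describe{
#'   \item{simulate}{writes `phenology.csv`, `ramet_genotypes.csv`,
#'     `coordinates.csv`, `seeds.csv`, `truth.csv`}
#'   \item{assign-clones}{`ramet_genotypes.csv` -> `mll_assignments.csv`}
#'   \item{paternity}{`seeds.csv` + genotypes + clones -> `paternity.csv`}
#'   \item{pto}{`phenology.csv` + clones -> `pto_daily.csv`,
#'     `pto_totals.csv`, `sex_ratios.csv`}
#'   \item{siring}{`paternity.csv` -> `siring.csv`}
#'   \item{trends}{`sex_ratios.csv` + `pto_daily.csv` + `siring.csv` ->
#'     `models_summary.json`}
#' }
#'
#' @param stage One of `"simulate"`, `"assign-clones"`, `"paternity"`,
#'   `"pto"`, `"siring"`, `"trends"`.
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, the named vector of output paths written.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "assign-clones", "paternity",
                              "pto", "siring", "trends"))
  if (!inherits(config, "run_config")) config <- run_config(config)
  p <- pipeline_paths(config)
  if (!dir.exists(config$dir)) dir.create(config$dir, recursive = TRUE)
  inputs <- character(0)
  outputs <- switch(
    stage,
    "simulate" = {
      study <- simulate_study(config$population)
      write_study(study, config$dir)
    },
    "assign-clones" = {
      inputs <- p["ramet_genotypes"]
      check_validation(validate_inputs(list(ramet_genotypes = inputs)))
      geno <- utils::read.csv(inputs, stringsAsFactors = FALSE)
      cl <- assign_clones(geno, max_diff = config$analysis$max_diff)
      write_csv_atomic(cl, p["mll_assignments"])
      p["mll_assignments"]
    },
    "paternity" = {
      inputs <- p[c("seeds", "ramet_genotypes", "mll_assignments")]
      check_validation(validate_inputs(list(seeds = p[["seeds"]],
                                            ramet_genotypes = p[["ramet_genotypes"]])))
      geno <- utils::read.csv(p["ramet_genotypes"], stringsAsFactors = FALSE)
      seeds <- utils::read.csv(p["seeds"], stringsAsFactors = FALSE)
      cl <- assign_clones(geno, max_diff = config$analysis$max_diff)
      pat <- assign_paternity(seeds, geno, cl, config = config$paternity)
      write_csv_atomic(pat$assignments, p["paternity"])
      p["paternity"]
    },
    "pto" = {
      inputs <- p[c("phenology", "ramet_genotypes")]
      check_validation(validate_inputs(list(phenology = p[["phenology"]],
                                            ramet_genotypes = p[["ramet_genotypes"]])))
      ph <- utils::read.csv(p["phenology"], stringsAsFactors = FALSE)
      geno <- utils::read.csv(p["ramet_genotypes"], stringsAsFactors = FALSE)
      cl <- assign_clones(geno, max_diff = config$analysis$max_diff)
      ptor <- pto_ramet_day(ph, cl)
      ptod <- pto_genet(ptor, male_phase_only = config$analysis$male_phase_only)
      sr <- sex_ratio_table(derive_inflorescences(ph), cl)
      write_csv_atomic(ptod, p["pto_daily"])
      write_csv_atomic(pto_totals(ptod), p["pto_totals"])
      write_csv_atomic(sr, p["sex_ratios"])
      p[c("pto_daily", "pto_totals", "sex_ratios")]
    },
    "siring" = {
      inputs <- p["paternity"]
      pat <- read_table_checked(p[["paternity"]],
                                c("seed_id", "mll_id", "pi", "selfed",
                                  "pollination_day", "mother_mll"), "paternity")
      rs <- siring_success(pat, exclude_selfed = config$analysis$exclude_selfed)
      write_csv_atomic(rs, p["siring"])
      p["siring"]
    },
    "trends" = {
      inputs <- p[c("sex_ratios", "pto_daily", "siring")]
      sr <- read_table_checked(p[["sex_ratios"]],
                               c("inflorescence_id", "mll_id", "first_day",
                                 "n_male", "n_total"), "sex ratios")
      ptod <- read_table_checked(p[["pto_daily"]],
                                 c("mll_id", "day", "K_day"), "daily PTO")
      rs <- read_table_checked(p[["siring"]], c("mll_id", "day", "RS"),
                               "siring")
      sex_fit <- fit_sexratio_trend(sr)
      pto_fit <- fit_pto_trend(ptod)
      sir_fit <- fit_siring_model(rs, ptod,
                                  offset_const = config$analysis$offset_const)
      jsonlite::write_json(models_summary(sex_fit, pto_fit, sir_fit),
                           p[["models_summary"]], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      p["models_summary"]
    })
  write_provenance(stage, config, inputs, outputs)
  invisible(outputs)
}

check_validation <- function(report) {
  if (!attr(report, "ok")) {
    bad <- report[report$status == "fail", , drop = FALSE]
    stop("input validation failed:\n",
         paste(sprintf("  %s [%s]: %s", bad$file, bad$check, bad$detail),
               collapse = "\n"), call. = FALSE)
  }
  invisible(report)
}

models_summary <- function(sex_fit, pto_fit, sir_fit) {
  trend_block <- function(x) list(
    n = x$n, n_mll = x$n_mll,
    intercept = x$intercept, intercept_se = x$intercept_se,
    edf = x$edf, statistic = x$statistic, statistic_name = x$statistic_name,
    p_value = x$p_value, aic_smooth = x$aic_smooth, aic_linear = x$aic_linear,
    peak_day = x$peak_day, re_sd = as.list(x$re_sd),
    dropped_inner = x$dropped_inner, converged = x$converged)
  list(sex_allocation = trend_block(sex_fit),
       pto = trend_block(pto_fit),
       siring = list(n_obs = sir_fit$n_obs, n_sire_mlls = sir_fit$n_sire_mlls,
                     aic = as.list(sir_fit$aic), selected = sir_fit$selected,
                     coefficients = sir_fit$coefficients,
                     f_tests = sir_fit$f_tests))
}

write_provenance <- function(stage, config, inputs, outputs) {
  cfg_yaml <- yaml::as.yaml(list(population = unclass(config$population),
                                 paternity = unclass(config$paternity),
                                 analysis = config$analysis))
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(cfg_yaml, tmp)
  prov <- list(
    stage = stage,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    rng_seed = config$population$rng_seed,
    config_md5 = unname(tools::md5sum(tmp)),
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(unlist(inputs))), basename(unlist(inputs)))),
    outputs = basename(unlist(outputs)),
    package_version = as.character(utils::packageVersion("floralsync")),
    r_version = as.character(getRversion()))
  jsonlite::write_json(prov,
                       file.path(config$dir,
                                 paste0(gsub("-", "_", stage),
                                        "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}

#' Run the whole pipeline
#'
#' Runs every stage in order: simulate, assign-clones, paternity, pto,
#' siring, trends. With `simulate = FALSE` the first stage is skipped and
#' the pipeline runs on whatever input CSVs are already in the working
#' directory.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @param simulate Run the simulator stage first (default `TRUE`).
#' @return Invisibly, the named vector of all output paths.
#' @export
run_pipeline <- function(config, simulate = TRUE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  stages <- c(if (simulate) "simulate", "assign-clones", "paternity", "pto",
              "siring", "trends")
  out <- lapply(stages, run_stage, config = config)
  invisible(unlist(out))
}
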