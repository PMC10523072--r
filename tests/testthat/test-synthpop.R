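test_that("population generator reproduces the target clonal structure", {
  stats <- t(sapply(1:20, function(seed) {
    pop <- generate_population(population_config(rng_seed = seed))
    c(n = nrow(pop$ramets),
      singletons = mean(pop$genets$n_ramets == 1L),
      max = max(pop$genets$n_ramets))
  }))
  # law designed for ~943 ramets in 169 genets, ~40% singletons, max 35
  expect_gt(mean(stats[, "n"]), 880)
  expect_lt(mean(stats[, "n"]), 1010)
  expect_gt(mean(stats[, "singletons"]), 0.33)
  expect_lt(mean(stats[, "singletons"]), 0.47)
  expect_true(all(stats[, "max"] <= 35))

  # ramets of a genet cluster around its centre
  pop <- generate_population(population_config(rng_seed = 1))
  big <- pop$genets$genet_id[which.max(pop$genets$n_ramets)]
  members <- pop$ramets[pop$ramets$genet_id == big, ]
  centre <- pop$genets[pop$genets$genet_id == big, ]
  d <- sqrt((members$x_m - centre$centre_x)^2 + (members$y_m - centre$centre_y)^2)
  expect_lt(mean(d), 4 * 1.5)  # within a few scatter SDs
})

test_that("degenerate and deterministic population cases behave", {
  cfg1 <- population_config(
    n_genets = 1, rng_seed = 3,
    ramet_count_law = list(singleton_prob = 1, size = 1, mu = 1, max = 1L))
  pop1 <- generate_population(cfg1)
  expect_identical(nrow(pop1$ramets), 1L)

  cfg <- population_config(n_genets = 30, rng_seed = 11)
  expect_identical(generate_population(cfg), generate_population(cfg))

  expect_error(population_config(season = c(240, 199)), "season")
  expect_error(population_config(genotyping_error = 1.5), "probability")
  expect_error(population_config(n_genets = 0), "n_genets")
})

test_that("phenology honours synchronous protogyny and conserves flowers", {
  cfg <- population_config(n_genets = 60, rng_seed = 5)
  pop <- generate_population(cfg)
  ph <- generate_phenology(pop, cfg)
  daily <- ph$phenology

  # functionally unisexual every day
  expect_true(all(!(daily$n_open_female > 0 & daily$n_open_male > 0)))

  # every female-phase day strictly precedes every male-phase day
  by_infl <- split(daily, daily$inflorescence_id)
  ok <- vapply(by_infl, function(d) {
    fdays <- d$day[d$n_open_female > 0]
    mdays <- d$day[d$n_open_male > 0]
    length(fdays) == 0L || length(mdays) == 0L || max(fdays) < min(mdays)
  }, logical(1))
  expect_true(all(ok))

  # conservation: open counts sum to the inflorescence totals
  sums_f <- vapply(by_infl, function(d) sum(d$n_open_female), numeric(1))
  sums_m <- vapply(by_infl, function(d) sum(d$n_open_male), numeric(1))
  m <- match(names(by_infl), ph$inflorescences$inflorescence_id)
  expect_equal(unname(sums_f), ph$inflorescences$n_female[m])
  expect_equal(unname(sums_m), ph$inflorescences$n_male[m])

  # all days inside the season
  expect_true(all(daily$day >= cfg$season[1] & daily$day <= cfg$season[2]))
})

test_that("population-level female peak precedes or coincides with male peak", {
  peaks <- t(sapply(1:20, function(seed) {
    cfg <- population_config(rng_seed = seed)
    ph <- generate_phenology(generate_population(cfg), cfg)
    daily <- ph$phenology
    fm <- tapply(daily$n_open_male, daily$day, sum)
    ff <- tapply(daily$n_open_female, daily$day, sum)
    c(female = as.integer(names(ff)[which.max(ff)]),
      male = as.integer(names(fm)[which.max(fm)]))
  }))
  gap <- peaks[, "female"] - peaks[, "male"]
  # female peak typically precedes the male peak, never trails it by much
  expect_lte(stats::median(gap), 0)
  expect_true(all(gap <= 4L))
  expect_true(all(peaks[, "male"] >= 199 & peaks[, "male"] <= 240))
})

test_that("genotypes follow the sampled allele frequencies and somatic rules", {
  cfg <- population_config(n_genets = 300, rng_seed = 7, somatic_mlg_rate = 0,
                           genotyping_error = 0)
  pop <- generate_population(cfg)
  gt <- generate_genotypes(pop, cfg)
  # genet allele draws match the drawn frequencies (Hardy-Weinberg sampling)
  for (l in seq_len(cfg$n_loci)) {
    cols <- paste0("L", l, c("_a1", "_a2"))
    alleles <- unlist(gt$genet_genotypes[, cols])
    f <- gt$allele_freqs[[l]]
    counts <- table(factor(alleles, levels = names(f)))
    p <- suppressWarnings(stats::chisq.test(counts, p = f)$p.value)
    expect_gt(p, 1e-4)
  }

  # no noise: observed distinct genotypes = genets
  mlgs <- group_mlgs(gt$ramet_genotypes)
  expect_identical(length(unique(mlgs$mlg_id)), cfg$n_genets)

  # somatic variants differ by exactly one allele from the genet genotype
  cfg2 <- population_config(n_genets = 80, rng_seed = 8, somatic_mlg_rate = 0.2,
                            genotyping_error = 0)
  pop2 <- generate_population(cfg2)
  gt2 <- generate_genotypes(pop2, cfg2)
  expect_gte(length(unique(group_mlgs(gt2$ramet_genotypes)$mlg_id)),
             cfg2$n_genets)
  gmat <- genotype_matrix_for_test(gt2$genet_genotypes)
  rmat <- genotype_matrix_for_test(gt2$true_genotypes)
  gidx <- match(pop2$ramets$genet_id, gt2$genet_genotypes$genet_id)
  for (r in match(gt2$somatic_ramets, pop2$ramets$ramet_id)) {
    expect_identical(allelic_distance(rmat[r, ], gmat[gidx[r], ]), 1L)
  }
})

test_that("mating follows flower numbers and the dispersal kernel", {
  # two donors with 3 vs 1 open male flowers, uniform kernel: 0.75 / 0.25
  pop <- structure(list(
    genets = data.frame(genet_id = c("G1", "G2", "G3"),
                        centre_x = c(0, 10, 20), centre_y = 0, n_ramets = 1L),
    ramets = data.frame(ramet_id = c("R1", "R2", "R3"),
                        genet_id = c("G1", "G2", "G3"),
                        x_m = c(0, 10, 20), y_m = 0)), class = "floral_population")
  phen <- data.frame(day = 200L, ramet_id = c("R1", "R2", "R3"),
                     inflorescence_id = c("I1", "I2", "I3"),
                     n_open_female = c(2000L, 0L, 0L),
                     n_open_male = c(0L, 3L, 1L))
  freqs <- list(L1 = c("101" = 0.5, "103" = 0.5))
  geno <- list(true_genotypes = data.frame(ramet_id = c("R1", "R2", "R3"),
                                           L1_a1 = c(101L, 101L, 103L),
                                           L1_a2 = c(101L, 103L, 103L)),
               allele_freqs = freqs)
  cfg <- population_config(n_genets = 3, rng_seed = 42, kernel_scale = Inf,
                           seed_sample_fraction = 1, genotyping_error = 0,
                           n_loci = 1)
  mt <- simulate_mating(phen, geno, pop, cfg)
  expect_identical(nrow(mt$seeds), 2000L)
  share_r2 <- mean(mt$truth$true_sire_ramet == "R2")
  expect_lt(abs(share_r2 - 0.75), 0.03)  # ~99% binomial CI at n = 2000

  # single available donor: monopoly
  phen1 <- phen
  phen1$n_open_male <- c(0L, 5L, 0L)
  mt1 <- simulate_mating(phen1, geno, pop, cfg)
  expect_true(all(mt1$truth$true_sire_ramet == "R2"))

  # steep kernel shortens realized mating distances (paired seeds)
  cfg_near <- population_config(n_genets = 60, rng_seed = 17, kernel_scale = 1)
  cfg_far <- population_config(n_genets = 60, rng_seed = 17, kernel_scale = Inf)
  study_near <- simulate_study(cfg_near)
  study_far <- simulate_study(cfg_far)
  dist_of <- function(study) {
    r <- study$population$ramets
    i <- match(study$truth$mother_ramet_id, r$ramet_id)
    j <- match(study$truth$true_sire_ramet, r$ramet_id)
    mean(sqrt((r$x_m[i] - r$x_m[j])^2 + (r$y_m[i] - r$y_m[j])^2))
  }
  expect_lt(dist_of(study_near), dist_of(study_far))

  # days with female but no male flowers anywhere yield no seeds, logged
  phen0 <- data.frame(day = 201L, ramet_id = "R1", inflorescence_id = "I1",
                      n_open_female = 10L, n_open_male = 0L)
  mt0 <- simulate_mating(phen0, geno, pop, cfg)
  expect_identical(nrow(mt0$seeds), 0L)
  expect_identical(mt0$unpollinated$n_flowers, 10L)
})

test_that("truth table is consistent and pipeline is deterministic", {
  cfg <- test_config(13, n_genets = 50)
  study <- simulate_study(cfg)
  # sires had open male flowers on the pollination day
  ph <- study$phenology
  key <- paste(ph$ramet_id, ph$day)
  male_open <- stats::setNames(ph$n_open_male, key)
  sire_key <- paste(study$truth$true_sire_ramet, study$truth$pollination_day)
  expect_true(all(male_open[sire_key] > 0))
  # selfed flag means sire genet equals mother genet
  expect_identical(study$truth$is_selfed,
                   study$truth$true_sire_genet == study$truth$mother_genet)
  # determinism end to end
  study2 <- simulate_study(cfg)
  expect_identical(study, study2)
})

test_that("selfing rises with mean genet size at fixed kernel and density", {
  # genet count falls as genet size rises, holding total ramets near 300
  mean_selfing <- function(n_genets, singleton, mu) {
    mean(sapply(1:10, function(seed) {
      cfg <- population_config(
        n_genets = n_genets, rng_seed = seed, kernel_scale = 5,
        ramet_count_law = list(singleton_prob = singleton, size = 1,
                               mu = mu, max = 35L))
      mean(simulate_study(cfg)$truth$is_selfed)
    }))
  }
  sweep <- c(small = mean_selfing(250, 0.9, 2),
             mid = mean_selfing(50, 0.3, 6),
             large = mean_selfing(20, 0.05, 15))
  expect_lt(sweep["small"], sweep["mid"])
  expect_lt(sweep["mid"], sweep["large"])
})
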