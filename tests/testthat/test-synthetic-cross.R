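het_father <- list(INF = c("INF", "inf"), FLW = c("F", "f"), m = c("1", "0"))
hom_mother <- list(INF = c("inf", "inf"), FLW = c("F", "f"), m = c("0", "0"))
tight <- c(INF = 0, FLW = 0, m = 0)

test_that("draw_gamete respects restitution modes at the INF locus", {
  set.seed(1)
  # FDR from a heterozygous parent always retains both alleles
  for (i in 1:50) {
    g <- draw_gamete(het_father, unreduced = TRUE, restitution_mode = "FDR",
                     recomb = tight)
    expect_setequal(g$INF, c("INF", "inf"))
    expect_length(g$INF, 2L)
  }
  # homozygous parent yields only recessive alleles in any mode
  for (mode in c("FDR", "SDR", "IMR")) {
    g <- draw_gamete(hom_mother, unreduced = TRUE, restitution_mode = mode,
                     recomb = tight)
    expect_true(all(g$INF == "inf"))
  }
  g <- draw_gamete(hom_mother, unreduced = FALSE, recomb = tight)
  expect_identical(g$INF, "inf")
  expect_length(g$INF, 1L)
})

test_that("SDR gametes are homozygous with each allele at rate 1/2", {
  set.seed(7)
  n <- 10000L
  inf_inf <- 0L
  for (i in seq_len(n)) {
    g <- draw_gamete(het_father, unreduced = TRUE, restitution_mode = "SDR",
                     recomb = tight)
    expect_identical(g$INF[1], g$INF[2])   # always homozygous
    if (all(g$INF == "inf")) inf_inf <- inf_inf + 1L
  }
  # binomial oracle: p = 0.5, 3 SDs
  expect_lt(abs(inf_inf / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("reduced gametes recombine relative to the INF anchor", {
  set.seed(8)
  n <- 4000L
  r <- c(INF = 0, FLW = 0.5, m = 0.1)
  recomb_m <- recomb_f <- 0L
  for (i in seq_len(n)) {
    g <- draw_gamete(het_father, recomb = r)
    parental_m <- (g$INF == "INF" && g$m == "1") || (g$INF == "inf" && g$m == "0")
    parental_f <- (g$INF == "INF" && g$FLW == "F") || (g$INF == "inf" && g$FLW == "f")
    if (!parental_m) recomb_m <- recomb_m + 1L
    if (!parental_f) recomb_f <- recomb_f + 1L
  }
  expect_lt(abs(recomb_m / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  expect_lt(abs(recomb_f / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("unknown restitution mode is a configuration error", {
  expect_error(draw_gamete(het_father, unreduced = TRUE, restitution_mode = "XDR"),
               class = "bulkmark_validation_error")
  expect_error(cross_config(restitution_mode = "XDR"),
               class = "bulkmark_validation_error")
})

test_that("cross_config validates probabilities and recombination fractions", {
  expect_error(cross_config(unreduced_pollen_rate = 1.2), class = "bulkmark_validation_error")
  expect_error(cross_config(marker_inf_recomb = 0.6), class = "bulkmark_validation_error")
  expect_error(cross_config(n_offspring = 0), class = "bulkmark_validation_error")
})

test_that("all-reduced pollen gives a diploid 1:1 pseudo-backcross", {
  cfg <- cross_config(n_offspring = 2000L, unreduced_pollen_rate = 0,
                      nonflowering_penetrance = 0, rng_seed = 11L)
  pl <- simulate_population(cfg)
  expect_true(all(pl$ploidy == 2L))
  n_mop <- sum(pl$phenotype == "mophead")
  expect_lt(abs(n_mop / nrow(pl) - 0.5), 3 * sqrt(0.25 / nrow(pl)))
})

test_that("FDR cannot produce triploid mophead plants; SDR matches enumeration", {
  # FDR 2n gametes keep the dominant allele, so triploid mophead is impossible
  cfg <- cross_config(n_offspring = 10000L, unreduced_pollen_rate = 1,
                      restitution_mode = "FDR", marker_inf_recomb = 0,
                      nonflowering_penetrance = 0, rng_seed = 21L)
  pl <- simulate_population(cfg)
  expect_true(all(pl$ploidy == 3L))                      # every pollen grain was 2n
  expect_true(all(grepl("INF", pl$INF, fixed = TRUE)))   # FDR keeps the dominant allele
  expect_identical(sum(pl$phenotype == "mophead"), 0L)

  # enumeration oracle for P(triploid & mophead): a triploid is mophead iff
  # the maternal allele is inf AND the paternal SDR gamete duplicated inf
  enumerate_trip_mophead <- function(mother_inf, u) {
    p_mat_inf <- mean(mother_inf == "inf")
    p_2n_infinf <- 0.5   # SDR duplicates one of the two paternal alleles
    u * p_mat_inf * p_2n_infinf
  }
  u <- 0.75
  cfg <- cross_config(n_offspring = 10000L, unreduced_pollen_rate = u,
                      restitution_mode = "SDR", nonflowering_penetrance = 0,
                      rng_seed = 22L)
  pl <- simulate_population(cfg)
  p_hat <- mean(pl$ploidy == 3L & pl$phenotype == "mophead")
  p_exp <- enumerate_trip_mophead(c("inf", "inf"), u)   # = u/2 for inf/inf mother
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))

  # with a heterozygous mother the same enumeration gives u/4
  cfg_het <- cross_config(n_offspring = 10000L, unreduced_pollen_rate = u,
                          restitution_mode = "SDR", nonflowering_penetrance = 0,
                          maternal_genotype = list(INF = c("INF", "inf"),
                                                   FLW = c("F", "f")),
                          rng_seed = 23L)
  pl_het <- simulate_population(cfg_het)
  p_hat_het <- mean(pl_het$ploidy == 3L & pl_het$phenotype == "mophead")
  p_exp_het <- enumerate_trip_mophead(c("INF", "inf"), u)  # = u/4
  expect_equal(p_exp_het, u / 4)
  expect_lt(abs(p_hat_het - p_exp_het), 3 * sqrt(p_exp_het * (1 - p_exp_het) / 10000))
})

test_that("triploid fraction follows the unreduced pollen rate", {
  cfg <- cross_config(n_offspring = 10000L, unreduced_pollen_rate = 0.75,
                      rng_seed = 31L)
  pl <- simulate_population(cfg)
  expect_lt(abs(mean(pl$ploidy == 3L) - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  expect_true(all(pl$ploidy_class[pl$ploidy == 3L] == "triploid"))
  expect_true(all(pl$ploidy_class[pl$ploidy == 2L] == "diploid"))
})

test_that("seeded population runs are reproducible and seeds differ", {
  cfg <- cross_config(n_offspring = 200L, rng_seed = 5L)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  cfg2 <- cross_config(n_offspring = 200L, rng_seed = 6L)
  expect_false(identical(simulate_population(cfg), simulate_population(cfg2)))
})

test_that("true pool frequencies match brute-force per-chromosome enumeration", {
  contigs <- simulate_contig_set(n_contigs = 6L, n_linked = 1L,
                                 positions_range = c(2L, 4L),
                                 linked_positions = 3L, rng_seed = 41L)
  cfg <- cross_config(n_offspring = 10L, marker_loci = contig_marker_loci(contigs),
                      rng_seed = 42L)
  pl <- simulate_population(cfg)
  tf <- true_pool_frequencies(pl, contigs)
  # brute force: walk every plant's chromosomes allele by allele
  for (i in seq_len(nrow(tf))) {
    row <- contigs$positions[contigs$positions$contig_id == tf$contig[i] &
                               contigs$positions$pos == tf$pos[i], ]
    locus <- contigs$contigs$locus[contigs$contigs$contig_id == tf$contig[i]]
    alt_copies <- 0L; total <- 0L
    for (p in seq_len(nrow(pl))) {
      alleles <- strsplit(pl[[locus]][p], "/", fixed = TRUE)[[1]]
      for (a in alleles) {
        base <- if (a == "1") {
          if (row$allele1_is_alt) row$alt else row$ref
        } else {
          if (row$allele1_is_alt) row$ref else row$alt
        }
        total <- total + 1L
        if (base == row$alt) alt_copies <- alt_copies + 1L
      }
    }
    expect_equal(tf$true_alt_freq[i], alt_copies / total)
  }
})

test_that("pool pileups conserve counts and honour the noise model", {
  contigs <- simulate_contig_set(n_contigs = 10L, rng_seed = 51L)
  cfg <- cross_config(n_offspring = 60L, marker_loci = contig_marker_loci(contigs),
                      rng_seed = 52L)
  pl <- simulate_population(cfg)
  noise <- gbs_noise_model(coverage_mean = 50, coverage_dispersion = 5,
                           seq_error_rate = 0.01, dropout_rate = 0.1)
  pu <- simulate_pool_pileup(pl, contigs, noise, rng_seed = 53L)
  expect_s3_class(pu, "pool_pileup")
  expect_true(all(pu$count > 0))
  # conservation: per-position counts sum to the coverage reported downstream
  cov <- tapply(pu$count, paste(pu$contig, pu$pos), sum)
  expect_true(all(cov > 0))
  # reproducible under the same seed, different under another
  expect_identical(pu, simulate_pool_pileup(pl, contigs, noise, rng_seed = 53L))
  expect_false(identical(pu, simulate_pool_pileup(pl, contigs, noise, rng_seed = 54L)))
  expect_error(simulate_pool_pileup(pl[0, ], contigs, noise),
               class = "bulkmark_validation_error")
})

test_that("error-free pileups reflect exact pool frequencies", {
  # one contig, one position; mother and father both carry alt ("1"/"1" x "1"/"1")
  contigs <- contig_set(
    data.frame(contig_id = "c1", length = 100L, locus = "mk",
               linked_to_inf = FALSE, segregation = "both",
               stringsAsFactors = FALSE),
    data.frame(contig_id = "c1", pos = 10L, ref = "A", alt = "C",
               allele1_is_alt = TRUE, stringsAsFactors = FALSE))
  plants_hom_ref <- structure(
    data.frame(plant_id = sprintf("p%d", 1:20), ploidy = 2L,
               mk = "0/0", stringsAsFactors = FALSE),
    class = c("plant_records", "data.frame"))
  noise0 <- gbs_noise_model(coverage_mean = 100, coverage_dispersion = 1e9,
                            seq_error_rate = 0, dropout_rate = 0)
  pu <- simulate_pool_pileup(plants_hom_ref, contigs, noise0, rng_seed = 61L)
  expect_true(all(pu$allele == "A"))       # alternate count exactly 0

  # all-heterozygous diploid pool: expected alt count cov/2, binomial spread
  plants_het <- structure(
    data.frame(plant_id = sprintf("p%d", 1:20), ploidy = 2L,
               mk = "0/1", stringsAsFactors = FALSE),
    class = c("plant_records", "data.frame"))
  alt_counts <- vapply(1:200, function(s) {
    pu <- simulate_pool_pileup(plants_het, contigs, noise0, rng_seed = 100L + s)
    sum(pu$count[pu$allele == "C"])
  }, numeric(1))
  covs <- vapply(1:200, function(s) {
    pu <- simulate_pool_pileup(plants_het, contigs, noise0, rng_seed = 100L + s)
    sum(pu$count)
  }, numeric(1))
  expect_lt(abs(mean(alt_counts / covs) - 0.5), 3 * sqrt(0.25 / sum(covs)))

  # mophead-pool premise: plants all homozygous alt -> true alt frequency 1
  plants_mop <- structure(
    data.frame(plant_id = sprintf("p%d", 1:65),
               ploidy = rep(c(2L, 3L), length.out = 65),
               mk = rep(c("1/1", "1/1/1"), length.out = 65),
               stringsAsFactors = FALSE),
    class = c("plant_records", "data.frame"))
  expect_equal(true_pool_frequencies(plants_mop, contigs)$true_alt_freq, 1)
  pu <- simulate_pool_pileup(plants_mop, contigs, noise0, rng_seed = 62L)
  expect_true(all(pu$allele == "C"))
})
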