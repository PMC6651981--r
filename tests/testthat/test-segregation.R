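test_that("chi_square_ratio matches the published 1:1 test and hand values", {
  res <- chi_square_ratio(c(43, 36))
  expect_equal(res$chi2, 0.6202, tolerance = 1e-4 / 0.6202)
  expect_equal(res$df, 1L)
  expect_false(res$significant)
  expect_equal(chi_square_ratio(c(50, 50))$chi2, 0)
  expect_equal(chi_square_ratio(c(30, 10))$chi2, 10)   # (10^2/20) * 2
  expect_true(chi_square_ratio(c(30, 10))$significant)
  # 3:1 ratio support
  expect_equal(chi_square_ratio(c(75, 25), c(3, 1))$chi2, 0)
})

test_that("chi_square_ratio agrees with stats::chisq.test on 2-class inputs", {
  for (n in c(10L, 79L, 144L, 200L)) {
    for (a in 0:n) {
      obs <- c(a, n - a)
      got <- chi_square_ratio(obs)$chi2
      want <- suppressWarnings(
        unname(stats::chisq.test(obs, p = c(0.5, 0.5), correct = FALSE)$statistic))
      expect_equal(got, want)
    }
  }
})

test_that("chi_square_ratio validates its input", {
  expect_error(chi_square_ratio(c(0, 0)), class = "bulkmark_validation_error")
  expect_error(chi_square_ratio(c(-1, 5)), class = "bulkmark_validation_error")
  expect_error(chi_square_ratio(c(10, 10), c(1, 0)), class = "bulkmark_validation_error")
  expect_error(chi_square_ratio(c(10, 10), c(1, 1, 1)), class = "bulkmark_validation_error")
})

test_that("predict_phenotype implements dominant-recessive coupling at any ploidy", {
  expect_identical(predict_phenotype("A1/A1/A1", "A1"), "mophead")
  expect_identical(predict_phenotype("A2/A2", "A1"), "lacecap")
  # heterozygous triploid: either dosage is lacecap
  expect_identical(predict_phenotype("A1/A1/A2", "A1"), "lacecap")
  expect_identical(predict_phenotype("A1/A2/A2", "A1"), "lacecap")
  expect_identical(predict_phenotype(c("A1/A1", "A1/A2"), "A1"),
                   c("mophead", "lacecap"))
  expect_error(predict_phenotype("A1/AX", "A1", alleles = c("A1", "A2")),
               class = "bulkmark_validation_error")
  expect_error(predict_phenotype("", "A1"), class = "bulkmark_validation_error")
})

test_that("co-segregation on the marker-test fixture reproduces 99.7%", {
  pl <- make_marker_test_population()
  expect_equal(cosegregation_percent(pl, "A109A110", "A1"), 99.7)
  # dropping the discordant plant gives 100.0
  concordant <- pl[!(pl$phenotype == "lacecap" & pl$A109A110 == "A1/A1/A1"), ]
  expect_equal(cosegregation_percent(concordant, "A109A110", "A1"), 100.0)
})

test_that("co-segregation excludes intermediates and is order/id invariant", {
  pl <- make_marker_test_population()
  base <- cosegregation_percent(pl, "A109A110", "A1")
  # including the 3 intermediates would change the denominator; they must not
  no_int <- pl[pl$phenotype != "intermediate", ]
  expect_equal(cosegregation_percent(no_int, "A109A110", "A1"), base)
  set.seed(2)
  perm <- pl[sample(nrow(pl)), ]
  perm$plant_id <- sprintf("Z%04d", seq_len(nrow(perm)))
  expect_equal(cosegregation_percent(perm, "A109A110", "A1"), base)
})

test_that("a fully coupled marker co-segregates at exactly 100%", {
  contigs <- simulate_contig_set(n_contigs = 2L, n_linked = 1L, rng_seed = 71L)
  cfg <- cross_config(n_offspring = 500L, marker_inf_recomb = 0,
                      nonflowering_penetrance = 0,
                      marker_loci = contig_marker_loci(contigs), rng_seed = 72L)
  pl <- simulate_population(cfg)
  linked_locus <- contigs$contigs$locus[contigs$contigs$linked_to_inf]
  expect_equal(cosegregation_percent(pl, linked_locus, "0"), 100.0)
})

test_that("an unlinked marker converges to 50% co-segregation", {
  contigs <- simulate_contig_set(n_contigs = 1L, n_linked = 0L, rng_seed = 81L)
  cfg <- cross_config(n_offspring = 10000L, unreduced_pollen_rate = 0,
                      nonflowering_penetrance = 0,
                      marker_loci = contig_marker_loci(contigs), rng_seed = 82L)
  pl <- simulate_population(cfg)
  locus <- contigs$contigs$locus
  got <- cosegregation_percent(pl, locus, "0")
  expect_lt(abs(got - 50), 100 * 3 * sqrt(0.25 / nrow(pl)))
})

test_that("shuffled genotypes of a 1:1 marker give ~50% co-segregation", {
  pl <- make_marker_test_population()
  pl <- pl[pl$phenotype %in% c("lacecap", "mophead"), ]
  # make the marker segregate 1:1 between all-recessive and carrier states
  pl$A109A110 <- rep(c("A1/A1", "A1/A2"), length.out = nrow(pl))
  set.seed(9)
  vals <- vapply(1:200, function(i) {
    pl$A109A110 <- sample(pl$A109A110)
    cosegregation_percent(pl, "A109A110", "A1")
  }, numeric(1))
  expect_lt(abs(mean(vals) - 50), 3 * 100 * sqrt(0.25 / (200 * nrow(pl))))
})

test_that("non-flowering association counts recessive-coupled homozygotes", {
  pl <- make_marker_test_population()
  # fixture: 48 triploid non-flowering homozygous A1, 5 diploid het
  expect_equal(nonflowering_association(pl, "A109A110", "A1"),
               round_half_up(100 * 48 / 53, 1))
  hom <- pl[pl$phenotype == "non_flowering" & pl$A109A110 == "A1/A1/A1", ]
  expect_equal(nonflowering_association(hom, "A109A110", "A1"), 100.0)
  het <- pl[pl$phenotype == "non_flowering" & pl$A109A110 == "A1/A2", ]
  expect_equal(nonflowering_association(het, "A109A110", "A1"), 0.0)
  # 43 of 48 homozygous -> 89.6
  mix <- hom
  mix$A109A110[1:5] <- "A1/A2/A2"
  expect_equal(nonflowering_association(mix, "A109A110", "A1"), 89.6)
  expect_error(nonflowering_association(pl[pl$phenotype == "lacecap", ],
                                        "A109A110", "A1"),
               class = "bulkmark_validation_error")
})

test_that("cultivar association summarizes the packaged collection", {
  cult <- read_cultivar_csv(table3_path())
  expect_equal(nrow(cult), 56L)
  res <- associate_cultivar_variants(cult)
  expect_equal(res$n_distinct, 6L)
  expect_identical(res$variants, paste0("B", 1:6))
  expect_identical(res$recessive_associated, c("B1", "B2"))
  expect_identical(res$conflicts, "B2")
  # exactly 2 lacecap cultivars are homozygous B2
  expect_equal(sum(cult$type == "L" & cult$variant1 == "B2" & cult$variant2 == "B2"),
               2L)
})

test_that("cultivar association edge cases", {
  one <- data.frame(name = "x", type = "M", variant1 = "B1", variant2 = "B1")
  res <- associate_cultivar_variants(one)
  expect_equal(res$n_distinct, 1L)
  expect_identical(res$recessive_associated, "B1")
  expect_length(res$conflicts, 0L)
  allhet <- data.frame(name = c("x", "y"), type = c("M", "L"),
                       variant1 = c("B1", "B2"), variant2 = c("B2", "B3"))
  expect_length(associate_cultivar_variants(allhet)$recessive_associated, 0L)
  expect_error(associate_cultivar_variants(data.frame(name = "x", type = "Q",
                                                      variant1 = "B1",
                                                      variant2 = "B1")),
               class = "bulkmark_validation_error")
})
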