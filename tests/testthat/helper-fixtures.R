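# Shared fixtures and independent oracles, built in code at test time.

# Population consistent with the published marker-test outcome: 73 mophead
# plants homozygous for the recessive-coupled variant A1, 279 lacecap
# plants of which 278 carry the dominant-coupled A2 and one (triploid) is
# discordantly homozygous A1.  Intermediate and non-flowering plants are
# present to exercise their exclusion from co-segregation denominators.
make_marker_test_population <- function() {
  rows <- list()
  add <- function(n, ploidy, phenotype, geno) {
    data.frame(ploidy = rep(ploidy, n), phenotype = phenotype, A109A110 = geno,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    add(36, 2L, "mophead", "A1/A1"),
    add(37, 3L, "mophead", "A1/A1/A1"),
    add(43, 2L, "lacecap", "A1/A2"),
    add(117, 3L, "lacecap", "A1/A2/A2"),
    add(117, 3L, "lacecap", "A1/A1/A2"),
    add(1, 2L, "lacecap", "A2/A2"),
    add(1, 3L, "lacecap", "A1/A1/A1"),   # the discordant triploid lacecap
    add(3, 3L, "intermediate", "A1/A1/A2"),
    add(48, 3L, "non_flowering", "A1/A1/A1"),
    add(5, 2L, "non_flowering", "A1/A2")
  )
  df$plant_id <- sprintf("F%04d", seq_len(nrow(df)))
  df$ploidy_class <- ifelse(df$ploidy == 2L, "diploid", "triploid")
  df <- df[, c("plant_id", "ploidy", "ploidy_class", "phenotype", "A109A110")]
  attr(df, "loci") <- "A109A110"
  class(df) <- c("plant_records", "data.frame")
  df
}

# Long-format pileup from a list of positions:
#   list(list(contig=, pos=, ref=, counts=c(A=10, C=5)), ...)
make_pileup <- function(positions) {
  rows <- lapply(positions, function(p) {
    data.frame(contig = p$contig, pos = p$pos,
               ref = p$ref %||% names(p$counts)[1],
               allele = names(p$counts), count = unname(p$counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pool_pileup", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force variant-caller: enumerates every
# (position, allele) pair and applies the three gates one by one, with no
# shared code with call_variants().
oracle_call_variants <- function(pileup, min_coverage, max_coverage_factor,
                                 min_count, min_freq) {
  df <- as.data.frame(pileup)
  key <- paste(df$contig, df$pos)
  cov <- tapply(df$count, key, sum)
  mean_cov <- mean(cov[cov > 0])
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    position_cov <- sum(sub$count)
    if (position_cov < min_coverage) next
    if (position_cov > max_coverage_factor * mean_cov) next
    passing <- character(0)
    for (i in seq_len(nrow(sub))) {
      ok_count <- sub$count[i] >= min_count
      ok_freq <- sub$count[i] / position_cov >= min_freq
      if (ok_count && ok_freq) passing <- c(passing, sub$allele[i])
    }
    if (length(passing) >= 2L) {
      keep <- sub[sub$allele %in% passing, , drop = FALSE]
      keep$coverage <- position_cov
      keep$freq <- keep$count / position_cov
      out[[k]] <- keep
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$pos, res$allele), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random pileup generator for oracle-equivalence and monotonicity tests.
random_pileup <- function(n_positions, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(n_positions), function(i) {
    k <- sample(1:4, 1)
    al <- sample(bases, k)
    data.frame(contig = sprintf("c%02d", sample(1:8, 1)),
               pos = i, ref = al[1], allele = al,
               count = stats::rnbinom(k, mu = 25, size = 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pool_pileup", "data.frame")
  out
}

# The deep-coverage synthetic world used by the end-to-end recovery
# property: 1 INF-coupled contig among unlinked contigs, error rate 0.3%,
# every position at the stated 40x coverage floor (dispersion ~0), no
# dropout, pools of 99 diploid and 65 mophead plants.
build_recovery_world <- function(seed, n_contigs = 51L, n_offspring = 422L) {
  contigs <- simulate_contig_set(n_contigs = n_contigs, n_linked = 1L,
                                 rng_seed = seed * 10L + 1L)
  cfg <- cross_config(n_offspring = n_offspring,
                      marker_loci = contig_marker_loci(contigs),
                      rng_seed = seed * 10L + 2L)
  plants <- simulate_population(cfg)
  pools <- suppressWarnings(define_pools(plants, rng_seed = seed * 10L + 3L))
  noise <- gbs_noise_model(coverage_mean = 40, coverage_dispersion = 1e9,
                           seq_error_rate = 0.003, dropout_rate = 0)
  dip <- simulate_pool_pileup(plants[plants$plant_id %in% pools$diploid$plant_ids, ],
                              contigs, noise, rng_seed = seed * 10L + 4L)
  mop <- simulate_pool_pileup(plants[plants$plant_id %in% pools$mophead$plant_ids, ],
                              contigs, noise, rng_seed = seed * 10L + 5L)
  list(contigs = contigs, plants = plants, pools = pools,
       diploid_pileup = dip, mophead_pileup = mop,
       linked_contig = contigs$contigs$contig_id[contigs$contigs$linked_to_inf])
}

table3_path <- function() {
  system.file("extdata", "cultivar_collection_a109a110.csv", package = "bulkmark")
}
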