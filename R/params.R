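#' Variant filter parameters
#'
#' Gate set used by [call_variants()], mirroring a "basic variant
#' detection" filter on pooled pileups: a per-position coverage window and
#' per-allele minimum count and minimum frequency.  A position is evaluated
#' only if its coverage lies between `min_coverage` and
#' `max_coverage_factor` times the pool's mean coverage (excluding
#' zero-coverage positions); an allele is reported only if its read count
#' is at least `min_count` and its frequency (count / position coverage) is
#' at least `min_freq`.
#'
#' Defaults are the diploid-pool settings (minimum coverage 15); the trait
#' (mophead) pool conventionally uses `min_coverage = 8`.  `reported_ploidy`
#' is carried as metadata only: it labels the nominal ploidy of the pooled
#' sample in outputs and has no effect on which positions pass.
#'
#' @param min_coverage minimum position coverage (reads).
#' @param max_coverage_factor positions with coverage above
#'   `max_coverage_factor * mean_coverage_excluding_zero(pileup)` are
#'   ignored (collapsed repeats).
#' @param min_count minimum per-allele read count.
#' @param min_freq minimum per-allele frequency, in (0, 1].
#' @param reported_ploidy nominal pool ploidy recorded as metadata.
#' @return an object of class `variant_filter_params`.
#' @seealso [call_variants()], [selection_params()]
#' @export
variant_filter_params <- function(min_coverage = 15L,
                                  max_coverage_factor = 4,
                                  min_count = 3L,
                                  min_freq = 0.18,
                                  reported_ploidy = 4L) {
  min_coverage <- check_count(min_coverage, "min_coverage", min = 1L)
  min_count <- check_count(min_count, "min_count", min = 1L)
  if (!is.numeric(min_freq) || length(min_freq) != 1L || is.na(min_freq) ||
      min_freq <= 0 || min_freq > 1) {
    bm_validation_error("`min_freq` must be in (0, 1]")
  }
  if (!is.numeric(max_coverage_factor) || length(max_coverage_factor) != 1L ||
      is.na(max_coverage_factor) || max_coverage_factor <= 1) {
    bm_validation_error("`max_coverage_factor` must be > 1")
  }
  reported_ploidy <- check_count(reported_ploidy, "reported_ploidy", min = 1L)
  structure(
    list(min_coverage = min_coverage,
         max_coverage_factor = max_coverage_factor,
         min_count = min_count,
         min_freq = min_freq,
         reported_ploidy = reported_ploidy),
    class = "variant_filter_params"
  )
}

#' @export
print.variant_filter_params <- function(x, ...) {
  cat("<variant_filter_params>\n")
  cat(sprintf("  coverage window : [%d, %.3g x mean coverage]\n",
              x$min_coverage, x$max_coverage_factor))
  cat(sprintf("  allele gates    : count >= %d, frequency >= %.2f\n",
              x$min_count, x$min_freq))
  cat(sprintf("  reported ploidy : %d (metadata only)\n", x$reported_ploidy))
  invisible(x)
}

#' Candidate selection parameters
#'
#' Thresholds for the single-bulk candidate contig selection: a position is
#' informative if its alternate-allele frequency in the diploid reference
#' pool lies inside the closed heterozygosity band `[het_low, het_high]`,
#' and a contig is a candidate if it carries at least
#' `min_positions_per_contig` such positions whose mean major-allele
#' frequency in the trait pool exceeds `fixed_min` (near-fixation).
#'
#' @param het_low,het_high closed heterozygosity band for the diploid-pool
#'   alternate allele frequency (defaults 0.25 and 0.75, the expected pool
#'   frequencies when exactly one parent is heterozygous).
#' @param fixed_min strict lower bound for the trait-pool mean major-allele
#'   frequency (default 0.95).
#' @param min_positions_per_contig minimum number of evaluable informative
#'   positions per candidate contig (default 2).
#' @return an object of class `selection_params`.
#' @seealso [select_candidate_contigs()], [run_bulk_analysis()]
#' @export
selection_params <- function(het_low = 0.25, het_high = 0.75,
                             fixed_min = 0.95,
                             min_positions_per_contig = 2L) {
  for (nm in c("het_low", "het_high", "fixed_min")) {
    check_prob(get(nm), nm)
  }
  if (!(0 < het_low && het_low < het_high && het_high < fixed_min && fixed_min <= 1)) {
    bm_validation_error("need 0 < het_low < het_high < fixed_min <= 1")
  }
  min_positions_per_contig <- check_count(min_positions_per_contig,
                                          "min_positions_per_contig", min = 1L)
  structure(
    list(het_low = het_low, het_high = het_high, fixed_min = fixed_min,
         min_positions_per_contig = min_positions_per_contig),
    class = "selection_params"
  )
}

#' @export
print.selection_params <- function(x, ...) {
  cat("<selection_params>\n")
  cat(sprintf("  diploid-pool het band : [%.2f, %.2f]\n", x$het_low, x$het_high))
  cat(sprintf("  trait-pool fixation   : > %.2f\n", x$fixed_min))
  cat(sprintf("  min positions/contig  : %d\n", x$min_positions_per_contig))
  invisible(x)
}

#' Ploidy classification thresholds
#'
#' 2C DNA content windows (pg) used by [classify_ploidy()].  The defaults
#' classify 2C in \[4.1, 4.5\] pg as diploid, \[6.4, 6.7\] pg as triploid and
#' >= 7.05 pg as higher ploidy (aneuploid/tetraploid, "more than 54
#' chromosomes"); everything else is unclassified.  Intervals are closed;
#' `higher_min` defaults to 7.05 so that a 2C of 7.1 pg falls in the
#' higher-ploidy class.
#'
#' @param diploid_low,diploid_high diploid window in pg.
#' @param triploid_low,triploid_high triploid window in pg.
#' @param higher_min minimum 2C (pg) for the higher-ploidy class.
#' @return an object of class `ploidy_thresholds`.
#' @export
ploidy_thresholds <- function(diploid_low = 4.1, diploid_high = 4.5,
                              triploid_low = 6.4, triploid_high = 6.7,
                              higher_min = 7.05) {
  v <- c(diploid_low, diploid_high, triploid_low, triploid_high, higher_min)
  if (any(!is.finite(v)) || any(v <= 0) || any(diff(v) <= 0)) {
    bm_validation_error(
      "need 0 < diploid_low < diploid_high < triploid_low < triploid_high < higher_min")
  }
  structure(
    list(diploid_low = diploid_low, diploid_high = diploid_high,
         triploid_low = triploid_low, triploid_high = triploid_high,
         higher_min = higher_min),
    class = "ploidy_thresholds"
  )
}

#' @export
print.ploidy_thresholds <- function(x, ...) {
  cat("<ploidy_thresholds> (2C pg)\n")
  cat(sprintf("  diploid  : [%.2f, %.2f]\n", x$diploid_low, x$diploid_high))
  cat(sprintf("  triploid : [%.2f, %.2f]\n", x$triploid_low, x$triploid_high))
  cat(sprintf("  higher   : >= %.2f\n", x$higher_min))
  invisible(x)
}
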