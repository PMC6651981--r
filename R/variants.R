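#' Mean coverage excluding zero-coverage positions
#'
#' Arithmetic mean of per-position coverage (sum of allele counts) over
#' the positions of a pileup with coverage > 0.  This is the reference
#' value for the upper coverage gate of [call_variants()].
#'
#' @param pileup a `pool_pileup` data frame (long format: `contig`,
#'   `pos`, `allele`, `count`).
#' @return mean coverage over positions with coverage > 0; `0` with a
#'   warning if every position has zero coverage.
#' @export
mean_coverage_excluding_zero <- function(pileup) {
  cov <- .position_coverage(pileup)
  if (nrow(cov) == 0L) bm_abort("empty pileup", class = "bulkmark_validation_error")
  nz <- cov$coverage[cov$coverage > 0]
  if (length(nz) == 0L) {
    warning("all positions have zero coverage; mean coverage is 0", call. = FALSE)
    return(0)
  }
  mean(nz)
}

# Per-position coverage table from a long-format pileup.
.position_coverage <- function(pileup) {
  if (!is.data.frame(pileup) ||
      !all(c("contig", "pos", "allele", "count") %in% names(pileup))) {
    bm_validation_error("pileup needs columns contig, pos, allele, count")
  }
  if (nrow(pileup) == 0L) {
    return(data.frame(contig = character(), pos = integer(), coverage = numeric()))
  }
  dt <- data.table::as.data.table(pileup)
  as.data.frame(dt[, list(coverage = sum(count)), by = c("contig", "pos")])
}

#' Call polymorphic positions from a pooled pileup
#'
#' Applies the basic variant detection gates to a per-position allele
#' count pileup.  A position is evaluated only if
#' `min_coverage <= coverage <= max_coverage_factor * mean_coverage`,
#' where the mean excludes zero-coverage positions; an allele is reported
#' only if its count is at least `min_count` and its frequency
#' (count / position coverage, the denominator including sub-threshold
#' alleles) is at least `min_freq`; and a call is emitted only for
#' positions with at least two reported alleles (polymorphic).
#'
#' @param pileup a `pool_pileup` data frame (columns `contig`, `pos`,
#'   `allele`, `count`, optionally `ref`).
#' @param params a [variant_filter_params()] object.
#' @param mean_coverage optional precomputed
#'   [mean_coverage_excluding_zero()] value; supply it when re-filtering
#'   a subset so the coverage window stays anchored to the original pool.
#' @return a data frame of class `variant_calls` (one row per reported
#'   allele): `contig`, `pos`, `ref` (if present in the pileup),
#'   `allele`, `count`, `coverage`, `freq`; attribute `mean_coverage`
#'   records the window anchor.
#' @export
call_variants <- function(pileup, params = variant_filter_params(),
                          mean_coverage = NULL) {
  if (!inherits(params, "variant_filter_params")) {
    bm_validation_error("`params` must be a variant_filter_params object")
  }
  has_ref <- "ref" %in% names(pileup)
  empty <- data.frame(contig = character(), pos = integer(),
                      allele = character(), count = integer(),
                      coverage = integer(), freq = numeric(),
                      stringsAsFactors = FALSE)
  if (has_ref) empty$ref <- character(0)
  if (!is.data.frame(pileup) || nrow(pileup) == 0L) {
    class(empty) <- c("variant_calls", "data.frame")
    attr(empty, "mean_coverage") <- mean_coverage %||% NA_real_
    return(empty)
  }
  dt <- data.table::as.data.table(pileup)
  if (inherits(pileup, "variant_calls") && "coverage" %in% names(pileup)) {
    # re-filtering existing calls: keep the recorded position coverage so
    # frequencies are not distorted by alleles already filtered out
    if (is.null(mean_coverage)) {
      mean_coverage <- attr(pileup, "mean_coverage") %||%
        mean(unique(dt[, c("contig", "pos", "coverage"), with = FALSE])$coverage)
    }
  } else {
    if (is.null(mean_coverage)) mean_coverage <- mean_coverage_excluding_zero(pileup)
    dt[, coverage := sum(count), by = c("contig", "pos")]
  }
  max_cov <- params$max_coverage_factor * mean_coverage
  dt <- dt[coverage >= params$min_coverage & coverage <= max_cov]
  if (nrow(dt)) {
    dt[, freq := count / coverage]
    dt <- dt[count >= params$min_count & freq >= params$min_freq]
  }
  if (nrow(dt)) {
    dt[, n_alleles := .N, by = c("contig", "pos")]
    dt <- dt[n_alleles >= 2L]
    dt[, n_alleles := NULL]
  }
  cols <- c("contig", "pos", if (has_ref) "ref", "allele", "count", "coverage", "freq")
  out <- if (nrow(dt)) {
    as.data.frame(dt[, cols, with = FALSE])
  } else {
    empty$coverage <- integer(0); empty$freq <- numeric(0)
    empty[, cols, drop = FALSE]
  }
  out <- out[order(out$contig, out$pos, -out$count, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  attr(out, "mean_coverage") <- mean_coverage
  out
}

#' Convert variant calls back to a pileup
#'
#' Re-expresses a `variant_calls` table as a `pool_pileup` containing only
#' the reported alleles.  Mainly useful for idempotence checks: calling
#' [call_variants()] on the result (anchored to the original mean
#' coverage) re-emits the same calls.
#'
#' @param calls a `variant_calls` data frame.
#' @return a `pool_pileup` data frame.
#' @export
as_pool_pileup <- function(calls) {
  if (!is.data.frame(calls) ||
      !all(c("contig", "pos", "allele", "count") %in% names(calls))) {
    bm_validation_error("`calls` needs columns contig, pos, allele, count")
  }
  cols <- c("contig", "pos", if ("ref" %in% names(calls)) "ref", "allele", "count")
  out <- as.data.frame(calls)[, cols, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pool_pileup", "data.frame")
  out
}
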