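#' Select heterozygous positions from diploid-pool variant calls
#'
#' Retains the polymorphic positions whose alternate-allele frequency in
#' the diploid reference pool lies inside the closed heterozygosity band
#' `[het_low, het_high]`.  When the calls carry a `ref` column the
#' alternate allele is the highest-frequency non-reference allele;
#' otherwise the minor of the two most frequent alleles is used (the band
#' is symmetric about 0.5, so band membership is unaffected).
#'
#' @param diploid_calls a `variant_calls` data frame from the diploid
#'   pool (see [call_variants()]).
#' @param params a [selection_params()] object.
#' @return data frame of class `candidate_positions`: `contig`, `pos`,
#'   `ref` (if available), `dip_allele` (the tracked alternate allele)
#'   and `dip_af` (its frequency).
#' @export
select_heterozygous_positions <- function(diploid_calls, params = selection_params()) {
  if (!inherits(params, "selection_params")) {
    bm_validation_error("`params` must be a selection_params object")
  }
  if (!is.data.frame(diploid_calls) ||
      !all(c("contig", "pos", "allele", "freq") %in% names(diploid_calls))) {
    bm_validation_error("`diploid_calls` needs columns contig, pos, allele, freq")
  }
  has_ref <- "ref" %in% names(diploid_calls)
  empty <- data.frame(contig = character(), pos = integer(),
                      dip_allele = character(), dip_af = numeric(),
                      stringsAsFactors = FALSE)
  if (has_ref) empty$ref <- character(0)
  if (nrow(diploid_calls) == 0L) {
    class(empty) <- c("candidate_positions", "data.frame")
    return(empty)
  }
  dt <- data.table::as.data.table(diploid_calls)
  res <- dt[, {
    if (has_ref && any(allele != ref[1])) {
      nr_i <- which(allele != ref[1])
      j <- nr_i[order(-freq[nr_i], allele[nr_i])[1]]
      list(ref = ref[1], dip_allele = allele[j], dip_af = freq[j])
    } else {
      # no reference column: track the minor of the top two alleles
      o <- order(-freq, allele)
      j <- o[min(2L, .N)]
      list(ref = if (has_ref) ref[1] else NA_character_,
           dip_allele = allele[j], dip_af = freq[j])
    }
  }, by = c("contig", "pos")]
  out <- as.data.frame(res)
  if (!has_ref) out$ref <- NULL
  out <- out[out$dip_af >= params$het_low & out$dip_af <= params$het_high, , drop = FALSE]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_positions", "data.frame")
  out
}

#' Record the trait-pool allele frequency at candidate positions
#'
#' Annotates each diploid-pool heterozygous position with the
#' major-allele frequency at the same coordinate in the trait (mophead)
#' pool pileup.  Positions whose trait-pool coverage is below
#' `params$min_coverage` (including positions absent from the trait
#' pileup) are marked unevaluable; they are kept in the table but
#' excluded from contig means by [select_candidate_contigs()].
#'
#' @param positions a `candidate_positions` data frame from
#'   [select_heterozygous_positions()].
#' @param trait_pileup a `pool_pileup` for the trait pool (raw counts,
#'   not variant calls: fixation must be measurable even where the trait
#'   pool is monomorphic and would yield no polymorphic call).
#' @param params a [variant_filter_params()] for the trait pool (its
#'   `min_coverage`, conventionally 8, is the evaluability gate).
#' @return the input with columns `trait_coverage`, `trait_major_allele`,
#'   `trait_major_freq`, `evaluable` appended.
#' @export
lookup_trait_pool_frequency <- function(positions, trait_pileup,
                                        params = variant_filter_params(min_coverage = 8L)) {
  if (!inherits(params, "variant_filter_params")) {
    bm_validation_error("`params` must be a variant_filter_params object")
  }
  if (!is.data.frame(positions) ||
      !all(c("contig", "pos", "dip_af") %in% names(positions))) {
    bm_validation_error("`positions` must come from select_heterozygous_positions()")
  }
  out <- as.data.frame(positions)
  if (nrow(out) == 0L) {
    out$trait_coverage <- integer(0); out$trait_major_allele <- character(0)
    out$trait_major_freq <- numeric(0); out$evaluable <- logical(0)
    class(out) <- c("candidate_positions", "data.frame")
    return(out)
  }
  if (!is.data.frame(trait_pileup) ||
      !all(c("contig", "pos", "allele", "count") %in% names(trait_pileup))) {
    bm_validation_error("`trait_pileup` needs columns contig, pos, allele, count")
  }
  dt <- data.table::as.data.table(trait_pileup)
  summ <- if (nrow(dt)) {
    as.data.frame(dt[, list(
      trait_coverage = sum(count),
      trait_major_allele = allele[order(-count, allele)[1]],
      trait_major_count = max(count)
    ), by = c("contig", "pos")])
  } else {
    data.frame(contig = character(), pos = integer(), trait_coverage = integer(),
               trait_major_allele = character(), trait_major_count = integer())
  }
  i <- match(paste(out$contig, out$pos), paste(summ$contig, summ$pos))
  out$trait_coverage <- ifelse(is.na(i), 0L, summ$trait_coverage[i])
  out$trait_major_allele <- ifelse(is.na(i), NA_character_, summ$trait_major_allele[i])
  out$trait_major_freq <- ifelse(is.na(i), NA_real_,
                                 summ$trait_major_count[i] / summ$trait_coverage[i])
  out$evaluable <- out$trait_coverage >= params$min_coverage
  absent <- setdiff(unique(out$contig), unique(summ$contig))
  if (length(absent)) {
    message(sprintf("%d contig(s) absent from the trait pileup; their positions are unevaluable",
                    length(absent)))
  }
  class(out) <- c("candidate_positions", "data.frame")
  out
}

#' Select candidate contigs linked to the recessive locus
#'
#' Groups annotated candidate positions by contig and selects the contigs
#' satisfying the single-bulk signature: at least
#' `min_positions_per_contig` evaluable positions, mean diploid-pool
#' alternate-allele frequency inside the closed band
#' `[het_low, het_high]`, and mean trait-pool major-allele frequency
#' strictly above `fixed_min` (near-fixation).  Means are computed over
#' exactly the evaluable positions listed for each contig.
#'
#' Output order is deterministic and independent of input row order:
#' descending mean trait frequency, ties broken by descending position
#' count, then lexicographic contig id.  Contigs where the fixed
#' trait-pool allele is not among the tracked diploid-pool alleles are
#' flagged (`phase_consistent = FALSE`) but not removed; allele phase is
#' resolved downstream by the marker co-segregation analysis.
#'
#' @param annotated a `candidate_positions` data frame from
#'   [lookup_trait_pool_frequency()].
#' @param params a [selection_params()] object.
#' @return data frame of class `candidate_contigs`: `contig`,
#'   `n_positions`, `mean_af_diploid`, `mean_af_trait`,
#'   `phase_consistent`; attribute `positions` holds the per-position
#'   table of the selected contigs.
#' @export
select_candidate_contigs <- function(annotated, params = selection_params()) {
  if (!inherits(params, "selection_params")) {
    bm_validation_error("`params` must be a selection_params object")
  }
  need <- c("contig", "pos", "dip_af", "trait_major_freq", "evaluable")
  if (!is.data.frame(annotated) || !all(need %in% names(annotated))) {
    bm_validation_error("`annotated` must come from lookup_trait_pool_frequency()")
  }
  ev <- annotated[annotated$evaluable %in% TRUE, , drop = FALSE]
  empty <- data.frame(contig = character(), n_positions = integer(),
                      mean_af_diploid = numeric(), mean_af_trait = numeric(),
                      phase_consistent = logical(), stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) {
    class(empty) <- c("candidate_contigs", "data.frame")
    attr(empty, "positions") <- ev
    return(empty)
  }
  dt <- data.table::as.data.table(ev)
  agg <- as.data.frame(dt[, list(
    n_positions = .N,
    mean_af_diploid = mean(dip_af),
    mean_af_trait = mean(trait_major_freq),
    phase_consistent = all(trait_major_allele %in% c(dip_allele,
                                                     if ("ref" %in% names(ev)) ref))
  ), by = "contig"])
  sel <- agg[agg$n_positions >= params$min_positions_per_contig &
               agg$mean_af_diploid >= params$het_low &
               agg$mean_af_diploid <= params$het_high &
               agg$mean_af_trait > params$fixed_min, , drop = FALSE]
  sel <- sel[order(-sel$mean_af_trait, -sel$n_positions, sel$contig), , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("candidate_contigs", "data.frame")
  attr(sel, "positions") <- ev[ev$contig %in% sel$contig, , drop = FALSE]
  sel
}

#' Run the full single-bulk candidate analysis
#'
#' Deterministic composition of the pipeline stages on two pooled
#' pileups: variant calling on the diploid reference pool, selection of
#' heterozygous-band positions, lookup of the trait-pool major-allele
#' frequency at those positions, and candidate contig selection.
#'
#' @param diploid_pileup,trait_pileup `pool_pileup` data frames sharing
#'   one contig coordinate space.
#' @param diploid_filter,trait_filter [variant_filter_params()] for each
#'   pool (defaults: minimum coverage 15 and 8).
#' @param selection a [selection_params()] object.
#' @return an object of class `bulk_analysis`: a list with `candidates`
#'   (see [select_candidate_contigs()]), `positions` (annotated
#'   candidate positions) and `stage_counts` (named per-stage summary:
#'   positions and mean coverage per pool, polymorphic calls,
#'   heterozygous-band positions, evaluable positions, candidate
#'   contigs).
#' @export
run_bulk_analysis <- function(diploid_pileup, trait_pileup,
                              diploid_filter = variant_filter_params(min_coverage = 15L),
                              trait_filter = variant_filter_params(min_coverage = 8L),
                              selection = selection_params()) {
  dip_cov <- .position_coverage(diploid_pileup)
  trait_cov <- .position_coverage(trait_pileup)
  calls <- call_variants(diploid_pileup, diploid_filter)
  het <- select_heterozygous_positions(calls, selection)
  ann <- lookup_trait_pool_frequency(het, trait_pileup, trait_filter)
  cand <- select_candidate_contigs(ann, selection)
  stage_counts <- list(
    n_positions_diploid = nrow(dip_cov),
    n_positions_trait = nrow(trait_cov),
    mean_coverage_diploid = if (nrow(dip_cov)) mean_coverage_excluding_zero(diploid_pileup) else NA_real_,
    mean_coverage_trait = if (nrow(trait_cov)) mean_coverage_excluding_zero(trait_pileup) else NA_real_,
    n_polymorphic_calls = length(unique(paste(calls$contig, calls$pos))),
    n_heterozygous_positions = nrow(het),
    n_evaluable_positions = sum(ann$evaluable),
    n_candidate_contigs = nrow(cand)
  )
  structure(list(candidates = cand, positions = ann, stage_counts = stage_counts),
            class = "bulk_analysis")
}

#' @export
print.bulk_analysis <- function(x, ...) {
  s <- x$stage_counts
  cat("<bulk_analysis>\n")
  cat(sprintf("  diploid pool : %d positions, mean coverage %.1f\n",
              s$n_positions_diploid, s$mean_coverage_diploid))
  cat(sprintf("  trait pool   : %d positions, mean coverage %.1f\n",
              s$n_positions_trait, s$mean_coverage_trait))
  cat(sprintf("  polymorphic positions (diploid)  : %d\n", s$n_polymorphic_calls))
  cat(sprintf("  heterozygous-band positions      : %d\n", s$n_heterozygous_positions))
  cat(sprintf("  evaluable in trait pool          : %d\n", s$n_evaluable_positions))
  cat(sprintf("  candidate contigs                : %d\n", s$n_candidate_contigs))
  if (nrow(x$candidates)) {
    cat("\n")
    print(as.data.frame(x$candidates))
  }
  invisible(x)
}
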