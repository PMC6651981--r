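#' Pearson chi-square test for a segregation ratio
#'
#' Tests observed class counts against an expected ratio (e.g. 1:1 or
#' 3:1) with the Pearson chi-square statistic, no continuity correction,
#' `df = classes - 1`.
#'
#' @param observed vector of non-negative class counts (total > 0).
#' @param expected_ratio positive weights of the expected ratio; default
#'   1:1:...:1.
#' @param alpha significance level (default 0.05).
#' @return list with `chi2`, `df`, `p_value` and `significant` (logical,
#'   `chi2` above the central chi-square `1 - alpha` quantile).
#' @examples
#' chi_square_ratio(c(43, 36))        # chi2 = 0.6202..., not significant
#' chi_square_ratio(c(30, 10), c(1, 1))
#' @export
chi_square_ratio <- function(observed, expected_ratio = rep(1, length(observed)),
                             alpha = 0.05) {
  if (!is.numeric(observed) || length(observed) < 2L || any(is.na(observed)) ||
      any(observed < 0)) {
    bm_validation_error("`observed` must be >= 2 non-negative counts")
  }
  if (sum(observed) <= 0) bm_validation_error("total observed count must be > 0")
  if (length(expected_ratio) != length(observed) || any(expected_ratio <= 0)) {
    bm_validation_error("`expected_ratio` must match `observed` in length with positive weights")
  }
  check_prob(alpha, "alpha")
  expected <- sum(observed) * expected_ratio / sum(expected_ratio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2,
       df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE),
       significant = chi2 > qchisq(1 - alpha, df))
}

# Split "/"-joined genotype strings into allele vectors; NA -> NULL.
.parse_genotypes <- function(g) {
  out <- strsplit(as.character(g), "/", fixed = TRUE)
  out[is.na(g) | g == ""] <- list(NULL)
  out
}

#' Predict phenotype from a marker genotype under the coupling model
#'
#' Under dominant-recessive action with the marker in coupling phase, a
#' plant is predicted mophead iff every allele of its marker genotype
#' equals the recessive-coupled allele, and lacecap otherwise.  This is
#' valid for any ploidy; in particular the dosage ambiguity of
#' heterozygous triploids (1/1/2 vs 1/2/2) is irrelevant, since only the
#' presence of a dominant-coupled allele matters.
#'
#' @param genotype a genotype: character vector of alleles, a single
#'   `/`-joined string, or a list of either (vectorized).
#' @param recessive_coupled_allele allele symbol in coupling with the
#'   recessive (mophead) allele.
#' @param alleles optional declared allele alphabet; genotypes containing
#'   symbols outside it raise an error.
#' @return character vector of `"mophead"` / `"lacecap"`.
#' @examples
#' predict_phenotype("A1/A1/A1", "A1")   # mophead
#' predict_phenotype("A1/A2", "A1")      # lacecap
#' @export
predict_phenotype <- function(genotype, recessive_coupled_allele, alleles = NULL) {
  gl <- if (is.list(genotype)) {
    lapply(genotype, function(g) if (length(g) == 1L && grepl("/", g)) {
      strsplit(g, "/", fixed = TRUE)[[1]]
    } else g)
  } else {
    .parse_genotypes(genotype)
  }
  if (any(vapply(gl, length, integer(1)) == 0L)) {
    bm_validation_error("empty genotype")
  }
  if (!is.null(alleles)) {
    bad <- setdiff(unique(unlist(gl)), alleles)
    if (length(bad)) {
      bm_abort(sprintf("unknown allele symbol(s): %s", paste(bad, collapse = ", ")),
               class = "bulkmark_validation_error")
    }
  }
  vapply(gl, function(a) {
    if (all(a == recessive_coupled_allele)) "mophead" else "lacecap"
  }, character(1))
}

#' Genotype-phenotype co-segregation percentage
#'
#' Fraction (as a percent, one decimal, rounded half-up) of phenotyped,
#' genotyped plants whose marker genotype predicts their recorded
#' inflorescence phenotype under the coupling model
#' ([predict_phenotype()]).  Only plants with phenotype `lacecap` or
#' `mophead` and a non-missing genotype at the marker enter numerator and
#' denominator; intermediate, non-flowering and unknown phenotypes are
#' excluded.
#'
#' @param plants a `plant_records` data frame (columns `phenotype` and
#'   one genotype column per marker).
#' @param marker_id name of the genotype column to test.
#' @param recessive_coupled_allele allele in coupling with the mophead
#'   allele.
#' @return percentage in \[0, 100\], rounded half-up to one decimal.
#' @export
cosegregation_percent <- function(plants, marker_id, recessive_coupled_allele) {
  if (!is.data.frame(plants) || !"phenotype" %in% names(plants)) {
    bm_validation_error("`plants` must have a phenotype column")
  }
  if (!marker_id %in% names(plants)) {
    bm_validation_error(sprintf("no genotype column '%s'", marker_id))
  }
  ph <- as.character(plants$phenotype)
  g <- plants[[marker_id]]
  keep <- ph %in% c("lacecap", "mophead") & !is.na(g) & g != ""
  if (!any(keep)) {
    bm_abort("no flowering plants with genotypes at this marker",
             class = "bulkmark_validation_error")
  }
  pred <- predict_phenotype(g[keep], recessive_coupled_allele)
  round_half_up(100 * mean(pred == ph[keep]), 1)
}

#' Association of a marker with the non-flowering trait
#'
#' Percentage of non-flowering plants (with a genotype at the marker)
#' whose genotype is homozygous for the recessive-coupled allele,
#' rounded half-up to one decimal.  High values indicate coupling of the
#' non-flowering allele with the recessive (mophead) haplotype.
#'
#' @inheritParams cosegregation_percent
#' @return percentage in \[0, 100\], one decimal.
#' @export
nonflowering_association <- function(plants, marker_id, recessive_coupled_allele) {
  if (!is.data.frame(plants) || !"phenotype" %in% names(plants)) {
    bm_validation_error("`plants` must have a phenotype column")
  }
  if (!marker_id %in% names(plants)) {
    bm_validation_error(sprintf("no genotype column '%s'", marker_id))
  }
  g <- plants[[marker_id]]
  keep <- as.character(plants$phenotype) == "non_flowering" & !is.na(g) & g != ""
  if (!any(keep)) {
    bm_abort("no non-flowering plants with genotypes at this marker",
             class = "bulkmark_validation_error")
  }
  hom <- predict_phenotype(g[keep], recessive_coupled_allele) == "mophead"
  round_half_up(100 * mean(hom), 1)
}

#' Associate marker sequence variants with the recessive phenotype in a
#' cultivar collection
#'
#' Summarizes the variant alleles observed at one marker locus across a
#' cultivar collection: the distinct variant labels, the variants
#' occurring in homozygous state in at least one mophead (`M`) cultivar
#' (recessive-associated, i.e. candidate mophead-coupled variants), and
#' among those the conflicted variants that are also homozygous in at
#' least one lacecap (`L`) cultivar (partial linkage).
#'
#' @param cultivars data frame with columns `name`, `type` (`"M"` or
#'   `"L"`), `variant1`, `variant2` (unordered genotype pair of variant
#'   labels); a `c2_pg` column, if present, is ignored here.
#' @return list with `n_distinct`, `variants` (sorted labels),
#'   `recessive_associated`, `conflicts`, and `genotype_counts` (a data
#'   frame of genotype-by-phenotype counts).
#' @examples
#' path <- system.file("extdata", "cultivar_collection_a109a110.csv",
#'                     package = "bulkmark")
#' associate_cultivar_variants(read_cultivar_csv(path))
#' @export
associate_cultivar_variants <- function(cultivars) {
  need <- c("name", "type", "variant1", "variant2")
  if (!is.data.frame(cultivars) || !all(need %in% names(cultivars))) {
    bm_validation_error(paste("`cultivars` must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(cultivars) == 0L) bm_validation_error("empty cultivar table")
  if (!all(cultivars$type %in% c("M", "L"))) {
    bm_validation_error("`type` must be 'M' (mophead) or 'L' (lacecap)")
  }
  labels <- sort(unique(c(cultivars$variant1, cultivars$variant2)))
  hom <- cultivars$variant1 == cultivars$variant2
  hom_m <- sort(unique(cultivars$variant1[hom & cultivars$type == "M"]))
  hom_l <- sort(unique(cultivars$variant1[hom & cultivars$type == "L"]))
  geno <- apply(cbind(cultivars$variant1, cultivars$variant2), 1L,
                function(v) paste(sort(v), collapse = "/"))
  counts <- as.data.frame(table(genotype = geno, type = cultivars$type),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  rownames(counts) <- NULL
  list(n_distinct = length(labels),
       variants = labels,
       recessive_associated = hom_m,
       conflicts = intersect(hom_m, hom_l),
       genotype_counts = counts)
}
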