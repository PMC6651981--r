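PHENOTYPES <- c("lacecap", "mophead", "intermediate", "non_flowering", "unknown")
RESTITUTION_MODES <- c("SDR", "FDR", "IMR")

#' GbS noise model for pooled pileup simulation
#'
#' Parameterizes per-position read coverage and sequencing error for
#' [simulate_pool_pileup()].  Coverage is drawn from a negative binomial
#' (mean `coverage_mean`, size `coverage_dispersion`; variance
#' `mu + mu^2/size`, so small sizes give variance far above the mean) with
#' an extra atom at zero (`dropout_rate`) for positions lost entirely to
#' library/restriction-site sampling.
#'
#' The defaults emulate heavily overdispersed reduced-representation
#' coverage with mean coverage over covered positions around 99x.  A
#' negative binomial cannot reproduce the extreme upper tail of real
#' pooled GbS coverage (driven by collapsed repeats, where SDs several
#' times the mean are observed); the defaults match the location of the
#' covered-position coverage distribution, not its full tail.
#'
#' @param coverage_mean expected reads per position (negative-binomial
#'   mean, before dropout; > 0).  With the default dispersion this yields
#'   a mean of roughly 99x over positions with nonzero coverage.
#' @param coverage_dispersion negative-binomial size parameter (> 0);
#'   smaller means more overdispersed.
#' @param seq_error_rate per-base substitution probability in \[0, 0.1\];
#'   an erroneous read reports one of the three other bases uniformly.
#' @param dropout_rate extra probability in \[0, 1) that a position gets
#'   zero coverage in a pool.
#' @return an object of class `gbs_noise_model`.
#' @export
gbs_noise_model <- function(coverage_mean = 45,
                            coverage_dispersion = 0.1,
                            seq_error_rate = 0.003,
                            dropout_rate = 0.2) {
  check_positive(coverage_mean, "coverage_mean")
  check_positive(coverage_dispersion, "coverage_dispersion")
  if (!is.numeric(seq_error_rate) || length(seq_error_rate) != 1L ||
      is.na(seq_error_rate) || seq_error_rate < 0 || seq_error_rate > 0.1) {
    bm_validation_error("`seq_error_rate` must be in [0, 0.1]")
  }
  check_prob(dropout_rate, "dropout_rate")
  if (dropout_rate >= 1) bm_validation_error("`dropout_rate` must be < 1")
  structure(
    list(coverage_mean = coverage_mean,
         coverage_dispersion = coverage_dispersion,
         seq_error_rate = seq_error_rate,
         dropout_rate = dropout_rate),
    class = "gbs_noise_model"
  )
}

#' Contig set for pileup simulation
#'
#' A set of assembly contigs carrying polymorphic positions, standing in
#' for the reference the pooled reads are mapped against.  Each contig is
#' tied to one simulated marker locus (all positions on a contig are in
#' complete linkage); `linked_to_inf` flags the contigs whose marker locus
#' is in coupling phase with the recessive inflorescence (INF) locus.
#'
#' At every position the biallelic truth maps the abstract marker alleles
#' to bases: allele `"1"` (the allele on the heterozygous parent's
#' dominant-coupled haplotype) shows the `alt` base when `allele1_is_alt`
#' is `TRUE`, otherwise the `ref` base.
#'
#' @param contigs data frame with columns `contig_id`, `length`, `locus`,
#'   `linked_to_inf` (logical), `segregation` (one of `"father"`,
#'   `"mother"`, `"both"`: which parent is heterozygous at the contig's
#'   marker locus).
#' @param positions data frame with columns `contig_id`, `pos` (1-based),
#'   `ref`, `alt` (distinct bases) and `allele1_is_alt` (logical).
#' @return an object of class `contig_set`.
#' @seealso [simulate_contig_set()], [simulate_pool_pileup()]
#' @export
contig_set <- function(contigs, positions) {
  need_c <- c("contig_id", "length", "locus", "linked_to_inf", "segregation")
  need_p <- c("contig_id", "pos", "ref", "alt", "allele1_is_alt")
  if (!is.data.frame(contigs) || !all(need_c %in% names(contigs))) {
    bm_validation_error(paste("`contigs` must have columns:", paste(need_c, collapse = ", ")))
  }
  if (!is.data.frame(positions) || !all(need_p %in% names(positions))) {
    bm_validation_error(paste("`positions` must have columns:", paste(need_p, collapse = ", ")))
  }
  if (anyDuplicated(contigs$contig_id)) bm_validation_error("duplicate contig_id")
  if (!all(positions$contig_id %in% contigs$contig_id)) {
    bm_validation_error("positions refer to unknown contigs")
  }
  if (anyDuplicated(positions[, c("contig_id", "pos")])) {
    bm_validation_error("duplicate (contig_id, pos)")
  }
  len <- contigs$length[match(positions$contig_id, contigs$contig_id)]
  if (any(positions$pos < 1) || any(positions$pos > len) ||
      any(positions$pos != floor(positions$pos))) {
    bm_validation_error("positions must be 1-based integers within contig length")
  }
  if (any(positions$ref == positions$alt)) {
    bm_validation_error("ref and alt bases must differ")
  }
  if (!all(contigs$segregation %in% c("father", "mother", "both"))) {
    bm_validation_error("segregation must be one of father/mother/both")
  }
  structure(list(contigs = contigs, positions = positions), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contigs (%d linked to INF), %d polymorphic positions\n",
              nrow(x$contigs), sum(x$contigs$linked_to_inf), nrow(x$positions)))
  invisible(x)
}

#' Simulate a contig set
#'
#' Generates random contigs with polymorphic positions for
#' [simulate_pool_pileup()].  Linked contigs carry `linked_positions`
#' marker-signature positions (father heterozygous in coupling with the
#' INF locus, mother homozygous); unlinked contigs draw their number of
#' positions uniformly from `positions_range` and their segregation type
#' from `segregation_probs`.
#'
#' Contig lengths are drawn log-uniformly from `length_range` (defaults
#' span the short, fragmented contigs typical of a draft assembly of a
#' large, repetitive genome).
#'
#' @param n_contigs total number of contigs.
#' @param n_linked how many contigs are in coupling phase with the INF
#'   locus (must be <= `n_contigs`).
#' @param positions_range integer range of polymorphic positions per
#'   unlinked contig.
#' @param linked_positions positions per linked contig.  The default (12)
#'   models a multi-kilobase contig in a highly heterozygous outcrosser
#'   carrying about a dozen fully linked marker-signature SNPs.
#' @param length_range contig length range in bp.
#' @param segregation_probs named probabilities for which parent is
#'   heterozygous at an unlinked contig's marker locus.
#' @param rng_seed optional integer seed (RNG state is restored on exit).
#' @return a [contig_set()].
#' @export
simulate_contig_set <- function(n_contigs = 50L, n_linked = 1L,
                                positions_range = c(2L, 10L),
                                linked_positions = 12L,
                                length_range = c(213L, 17716L),
                                segregation_probs = c(father = 0.5, mother = 0.25, both = 0.25),
                                rng_seed = NULL) {
  n_contigs <- check_count(n_contigs, "n_contigs", min = 1L)
  n_linked <- check_count(n_linked, "n_linked", min = 0L)
  if (n_linked > n_contigs) bm_validation_error("n_linked must be <= n_contigs")
  linked_positions <- check_count(linked_positions, "linked_positions", min = 1L)
  with_seed(rng_seed, {
    id <- sprintf("ctg%04d", seq_len(n_contigs))
    linked <- seq_len(n_contigs) <= n_linked
    len <- pmax(round(exp(runif(n_contigs, log(length_range[1]), log(length_range[2])))),
                linked_positions + 1L)
    seg <- ifelse(linked, "father",
                  sample(names(segregation_probs), n_contigs, replace = TRUE,
                         prob = segregation_probs))
    contigs <- data.frame(contig_id = id, length = len,
                          locus = paste0("m_", id),
                          linked_to_inf = linked,
                          segregation = seg,
                          stringsAsFactors = FALSE)
    bases <- c("A", "C", "G", "T")
    pos_list <- lapply(seq_len(n_contigs), function(i) {
      k <- if (linked[i]) linked_positions else
        sample(seq(positions_range[1], positions_range[2]), 1L)
      pp <- sort(sample.int(len[i], k))
      refalt <- t(vapply(seq_len(k), function(j) sample(bases, 2L), character(2)))
      data.frame(contig_id = id[i], pos = pp,
                 ref = refalt[, 1], alt = refalt[, 2],
                 allele1_is_alt = runif(k) < 0.5,
                 stringsAsFactors = FALSE)
    })
    contig_set(contigs, do.call(rbind, pos_list))
  })
}

#' Marker locus table of a contig set
#'
#' Extracts the marker loci implied by a contig set, in the form consumed
#' by [cross_config()]'s `marker_loci` argument.
#'
#' @param contigs a [contig_set()].
#' @return data frame with columns `locus`, `linked`, `segregation`.
#' @export
contig_marker_loci <- function(contigs) {
  if (!inherits(contigs, "contig_set")) bm_validation_error("`contigs` must be a contig_set")
  data.frame(locus = contigs$contigs$locus,
             linked = contigs$contigs$linked_to_inf,
             segregation = contigs$contigs$segregation,
             stringsAsFactors = FALSE)
}

#' Configuration of a synthetic pseudo-backcross
#'
#' Full parameterization of the simulated cross: a homozygous-recessive
#' mophead mother (`inf/inf`) crossed with a heterozygous lacecap father
#' (`INF/inf`) whose pollen is unreduced (2n) with probability
#' `unreduced_pollen_rate`, producing triploid offspring by sexual
#' polyploidization.  Female gametes are always reduced.  A flowering
#' locus (`F`/`f`; `f/f` plants fail to flower with probability
#' `nonflowering_penetrance`) is linked to the INF locus at recombination
#' fraction `flowering_locus_recomb`, with the non-flowering allele `f` in
#' coupling with `inf` in the father.  Additional biallelic marker loci
#' (alleles `"1"`/`"0"`; `"1"` on the heterozygous parent's
#' dominant-coupled haplotype for linked loci) are taken from
#' `marker_loci`, usually via [contig_marker_loci()].
#'
#' Defaults reproduce the observed study design: 422 offspring, about 75%
#' triploid, SDR-mode 2n pollen, markers in tight coupling (r = 0.003,
#' matching 99.7% co-segregation) and a flowering locus at r = 0.10.
#'
#' @param n_offspring number of F1 plants to simulate (>= 1).
#' @param unreduced_pollen_rate probability a fertilizing pollen grain is
#'   unreduced (2n).
#' @param restitution_mode cytological origin of 2n gametes: `"FDR"`
#'   (first division restitution, heterozygosity retained at every
#'   locus), `"SDR"` (second division restitution, homozygous at every
#'   locus) or `"IMR"` (intermediate, heterozygous per locus with
#'   probability `imr_het_prob`).
#' @param imr_het_prob per-locus heterozygosity retention probability for
#'   IMR gametes.
#' @param marker_inf_recomb recombination fraction between each
#'   INF-linked marker locus and the INF locus, in \[0, 0.5\].
#' @param flowering_locus_recomb recombination fraction between the
#'   flowering locus and the INF locus.
#' @param nonflowering_penetrance probability an `f/f` (or `f/f/f`) plant
#'   fails to flower; non-flowering overrides the recorded inflorescence
#'   phenotype.
#' @param marker_loci data frame (`locus`, `linked`, `segregation`) of
#'   marker loci, e.g. from [contig_marker_loci()]; may be `NULL` for a
#'   cross with only the INF and flowering loci.
#' @param maternal_genotype,paternal_genotype optional named lists of
#'   2-allele character vectors overriding the default parental
#'   haplotypes (element order is haplotype order; the father's
#'   haplotype 1 carries `INF`).
#' @param rng_seed optional integer seed used by [simulate_population()].
#' @return an object of class `cross_config`.
#' @export
cross_config <- function(n_offspring = 422L,
                         unreduced_pollen_rate = 0.75,
                         restitution_mode = c("SDR", "FDR", "IMR"),
                         imr_het_prob = 0.5,
                         marker_inf_recomb = 0.003,
                         flowering_locus_recomb = 0.10,
                         nonflowering_penetrance = 0.8,
                         marker_loci = NULL,
                         maternal_genotype = NULL,
                         paternal_genotype = NULL,
                         rng_seed = NULL) {
  n_offspring <- check_count(n_offspring, "n_offspring", min = 1L)
  check_prob(unreduced_pollen_rate, "unreduced_pollen_rate")
  restitution_mode <- restitution_mode[1]
  if (!restitution_mode %in% RESTITUTION_MODES) {
    bm_validation_error(sprintf("unknown restitution mode '%s' (use SDR, FDR or IMR)",
                                restitution_mode))
  }
  check_prob(imr_het_prob, "imr_het_prob")
  check_recomb(marker_inf_recomb, "marker_inf_recomb")
  check_recomb(flowering_locus_recomb, "flowering_locus_recomb")
  check_prob(nonflowering_penetrance, "nonflowering_penetrance")

  if (is.null(marker_loci)) {
    marker_loci <- data.frame(locus = character(), linked = logical(),
                              segregation = character(), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(marker_loci) ||
      !all(c("locus", "linked", "segregation") %in% names(marker_loci))) {
    bm_validation_error("`marker_loci` needs columns locus, linked, segregation")
  }
  if (any(marker_loci$locus %in% c("INF", "FLW"))) {
    bm_validation_error("marker locus names INF and FLW are reserved")
  }

  loci <- c("INF", "FLW", marker_loci$locus)
  # recombination fraction of every locus with the INF anchor
  recomb <- c(INF = 0, FLW = flowering_locus_recomb,
              stats::setNames(ifelse(marker_loci$linked, marker_inf_recomb, 0.5),
                              marker_loci$locus))

  if (is.null(maternal_genotype)) {
    maternal_genotype <- c(
      list(INF = c("inf", "inf"), FLW = c("F", "f")),
      stats::setNames(lapply(marker_loci$segregation, function(s) {
        if (s %in% c("mother", "both")) c("1", "0") else c("0", "0")
      }), marker_loci$locus)
    )
  }
  if (is.null(paternal_genotype)) {
    # haplotype 1 carries INF (and, for linked markers, allele "1")
    paternal_genotype <- c(
      list(INF = c("INF", "inf"), FLW = c("F", "f")),
      stats::setNames(lapply(marker_loci$segregation, function(s) {
        if (s %in% c("father", "both")) c("1", "0") else c("0", "0")
      }), marker_loci$locus)
    )
  }
  for (g in list(maternal_genotype, paternal_genotype)) {
    if (!all(loci %in% names(g)) ||
        !all(vapply(g, function(a) is.character(a) && length(a) == 2L, logical(1)))) {
      bm_validation_error("parental genotypes must be named lists of 2-allele character vectors covering all loci")
    }
  }
  structure(
    list(n_offspring = n_offspring,
         unreduced_pollen_rate = unreduced_pollen_rate,
         restitution_mode = restitution_mode,
         imr_het_prob = imr_het_prob,
         marker_inf_recomb = marker_inf_recomb,
         flowering_locus_recomb = flowering_locus_recomb,
         nonflowering_penetrance = nonflowering_penetrance,
         marker_loci = marker_loci,
         loci = loci,
         recomb = recomb,
         maternal_genotype = maternal_genotype[loci],
         paternal_genotype = paternal_genotype[loci],
         rng_seed = rng_seed),
    class = "cross_config"
  )
}

#' @export
print.cross_config <- function(x, ...) {
  cat("<cross_config>\n")
  cat(sprintf("  offspring            : %d\n", x$n_offspring))
  cat(sprintf("  unreduced pollen rate: %.3g (%s)\n",
              x$unreduced_pollen_rate, x$restitution_mode))
  cat(sprintf("  marker loci          : %d (%d linked to INF, r = %.3g)\n",
              nrow(x$marker_loci), sum(x$marker_loci$linked), x$marker_inf_recomb))
  cat(sprintf("  flowering locus      : r = %.3g, penetrance %.2f\n",
              x$flowering_locus_recomb, x$nonflowering_penetrance))
  invisible(x)
}

#' Draw a single gamete from a diploid parent
#'
#' Draws one gamete at all loci of a diploid parental genotype.  A reduced
#' gamete carries one allele per locus: the haplotype transmitted at the
#' INF anchor locus is chosen uniformly and every other locus follows it
#' except with its recombination probability.  Unreduced (2n) gametes
#' carry two alleles per locus according to the restitution mode: FDR
#' retains both parental alleles at every locus, SDR carries two copies of
#' one allele per locus (haplotype chosen with the same recombination
#' structure), and IMR retains heterozygosity at each locus independently
#' with probability `imr_het_prob`.
#'
#' @param parent_genotype named list of 2-allele character vectors, one
#'   per locus (element order = haplotype order).
#' @param unreduced logical: draw a 2n gamete?
#' @param restitution_mode `"FDR"`, `"SDR"` or `"IMR"` (used only when
#'   `unreduced`).
#' @param imr_het_prob per-locus heterozygosity retention for IMR.
#' @param recomb named numeric vector of recombination fractions between
#'   each locus and the anchor locus; loci absent from `recomb` segregate
#'   independently (0.5).
#' @param anchor name of the anchor locus (default `"INF"` if present,
#'   else the first locus).
#' @return named list of character vectors (length 1 per locus if
#'   reduced, 2 if unreduced).
#' @examples
#' g <- list(INF = c("INF", "inf"), m = c("1", "0"))
#' draw_gamete(g, unreduced = TRUE, restitution_mode = "FDR",
#'             recomb = c(INF = 0, m = 0))
#' @export
draw_gamete <- function(parent_genotype, unreduced = FALSE,
                        restitution_mode = "SDR", imr_het_prob = 0.5,
                        recomb = NULL, anchor = NULL) {
  if (!is.list(parent_genotype) || is.null(names(parent_genotype)) ||
      !all(vapply(parent_genotype, function(a) is.character(a) && length(a) == 2L,
                  logical(1)))) {
    bm_validation_error("`parent_genotype` must be a named list of 2-allele character vectors")
  }
  if (isTRUE(unreduced) && !restitution_mode %in% RESTITUTION_MODES) {
    bm_abort(sprintf("unknown restitution mode '%s'", restitution_mode),
             class = "bulkmark_validation_error")
  }
  loci <- names(parent_genotype)
  anchor <- anchor %||% if ("INF" %in% loci) "INF" else loci[1]
  r <- stats::setNames(rep(0.5, length(loci)), loci)
  if (!is.null(recomb)) r[intersect(loci, names(recomb))] <- recomb[intersect(loci, names(recomb))]
  z <- sample.int(2L, 1L)
  idx <- ifelse(runif(length(loci)) < r, 3L - z, z)
  idx[loci == anchor] <- z
  names(idx) <- loci
  if (!isTRUE(unreduced)) {
    return(stats::setNames(lapply(loci, function(l) parent_genotype[[l]][idx[l]]), loci))
  }
  out <- switch(restitution_mode,
    FDR = lapply(loci, function(l) parent_genotype[[l]]),
    SDR = lapply(loci, function(l) rep(parent_genotype[[l]][idx[l]], 2L)),
    IMR = {
      het <- runif(length(loci)) < imr_het_prob
      names(het) <- loci
      lapply(loci, function(l) {
        if (het[l]) parent_genotype[[l]] else rep(parent_genotype[[l]][idx[l]], 2L)
      })
    }
  )
  stats::setNames(out, loci)
}

# Vectorized haplotype-index draw for n offspring at loci with
# recombination fractions r (relative to the anchor, which has r = 0).
.hap_index_matrix <- function(n, r) {
  L <- length(r)
  z <- sample.int(2L, n, replace = TRUE)
  flip <- matrix(runif(n * L), n, L) < rep(r, each = n)
  idx <- matrix(z, n, L)
  idx[flip] <- 3L - idx[flip]
  colnames(idx) <- names(r)
  idx
}

#' Simulate a mixed-ploidy F1 population
#'
#' Generates `config$n_offspring` F1 plants.  Each offspring unites one
#' reduced maternal gamete with a paternal gamete that is unreduced with
#' probability `unreduced_pollen_rate` (giving a triploid plant) and
#' reduced otherwise (diploid).  The inflorescence phenotype is mophead
#' iff every INF-locus allele is recessive (`inf`), lacecap otherwise;
#' plants homozygous for the non-flowering allele `f` at the flowering
#' locus are recorded as `non_flowering` with the configured penetrance,
#' overriding the inflorescence record.  A 2C DNA content consistent with
#' the plant's ploidy is drawn and classified with [classify_ploidy()].
#'
#' @param config a [cross_config()].
#' @return a data frame of class `plant_records` with columns `plant_id`,
#'   `ploidy` (2 or 3), `ploidy_class`, `c2_pg`, `phenotype`, and one
#'   column per locus holding the `/`-joined allele multiset (attribute
#'   `"loci"` lists the genotype columns).
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "cross_config")) {
    bm_validation_error("`config` must be a cross_config object")
  }
  with_seed(config$rng_seed, {
    n <- config$n_offspring
    loci <- config$loci
    r <- config$recomb[loci]
    mg <- config$maternal_genotype
    pg <- config$paternal_genotype

    midx <- .hap_index_matrix(n, r)
    unred <- runif(n) < config$unreduced_pollen_rate
    pidx <- .hap_index_matrix(n, r)
    imr_het <- if (config$restitution_mode == "IMR") {
      matrix(runif(n * length(loci)), n) < config$imr_het_prob
    } else NULL

    geno <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))
    inf_recessive <- rep(TRUE, n)   # all alleles 'inf' so far
    flw_recessive <- rep(TRUE, n)   # all alleles 'f' so far
    for (j in seq_along(loci)) {
      l <- loci[j]
      mat <- mg[[l]][midx[, j]]
      p1 <- pg[[l]][pidx[, j]]
      p2 <- rep(NA_character_, n)
      if (any(unred)) {
        mode <- config$restitution_mode
        if (mode == "FDR") {
          p1[unred] <- pg[[l]][1]
          p2[unred] <- pg[[l]][2]
        } else if (mode == "SDR") {
          p2[unred] <- p1[unred]
        } else { # IMR
          het <- imr_het[, j] & unred
          hom <- !imr_het[, j] & unred
          p1[het] <- pg[[l]][1]
          p2[het] <- pg[[l]][2]
          p2[hom] <- p1[hom]
        }
      }
      al <- cbind(mat, p1, p2)
      geno[, j] <- apply(al, 1L, function(a) {
        paste(sort(a[!is.na(a)], method = "radix"), collapse = "/")
      })
      if (l == "INF") {
        inf_recessive <- mat == "inf" & p1 == "inf" & (is.na(p2) | p2 == "inf")
      }
      if (l == "FLW") {
        flw_recessive <- mat == "f" & p1 == "f" & (is.na(p2) | p2 == "f")
      }
    }

    phenotype <- ifelse(inf_recessive, "mophead", "lacecap")
    nonfl <- flw_recessive & runif(n) < config$nonflowering_penetrance
    phenotype[nonfl] <- "non_flowering"

    ploidy <- ifelse(unred, 3L, 2L)
    c2 <- ifelse(unred,
                 pmin(pmax(rnorm(n, 6.6, 0.07), 6.4), 6.7),
                 pmin(pmax(rnorm(n, 4.35, 0.09), 4.1), 4.5))

    out <- data.frame(plant_id = sprintf("P%04d", seq_len(n)),
                      ploidy = ploidy,
                      ploidy_class = as.character(classify_ploidy(c2)),
                      c2_pg = round(c2, 2),
                      phenotype = factor(phenotype, levels = PHENOTYPES),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(geno, stringsAsFactors = FALSE))
    attr(out, "loci") <- loci
    class(out) <- c("plant_records", "data.frame")
    out
  })
}

#' Define the sequencing pools
#'
#' Builds the two pool memberships of the single-bulk design: a reference
#' pool of diploid plants regardless of phenotype and a trait pool of
#' mophead plants regardless of ploidy.  Pools may overlap (diploid
#' mophead plants belong to both).  If fewer plants are available than
#' requested, all available plants are used with a warning.
#'
#' @param plants a `plant_records` data frame.
#' @param n_diploid diploid-pool size (default 99).
#' @param n_mophead trait-pool size (default 65).
#' @param rng_seed optional seed for the membership sample.
#' @return list of two `pool_definition` objects (`diploid`, `mophead`),
#'   each a list with `pool_id`, `plant_ids` and `rule`.
#' @export
define_pools <- function(plants, n_diploid = 99L, n_mophead = 65L, rng_seed = NULL) {
  if (!inherits(plants, "plant_records")) {
    bm_validation_error("`plants` must be a plant_records data frame")
  }
  with_seed(rng_seed, {
    dip <- plants$plant_id[plants$ploidy == 2L]
    mop <- plants$plant_id[plants$phenotype == "mophead"]
    pick <- function(ids, k, what) {
      if (length(ids) == 0L) bm_validation_error(paste("no plants available for the", what, "pool"))
      if (length(ids) < k) {
        warning(sprintf("only %d plants available for the %s pool (requested %d)",
                        length(ids), what, k), call. = FALSE)
        ids
      } else sample(ids, k)
    }
    list(
      diploid = structure(list(
        pool_id = "diploid", plant_ids = sort(pick(dip, n_diploid, "diploid")),
        rule = "all diploid plants regardless of phenotype"), class = "pool_definition"),
      mophead = structure(list(
        pool_id = "mophead", plant_ids = sort(pick(mop, n_mophead, "mophead")),
        rule = "all mophead plants regardless of ploidy"), class = "pool_definition")
    )
  })
}

# Dosage of marker allele "1" for each plant at a locus, from the
# "/"-joined genotype string.
.allele1_dosage <- function(geno_strings) {
  vapply(strsplit(geno_strings, "/", fixed = TRUE),
         function(a) sum(a == "1"), numeric(1))
}

#' True pool allele frequencies at contig positions
#'
#' Computes, for every polymorphic position of a contig set, the exact
#' alternate-allele frequency in a pool of plants:
#' (summed alternate-allele dosage over plants) / (summed ploidy over
#' plants).  This is the noise-free quantity that
#' [simulate_pool_pileup()] perturbs with coverage sampling and
#' sequencing error.
#'
#' @param plants `plant_records` for the pool members (subset rows before
#'   calling to restrict to a pool).
#' @param contigs a [contig_set()].
#' @return data frame `contig`, `pos`, `ref`, `alt`, `true_alt_freq`.
#' @export
true_pool_frequencies <- function(plants, contigs) {
  if (!inherits(contigs, "contig_set")) bm_validation_error("`contigs` must be a contig_set")
  if (!is.data.frame(plants) || nrow(plants) == 0L) {
    bm_abort("empty plant list", class = "bulkmark_validation_error")
  }
  total_ploidy <- sum(plants$ploidy)
  pos <- contigs$positions
  ctg <- contigs$contigs
  loci <- ctg$locus[match(pos$contig_id, ctg$contig_id)]
  missing_loci <- setdiff(unique(loci), names(plants))
  if (length(missing_loci)) {
    bm_validation_error(paste("plants lack genotypes for loci:",
                              paste(missing_loci, collapse = ", ")))
  }
  dos1 <- vapply(unique(loci), function(l) sum(.allele1_dosage(plants[[l]])),
                 numeric(1))
  d1 <- dos1[loci]
  alt_dosage <- ifelse(pos$allele1_is_alt, d1, total_ploidy - d1)
  data.frame(contig = pos$contig_id, pos = pos$pos,
             ref = pos$ref, alt = pos$alt,
             true_alt_freq = alt_dosage / total_ploidy,
             stringsAsFactors = FALSE)
}

#' Simulate a pooled GbS pileup
#'
#' Draws an observed per-position allele-count pileup for a pool of
#' plants over a contig set.  At each position the true pool alternate
#' frequency is computed with [true_pool_frequencies()]; observed
#' coverage is drawn from the overdispersed model in `noise` (zero with
#' probability `dropout_rate`); read counts are multinomial over the four
#' bases with per-base substitution errors at `seq_error_rate` (an
#' erroneous read reports one of the other three bases uniformly).
#' Positions with zero observed coverage are omitted from the pileup, and
#' allele counts at every emitted position sum to its coverage.
#'
#' @param plants `plant_records` for the pool members.
#' @param contigs a [contig_set()].
#' @param noise a [gbs_noise_model()].
#' @param rng_seed optional integer seed.
#' @return a data frame of class `pool_pileup` in long format: `contig`,
#'   `pos`, `ref`, `allele`, `count` (only alleles with count > 0).
#' @export
simulate_pool_pileup <- function(plants, contigs, noise = gbs_noise_model(),
                                 rng_seed = NULL) {
  if (!inherits(noise, "gbs_noise_model")) {
    bm_validation_error("`noise` must be a gbs_noise_model")
  }
  tf <- true_pool_frequencies(plants, contigs)  # validates plants/contigs
  with_seed(rng_seed, {
    m <- nrow(tf)
    cov <- rnbinom(m, mu = noise$coverage_mean, size = noise$coverage_dispersion)
    cov[runif(m) < noise$dropout_rate] <- 0L
    e <- noise$seq_error_rate
    bases <- c("A", "C", "G", "T")
    rows <- vector("list", m)
    for (i in seq_len(m)) {
      if (cov[i] == 0L) next
      f <- tf$true_alt_freq[i]
      p <- rep(e / 3, 4L)
      names(p) <- bases
      p[tf$alt[i]] <- f * (1 - e) + (1 - f) * e / 3
      p[tf$ref[i]] <- (1 - f) * (1 - e) + f * e / 3
      cnt <- as.vector(rmultinom(1L, cov[i], p))
      keep <- cnt > 0L
      if (!any(keep)) next
      rows[[i]] <- data.frame(contig = tf$contig[i], pos = tf$pos[i],
                              ref = tf$ref[i], allele = bases[keep],
                              count = cnt[keep], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) {
      out <- data.frame(contig = character(), pos = integer(), ref = character(),
                        allele = character(), count = integer(),
                        stringsAsFactors = FALSE)
    }
    class(out) <- c("pool_pileup", "data.frame")
    rownames(out) <- NULL
    out
  })
}
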