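#' Compute 2C DNA content from flow-cytometry fluorescence
#'
#' Converts mean fluorescence of a sample to a 2C DNA content (pg) against
#' an internal reference standard measured in the same run:
#' `2C = sample_fluor_mean * standard_2c_pg / standard_fluor_mean`.
#' The default standard is *Pisum sativum* 'Ctirad' with 2C = 9.09 pg.
#'
#' The estimate is homogeneous of degree zero in the fluorescence scale:
#' multiplying both fluorescence means by the same positive factor leaves
#' the result unchanged, so arbitrary instrument units are fine.
#'
#' @param sample_fluor_mean mean fluorescence of the sample peak
#'   (arbitrary units, > 0); vectorized.
#' @param standard_fluor_mean mean fluorescence of the standard peak
#'   (same units, > 0).
#' @param standard_2c_pg 2C DNA content of the standard in pg.
#' @return numeric vector of 2C DNA contents in pg.
#' @examples
#' compute_2c(100, 100)            # 9.09
#' compute_2c(0.484 * 200, 200)    # ~4.40
#' @export
compute_2c <- function(sample_fluor_mean, standard_fluor_mean,
                       standard_2c_pg = 9.09) {
  if (!is.numeric(sample_fluor_mean) || !is.numeric(standard_fluor_mean) ||
      !is.numeric(standard_2c_pg)) {
    bm_validation_error("fluorescence means and standard 2C must be numeric")
  }
  if (any(!is.finite(sample_fluor_mean)) || any(sample_fluor_mean <= 0) ||
      any(!is.finite(standard_fluor_mean)) || any(standard_fluor_mean <= 0) ||
      any(!is.finite(standard_2c_pg)) || any(standard_2c_pg <= 0)) {
    bm_validation_error("fluorescence means and standard 2C must be strictly positive")
  }
  sample_fluor_mean * standard_2c_pg / standard_fluor_mean
}

#' Classify plants into ploidy classes from 2C DNA content
#'
#' Assigns each 2C value (pg) to `"diploid"`, `"triploid"`,
#' `"higher_ploidy"` or `"unclassified"` using closed threshold windows
#' (see [ploidy_thresholds()]).  Values falling in the gaps between
#' windows are returned as `"unclassified"` with a warning rather than
#' being forced into a neighbouring class.
#'
#' @param c2_pg numeric vector of 2C DNA contents in pg (> 0).
#' @param thresholds a [ploidy_thresholds()] object.
#' @return factor with levels `diploid`, `triploid`, `higher_ploidy`,
#'   `unclassified`.
#' @examples
#' classify_ploidy(c(4.4, 6.6, 8.5))
#' @export
classify_ploidy <- function(c2_pg, thresholds = ploidy_thresholds()) {
  if (!inherits(thresholds, "ploidy_thresholds")) {
    bm_validation_error("`thresholds` must be a ploidy_thresholds object")
  }
  if (!is.numeric(c2_pg) || any(!is.finite(c2_pg)) || any(c2_pg <= 0)) {
    bm_validation_error("`c2_pg` must be positive and finite")
  }
  t <- thresholds
  cls <- rep("unclassified", length(c2_pg))
  cls[c2_pg >= t$diploid_low & c2_pg <= t$diploid_high] <- "diploid"
  cls[c2_pg >= t$triploid_low & c2_pg <= t$triploid_high] <- "triploid"
  cls[c2_pg >= t$higher_min] <- "higher_ploidy"
  n_gap <- sum(cls == "unclassified")
  if (n_gap > 0) {
    warning(sprintf("%d value(s) fall between ploidy windows; returned as unclassified",
                    n_gap), call. = FALSE)
  }
  factor(cls, levels = c("diploid", "triploid", "higher_ploidy", "unclassified"))
}

#' Classify a table of flow-cytometry measurements
#'
#' Convenience wrapper applying [compute_2c()] and [classify_ploidy()] to a
#' per-plant measurement table, with an optional coefficient-of-variation
#' quality gate (measurements whose peak CV exceeds `max_cv` are dropped).
#'
#' @param measurements data frame with columns `plant_id`,
#'   `sample_fluor_mean`, `standard_fluor_mean`, optionally `cv` (peak
#'   coefficient of variation as a fraction) and `standard_2c_pg`.
#' @param thresholds a [ploidy_thresholds()] object.
#' @param standard_2c_pg default standard 2C (pg) when the table carries no
#'   `standard_2c_pg` column.
#' @param max_cv optional quality gate: rows with `cv > max_cv` are removed
#'   (the conventional gate is 0.04, i.e. CV < 4%).  `NULL` disables it.
#' @return data frame with columns `plant_id`, `c2_pg`, `ploidy_class`.
#' @export
classify_flow_table <- function(measurements, thresholds = ploidy_thresholds(),
                                standard_2c_pg = 9.09, max_cv = NULL) {
  need <- c("plant_id", "sample_fluor_mean", "standard_fluor_mean")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    bm_validation_error(paste("`measurements` must contain columns:",
                              paste(need, collapse = ", ")))
  }
  m <- measurements
  if (!is.null(max_cv)) {
    check_prob(max_cv, "max_cv")
    if (!"cv" %in% names(m)) {
      bm_validation_error("`max_cv` given but `measurements` has no `cv` column")
    }
    m <- m[!is.na(m$cv) & m$cv <= max_cv, , drop = FALSE]
  }
  std <- if ("standard_2c_pg" %in% names(m)) m$standard_2c_pg else standard_2c_pg
  c2 <- compute_2c(m$sample_fluor_mean, m$standard_fluor_mean, std)
  data.frame(plant_id = m$plant_id,
             c2_pg = c2,
             ploidy_class = classify_ploidy(c2, thresholds),
             stringsAsFactors = FALSE)
}
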