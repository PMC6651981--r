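#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rmultinom rnbinom rnorm runif pchisq qchisq
#' @importFrom utils read.csv write.csv packageVersion
NULL

# let data.table's `[` see this package as data.table-aware
.datatable.aware <- TRUE

# Signal a validation error with a dedicated condition class so callers
# (and the CLI) can distinguish bad input from programming errors.
bm_abort <- function(msg, class = "bulkmark_error", call = sys.call(-1)) {
  stop(structure(
    class = c(class, "bulkmark_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

bm_validation_error <- function(msg) {
  bm_abort(msg, class = "bulkmark_validation_error")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    bm_validation_error(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

check_recomb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 0.5) {
    bm_validation_error(sprintf("`%s` must be a recombination fraction in [0, 0.5]", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    bm_validation_error(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    bm_validation_error(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding").  Reported
#' percentages in this package follow the conventional half-up rule so that
#' e.g. `99.75` prints as `99.8`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(99.65, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    bm_validation_error("`rng_seed` must be a single integer or NULL")
  }
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table non-standard evaluation columns
utils::globalVariables(c(
  "coverage", "count", "freq", "n_alleles", "contig", "pos", "allele",
  "evaluable", "dip_af", "trait_major_freq", "trait_major_allele",
  "dip_allele", "n_positions", "mean_af_diploid", "mean_af_trait", "ref"
))

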