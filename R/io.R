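PILEUP_HEADER <- "#bulkmark-pileup-tsv v1"

#' Write a pool pileup to TSV
#'
#' Serializes a long-format pileup to the versioned pileup TSV: a format
#' header line, then tab-separated `contig`, `pos`, `ref`, `counts` rows
#' with allele counts encoded as `allele:count` pairs joined by `;`
#' (e.g. `A:10;C:5`).  Coordinates are 1-based.
#'
#' @param pileup a `pool_pileup` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  if (!is.data.frame(pileup) ||
      !all(c("contig", "pos", "allele", "count") %in% names(pileup))) {
    bm_validation_error("pileup needs columns contig, pos, allele, count")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(PILEUP_HEADER, "contig\tpos\tref\tcounts"), con)
  if (nrow(pileup)) {
    dt <- data.table::as.data.table(pileup)
    if (!"ref" %in% names(dt)) dt[, ref := "."]
    rows <- dt[order(contig, pos, allele),
               list(ref = ref[1],
                    counts = paste(sprintf("%s:%d", allele, as.integer(count)),
                                   collapse = ";")),
               by = c("contig", "pos")]
    writeLines(sprintf("%s\t%d\t%s\t%s", rows$contig, rows$pos, rows$ref, rows$counts),
               con)
  }
  invisible(path)
}

#' Read a pool pileup from TSV
#'
#' Parses the versioned pileup TSV written by [write_pileup_tsv()].
#' Unknown allele tokens (e.g. indel tokens) are preserved verbatim.
#' Duplicate `(contig, pos)` rows and malformed rows are errors naming
#' the offending line; an empty file yields an empty pileup with a
#' warning.
#'
#' @param path input file path.
#' @return a `pool_pileup` data frame (`contig`, `pos`, `ref`, `allele`,
#'   `count`).
#' @export
read_pileup_tsv <- function(path) {
  if (!file.exists(path)) bm_validation_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      allele = character(), count = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("pool_pileup", "data.frame")
  if (length(lines) == 0L) {
    warning("empty pileup file", call. = FALSE)
    return(empty)
  }
  if (!startsWith(lines[1], "#bulkmark-pileup-tsv")) {
    bm_validation_error("missing pileup format header line")
  }
  body <- lines[-1]
  if (length(body) && startsWith(body[1], "contig\t")) body <- body[-1]
  if (length(body) == 0L) {
    warning("pileup file has no data rows", call. = FALSE)
    return(empty)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  seen <- character(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    line_no <- i + 2L  # header + column line
    if (length(p) != 4L || is.na(suppressWarnings(as.integer(p[2])))) {
      bm_abort(sprintf("malformed pileup row at line %d", line_no),
               class = "bulkmark_validation_error")
    }
    key <- paste(p[1], p[2])
    if (key %in% seen) {
      bm_abort(sprintf("duplicate position %s:%s at line %d", p[1], p[2], line_no),
               class = "bulkmark_validation_error")
    }
    seen <- c(seen, key)
    toks <- strsplit(p[4], ";", fixed = TRUE)[[1]]
    ac <- regmatches(toks, regexec("^(.+):([0-9]+)$", toks))
    if (any(vapply(ac, length, integer(1)) != 3L)) {
      bm_abort(sprintf("malformed allele counts at line %d", line_no),
               class = "bulkmark_validation_error")
    }
    out[[i]] <- data.frame(
      contig = p[1], pos = as.integer(p[2]), ref = p[3],
      allele = vapply(ac, `[`, character(1), 2L),
      count = as.integer(vapply(ac, `[`, character(1), 3L)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pool_pileup", "data.frame")
  res
}

#' Write variant calls as minimal VCF 4.2
#'
#' One data line per called position, `REF` from the calls' reference
#' allele, `ALT` the comma-joined reported non-reference alleles, and
#' `INFO` carrying `DP` (position coverage) and `AF` (per-ALT frequency,
#' 4 decimals).  `POS` is 1-based.  Input must be sorted by
#' `(contig, pos)`.
#'
#' @param calls a `variant_calls` data frame with a `ref` column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  if (!is.data.frame(calls) ||
      !all(c("contig", "pos", "ref", "allele", "count", "coverage", "freq")
           %in% names(calls))) {
    bm_validation_error("`calls` must be variant calls with a ref column")
  }
  key <- order(calls$contig, calls$pos)
  pos_order <- unique(paste(calls$contig, calls$pos))
  if (!identical(pos_order, unique(paste(calls$contig[key], calls$pos[key])))) {
    bm_validation_error("calls must be sorted by (contig, pos)")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=bulkmark-%s", as.character(packageVersion("bulkmark"))),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Position read depth">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency (count/DP)">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(calls)) {
    dt <- data.table::as.data.table(calls)
    rows <- dt[, {
      nonref <- allele != ref[1]
      o <- order(-freq[nonref], allele[nonref])
      alts <- allele[nonref][o]
      afs <- freq[nonref][o]
      list(ref = ref[1], alt = paste(alts, collapse = ","),
           dp = coverage[1],
           af = paste(sprintf("%.4f", afs), collapse = ","))
    }, by = c("contig", "pos")]
    rows <- rows[nchar(rows$alt) > 0L]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AF=%s",
                       rows$contig, rows$pos, rows$ref, rows$alt,
                       as.integer(rows$dp), rows$af), con)
  }
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' Parses CHROM, POS, REF, ALT and the DP/AF INFO fields back into a
#' per-allele table.  Intended for round-tripping this package's own
#' output, not as a general VCF reader.
#'
#' @param path VCF file path.
#' @return data frame `contig`, `pos`, `ref`, `allele`, `freq`, `coverage`.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) bm_validation_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      allele = character(), freq = numeric(), coverage = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) {
    info <- strsplit(p[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                            vapply(kv, `[`, character(1), 1L))
    alts <- strsplit(p[5], ",", fixed = TRUE)[[1]]
    afs <- as.numeric(strsplit(vals[["AF"]], ",", fixed = TRUE)[[1]])
    data.frame(contig = p[1], pos = as.integer(p[2]), ref = p[4],
               allele = alts, freq = afs,
               coverage = as.integer(vals[["DP"]]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write/read a population table
#'
#' The population CSV has columns `plant_id`, `ploidy`, `ploidy_class`,
#' `c2_pg`, `phenotype`, then one column per locus holding `/`-joined
#' allele symbols.
#'
#' @param plants a `plant_records` data frame.
#' @param path file path.
#' @return `path` (write) or a `plant_records` data frame (read).
#' @export
write_population_csv <- function(plants, path) {
  write.csv(as.data.frame(plants), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  if (!file.exists(path)) bm_validation_error(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "phenotype")
  if (!all(need %in% names(df))) {
    bm_validation_error("population CSV needs at least plant_id and phenotype columns")
  }
  fixed <- c("plant_id", "ploidy", "ploidy_class", "c2_pg", "phenotype")
  attr(df, "loci") <- setdiff(names(df), fixed)
  class(df) <- c("plant_records", "data.frame")
  df
}

#' Read a cultivar collection CSV
#'
#' Columns: `name`, `type` (`M` mophead / `L` lacecap), `c2_pg` (may be
#' empty), `variant1`, `variant2`.  The packaged file
#' `cultivar_collection_a109a110.csv` encodes the published 56-variety
#' genotype table at the A109A110 marker locus.
#'
#' @param path CSV file path.
#' @return data frame of cultivar records.
#' @export
read_cultivar_csv <- function(path) {
  if (!file.exists(path)) bm_validation_error(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "type", "variant1", "variant2")
  if (!all(need %in% names(df))) {
    bm_validation_error(paste("cultivar CSV needs columns:", paste(need, collapse = ", ")))
  }
  df
}

#' Write candidate contigs as TSV and BED
#'
#' `write_candidates_tsv()` writes the ranked candidate table.
#' `write_candidates_bed()` writes the span of each candidate contig's
#' informative positions as BED (0-based half-open, per the BED
#' standard; all internal coordinates remain 1-based).
#'
#' @param candidates a `candidate_contigs` data frame (with its
#'   `positions` attribute, as returned by [select_candidate_contigs()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  df <- as.data.frame(candidates)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_candidates_tsv
#' @export
write_candidates_bed <- function(candidates, path) {
  pos <- attr(candidates, "positions")
  if (is.null(pos) || nrow(as.data.frame(candidates)) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  dt <- data.table::as.data.table(pos[pos$contig %in% candidates$contig, ])
  spans <- dt[, list(start = min(pos) - 1L, end = max(pos)), by = "contig"]
  spans <- spans[match(candidates$contig, spans$contig)]
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d",
                     spans$contig, spans$start, spans$end,
                     candidates$contig,
                     as.integer(round(1000 * candidates$mean_af_trait))),
             path)
  invisible(path)
}

#' Run configuration (YAML)
#'
#' Reads or writes a run configuration as YAML.  The configuration is a
#' plain named list; parameter objects are stored as their underlying
#' lists and revalidated by the consuming constructors.
#'
#' @param config named list.
#' @param path YAML file path.
#' @return the configuration list (read) or `path` (write).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) bm_validation_error(sprintf("file not found: %s", path))
  yaml::read_yaml(path)
}

#' Provenance block for a run
#'
#' Machine-readable provenance written next to every CLI result: package
#' version, RNG seed, and an MD5 hash of the serialized configuration.
#'
#' @param config named configuration list.
#' @param seed RNG seed used (or `NA`).
#' @return named list (`package`, `version`, `seed`, `config_md5`,
#'   `timestamp`).
#' @export
provenance <- function(config = list(), seed = NA) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  list(package = "bulkmark",
       version = as.character(packageVersion("bulkmark")),
       seed = seed,
       config_md5 = unname(tools::md5sum(tmp)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
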