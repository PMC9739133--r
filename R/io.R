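# Plain-text table dialects. Coordinates are 1-based inclusive everywhere
# (the VCF convention; BED-style half-open intervals are never emitted).

ALLELE_DEPTH_COLS <- c("chrom", "pos", "ref",
                       paste0("var_", NUCLEOTIDES), paste0("ck_", NUCLEOTIDES))

#' Write an allele-depth table
#'
#' Tab-separated, header required, rows sorted by (chrom, pos) on write.
#'
#' @param tbl data.frame with the allele-depth columns (`chrom`, `pos`,
#'   `ref`, `var_A..var_T`, `ck_A..ck_T`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_depths <- function(tbl, path) {
  if (!all(ALLELE_DEPTH_COLS %in% names(tbl))) {
    stop_("allele-depth table is missing required columns")
  }
  tbl <- tbl[order(tbl$chrom, tbl$pos), ALLELE_DEPTH_COLS]
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate an allele-depth table
#'
#' Accepts the canonical TSV dialect (header line, `#` comment lines
#' allowed) or, when the file name ends in `.vcf`, a VCF whose samples
#' `Var` and `CK` carry per-allele `AD` depths (requires the
#' VariantAnnotation package). Malformed rows are rejected with their line
#' numbers. Records are returned sorted by (chrom, pos).
#'
#' @param path file to read.
#' @param var_sample,ck_sample VCF sample names for the two bulks.
#' @return Validated allele-depth data.frame.
#' @export
read_allele_depths <- function(path, var_sample = "Var", ck_sample = "CK") {
  if (!file.exists(path)) stop_("file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(read_allele_depths_vcf(path, var_sample, ck_sample))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) < 2L) stop_("no data rows in ", path)
  tbl <- read.delim(text = lines[keep], stringsAsFactors = FALSE,
                    colClasses = "character")
  missing <- setdiff(ALLELE_DEPTH_COLS, names(tbl))
  if (length(missing)) {
    stop_("missing required column(s): ", paste(missing, collapse = ", "))
  }
  data_lines <- lineno[-1L]
  num_cols <- c("pos", paste0("var_", NUCLEOTIDES), paste0("ck_", NUCLEOTIDES))
  bad <- rep(FALSE, nrow(tbl))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(tbl[[cl]]))
    bad <- bad | is.na(v) | v < 0 | v != floor(v)
    tbl[[cl]] <- v
  }
  if (any(bad)) {
    stop_("malformed row(s) at line(s) ",
          paste(data_lines[bad], collapse = ", "),
          " of ", path, " (non-negative integers required)")
  }
  tbl <- tbl[order(tbl$chrom, tbl$pos), ALLELE_DEPTH_COLS]
  rownames(tbl) <- NULL
  tbl
}

# VCF input convenience: expand per-sample AD fields to the 4-nucleotide
# depth vectors; non-SNV alleles are dropped with a warning.
read_allele_depths_vcf <- function(path, var_sample = "Var",
                                   ck_sample = "CK") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_("reading VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  for (s in c(var_sample, ck_sample)) {
    if (!s %in% samples) stop_("VCF is missing required sample: ", s)
  }
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop_("VCF has no AD (allele depth) genotype field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_list <- as.list(rr$ALT)
  n <- length(rr)
  depth_row <- function(sample_i, i) {
    out <- setNames(rep(0L, 4L), NUCLEOTIDES)
    alleles <- c(ref[i], vapply(alt_list[[i]], as.character, character(1)))
    # AD comes back as a list-matrix (ragged) or a 3-d array (rectangular)
    depths <- if (is.list(ad)) ad[[i, sample_i]] else ad[i, sample_i, ]
    depths[is.na(depths)] <- 0L
    dropped <- FALSE
    for (j in seq_along(alleles)) {
      if (alleles[j] %in% NUCLEOTIDES && j <= length(depths)) {
        out[alleles[j]] <- out[alleles[j]] + depths[j]
      } else {
        dropped <- TRUE
      }
    }
    attr(out, "dropped") <- dropped
    out
  }
  vm <- matrix(0L, n, 4L, dimnames = list(NULL, NUCLEOTIDES))
  cm <- matrix(0L, n, 4L, dimnames = list(NULL, NUCLEOTIDES))
  any_dropped <- FALSE
  for (i in seq_len(n)) {
    v <- depth_row(var_sample, i)
    c_ <- depth_row(ck_sample, i)
    any_dropped <- any_dropped || attr(v, "dropped") || attr(c_, "dropped")
    vm[i, ] <- v
    cm[i, ] <- c_
  }
  if (any_dropped) {
    warning("non-SNV alleles dropped from one or more VCF records",
            call. = FALSE)
  }
  tbl <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ifelse(ref %in% NUCLEOTIDES, ref, "N"),
    vm, cm
  )
  names(tbl)[4:11] <- c(paste0("var_", NUCLEOTIDES), paste0("ck_", NUCLEOTIDES))
  tbl <- tbl[order(tbl$chrom, tbl$pos), ]
  rownames(tbl) <- NULL
  tbl
}

#' Write / read a marker genotype table (CSV)
#'
#' Rows are individuals; columns are `id`, `phenotype` and one column per
#' marker with genotypes in `{AA, AB, BB}` (empty / NA for missing).
#'
#' @param tbl marker genotype data.frame.
#' @param path file path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
write_marker_genotypes <- function(tbl, path) {
  write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_genotypes
#' @export
read_marker_genotypes <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(tbl)) stop_("marker genotype table needs an `id` column")
  geno_cols <- setdiff(names(tbl), c("id", "phenotype"))
  for (cl in geno_cols) {
    v <- tbl[[cl]]
    ok <- is.na(v) | v %in% c("AA", "AB", "BB", "")
    if (!all(ok)) {
      stop_("invalid genotype code(s) in column ", cl, ": ",
            paste(unique(v[!ok]), collapse = ", "))
    }
    tbl[[cl]][v == ""] <- NA_character_
  }
  tbl
}

#' Read a marker-position table
#'
#' Tab- or comma-separated with columns `marker`, `chrom`, `pos`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_marker_positions <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tbl <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(tbl))) {
    stop_("marker-position table needs columns ", paste(need, collapse = ", "))
  }
  tbl
}

#' Read an exon-coordinate table
#'
#' TSV with columns `gene`, `start`, `end`, `strand` (1-based inclusive
#' gene coordinates).
#'
#' @param path file path.
#' @return data.frame sorted by `start`.
#' @export
read_exon_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "start", "end", "strand")
  if (!all(need %in% names(tbl))) {
    stop_("exon table needs columns ", paste(need, collapse = ", "))
  }
  tbl[order(tbl$start), ]
}

#' Run configuration: plain-text key=value round trip
#'
#' Every pipeline stage reads its parameters from a run configuration (or
#' CLI flags). The on-disk form is one `key = value` per line, `#`
#' comments allowed; values that parse as numbers are returned numeric.
#'
#' @param path file path.
#' @param config named list to write.
#' @return Named list (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop_("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  keys <- sort(names(config))
  writeLines(paste(keys, "=",
                   vapply(config[keys], function(v) format(v, scientific = FALSE),
                          character(1))),
             path)
  invisible(path)
}

# JSON writer used for reports and truth records.
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
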