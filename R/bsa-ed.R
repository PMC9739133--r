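#' Allele frequencies from a 4-nucleotide depth vector
#'
#' @param depths numeric vector of length 4 (A, C, G, T counts), all >= 0.
#' @return Frequency vector summing to 1, or a vector of `NA` (the
#'   "no-coverage" flag) when total depth is 0; no-coverage records are
#'   excluded downstream.
#' @export
allele_frequencies <- function(depths) {
  if (length(depths) != 4L) stop_("`depths` must have length 4 (A,C,G,T)")
  if (any(is.na(depths)) || any(depths < 0)) stop_("depths must be >= 0")
  total <- sum(depths)
  if (total == 0) return(rep(NA_real_, 4L))
  depths / total
}

#' Euclidean-distance statistic between two bulks' allele frequencies
#'
#' `ED = sqrt(sum_a (f_var_a - f_ck_a)^2)` over the four nucleotides; the
#' k-th power `ED^k` (default k = 5) suppresses unlinked noise relative to
#' linked signal. ED is bounded by `sqrt(2)` and symmetric in the bulks.
#'
#' @param freq_var,freq_ck frequency vectors of equal length.
#' @param k positive integer exponent (default 5).
#' @return List with elements `ed` and `edk`.
#' @examples
#' ed_statistic(c(2/3, 0, 1/3, 0), c(0, 0, 1, 0))  # ~0.9428, ~0.7449
#' @export
ed_statistic <- function(freq_var, freq_ck, k = 5) {
  if (length(freq_var) != length(freq_ck)) {
    stop_("frequency vectors must have equal length")
  }
  if (!is_count(k) || k < 1) stop_("`k` must be a positive integer")
  ed <- sqrt(sum((freq_var - freq_ck)^2))
  list(ed = ed, edk = ed^k)
}

#' Score every SNV record with ED and ED^k
#'
#' Vectorized scoring of an allele-depth table (see
#' [read_allele_depths()] for the dialect): per-bulk allele frequencies,
#' ED, ED^k, and a `retained` flag combining coverage and the minimum
#' depth filter.
#'
#' @param tbl allele-depth data.frame with columns `chrom`, `pos`,
#'   `var_A..var_T`, `ck_A..ck_T`.
#' @param k ED exponent (default 5).
#' @param min_depth minimum per-bulk total depth for a record to be
#'   retained (default 10).
#' @return The table with added columns `var_total`, `ck_total`, `ed`,
#'   `edk`, `retained`.
#' @export
score_snvs <- function(tbl, k = 5, min_depth = 10) {
  var_cols <- paste0("var_", NUCLEOTIDES)
  ck_cols <- paste0("ck_", NUCLEOTIDES)
  if (!all(c("chrom", "pos", var_cols, ck_cols) %in% names(tbl))) {
    stop_("allele-depth table is missing required columns")
  }
  vm <- as.matrix(tbl[var_cols])
  cm <- as.matrix(tbl[ck_cols])
  if (any(vm < 0) || any(cm < 0)) stop_("negative depths")
  vt <- rowSums(vm)
  ct <- rowSums(cm)
  fv <- vm / ifelse(vt > 0, vt, NA_real_)
  fc <- cm / ifelse(ct > 0, ct, NA_real_)
  ed <- sqrt(rowSums((fv - fc)^2))
  tbl$var_total <- vt
  tbl$ck_total <- ct
  tbl$ed <- ed
  tbl$edk <- ed^k
  tbl$retained <- vt >= min_depth & ct >= min_depth & !is.na(ed)
  tbl
}

#' Genome-wide top-fraction threshold on ED^k
#'
#' Nearest-rank rule on the sorted values: with `n` values and fraction
#' `f`, the threshold is the value at rank `n - floor(n * f) + 1`; SNVs
#' with `ED^k >= threshold` are significant, so ties at the threshold are
#' included. When `floor(n * f) == 0` (the fraction selects none) the
#' threshold is the maximum value and only records tied with it are
#' significant.
#'
#' @param edk_values non-empty numeric vector.
#' @param fraction top fraction in (0, 1); default 0.01 (top 1 percent).
#' @return The threshold value.
#' @export
top_fraction_threshold <- function(edk_values, fraction = 0.01) {
  if (length(edk_values) == 0L) stop_("no ED^k values")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_("`fraction` must be in (0, 1)")
  }
  s <- sort(edk_values)
  n <- length(s)
  m <- floor(n * fraction)
  s[max(1L, min(n, n - m + 1L))]
}

#' Merge significant SNVs into candidate regions
#'
#' Significant SNVs (ED^k at or above the threshold) on the same
#' chromosome separated by at most `max_gap` bp are merged; a region's
#' start/stop are the min/max significant positions, its SNV count is the
#' number of significant SNVs merged, and its length is `stop - start`.
#' Regions with fewer than `min_snvs` SNVs are dropped.
#'
#' @param snv_records scored data.frame (see [score_snvs()]) with columns
#'   `chrom`, `pos`, `edk`, sorted by (chrom, pos).
#' @param threshold significance threshold on `edk`.
#' @param max_gap maximum within-region gap in bp (default 1e6).
#' @param min_snvs minimum significant SNVs per region (default 3).
#' @return data.frame with columns `chrom`, `start`, `stop`, `n_snvs`,
#'   `length`.
#' @export
call_regions <- function(snv_records, threshold, max_gap = 1e6, min_snvs = 3) {
  if (!all(c("chrom", "pos", "edk") %in% names(snv_records))) {
    stop_("`snv_records` needs columns chrom, pos, edk")
  }
  for (ch in unique(snv_records$chrom)) {
    if (is.unsorted(snv_records$pos[snv_records$chrom == ch])) {
      stop_("records must be sorted by (chrom, pos)")
    }
  }
  sig <- snv_records[!is.na(snv_records$edk) & snv_records$edk >= threshold, ]
  out <- data.frame(chrom = character(0), start = numeric(0),
                    stop = numeric(0), n_snvs = integer(0),
                    length = numeric(0))
  for (ch in unique(sig$chrom)) {
    p <- sig$pos[sig$chrom == ch]
    grp <- cumsum(c(1, diff(p) > max_gap))
    for (g in unique(grp)) {
      pg <- p[grp == g]
      if (length(pg) < min_snvs) next
      out <- rbind(out, data.frame(
        chrom = ch, start = min(pg), stop = max(pg),
        n_snvs = length(pg), length = max(pg) - min(pg)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Interval length under the stop − start convention
#'
#' @param start,stop 1-based positions with `start <= stop` (vectorized).
#' @return `stop - start` in bp.
#' @examples
#' region_length(37199, 2499485)  # 2462286
#' @export
region_length <- function(start, stop) {
  if (any(start > stop)) stop_("start must not exceed stop")
  stop - start
}

#' Run the full ED scanning stage
#'
#' Scores all SNVs ([score_snvs()]), derives the genome-wide top-fraction
#' threshold over retained records ([top_fraction_threshold()]) and calls
#' candidate regions ([call_regions()]).
#'
#' @inheritParams score_snvs
#' @param top_fraction top fraction for thresholding (default 0.01).
#' @param max_gap,min_snvs region-merge parameters (defaults 1e6 bp, 3).
#' @return Object of class `bsa_scan`: `snvs` (scored table with a
#'   `significant` column), `threshold`, `regions`, and the parameters.
#' @export
bsa_scan <- function(tbl, k = 5, top_fraction = 0.01, min_depth = 10,
                     max_gap = 1e6, min_snvs = 3) {
  if (nrow(tbl) == 0L) stop_("empty allele-depth table")
  scored <- score_snvs(tbl, k = k, min_depth = min_depth)
  kept <- scored[scored$retained, ]
  if (nrow(kept) == 0L) stop_("no SNV records pass the depth filter")
  threshold <- top_fraction_threshold(kept$edk, top_fraction)
  scored$significant <- scored$retained & scored$edk >= threshold
  regions <- call_regions(kept, threshold, max_gap = max_gap,
                          min_snvs = min_snvs)
  structure(
    list(snvs = scored, threshold = threshold, regions = regions,
         params = list(k = k, top_fraction = top_fraction,
                       min_depth = min_depth, max_gap = max_gap,
                       min_snvs = min_snvs)),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf(
    "bsa_scan: %d SNVs (%d retained, %d significant), ED^%d threshold %.4g\n",
    nrow(x$snvs), sum(x$snvs$retained), sum(x$snvs$significant),
    x$params$k, x$threshold))
  if (nrow(x$regions)) {
    cat("candidate regions:\n")
    print(x$regions)
  } else {
    cat("no candidate regions called\n")
  }
  invisible(x)
}
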