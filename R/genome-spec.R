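#' Describe the genome used by the F2 simulator
#'
#' A genome specification lists the chromosomes, the parent-diagnostic SNV
#' sites segregating between the two inbred parents, the position of the
#' single causal locus, and (optionally) a panel of scorable codominant
#' markers. It is the ground-truth scaffold that [simulate_f2()] and the
#' downstream generators draw from.
#'
#' Parental origins are coded `A` for the wildtype (green-leaf) parent and
#' `B` for the dominant mutant parent; a heterozygote is `AB`.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp, positive integer).
#' @param snv_sites data.frame with columns `chrom`, `pos` (1-based),
#'   `allele_a`, `allele_b` — the bases carried by the wildtype and mutant
#'   parent respectively. Positions must be strictly increasing within each
#'   chromosome and the two alleles must differ at every site.
#' @param causal_locus list or data.frame with fields `chrom` and `pos`;
#'   the single dominant locus. Must lie on exactly one listed chromosome.
#' @param marker_positions optional data.frame with columns `marker`,
#'   `chrom`, `pos` — the subset of positions scorable as codominant
#'   markers.
#' @param bp_per_cM physical-to-genetic scale used by meiosis (default
#'   5e5 bp/cM, a realistic figure for a *Brassica* genome).
#'
#' @return An object of class `genome_spec`.
#' @seealso [default_genome_spec()] for a ready-made specification.
#' @export
genome_spec <- function(chromosomes, snv_sites, causal_locus,
                        marker_positions = NULL, bp_per_cM = 5e5) {
  chromosomes <- as.data.frame(chromosomes)
  if (nrow(chromosomes) == 0L) {
    stop_("genome specification has no chromosomes")
  }
  if (!all(c("chrom", "length") %in% names(chromosomes))) {
    stop_("`chromosomes` needs columns chrom, length")
  }
  if (anyDuplicated(chromosomes$chrom)) stop_("duplicated chromosome names")
  if (any(chromosomes$length <= 0)) stop_("chromosome lengths must be positive")
  if (!is.numeric(bp_per_cM) || length(bp_per_cM) != 1L || bp_per_cM <= 0) {
    stop_("`bp_per_cM` must be a single positive number")
  }

  snv_sites <- as.data.frame(snv_sites)
  need <- c("chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(snv_sites))) {
    stop_("`snv_sites` needs columns ", paste(need, collapse = ", "))
  }
  if (!all(snv_sites$chrom %in% chromosomes$chrom)) {
    stop_("SNV sites on unknown chromosomes")
  }
  for (ch in unique(snv_sites$chrom)) {
    p <- snv_sites$pos[snv_sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop_("SNV positions must be strictly increasing on ", ch)
    }
    len <- chromosomes$length[chromosomes$chrom == ch]
    if (any(p < 1L) || any(p > len)) stop_("SNV position outside ", ch)
  }
  if (any(snv_sites$allele_a == snv_sites$allele_b)) {
    stop_("parental alleles must differ at every SNV site")
  }
  bad <- !(snv_sites$allele_a %in% NUCLEOTIDES & snv_sites$allele_b %in% NUCLEOTIDES)
  if (any(bad)) stop_("SNV alleles must be A/C/G/T")

  causal_locus <- as.list(causal_locus)
  if (!all(c("chrom", "pos") %in% names(causal_locus))) {
    stop_("`causal_locus` needs fields chrom, pos")
  }
  hit <- chromosomes$chrom == causal_locus$chrom
  if (sum(hit) != 1L) stop_("causal locus must lie on exactly one chromosome")
  if (causal_locus$pos < 1L || causal_locus$pos > chromosomes$length[hit]) {
    stop_("causal locus outside its chromosome")
  }

  if (!is.null(marker_positions)) {
    marker_positions <- as.data.frame(marker_positions)
    if (!all(c("marker", "chrom", "pos") %in% names(marker_positions))) {
      stop_("`marker_positions` needs columns marker, chrom, pos")
    }
    if (anyDuplicated(marker_positions$marker)) stop_("duplicated marker ids")
    if (!all(marker_positions$chrom %in% chromosomes$chrom)) {
      stop_("markers on unknown chromosomes")
    }
    lens <- chromosomes$length[match(marker_positions$chrom, chromosomes$chrom)]
    if (any(marker_positions$pos < 1) || any(marker_positions$pos > lens)) {
      stop_("marker position outside its chromosome")
    }
  }

  structure(
    list(
      chromosomes = chromosomes,
      snv_sites = snv_sites,
      causal_locus = causal_locus,
      marker_positions = marker_positions,
      bp_per_cM = bp_per_cM
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$snv_sites), "SNV sites\n")
  cat("  causal locus:", x$causal_locus$chrom, x$causal_locus$pos, "\n")
  if (!is.null(x$marker_positions)) {
    cat("  markers:", nrow(x$marker_positions), "\n")
  }
  cat("  scale:", x$bp_per_cM, "bp/cM\n")
  invisible(x)
}

#' Default three-chromosome genome specification
#'
#' Emulates the mapping context of a *Brassica oleracea* BSR-seq study:
#' three chromosomes of realistic size, `n_snvs` parent-diagnostic SNVs
#' spread over them, a dominant causal locus near the top of the first
#' chromosome (with a diagnostic SNV placed exactly at the locus), and a
#' six-marker codominant panel flanking the locus at roughly 0.5, 1 and
#' 2 cM on either side.
#'
#' @param n_snvs total number of SNV sites (default 5000).
#' @param seed integer seed controlling site placement and allele draws.
#' @param causal_pos causal-locus position on the first chromosome.
#' @param bp_per_cM physical-to-genetic scale (default 5e5).
#' @return A [genome_spec()] object.
#' @export
default_genome_spec <- function(n_snvs = 5000, seed = 1,
                                causal_pos = 2e6, bp_per_cM = 5e5) {
  chromosomes <- data.frame(
    chrom = c("C03", "C05", "C09"),
    length = c(60e6, 50e6, 55e6)
  )
  with_seed(seed, {
    n_per <- diff(round(seq(0, n_snvs, length.out = nrow(chromosomes) + 1L)))
    sites <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
      pos <- sort(sample.int(chromosomes$length[i], n_per[i]))
      data.frame(chrom = chromosomes$chrom[i], pos = pos)
    }))
    # guarantee a diagnostic SNV exactly at the causal locus
    if (!any(sites$chrom == "C03" & sites$pos == causal_pos)) {
      sites <- sites[!(sites$chrom == "C03" & sites$pos == causal_pos), ]
      sites <- rbind(sites, data.frame(chrom = "C03", pos = causal_pos))
      sites <- sites[order(match(sites$chrom, chromosomes$chrom), sites$pos), ]
      sites <- sites[!duplicated(sites[c("chrom", "pos")]), ]
    }
    sites$allele_a <- sample(NUCLEOTIDES, nrow(sites), replace = TRUE)
    shift <- sample.int(3L, nrow(sites), replace = TRUE)
    sites$allele_b <- NUCLEOTIDES[(match(sites$allele_a, NUCLEOTIDES) - 1L + shift) %% 4L + 1L]
    offsets_cM <- c(-2, -1, -0.5, 0.5, 1, 2)
    markers <- data.frame(
      marker = sprintf("M%02d", seq_along(offsets_cM)),
      chrom = "C03",
      pos = causal_pos + offsets_cM * bp_per_cM
    )
    genome_spec(chromosomes, sites,
                list(chrom = "C03", pos = causal_pos),
                marker_positions = markers, bp_per_cM = bp_per_cM)
  })
}
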