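#' Extract the CDS from a gene sequence and exon model
#'
#' Concatenates the exon subsequences (1-based inclusive gene coordinates)
#' and reverse-complements the result for minus-strand genes.
#'
#' @param sequence gene sequence (character or `DNAString`).
#' @param exons data.frame with columns `start`, `end`, sorted and
#'   non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @return The CDS as an upper-case character string.
#' @export
extract_cds <- function(sequence, exons, strand = "+") {
  sequence <- toupper(as.character(sequence))
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    stop_("`exons` needs columns start, end")
  }
  if (any(exons$start > exons$end)) stop_("exon start > end")
  if (is.unsorted(exons$start) ||
      any(utils::head(exons$end, -1) >= utils::tail(exons$start, -1))) {
    stop_("exons must be sorted and non-overlapping")
  }
  if (any(exons$start < 1) || any(exons$end > nchar(sequence))) {
    stop_("exon beyond sequence end")
  }
  cds <- paste(substring(sequence, exons$start, exons$end), collapse = "")
  if (strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  cds
}

# Translate from position 1 up to (not including) the first stop codon;
# trailing partial codons are ignored.
translate_to_stop <- function(cds) {
  aa <- translate_full(cds)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1L, stop_at - 1L) else aa
}

# Translate every complete codon (stops included as '*').
translate_full <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Detect sequence differences between two allele CDSs
#'
#' Global pairwise alignment of the alternate against the reference CDS
#' (defaults: match 1, mismatch −1, gap −2), reported as substitutions and
#' indels in reference-CDS coordinates. Indels inside repeat runs are
#' left-aligned, so coordinates are deterministic. An insertion at
#' position `p` inserts its bases immediately before reference base `p`;
#' a deletion at `p` removes `nchar(ref)` bases starting at `p`.
#'
#' @param ref_cds,alt_cds sequences over A/C/G/T.
#' @param match,mismatch,gap alignment scores.
#' @return data.frame with columns `cds_pos`, `type` (`substitution` /
#'   `insertion` / `deletion`), `ref`, `alt`; zero rows for identical
#'   sequences.
#' @export
diff_alleles <- function(ref_cds, alt_cds, match = 1, mismatch = -1, gap = -2) {
  ref_cds <- toupper(as.character(ref_cds))
  alt_cds <- toupper(as.character(alt_cds))
  if (nchar(ref_cds) == 0L || nchar(alt_cds) == 0L) stop_("empty sequence")
  if (grepl("[^ACGT]", ref_cds) || grepl("[^ACGT]", alt_cds)) {
    stop_("sequences must contain only A/C/G/T")
  }
  if (ref_cds == alt_cds) {
    return(data.frame(cds_pos = integer(0), type = character(0),
                      ref = character(0), alt = character(0)))
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = alt_cds, subject = ref_cds, type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = abs(gap))
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  r <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  ref_chars <- strsplit(ref_cds, "")[[1]]
  vars <- list()
  i <- 1L
  ref_pos <- 0L
  while (i <= length(r)) {
    if (r[i] != "-" && a[i] != "-") {
      ref_pos <- ref_pos + 1L
      if (r[i] != a[i]) {
        vars[[length(vars) + 1L]] <- data.frame(
          cds_pos = ref_pos, type = "substitution",
          ref = r[i], alt = a[i])
      }
      i <- i + 1L
    } else if (r[i] == "-") {
      # run of inserted bases; anchored before the next reference base
      j <- i
      while (j <= length(r) && r[j] == "-") j <- j + 1L
      ins <- paste(a[i:(j - 1L)], collapse = "")
      pos <- ref_pos + 1L
      norm <- left_align_indel(ref_chars, pos, ins)
      vars[[length(vars) + 1L]] <- data.frame(
        cds_pos = norm$pos, type = "insertion", ref = "", alt = norm$seq)
      i <- j
    } else {
      # run of deleted reference bases starting at ref_pos + 1
      j <- i
      while (j <= length(r) && a[j] == "-" && r[j] != "-") j <- j + 1L
      del <- paste(r[i:(j - 1L)], collapse = "")
      pos <- ref_pos + 1L
      norm <- left_align_indel(ref_chars, pos, del)
      vars[[length(vars) + 1L]] <- data.frame(
        cds_pos = norm$pos, type = "deletion", ref = norm$seq, alt = "")
      ref_pos <- ref_pos + (j - i)
      i <- j
    }
  }
  out <- do.call(rbind, vars)
  out <- out[order(out$cds_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shift an indel (insertion before `pos`, or deletion starting at `pos`)
# to its leftmost equivalent placement in a repeat run.
left_align_indel <- function(ref_chars, pos, seq) {
  chars <- strsplit(seq, "")[[1]]
  while (pos > 1L && ref_chars[pos - 1L] == chars[length(chars)]) {
    chars <- c(chars[length(chars)], chars[-length(chars)])
    pos <- pos - 1L
  }
  list(pos = pos, seq = paste(chars, collapse = ""))
}

# Apply variants (as from diff_alleles) to a reference CDS.
apply_variants <- function(ref_cds, variants) {
  variants <- variants[order(variants$cds_pos, decreasing = TRUE), , drop = FALSE]
  s <- ref_cds
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$type == "substitution") {
      substr(s, v$cds_pos, v$cds_pos + nchar(v$ref) - 1L) <- v$alt
    } else if (v$type == "insertion") {
      s <- paste0(substr(s, 1L, v$cds_pos - 1L), v$alt,
                  substr(s, v$cds_pos, nchar(s)))
    } else if (v$type == "deletion") {
      s <- paste0(substr(s, 1L, v$cds_pos - 1L),
                  substr(s, v$cds_pos + nchar(v$ref), nchar(s)))
    } else {
      stop_("unknown variant type: ", v$type)
    }
  }
  s
}

#' Classify the coding consequence of each variant
#'
#' Substitutions are translated in-codon with the standard genetic code:
#' identical amino acid gives `synonymous`, a different one `missense`, a
#' gained stop `nonsense`. An indel whose length is not divisible by 3 is
#' a `frameshift`; the mutated CDS is re-translated from the start codon
#' to the first stop and the truncated protein length (aa) is reported.
#' In-frame indels are labelled `inframe`.
#'
#' @param ref_cds reference CDS.
#' @param variants data.frame as returned by [diff_alleles()], sorted by
#'   position.
#' @return The variant table with added columns `consequence`, `codon`
#'   (index of the affected codon), `aa_ref`, `aa_alt`, `aa_change` (e.g.
#'   `"Arg132Lys"`), `truncated_protein_length` (`NA` unless a premature
#'   stop arises).
#' @export
classify_effects <- function(ref_cds, variants) {
  ref_cds <- toupper(as.character(ref_cds))
  variants <- as.data.frame(variants)
  if (nrow(variants) && is.unsorted(variants$cds_pos)) {
    stop_("variants must be sorted by position")
  }
  n <- nchar(ref_cds)
  wt_protein <- translate_to_stop(ref_cds)

  variants$consequence <- NA_character_
  variants$codon <- as.integer(ceiling(variants$cds_pos / 3))
  variants$aa_ref <- NA_character_
  variants$aa_alt <- NA_character_
  variants$aa_change <- NA_character_
  variants$truncated_protein_length <- NA_integer_

  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    limit <- if (v$type == "insertion") n + 1L else n
    if (v$cds_pos < 1L || v$cds_pos > limit) {
      stop_("variant position ", v$cds_pos, " beyond CDS of length ", n)
    }
    if (v$type == "substitution") {
      ci <- v$codon
      codon <- substr(ref_cds, 3L * ci - 2L, 3L * ci)
      if (nchar(codon) < 3L) stop_("substitution in a partial trailing codon")
      off <- v$cds_pos - 3L * (ci - 1L)
      alt_codon <- codon
      substr(alt_codon, off, off) <- v$alt
      aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
      aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
      variants$aa_ref[i] <- aa_ref
      variants$aa_alt[i] <- aa_alt
      variants$aa_change[i] <- paste0(AA3[aa_ref], ci, AA3[aa_alt])
      if (aa_ref == aa_alt) {
        variants$consequence[i] <- "synonymous"
      } else if (aa_alt == "*") {
        variants$consequence[i] <- "nonsense"
        variants$truncated_protein_length[i] <- ci - 1L
      } else {
        variants$consequence[i] <- "missense"
      }
    } else {
      indel_len <- nchar(if (v$type == "insertion") v$alt else v$ref)
      if (indel_len %% 3L == 0L) {
        variants$consequence[i] <- "inframe"
      } else {
        variants$consequence[i] <- "frameshift"
        mut <- apply_variants(ref_cds, variants[i, , drop = FALSE])
        variants$truncated_protein_length[i] <- nchar(translate_to_stop(mut))
      }
    }
  }
  attr(variants, "wt_protein_length") <- nchar(wt_protein)
  variants
}

#' Does an amino-acid position fall inside a protein domain?
#'
#' @param aa_position 1-based amino-acid position(s).
#' @param domain length-2 vector `c(start, end)`, inclusive.
#' @return Logical: `start <= position <= end`.
#' @examples
#' domain_overlap(132, c(6, 143))  # TRUE
#' @export
domain_overlap <- function(aa_position, domain) {
  if (length(domain) != 2L || domain[1] > domain[2]) {
    stop_("`domain` must be c(start, end) with start <= end")
  }
  if (any(aa_position < 1)) stop_("positions must be >= 1")
  aa_position >= domain[1] & aa_position <= domain[2]
}

#' Compare two alleles of a gene and annotate consequences
#'
#' End-to-end wrapper: extracts both CDSs, diffs them, classifies each
#' variant, and (optionally) flags whether affected codons fall inside a
#' conserved protein domain.
#'
#' @param ref_seq,alt_seq gene sequences (character or `DNAString`).
#' @param exons exon table for both alleles' shared gene model; intronic
#'   coordinates refer to the reference allele.
#' @param strand `"+"` or `"-"`.
#' @param domain optional `c(start, end)` amino-acid interval.
#' @return List with `cds_ref`, `cds_alt`, `variants` (classified, with an
#'   `in_domain` column when `domain` is given) and `wt_protein_length`.
#' @export
variant_report <- function(ref_seq, alt_seq, exons, strand = "+",
                           domain = NULL) {
  cds_ref <- extract_cds(ref_seq, exons, strand)
  # the alternate allele may differ in length; clamp its exon model end
  alt_exons <- as.data.frame(exons)
  shift <- nchar(as.character(alt_seq)) - nchar(as.character(ref_seq))
  alt_exons$end[nrow(alt_exons)] <- alt_exons$end[nrow(alt_exons)] + shift
  cds_alt <- extract_cds(alt_seq, alt_exons, strand)
  variants <- diff_alleles(cds_ref, cds_alt)
  variants <- classify_effects(cds_ref, variants)
  if (!is.null(domain) && nrow(variants)) {
    variants$in_domain <- domain_overlap(pmax(variants$codon, 1L), domain)
  }
  list(cds_ref = cds_ref, cds_alt = cds_alt, variants = variants,
       wt_protein_length = attr(variants, "wt_protein_length"))
}
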