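#' Generate a candidate-gene allele fixture with known variant truth
#'
#' Builds a two-exon gene (default 972 bp total: a 200 bp first exon, a
#' 150 bp intron, a 622 bp second exon) whose concatenated exons form an
#' 822 bp CDS starting with ATG and ending in TAA. The mutant allele
#' differs from the wildtype allele by exactly three engineered changes on
#' exon 2:
#'
#' * a synonymous substitution (third base of an Arg codon, CGG -> CGA),
#' * a missense substitution AGG -> AAG at codon 132 (CDS position 395,
#'   G -> A), changing Arg to Lys,
#' * a 1 bp insertion (C) causing a frameshift and a premature stop; the
#'   resulting truncated protein length is recorded in the truth record.
#'
#' The insertion site is chosen so that neither flanking base is C, making
#' the left-aligned coordinate unambiguous.
#'
#' @param seed integer seed for the background sequence.
#' @param dir optional directory; when given, writes `candidate_wt.fa`,
#'   `candidate_mut.fa`, `candidate_exons.tsv` and `candidate_truth.json`.
#' @param exon1_len,intron_len,total_len gene geometry (defaults 200 / 150
#'   / 972 bp).
#' @return List with `wt_gene`, `mut_gene` (character sequences), `exons`
#'   (data.frame gene/start/end/strand), `truth` (variant table plus
#'   wildtype and truncated protein lengths) and, when `dir` is given,
#'   `paths`.
#' @export
make_candidate_gene_fixture <- function(seed = 1, dir = NULL,
                                        exon1_len = 200, intron_len = 150,
                                        total_len = 972) {
  exon2_len <- total_len - exon1_len - intron_len
  cds_len <- exon1_len + exon2_len
  if (cds_len %% 3 != 0) stop_("exon geometry must give a CDS divisible by 3")
  n_codons <- cds_len %/% 3

  with_seed(seed, {
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    sense <- setdiff(sense, "ATG")  # keep internal ATGs out for clarity
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    body[131L] <- "AGG"  # codon 132 of the CDS (body starts at codon 2)
    body[99L] <- "CGG"   # codon 100, synonymous target
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    intron <- paste0("GT", paste(sample(NUCLEOTIDES, intron_len - 4L,
                                        replace = TRUE), collapse = ""), "AG")

    # insertion point: first CDS position >= 600 whose neighbours are not C
    cds_chars <- strsplit(cds, "")[[1]]
    ins_pos <- NA_integer_
    for (p in 600:(cds_len - 3L)) {
      if (cds_chars[p - 1L] != "C" && cds_chars[p] != "C") {
        ins_pos <- p
        break
      }
    }
    if (is.na(ins_pos)) stop_("could not place insertion")  # practically unreachable

    variants <- data.frame(
      cds_pos = c(300L, 395L, ins_pos),
      type = c("substitution", "substitution", "insertion"),
      ref = c("G", "G", ""),
      alt = c("A", "A", "C"),
      stringsAsFactors = FALSE
    )
    stopifnot(substr(cds, 300, 300) == "G", substr(cds, 395, 395) == "G")

    mut_cds <- apply_variants(cds, variants)
    wt_protein <- translate_to_stop(cds)
    mut_protein <- translate_to_stop(mut_cds)

    classified <- classify_effects(cds, variants)
    truth <- list(
      variants = classified,
      wt_protein_length = nchar(wt_protein),
      truncated_protein_length = nchar(mut_protein),
      note = paste("synthetic fixture; second substitution planted as",
                   "synonymous by choice")
    )

    # map CDS -> gene coordinates (all three variants sit on exon 2)
    to_gene <- function(p) ifelse(p <= exon1_len, p, p + intron_len)
    wt_gene <- paste0(substr(cds, 1L, exon1_len), intron,
                      substr(cds, exon1_len + 1L, cds_len))
    mut_exon2 <- substr(mut_cds, exon1_len + 1L, nchar(mut_cds))
    mut_gene <- paste0(substr(cds, 1L, exon1_len), intron, mut_exon2)
    truth$variants$gene_pos <- to_gene(truth$variants$cds_pos)

    exons <- data.frame(
      gene = "candidate",
      start = c(1L, exon1_len + intron_len + 1L),
      end = c(exon1_len, total_len),
      strand = "+"
    )

    out <- list(wt_gene = wt_gene, mut_gene = mut_gene,
                exons = exons, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        wt = file.path(dir, "candidate_wt.fa"),
        mut = file.path(dir, "candidate_mut.fa"),
        exons = file.path(dir, "candidate_exons.tsv"),
        truth = file.path(dir, "candidate_truth.json")
      )
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(candidate_wt = wt_gene)), paths$wt)
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(candidate_mut = mut_gene)), paths$mut)
      write.table(exons, paths$exons, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write_json_file(truth, paths$truth)
      out$paths <- paths
    }
    out
  })
}

#' Generate absorbance and Ct fixtures with planted truths
#'
#' The absorbance table carries three samples (green-leaf, albino and
#' variegated stages) with triplicate readings at 649/665/470 nm whose
#' replicate perturbations are symmetric, so the replicate mean equals the
#' planted value exactly; pigment truths are the formula outputs at those
#' means (20 mg dry mass in 10 mL extract). The Ct table plants fold
#' changes per condition against the green-leaf calibrator — including a
#' 2158.85-fold induction at the albino stage — with a constant reference
#' (actin) Ct.
#'
#' @param seed integer seed (controls the replicate jitter magnitudes).
#' @param dir optional directory; writes `absorbance.csv`, `ct.csv` and
#'   `assay_truth.json` when given.
#' @return List with `absorbance`, `ct` (data.frames) and `truth`
#'   (planted pigment contents, fold changes and ddCt values).
#' @export
make_assay_fixtures <- function(seed = 1, dir = NULL) {
  with_seed(seed, {
    samples <- c("S1", "S2", "S3")
    base <- data.frame(
      sample = samples,
      A649 = c(0.45, 0.03, 0.20),
      A665 = c(0.90, 0.06, 0.42),
      A470 = c(0.60, 0.05, 0.28)
    )
    jitter <- runif(3, 0.001, 0.004)  # one magnitude per wavelength
    reps <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
      data.frame(
        sample = base$sample[i], replicate = 1:3,
        A649 = base$A649[i] + c(-jitter[1], 0, jitter[1]),
        A665 = base$A665[i] + c(-jitter[2], 0, jitter[2]),
        A470 = base$A470[i] + c(-jitter[3], 0, jitter[3]),
        mass_mg = 20, volume_ml = 10
      )
    }))
    pig_truth <- pigment_content(base$A649, base$A665, base$A470,
                                 mass_mg = 20, volume_ml = 10)
    pig_truth <- cbind(sample = base$sample, pig_truth)

    folds <- c(S1 = 1, S2 = 2158.85, S3 = 50)
    ddct <- -log2(folds)
    ct_ref <- 20
    dct_cal <- 5
    ct_jit <- 0.05
    ct <- do.call(rbind, lapply(samples, function(s) {
      ct_t <- ct_ref + dct_cal + ddct[[s]]
      rbind(
        data.frame(sample = s, condition = s, role = "target",
                   gene = "candidate", replicate = 1:3,
                   ct = ct_t + c(-ct_jit, 0, ct_jit)),
        data.frame(sample = s, condition = s, role = "reference",
                   gene = "actin", replicate = 1:3,
                   ct = ct_ref + c(-ct_jit, 0, ct_jit))
      )
    }))
    truth <- list(
      pigments = pig_truth,
      fold_changes = as.list(folds),
      delta_delta_ct = as.list(ddct),
      calibrator = "S1"
    )
    out <- list(absorbance = reps, ct = ct, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        absorbance = file.path(dir, "absorbance.csv"),
        ct = file.path(dir, "ct.csv"),
        truth = file.path(dir, "assay_truth.json")
      )
      write.csv(reps, paths$absorbance, row.names = FALSE, quote = FALSE)
      write.csv(ct, paths$ct, row.names = FALSE, quote = FALSE)
      write_json_file(truth, paths$truth)
      out$paths <- paths
    }
    out
  })
}
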