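# Shared fixture builders (everything is generated in code at test time).

# A tiny one-chromosome genome: SNVs every 250 kb, causal locus mid-way,
# markers at +/- 0.5 and 2 cM (bp_per_cM = 5e5).
tiny_spec <- function(len = 20e6, causal = 10e6, bp_per_cM = 5e5) {
  pos <- sort(unique(c(seq(25e4, len - 25e4, by = 25e4), causal)))
  genome_spec(
    chromosomes = data.frame(chrom = "C1", length = len),
    snv_sites = data.frame(chrom = "C1", pos = pos,
                           allele_a = "A", allele_b = "G"),
    causal_locus = list(chrom = "C1", pos = causal),
    marker_positions = data.frame(
      marker = c("L2", "L05", "R05", "R2"),
      chrom = "C1",
      pos = causal + c(-2, -0.5, 0.5, 2) * bp_per_cM),
    bp_per_cM = bp_per_cM
  )
}

# A genome with zero genetic length (no recombination limit).
frozen_spec <- function() {
  genome_spec(
    chromosomes = data.frame(chrom = "C1", length = 1e6),
    snv_sites = data.frame(chrom = "C1", pos = c(1e5, 5e5, 9e5),
                           allele_a = c("A", "C", "G"),
                           allele_b = c("G", "T", "A")),
    causal_locus = list(chrom = "C1", pos = 5e5),
    marker_positions = data.frame(marker = "M1", chrom = "C1", pos = 5e5),
    bp_per_cM = 1e12  # ~0 Morgans: crossovers essentially impossible
  )
}

# Minimal allele-depth table with given per-bulk depth vectors.
depth_table <- function(chrom, pos, var, ck) {
  stopifnot(length(var) == 4L, length(ck) == 4L)
  out <- data.frame(chrom = chrom, pos = pos, ref = "A")
  out[paste0("var_", c("A", "C", "G", "T"))] <- as.list(var)
  out[paste0("ck_", c("A", "C", "G", "T"))] <- as.list(ck)
  out
}

# Random CDS of n_codons sense codons framed by ATG ... TAA.
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}
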