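test_that("extract_cds concatenates exons and honors strand", {
  seq30 <- paste(rep("ACGTGGATTC", 3), collapse = "")
  expect_identical(extract_cds(seq30, data.frame(start = 1, end = 30)), seq30)
  two <- extract_cds(seq30, data.frame(start = c(1, 21), end = c(10, 30)))
  expect_identical(nchar(two), 20L)
  expect_identical(two, paste0(substr(seq30, 1, 10), substr(seq30, 21, 30)))
  # minus strand: manual reverse complement oracle
  expect_identical(extract_cds("ATG", data.frame(start = 1, end = 3), "-"),
                   "CAT")
  expect_error(extract_cds("ACGT", data.frame(start = 2, end = 9)),
               "beyond sequence end")
  expect_error(extract_cds(seq30, data.frame(start = c(1, 5), end = c(10, 30))),
               "non-overlapping")
})

test_that("diff_alleles finds planted variants and is empty on identity", {
  expect_identical(nrow(diff_alleles("ACGTACGT", "ACGTACGT")), 0L)
  fx <- make_candidate_gene_fixture(seed = 3)
  cds_wt <- extract_cds(fx$wt_gene, fx$exons[c("start", "end")])
  # the mutant allele is 1 bp longer; extend its final exon accordingly
  mut_exons <- fx$exons[c("start", "end")]
  mut_exons$end[2] <- mut_exons$end[2] +
    nchar(fx$mut_gene) - nchar(fx$wt_gene)
  cds_mut <- extract_cds(fx$mut_gene, mut_exons)
  vars <- diff_alleles(cds_wt, cds_mut)
  expect_identical(nrow(vars), 3L)
  expect_identical(vars$cds_pos, fx$truth$variants$cds_pos)
  expect_identical(vars$type, fx$truth$variants$type)
  expect_error(diff_alleles("", "ACGT"), "empty")
  expect_error(diff_alleles("ACGT", "ACNT"), "A/C/G/T")
})

test_that("indels in homopolymers are left-aligned", {
  # insertion of C into the CCC run: leftmost placement is position 4
  ref <- "ATGCCCGGGTAA"
  alt <- "ATGCCCCGGGTAA"
  v <- diff_alleles(ref, alt)
  expect_identical(v$type, "insertion")
  expect_identical(v$cds_pos, 4L)
  expect_identical(v$alt, "C")
  # brute-force: all equivalent placements give the same alt sequence
  for (p in 4:7) {
    alt_p <- paste0(substr(ref, 1, p - 1), "C", substr(ref, p, nchar(ref)))
    expect_identical(alt_p, alt)
  }
  # deletion from the same run also left-aligns
  d <- diff_alleles(alt, ref)
  expect_identical(d$type, "deletion")
  expect_identical(d$cds_pos, 4L)
})

test_that("diff_alleles is symmetric up to indel type inversion", {
  set.seed(71)
  for (i in 1:10) {
    ref <- random_cds(20)
    alt <- ref
    p <- sample(4:(nchar(ref) - 3), 1)
    base <- sample(c("A", "C", "G", "T"), 1)
    alt <- paste0(substr(alt, 1, p - 1), base, substr(alt, p, nchar(alt)))
    fwd <- diff_alleles(ref, alt)
    rev <- diff_alleles(alt, ref)
    expect_identical(nrow(fwd), nrow(rev))
    expect_identical(sub("insertion", "deletion", fwd$type), rev$type)
    expect_identical(fwd$alt[fwd$type == "insertion"],
                     rev$ref[rev$type == "deletion"])
  }
})

test_that("substitution consequences match the genetic code", {
  # AGG -> AAG at codon 2: Arg -> Lys
  ref <- "ATGAGGTAA"
  v <- classify_effects(ref, data.frame(cds_pos = 5L, type = "substitution",
                                        ref = "G", alt = "A"))
  expect_identical(v$consequence, "missense")
  expect_identical(v$aa_change, "Arg2Lys")
  # CGG -> CGA third position: synonymous Arg
  v2 <- classify_effects("ATGCGGTAA",
                         data.frame(cds_pos = 6L, type = "substitution",
                                    ref = "G", alt = "A"))
  expect_identical(v2$consequence, "synonymous")
  # TGG -> TGA: stop gained
  v3 <- classify_effects("ATGTGGAAATAA",
                         data.frame(cds_pos = 6L, type = "substitution",
                                    ref = "G", alt = "A"))
  expect_identical(v3$consequence, "nonsense")
  expect_identical(v3$truncated_protein_length, 1L)
  expect_error(
    classify_effects("ATG", data.frame(cds_pos = 9L, type = "substitution",
                                       ref = "G", alt = "A")),
    "beyond CDS")
})

test_that("random substitutions agree with full re-translation oracle", {
  set.seed(72)
  translate_oracle <- function(cds) {
    n <- nchar(cds) %/% 3
    aa <- vapply(seq_len(n), function(i) {
      unname(Biostrings::GENETIC_CODE[substr(cds, 3 * i - 2, 3 * i)])
    }, character(1))
    stop_i <- match("*", aa)
    if (!is.na(stop_i)) aa <- aa[seq_len(stop_i - 1)]
    paste(aa, collapse = "")
  }
  n_checked <- 0
  for (i in 1:300) {
    cds <- random_cds(sample(10:40, 1))
    p <- sample(4:(nchar(cds) - 3), 1)
    old <- substr(cds, p, p)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    v <- classify_effects(cds, data.frame(cds_pos = p, type = "substitution",
                                          ref = old, alt = new))
    mut <- cds
    substr(mut, p, p) <- new
    prot_wt <- translate_oracle(cds)
    prot_mut <- translate_oracle(mut)
    oracle <- if (prot_mut == prot_wt) "synonymous"
      else if (nchar(prot_mut) < nchar(prot_wt)) "nonsense"
      else "missense"
    expect_identical(v$consequence, oracle)
    n_checked <- n_checked + 1
  }
  expect_identical(n_checked, 300)
})

test_that("frameshifts truncate and conserve the upstream protein", {
  set.seed(73)
  for (i in 1:50) {
    cds <- random_cds(40)
    p <- sample(10:60, 1)
    v <- classify_effects(cds, data.frame(cds_pos = p, type = "insertion",
                                          ref = "", alt = sample(c("A", "C", "G", "T"), 1)))
    expect_identical(v$consequence, "frameshift")
    mut <- bsrmap:::apply_variants(cds, v)
    prot_wt <- bsrmap:::translate_to_stop(cds)
    prot_mut <- bsrmap:::translate_to_stop(mut)
    expect_identical(nchar(prot_mut), v$truncated_protein_length)
    # conserved exactly up to the codon containing the indel
    upstream <- (ceiling(p / 3)) - 1
    keep <- min(upstream, nchar(prot_mut), nchar(prot_wt))
    expect_identical(substr(prot_mut, 1, keep), substr(prot_wt, 1, keep))
  }
})

test_that("the candidate-gene fixture classifies as planted", {
  fx <- make_candidate_gene_fixture(seed = 1)
  rep_ <- variant_report(fx$wt_gene, fx$mut_gene, fx$exons,
                         domain = c(6, 143))
  v <- rep_$variants
  expect_identical(nrow(v), 3L)
  expect_setequal(v$consequence, c("synonymous", "missense", "frameshift"))
  mis <- v[v$consequence == "missense", ]
  expect_identical(mis$aa_change, "Arg132Lys")
  expect_identical(mis$cds_pos, 395L)
  expect_true(mis$in_domain)
  fs <- v[v$consequence == "frameshift", ]
  expect_identical(fs$truncated_protein_length,
                   fx$truth$truncated_protein_length)
  expect_lt(fs$truncated_protein_length, fx$truth$wt_protein_length)
  expect_identical(rep_$wt_protein_length, fx$truth$wt_protein_length)
})

test_that("domain_overlap is inclusive on both boundaries", {
  expect_true(domain_overlap(132, c(6, 143)))
  expect_false(domain_overlap(5, c(6, 143)))
  expect_true(domain_overlap(6, c(6, 143)))
  expect_true(domain_overlap(143, c(6, 143)))
  expect_false(domain_overlap(144, c(6, 143)))
  expect_error(domain_overlap(10, c(9, 3)), "start <= end")
})
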