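test_that("recombinant gametes are counted as AB + 2 x BB", {
  tbl <- data.frame(
    id = sprintf("i%02d", 1:10),
    phenotype = "wildtype",
    M1 = c(rep("AA", 10)),
    M2 = c(rep("AA", 4), rep("AB", 5), "BB"),
    M3 = c(rep("AA", 8), NA, "AB"))
  expect_identical(count_recombinant_gametes(tbl, "M1"),
                   list(count = 0L, n = 10L))
  expect_identical(count_recombinant_gametes(tbl, "M2"),
                   list(count = 7L, n = 10L))
  # missing genotypes excluded marker-wise
  expect_identical(count_recombinant_gametes(tbl, "M3"),
                   list(count = 1L, n = 9L))
  tbl$phenotype[1] <- "mutant"
  expect_error(count_recombinant_gametes(tbl, "M1"), "recessive")
})

test_that("recombination fraction is count / 2n with a 0.5 cap", {
  expect_identical(recombination_fraction(0, 1331), 0)
  expect_equal(recombination_fraction(41, 1331), 41 / 2662)
  expect_warning(r <- recombination_fraction(2662, 1331), "capped")
  expect_identical(r, 0.5)
  expect_error(recombination_fraction(5, 0), "positive integer")
  expect_error(recombination_fraction(30, 10), "\\[0, 2n\\]")
})

test_that("Kosambi distances match closed-form values", {
  expect_identical(kosambi_distance(0), 0)
  expect_equal(kosambi_distance(0.25), 25 * log(3))
  # gamete counting with n = 1331 reproduces the conventional cM figures
  expect_equal(round(kosambi_distance(2 / 2662), 2), 0.08)
  expect_equal(round(kosambi_distance(1 / 2662), 2), 0.04)
  expect_equal(round(kosambi_distance(41 / 2662), 2), 1.54)
  expect_error(kosambi_distance(0.5), "unbounded")
})

test_that("Kosambi properties: small-r limit, round trip, monotonicity", {
  r <- seq(1e-5, 0.0099, length.out = 50)
  expect_true(all(abs(kosambi_distance(r) - 100 * r) / (100 * r) < 0.01))
  r2 <- seq(0, 0.49, length.out = 200)
  expect_equal(kosambi_inverse(kosambi_distance(r2)), r2, tolerance = 1e-12)
  expect_true(all(diff(kosambi_distance(r2)) > 0))
})

test_that("map distance is recovered across replicates (parameter recovery)", {
  # recessive-class model: each of the 2n gametes is independently
  # recombinant with probability r*; this oracle-level simulation isolates
  # the estimator (meiosis itself is exercised in test-simdata.R)
  set.seed(61)
  n <- 1331
  for (d_true in c(0.1, 1, 5)) {
    r_true <- kosambi_inverse(d_true)
    est <- replicate(200, {
      count <- rbinom(1, 2 * n, r_true)
      kosambi_distance(recombination_fraction(count, n))
    })
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - d_true), 3 * se + 1e-9)
  }
})

test_that("sides are assigned from shared recombinant individuals", {
  ids <- sprintf("i%02d", 1:40)
  tbl <- data.frame(id = ids, phenotype = "wildtype",
                    ML = "AA", MLfar = "AA", MR = "AA",
                    stringsAsFactors = FALSE)
  # left-side markers share recombinants (nested sets); right disjoint
  tbl$ML[1:2] <- "AB"
  tbl$MLfar[1:4] <- "AB"
  tbl$MR[11:13] <- "AB"
  positions <- data.frame(marker = c("MLfar", "ML", "MR"),
                          chrom = "C1", pos = c(1e6, 2e6, 3e6))
  res <- assign_sides(tbl, marker_map(tbl, positions))
  expect_identical(res$side[res$marker == "ML"],
                   res$side[res$marker == "MLfar"])
  expect_false(res$side[res$marker == "MR"] ==
                 res$side[res$marker == "ML"])
  expect_identical(res$side[res$marker == "MLfar"], "left")
  expect_identical(res$side[res$marker == "MR"], "right")
})

test_that("zero-recombinant markers stay unassigned and cannot flank", {
  tbl <- data.frame(id = sprintf("i%d", 1:20), phenotype = "wildtype",
                    M1 = "AA", M2 = "AA")
  tbl$M2[1] <- "AB"
  positions <- data.frame(marker = c("M1", "M2"), chrom = "C1",
                          pos = c(1e6, 2e6))
  res <- assign_sides(tbl, marker_map(tbl, positions))
  expect_identical(res$side[res$marker == "M1"], "unassigned")
  expect_error(flanking_interval(res), "not flanked")
})

test_that("flanking_interval picks the minimum-distance marker per side", {
  res <- data.frame(
    marker = c("A", "B", "C", "D"),
    chrom = "C1", pos = c(1e6, 1.9e6, 2.1e6, 3e6),
    recombinants = c(40, 2, 1, 11), n = 1331,
    r = c(40, 2, 1, 11) / 2662,
    cM = round(kosambi_distance(c(40, 2, 1, 11) / 2662), 2),
    side = c("left", "left", "right", "right"))
  fi <- flanking_interval(res)
  expect_identical(fi$left$marker, "B")   # 0.08 cM side minimum
  expect_identical(fi$right$marker, "C")  # 0.04 cM side minimum
  expect_identical(fi$span_bp, 2.1e6 - 1.9e6)
})

test_that("simulated panel maps the locus between the closest markers", {
  spec <- tiny_spec()
  pop <- simulate_f2(spec, 4000, seed = 62)
  geno <- genotype_markers(pop, spec, "wildtype")
  fm <- fine_map(geno, spec$marker_positions)
  res <- fm$markers
  # sides must match physical placement around the causal locus (10 Mb)
  assigned <- res[res$side != "unassigned", ]
  expect_true(all(assigned$side[assigned$pos < 1e7] == "left"))
  expect_true(all(assigned$side[assigned$pos > 1e7] == "right"))
  expect_false(is.null(fm$interval))
  expect_lte(fm$interval$left$pos, 1e7)
  expect_gte(fm$interval$right$pos, 1e7)
  # estimated distances are near truth (0.5 / 2 cM markers)
  far <- res[res$marker %in% c("L2", "R2"), ]
  expect_true(all(abs(far$cM - 2) < 1))
})
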