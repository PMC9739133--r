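test_that("zero genetic length gives pure parental haplotypes", {
  pop <- simulate_f2(frozen_spec(), 100, seed = 1)
  for (ind in unclass(pop)) {
    for (g in ind$gametes) {
      expect_length(g$C1$switches, 0)
    }
  }
})

test_that("dominant one-locus model segregates 3:1", {
  pop <- simulate_f2(tiny_spec(), 10000, seed = 2)
  n_mut <- sum(phenotypes(pop) == "mutant")
  se <- sqrt(10000 * 0.75 * 0.25)
  expect_lt(abs(n_mut - 7500), 3 * se)
})

test_that("Mendelian recovery: mutant fraction in exact binomial 99% interval", {
  n <- 2000
  pop <- simulate_f2(tiny_spec(), n, seed = 3)
  n_mut <- sum(phenotypes(pop) == "mutant")
  expect_gte(n_mut, qbinom(0.005, n, 0.75))
  expect_lte(n_mut, qbinom(0.995, n, 0.75))
})

test_that("recessive-class purity holds exactly", {
  spec <- tiny_spec()
  pop <- simulate_f2(spec, 500, seed = 4)
  wt <- unclass(pop)[phenotypes(pop) == "wildtype"]
  dos <- bsrmap:::dosage_matrix(wt, spec$causal_locus$chrom,
                                spec$causal_locus$pos)
  expect_true(all(dos == 0L))
})

test_that("gamete recombination fraction matches the Haldane expectation", {
  spec <- tiny_spec()
  pop <- simulate_f2(spec, 5000, seed = 5)  # 10,000 gametes
  p1 <- 5e6; p2 <- 10e6  # 10 cM apart -> d = 0.1 Morgan
  rec <- 0L
  for (ind in unclass(pop)) {
    for (g in ind$gametes) {
      o <- bsrmap:::origin_at(g, "C1", c(p1, p2))
      rec <- rec + (o[1] != o[2])
    }
  }
  r_exp <- (1 - exp(-2 * 0.1)) / 2
  se <- sqrt(r_exp * (1 - r_exp) / 10000)
  expect_lt(abs(rec / 10000 - r_exp), 3 * se)
})

test_that("populations and phenotype counts are seed-reproducible", {
  a <- simulate_f2(tiny_spec(), 117, seed = 42)
  b <- simulate_f2(tiny_spec(), 117, seed = 42)
  expect_identical(unclass(a), unclass(b))
  counts <- table(phenotypes(a))
  # the 117-plant F2 design: counts must be consistent with 3:1
  test <- chi_square_gof(c(counts[["mutant"]], counts[["wildtype"]]), c(3, 1))
  expect_true(test$pass)
})

test_that("simulate_f2 validates its inputs", {
  expect_error(simulate_f2(tiny_spec(), 0, seed = 1), "positive integer")
  expect_error(simulate_f2(tiny_spec(), 10, seed = 1, bp_per_cM = 0),
               "positive")
  expect_error(genome_spec(data.frame(chrom = character(0),
                                      length = numeric(0)),
                           data.frame(), list()), "no chromosomes")
})

test_that("build_bulks draws disjoint class-matched subsets", {
  pop <- simulate_f2(tiny_spec(), 400, seed = 6)
  design <- bulk_design(n_mutant_bulk = 50, n_wildtype_bulk = 20)
  bulks <- build_bulks(pop, design, seed = 7)
  expect_length(bulks$mutant, 50)
  expect_length(bulks$wildtype, 20)
  expect_true(all(phenotypes(bulks$mutant) == "mutant"))
  expect_true(all(phenotypes(bulks$wildtype) == "wildtype"))
  expect_length(intersect(attr(bulks$mutant, "indices"),
                          attr(bulks$wildtype, "indices")), 0)
  again <- build_bulks(pop, design, seed = 7)
  expect_identical(attr(bulks$mutant, "indices"),
                   attr(again$mutant, "indices"))
})

test_that("build_bulks errors name the class and shortfall", {
  pop <- simulate_f2(tiny_spec(), 117, seed = 8)
  ph <- table(phenotypes(pop))
  need <- ph[["wildtype"]] + 23
  expect_error(
    build_bulks(pop, bulk_design(n_mutant_bulk = 1, n_wildtype_bulk = need)),
    "wildtype.*shortfall 23")
})

test_that("allele depths reflect the bulk's true allele pool", {
  spec <- tiny_spec()
  pop <- simulate_f2(spec, 400, seed = 9)
  design <- bulk_design(mean_depth = 50, depth_dispersion = Inf)
  bulks <- build_bulks(pop, design, seed = 10)
  tab <- sample_allele_depths(bulks$wildtype, spec, design, seed = 11)
  # recessive bulk carries no mutant allele at the causal locus
  at_locus <- tab[tab$pos == spec$causal_locus$pos, ]
  expect_identical(at_locus$depth_G, 0L)  # allele_b is G in tiny_spec
  expect_gt(at_locus$depth_A, 0L)
})

test_that("mutant-bulk allele frequency at the locus approaches 2/3", {
  spec <- tiny_spec()
  pop <- simulate_f2(spec, 400, seed = 12)
  design <- bulk_design(n_mutant_bulk = 50, n_wildtype_bulk = 20,
                        mean_depth = 10000, depth_dispersion = Inf)
  bulks <- build_bulks(pop, design, seed = 13)
  tab <- sample_allele_depths(bulks$mutant, spec, design, seed = 14)
  at_locus <- tab[tab$pos == spec$causal_locus$pos, ]
  freq_b <- at_locus$depth_G / (at_locus$depth_A + at_locus$depth_G)
  # dominant class is 1 VV : 2 Vv, so pool allele frequency 2/3;
  # SE dominated by the finite bulk of 50 individuals (100 alleles)
  se <- sqrt((2 / 3) * (1 / 3) / 100)
  expect_lt(abs(freq_b - 2 / 3), 3 * se)
})

test_that("genotype_markers reads true origins per phenotype class", {
  spec <- tiny_spec()
  pop <- simulate_f2(spec, 2000, seed = 15)
  geno <- genotype_markers(pop, spec, "wildtype")
  expect_true(all(geno$phenotype == "wildtype"))
  # marker 0.5 cM from the locus: expected B-gamete count ~ 2 n r
  n <- nrow(geno)
  b_gam <- sum(geno$R05 == "AB") + 2 * sum(geno$R05 == "BB")
  expect_lt(abs(b_gam - 2 * n * 0.005), 3 * sqrt(2 * n * 0.005) + 1)
})

test_that("empty phenotype class yields an empty genotype table", {
  pop <- simulate_f2(frozen_spec(), 30, seed = 16)
  ph <- phenotypes(pop)
  cls <- if (any(ph == "wildtype")) "mutant" else "wildtype"
  # frozen genome: every individual is fully parental, so one class can be
  # emptied by filtering on the rarer phenotype of a tiny population
  few <- structure(unclass(pop)[ph == ph[1]], class = "f2_population")
  other <- setdiff(c("mutant", "wildtype"), ph[1])
  geno <- genotype_markers(few, frozen_spec(), other)
  expect_identical(nrow(geno), 0L)
  expect_true("M1" %in% names(geno))
})
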