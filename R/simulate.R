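#' Simulate an F2 population segregating one dominant locus
#'
#' Each F2 individual is formed from two independent F1 gametes. A gamete
#' is produced by meiosis without crossover interference: the crossover
#' count per chromosome is Poisson with mean equal to the chromosome's
#' genetic length in Morgans (`length / (bp_per_cM * 100)`), crossover
#' positions are uniform, and the parental origin of the leftmost segment
#' is a fair coin. The phenotype follows a one-locus dominant model: an
#' individual is `mutant` iff at least one haplotype carries the
#' mutant-parent (`B`) origin at the causal locus.
#'
#' @param spec a [genome_spec()].
#' @param n number of individuals (>= 1).
#' @param seed integer seed; identical `(spec, n, seed)` reproduce the
#'   population exactly.
#' @param bp_per_cM physical-to-genetic scale; defaults to the one stored
#'   in `spec`.
#' @return An object of class `f2_population`: a list of individuals, each
#'   holding two gamete haplotypes (per-chromosome origin switch points)
#'   and a phenotype in `{"mutant", "wildtype"}`.
#' @examples
#' spec <- default_genome_spec(n_snvs = 100)
#' pop <- simulate_f2(spec, 117, seed = 42)
#' table(phenotypes(pop))
#' @export
simulate_f2 <- function(spec, n, seed = NULL, bp_per_cM = spec$bp_per_cM) {
  if (!inherits(spec, "genome_spec")) stop_("`spec` must be a genome_spec")
  if (!is_count(n) || n < 1) stop_("`n` must be a positive integer")
  if (!is.numeric(bp_per_cM) || bp_per_cM <= 0) {
    stop_("`bp_per_cM` must be positive")
  }
  chroms <- spec$chromosomes
  morgans <- chroms$length / (bp_per_cM * 100)

  with_seed(seed, {
    individuals <- vector("list", n)
    for (i in seq_len(n)) {
      gametes <- list(
        meiosis_gamete(chroms, morgans),
        meiosis_gamete(chroms, morgans)
      )
      individuals[[i]] <- list(id = sprintf("F2_%04d", i), gametes = gametes)
    }
    # phenotype under complete dominance of the B (mutant-parent) allele
    for (i in seq_len(n)) {
      orig <- vapply(individuals[[i]]$gametes, function(g) {
        origin_at(g, spec$causal_locus$chrom, spec$causal_locus$pos)
      }, integer(1))
      individuals[[i]]$phenotype <-
        if (any(orig == 1L)) "mutant" else "wildtype"
    }
    structure(individuals, class = "f2_population", spec = spec)
  })
}

# One meiotic gamete: per chromosome, a starting parental origin (0 = A,
# 1 = B) and sorted crossover positions.
meiosis_gamete <- function(chroms, morgans) {
  g <- vector("list", nrow(chroms))
  names(g) <- chroms$chrom
  for (j in seq_len(nrow(chroms))) {
    nco <- rpois(1L, morgans[j])
    switches <- if (nco > 0L) sort(runif(nco, 0, chroms$length[j])) else numeric(0)
    g[[j]] <- list(start = sample(0:1, 1L), switches = switches)
  }
  g
}

# Parental origin (0 = A, 1 = B) of a gamete at one or more positions.
origin_at <- function(gamete, chrom, pos) {
  seg <- gamete[[chrom]]
  if (is.null(seg)) stop_("unknown chromosome: ", chrom)
  as.integer((seg$start + findInterval(pos, seg$switches)) %% 2L)
}

#' @export
print.f2_population <- function(x, ...) {
  ph <- phenotypes(x)
  cat("f2_population:", length(x), "individuals (",
      sum(ph == "mutant"), "mutant /", sum(ph == "wildtype"), "wildtype )\n")
  invisible(x)
}

#' Phenotypes of a simulated population
#' @param pop an `f2_population`.
#' @return Character vector in `{"mutant", "wildtype"}`.
#' @export
phenotypes <- function(pop) {
  vapply(pop, function(ind) ind$phenotype, character(1))
}

# Matrix of B-allele dosages (0/1/2) for a set of individuals at given
# positions on one chromosome; rows = individuals, cols = positions.
dosage_matrix <- function(individuals, chrom, pos) {
  m <- vapply(individuals, function(ind) {
    origin_at(ind$gametes[[1]], chrom, pos) +
      origin_at(ind$gametes[[2]], chrom, pos)
  }, integer(length(pos)))
  # vapply drops to a plain vector when length(pos) == 1
  if (is.null(dim(m))) matrix(m, ncol = 1L) else t(m)
}

#' Bulk design for BSR-seq pools
#'
#' @param n_mutant_bulk,n_wildtype_bulk individuals pooled per bulk
#'   (default 50/50, the BSR-seq bulk construction; a 50/20 preset matching
#'   the alternative field design is equally valid).
#' @param mean_depth expected sequencing depth per SNV site.
#' @param depth_dispersion negative-binomial size parameter of the per-site
#'   depth distribution; `Inf` gives Poisson depth. RNA-seq coverage is
#'   overdispersed, so the default is finite.
#' @return An object of class `bulk_design`.
#' @export
bulk_design <- function(n_mutant_bulk = 50, n_wildtype_bulk = 50,
                        mean_depth = 100, depth_dispersion = 10) {
  if (!is_count(n_mutant_bulk) || n_mutant_bulk < 1 ||
      !is_count(n_wildtype_bulk) || n_wildtype_bulk < 1) {
    stop_("bulk sizes must be integers >= 1")
  }
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop_("`mean_depth` must be positive")
  }
  if (!is.numeric(depth_dispersion) || depth_dispersion <= 0) {
    stop_("`depth_dispersion` must be positive (Inf for Poisson)")
  }
  structure(
    list(n_mutant_bulk = n_mutant_bulk, n_wildtype_bulk = n_wildtype_bulk,
         mean_depth = mean_depth, depth_dispersion = depth_dispersion),
    class = "bulk_design"
  )
}

#' Draw the two phenotype bulks from a population
#'
#' Bulks are disjoint random subsets of the matching phenotype class:
#' `n_mutant_bulk` mutant individuals form the Var bulk and
#' `n_wildtype_bulk` wildtype individuals form the CK bulk.
#'
#' @param pop an `f2_population`.
#' @param design a [bulk_design()].
#' @param seed integer seed; the same seed reproduces bulk membership.
#' @return List with elements `mutant` and `wildtype`, each a list of
#'   individuals (class `f2_bulk`).
#' @export
build_bulks <- function(pop, design = bulk_design(), seed = NULL) {
  if (!inherits(pop, "f2_population")) stop_("`pop` must be an f2_population")
  ph <- phenotypes(pop)
  avail <- c(mutant = sum(ph == "mutant"), wildtype = sum(ph == "wildtype"))
  want <- c(mutant = design$n_mutant_bulk, wildtype = design$n_wildtype_bulk)
  for (cls in names(want)) {
    if (avail[[cls]] < want[[cls]]) {
      stop_(sprintf(
        "insufficient %s individuals: need %d, have %d (shortfall %d)",
        cls, want[[cls]], avail[[cls]], want[[cls]] - avail[[cls]]))
    }
  }
  with_seed(seed, {
    pick <- function(cls) {
      idx <- which(ph == cls)
      sel <- sort(sample(idx, want[[cls]]))
      structure(unclass(pop)[sel], class = "f2_bulk",
                phenotype = cls, indices = sel)
    }
    list(mutant = pick("mutant"), wildtype = pick("wildtype"))
  })
}

#' Sample per-SNV allele depths for one bulk
#'
#' For every SNV site, total depth is drawn from a negative-binomial
#' distribution with mean `design$mean_depth` and size
#' `design$depth_dispersion` (Poisson when the dispersion is infinite);
#' reads are then assigned to the two parental alleles by sampling with
#' replacement from the bulk's true allele pool at that site.
#'
#' @param bulk an `f2_bulk` (or plain list of individuals).
#' @param spec the [genome_spec()] the bulk was simulated from.
#' @param design a [bulk_design()].
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `pos`, `ref` (the
#'   wildtype-parent base) and `depth_A`, `depth_C`, `depth_G`, `depth_T`.
#' @export
sample_allele_depths <- function(bulk, spec, design = bulk_design(),
                                 seed = NULL) {
  if (length(bulk) == 0L) stop_("`bulk` is empty")
  sites <- spec$snv_sites
  with_seed(seed, {
    out <- matrix(0L, nrow = nrow(sites), ncol = 4L,
                  dimnames = list(NULL, NUCLEOTIDES))
    for (ch in unique(sites$chrom)) {
      rows <- which(sites$chrom == ch)
      pos <- sites$pos[rows]
      dos <- dosage_matrix(bulk, ch, pos)
      p_b <- colSums(dos) / (2L * length(bulk))
      depth <- if (is.infinite(design$depth_dispersion)) {
        rpois(length(pos), design$mean_depth)
      } else {
        rnbinom(length(pos), size = design$depth_dispersion,
                mu = design$mean_depth)
      }
      d_b <- rbinom(length(pos), depth, p_b)
      d_a <- depth - d_b
      out[cbind(rows, match(sites$allele_a[rows], NUCLEOTIDES))] <- d_a
      out[cbind(rows, match(sites$allele_b[rows], NUCLEOTIDES))] <-
        out[cbind(rows, match(sites$allele_b[rows], NUCLEOTIDES))] + d_b
    }
    data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$allele_a,
               depth_A = out[, "A"], depth_C = out[, "C"],
               depth_G = out[, "G"], depth_T = out[, "T"])
  })
}

#' Simulate the joint allele-depth table for both bulks
#'
#' Convenience wrapper producing the canonical allele-depth table consumed
#' by [bsa_scan()]: Var (mutant bulk) and CK (wildtype bulk) depths side by
#' side.
#'
#' @inheritParams sample_allele_depths
#' @param bulks result of [build_bulks()].
#' @return data.frame with columns `chrom`, `pos`, `ref`,
#'   `var_A..var_T`, `ck_A..ck_T`.
#' @export
simulate_bulk_depths <- function(bulks, spec, design = bulk_design(),
                                 seed = NULL) {
  var <- sample_allele_depths(bulks$mutant, spec, design,
                              seed = derive_seed(seed, 1L))
  ck <- sample_allele_depths(bulks$wildtype, spec, design,
                             seed = derive_seed(seed, 2L))
  out <- var[c("chrom", "pos", "ref")]
  names(var)[4:7] <- paste0("var_", NUCLEOTIDES)
  names(ck)[4:7] <- paste0("ck_", NUCLEOTIDES)
  cbind(out, var[4:7], ck[4:7])
}

#' Genotype the marker panel on a phenotype class
#'
#' Codominant genotypes are read off the true haplotype origins:
#' `AA` = homozygous wildtype-parent origin, `BB` = homozygous
#' mutant-parent origin, `AB` = heterozygous.
#'
#' @param pop an `f2_population`.
#' @param spec the [genome_spec()] (must carry `marker_positions`).
#' @param phenotype_filter one of `"wildtype"`, `"mutant"`, `"all"`; fine
#'   mapping conventionally retains the recessive (wildtype) class.
#' @return data.frame with columns `id`, `phenotype` and one genotype
#'   column per marker. Zero retained individuals give a zero-row table.
#' @export
genotype_markers <- function(pop, spec,
                             phenotype_filter = c("wildtype", "mutant", "all")) {
  if (is.null(spec$marker_positions)) stop_("spec has no marker panel")
  phenotype_filter <- match.arg(phenotype_filter)
  ph <- phenotypes(pop)
  keep <- if (phenotype_filter == "all") seq_along(pop) else which(ph == phenotype_filter)
  mk <- spec$marker_positions
  out <- data.frame(
    id = vapply(unclass(pop)[keep], `[[`, character(1), "id"),
    phenotype = ph[keep],
    stringsAsFactors = FALSE
  )
  codes <- c("AA", "AB", "BB")
  for (j in seq_len(nrow(mk))) {
    if (length(keep) == 0L) {
      out[[mk$marker[j]]] <- character(0)
    } else {
      dos <- dosage_matrix(unclass(pop)[keep], mk$chrom[j], mk$pos[j])
      out[[mk$marker[j]]] <- codes[dos[, 1L] + 1L]
    }
  }
  out
}
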