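#' Count recombinant gametes at a marker in the recessive class
#'
#' In the homozygous-recessive mapping class every individual carries two
#' wildtype alleles at the locus, so each mutant-parent (`B`) allele seen
#' at a linked marker arrived on a gamete that recombined between marker
#' and locus: an `AB` individual contributes one recombinant gamete and a
#' `BB` individual two. Missing genotypes are excluded marker-wise.
#'
#' @param table marker genotype data.frame (see [genotype_markers()] /
#'   [read_marker_genotypes()]); if a `phenotype` column is present, every
#'   individual must be `wildtype`.
#' @param marker_id name of the marker column.
#' @return List with `count` (recombinant gametes) and `n` (non-missing
#'   individuals).
#' @export
count_recombinant_gametes <- function(table, marker_id) {
  if (!marker_id %in% names(table)) stop_("unknown marker: ", marker_id)
  if ("phenotype" %in% names(table) &&
      any(table$phenotype != "wildtype")) {
    stop_("recombinant counting requires the recessive (wildtype) class only")
  }
  g <- table[[marker_id]]
  g <- g[!is.na(g) & g != ""]
  bad <- setdiff(unique(g), c("AA", "AB", "BB"))
  if (length(bad)) stop_("invalid genotype code(s): ", paste(bad, collapse = ", "))
  list(count = sum(g == "AB") + 2L * sum(g == "BB"), n = length(g))
}

#' Recombination fraction from recombinant-gamete counts
#'
#' Each recessive-class individual contributes two scored gametes, so
#' `r = count / (2n)`. Estimates above 0.5 are capped at 0.5 with a
#' warning (free recombination).
#'
#' @param count recombinant gametes, `0 <= count <= 2n`.
#' @param n genotyped individuals (>= 1).
#' @return The recombination fraction.
#' @export
recombination_fraction <- function(count, n) {
  if (!is_count(n) || n < 1) stop_("`n` must be a positive integer")
  if (!is_count(count) || count > 2 * n) {
    stop_("`count` must be an integer in [0, 2n]")
  }
  r <- count / (2 * n)
  if (r > 0.5) {
    warning("recombination fraction ", signif(r, 4),
            " exceeds 0.5; capped at 0.5", call. = FALSE)
    r <- 0.5
  }
  r
}

#' Kosambi map distance
#'
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans, the Kosambi mapping
#' function allowing partial crossover interference. For small `r`,
#' `d ~ 100 r`.
#'
#' @param r recombination fraction(s), `0 <= r < 0.5`.
#' @return Map distance(s) in cM.
#' @examples
#' kosambi_distance(41 / 2662)  # ~1.54 cM
#' @export
kosambi_distance <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop_("`r` must satisfy 0 <= r < 0.5 (distance unbounded at 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' @param d map distance(s) in cM, `d >= 0`.
#' @return Recombination fraction(s): `r = (e^(d/25) - 1) / (2 (e^(d/25) + 1))`.
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0)) stop_("`d` must be >= 0")
  e <- exp(d / 25)
  (e - 1) / (2 * (e + 1))
}

#' Per-marker linkage estimates in the recessive class
#'
#' @param table recessive-class marker genotype data.frame.
#' @param positions data.frame with columns `marker`, `chrom`, `pos`
#'   giving physical marker placement.
#' @return data.frame with columns `marker`, `chrom`, `pos`,
#'   `recombinants`, `n`, `r`, `cM` (2 decimals, matching conventional
#'   reporting precision), `side` (filled by [assign_sides()]).
#' @export
marker_map <- function(table, positions) {
  positions <- as.data.frame(positions)
  markers <- positions$marker[positions$marker %in% names(table)]
  if (length(markers) == 0L) stop_("no marker columns found in the table")
  rows <- lapply(markers, function(m) {
    cc <- count_recombinant_gametes(table, m)
    r <- recombination_fraction(cc$count, cc$n)
    data.frame(
      marker = m,
      chrom = positions$chrom[positions$marker == m],
      pos = positions$pos[positions$marker == m],
      recombinants = cc$count, n = cc$n, r = r,
      cM = if (r < 0.5) round(kosambi_distance(r), 2) else Inf,
      side = NA_character_, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# ids of recombinant individuals (AB or BB) at a marker
recombinant_ids <- function(table, marker_id) {
  g <- table[[marker_id]]
  table$id[!is.na(g) & g %in% c("AB", "BB")]
}

#' Assign markers to sides of the locus
#'
#' Two markers lie on the same side iff they share recombinant
#' individuals: the overlap of their recombinant sets must exceed
#' `concordance` of the smaller set. Side groups are then ordered by
#' physical coordinate; the group with the smaller median position is
#' `left`, the larger `right`. Markers with zero recombinants cannot
#' separate and stay `unassigned`.
#'
#' @param table recessive-class marker genotype data.frame (must carry an
#'   `id` column).
#' @param marker_results output of [marker_map()].
#' @param concordance same-side threshold on the recombinant-set overlap
#'   fraction (default 0.5 of the smaller set).
#' @return `marker_results` with the `side` column filled
#'   (`left` / `right` / `unassigned`).
#' @export
assign_sides <- function(table, marker_results, concordance = 0.5) {
  res <- marker_results
  res$side <- "unassigned"
  informative <- res$marker[res$recombinants > 0]
  if (length(informative) < 2L) {
    if (length(informative) == 1L) res$side[res$marker == informative] <- "left"
    return(res)
  }
  sets <- lapply(informative, function(m) recombinant_ids(table, m))
  names(sets) <- informative

  # union-find over the same-side relation
  parent <- seq_along(informative)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(informative)) {
    for (j in seq_len(i - 1L)) {
      a <- sets[[i]]; b <- sets[[j]]
      ov <- length(intersect(a, b)) / min(length(a), length(b))
      if (ov >= concordance) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_along(informative), find, integer(1))
  groups <- split(informative, comp)
  med <- vapply(groups, function(ms) {
    stats::median(res$pos[res$marker %in% ms])
  }, numeric(1))
  ord <- order(med)
  if (length(groups) == 1L) {
    res$side[res$marker %in% groups[[1L]]] <- "left"
  } else {
    res$side[res$marker %in% groups[[ord[1L]]]] <- "left"
    res$side[res$marker %in% groups[[ord[length(ord)]]]] <- "right"
    # middle groups (3+ components) cannot be oriented reliably
  }
  res
}

#' Select the flanking markers and candidate interval
#'
#' Picks the marker with the smallest map distance on each side of the
#' locus; the physical span is `right position - left position` (the same
#' stop − start convention as [region_length()]).
#'
#' @param marker_results output of [assign_sides()] with `side` filled.
#' @return List with `left`, `right` (one-row data.frames) and `span_bp`.
#' @export
flanking_interval <- function(marker_results) {
  pick <- function(side) {
    cand <- marker_results[marker_results$side == side, ]
    if (nrow(cand) == 0L) {
      stop_("locus not flanked: no markers assigned to the ", side, " side")
    }
    cand[order(cand$cM, -cand$pos * (side == "left") +
                 cand$pos * (side == "right")), ][1L, ]
  }
  left <- pick("left")
  right <- pick("right")
  list(left = left, right = right,
       span_bp = region_length(left$pos, right$pos))
}

#' Fine-map the locus from recessive-class marker genotypes
#'
#' Wrapper running [marker_map()], [assign_sides()] and
#' [flanking_interval()].
#'
#' @inheritParams marker_map
#' @inheritParams assign_sides
#' @return Object of class `fine_map_result` with `markers` (per-marker
#'   table) and `interval` (flanking markers and physical span, or `NULL`
#'   with a `message` when the locus is not flanked).
#' @export
fine_map <- function(table, positions, concordance = 0.5) {
  res <- marker_map(table, positions)
  res <- assign_sides(table, res, concordance = concordance)
  interval <- tryCatch(flanking_interval(res), error = function(e) NULL)
  structure(
    list(markers = res, interval = interval,
         message = if (is.null(interval)) "locus not flanked" else NULL),
    class = "fine_map_result"
  )
}

#' @export
print.fine_map_result <- function(x, ...) {
  cat("fine mapping of", nrow(x$markers), "markers\n")
  print(x$markers)
  if (!is.null(x$interval)) {
    cat(sprintf("flanking interval: %s .. %s, span %s bp\n",
                x$interval$left$marker, x$interval$right$marker,
                format(x$interval$span_bp, big.mark = ",")))
  } else {
    cat(x$message, "\n")
  }
  invisible(x)
}
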