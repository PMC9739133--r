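#' Photosynthetic pigment content from absorbance readings
#'
#' Spectrophotometric quantification of an ethanol leaf extract from
#' absorbances at 649, 665 and 470 nm:
#'
#' * Chl a = 13.95 A665 − 6.88 A649
#' * Chl b = 24.96 A649 − 7.32 A665
#' * Carotenoid = (1000 A470 − 2.05 Chl a − 114.8 Chl b) / 245
#'
#' Concentrations (mg/L extract) are converted to dry-weight content as
#' `concentration * volume_ml / mass_mg` (mg per g dry weight) — the
#' standard dilution accounting for `mass_mg` of dried tissue extracted in
#' `volume_ml` of solvent. A negative formula output (possible outside the
#' formulas' valid absorbance range) is flagged, not clipped.
#'
#' @param a649,a665,a470 absorbances (vectorized; replicates should be
#'   averaged first, see [pigment_table()]).
#' @param mass_mg dry mass in mg (default 20).
#' @param volume_ml extract volume in mL (default 10).
#' @return data.frame with concentrations `chl_a`, `chl_b`, `chl_total`,
#'   `car` (mg/L), the `chl_ab_ratio` (`NA` when Chl b is 0), dry-weight
#'   contents `chl_a_dw`, `chl_b_dw`, `chl_total_dw`, `car_dw` (mg/g DW)
#'   and an `out_of_range` flag.
#' @examples
#' pigment_content(a649 = 0.5, a665 = 1.0, a470 = 1.0)
#' @export
pigment_content <- function(a649, a665, a470 = 0, mass_mg = 20,
                            volume_ml = 10) {
  if (any(c(a649, a665, a470) < 0)) stop_("absorbances must be >= 0")
  if (any(mass_mg <= 0) || any(volume_ml <= 0)) {
    stop_("mass and volume must be positive")
  }
  chl_a <- 13.95 * a665 - 6.88 * a649
  chl_b <- 24.96 * a649 - 7.32 * a665
  car <- (1000 * a470 - 2.05 * chl_a - 114.8 * chl_b) / 245
  chl_total <- chl_a + chl_b
  ratio <- ifelse(chl_b > 0, chl_a / chl_b, NA_real_)
  dw <- volume_ml / mass_mg
  data.frame(
    chl_a = chl_a, chl_b = chl_b, chl_total = chl_total, car = car,
    chl_ab_ratio = ratio,
    chl_a_dw = chl_a * dw, chl_b_dw = chl_b * dw,
    chl_total_dw = chl_total * dw, car_dw = car * dw,
    out_of_range = chl_a < 0 | chl_b < 0 | car < 0
  )
}

#' Pigment contents for a replicated absorbance table
#'
#' Averages replicate absorbances per sample, then applies
#' [pigment_content()].
#'
#' @param readings data.frame with columns `sample`, `replicate`, `A649`,
#'   `A665`, `A470` and optionally `mass_mg`, `volume_ml`.
#' @return data.frame of per-sample pigment contents.
#' @export
pigment_table <- function(readings) {
  need <- c("sample", "A649", "A665", "A470")
  if (!all(need %in% names(readings))) {
    stop_("`readings` needs columns ", paste(need, collapse = ", "))
  }
  if (!"mass_mg" %in% names(readings)) readings$mass_mg <- 20
  if (!"volume_ml" %in% names(readings)) readings$volume_ml <- 10
  agg <- aggregate(readings[c("A649", "A665", "A470", "mass_mg", "volume_ml")],
                   by = list(sample = readings$sample), FUN = mean)
  cbind(sample = agg$sample,
        pigment_content(agg$A649, agg$A665, agg$A470,
                        mass_mg = agg$mass_mg, volume_ml = agg$volume_ml))
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Cts are averaged on the Ct scale per (gene, condition, role);
#' then `dCt = Ct_target - Ct_reference` per condition,
#' `ddCt = dCt_condition - dCt_calibrator`, and `fold = 2^-ddCt`. The
#' calibrator condition has fold 1 by construction.
#'
#' @param ct data.frame with columns `condition`, `role` (`"target"` /
#'   `"reference"`), `ct`, and optionally `gene` (multiple target genes
#'   share the reference) and `replicate`.
#' @param calibrator name of the calibrator condition.
#' @return data.frame with columns `gene`, `condition`, `delta_ct`,
#'   `delta_delta_ct`, `fold`.
#' @examples
#' ct <- data.frame(
#'   condition = c("trt", "trt", "cal", "cal"),
#'   role = c("target", "reference", "target", "reference"),
#'   ct = c(20, 18, 25, 18))
#' relative_expression(ct, "cal")  # fold 32 in trt
#' @export
relative_expression <- function(ct, calibrator) {
  need <- c("condition", "role", "ct")
  if (!all(need %in% names(ct))) {
    stop_("`ct` needs columns ", paste(need, collapse = ", "))
  }
  if (!all(ct$role %in% c("target", "reference"))) {
    stop_("`role` must be 'target' or 'reference'")
  }
  if (any(ct$ct <= 0)) stop_("Ct values must be positive")
  if (!calibrator %in% ct$condition) {
    stop_("calibrator condition '", calibrator, "' not present")
  }
  if (!"gene" %in% names(ct)) {
    ct$gene <- ifelse(ct$role == "target", "target", "reference")
  }

  ref <- ct[ct$role == "reference", ]
  tgt <- ct[ct$role == "target", ]
  if (nrow(ref) == 0L) stop_("missing reference-role Ct rows")
  if (nrow(tgt) == 0L) stop_("missing target-role Ct rows")
  ref_mean <- aggregate(list(ct = ref$ct),
                        by = list(condition = ref$condition), FUN = mean)
  tgt_mean <- aggregate(list(ct = tgt$ct),
                        by = list(gene = tgt$gene, condition = tgt$condition),
                        FUN = mean)
  out <- merge(tgt_mean, ref_mean, by = "condition",
               suffixes = c("_target", "_reference"))
  if (nrow(out) < nrow(tgt_mean)) {
    stop_("missing reference-role Ct for some condition")
  }
  out$delta_ct <- out$ct_target - out$ct_reference
  cal <- out[out$condition == calibrator, c("gene", "delta_ct")]
  names(cal)[2] <- "delta_ct_cal"
  out <- merge(out, cal, by = "gene")
  out$delta_delta_ct <- out$delta_ct - out$delta_ct_cal
  out$fold <- 2^(-out$delta_delta_ct)
  out <- out[order(out$gene, out$condition),
             c("gene", "condition", "delta_ct", "delta_delta_ct", "fold")]
  rownames(out) <- NULL
  out
}
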