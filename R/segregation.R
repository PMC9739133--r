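#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' Tests observed phenotype counts against an expected segregation ratio.
#' Without continuity correction (the default), the statistic is
#' `sum((O - E)^2 / E)` with `E = total * w / sum(w)`; the critical value
#' at `alpha` comes from the chi-square distribution with `k - 1` degrees
#' of freedom (3.84 for two classes at alpha = 0.05).
#'
#' @param observed integer vector of class counts (length >= 2).
#' @param ratio positive weight vector of the same length, e.g. `c(3, 1)`.
#' @param yates apply Yates' continuity correction (default `FALSE`;
#'   two-class Mendelian tests in the mapping literature are conventionally
#'   uncorrected).
#' @param alpha significance level for the critical value (default 0.05).
#' @return Object of class `segregation_test` with fields `observed`,
#'   `expected`, `ratio`, `chisq`, `df`, `critical`, `p_value`, `pass`
#'   (`TRUE` when `chisq < critical`, i.e. the ratio is not rejected).
#' @examples
#' chi_square_gof(c(90, 27), c(3, 1))   # chisq ~ 0.23, fits 3:1
#' chi_square_gof(c(11, 13), c(1, 1))   # chisq ~ 0.17, fits 1:1
#' @export
chi_square_gof <- function(observed, ratio, yates = FALSE, alpha = 0.05) {
  if (length(observed) != length(ratio) || length(observed) < 2L) {
    stop_("`observed` and `ratio` must have equal length >= 2")
  }
  if (any(observed < 0)) stop_("negative observed counts")
  if (any(ratio <= 0)) stop_("ratio weights must be positive")
  total <- sum(observed)
  if (total <= 0) stop_("total observed count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) stop_("zero expected count")
  dev <- abs(observed - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chisq <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  critical <- qchisq(1 - alpha, df)
  structure(
    list(observed = observed, expected = expected, ratio = ratio,
         yates = yates, chisq = chisq, df = df, alpha = alpha,
         critical = critical,
         p_value = pchisq(chisq, df, lower.tail = FALSE),
         pass = chisq < critical),
    class = "segregation_test"
  )
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf(
    "chi-square GOF: observed (%s) vs ratio (%s)\n",
    paste(x$observed, collapse = ", "), paste(x$ratio, collapse = ":")))
  cat(sprintf("  chisq = %.4f (df = %d), critical(%.2f) = %.2f, p = %.4f\n",
              x$chisq, x$df, x$alpha, x$critical, x$p_value))
  cat(if (x$pass) "  fit accepted\n" else "  fit rejected\n")
  invisible(x)
}

#' Segregation ratio of mutant to wildtype counts
#'
#' @param mutant,wildtype phenotype class counts; `wildtype` must be
#'   positive (the ratio is undefined otherwise, as in uniform crosses).
#' @return `mutant / wildtype` rounded to 3 decimals.
#' @examples
#' segregation_ratio(90, 27)  # 3.333
#' @export
segregation_ratio <- function(mutant, wildtype) {
  if (!is_count(mutant) || !is_count(wildtype)) {
    stop_("counts must be non-negative integers")
  }
  if (wildtype == 0) stop_("ratio undefined: wildtype count is 0")
  round(mutant / wildtype, 3)
}

#' Infer the inheritance model from a set of cross results
#'
#' Applies the classical single-dominant-locus checks: a uniform mutant F1
#' (and backcross to the dominant parent), an F2 fitting 3:1, and a
#' backcross to the recessive parent fitting 1:1. Population labels:
#' `P1` (mutant parent), `P2` (recessive parent), `F1`, `F2`, `BC1P1`
#' (backcross to P1), `BC1P2` (backcross to P2).
#'
#' @param crosses data.frame with columns `population`, `total`, `mutant`,
#'   `wildtype`; `mutant + wildtype` must equal `total` in each row. F1 and
#'   F2 rows are required.
#' @param alpha significance level for the chi-square tests.
#' @return Object of class `inheritance_report`: the dominance `call`
#'   (`"single dominant nuclear locus"` or a rejection message), a
#'   `consistent` flag, and the attached `tests`.
#' @export
infer_inheritance <- function(crosses, alpha = 0.05) {
  crosses <- as.data.frame(crosses)
  need <- c("population", "total", "mutant", "wildtype")
  if (!all(need %in% names(crosses))) {
    stop_("`crosses` needs columns ", paste(need, collapse = ", "))
  }
  if (any(crosses$mutant + crosses$wildtype != crosses$total)) {
    stop_("mutant + wildtype must equal total in every row")
  }
  required <- c("F1", "F2")
  missing <- setdiff(required, crosses$population)
  if (length(missing)) {
    stop_("missing required populations: ", paste(missing, collapse = ", "))
  }

  tests <- list()
  reasons <- character(0)

  f1 <- crosses[crosses$population == "F1", ]
  f1_uniform <- all(f1$wildtype == 0)
  if (!f1_uniform) {
    reasons <- c(reasons,
                 "not consistent with single dominant nuclear gene (uniform mutant F1 expected)")
  }

  f2 <- crosses[crosses$population == "F2", ][1L, ]
  tests$F2 <- chi_square_gof(c(f2$mutant, f2$wildtype), c(3, 1), alpha = alpha)
  if (!tests$F2$pass) {
    reasons <- c(reasons, "single-locus dominant model rejected (F2 departs from 3:1)")
  }

  if ("BC1P2" %in% crosses$population) {
    bc <- crosses[crosses$population == "BC1P2", ][1L, ]
    tests$BC1P2 <- chi_square_gof(c(bc$mutant, bc$wildtype), c(1, 1),
                                  alpha = alpha)
    if (!tests$BC1P2$pass) {
      reasons <- c(reasons, "backcross to recessive parent departs from 1:1")
    }
  }
  if ("BC1P1" %in% crosses$population) {
    bc1 <- crosses[crosses$population == "BC1P1", ]
    if (!all(bc1$wildtype == 0)) {
      reasons <- c(reasons, "backcross to dominant parent not uniformly mutant")
    }
  }

  consistent <- length(reasons) == 0L
  structure(
    list(
      call = if (consistent) "single dominant nuclear locus" else reasons[1L],
      consistent = consistent,
      reasons = reasons,
      f1_uniform = f1_uniform,
      tests = tests
    ),
    class = "inheritance_report"
  )
}

#' @export
print.inheritance_report <- function(x, ...) {
  cat("inheritance call:", x$call, "\n")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %s: chisq = %.4f (%s)\n", nm, t$chisq,
                if (t$pass) "fit" else "rejected"))
  }
  invisible(x)
}
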