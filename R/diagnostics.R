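# Diagnostic-performance statistics for binary predictors of amyloid status:
# 2x2 contingency construction, sensitivity/specificity/predictive values with
# exact binomial CIs, odds ratios, Fisher and chi-square tests, Cohen's kappa,
# and concordance counting.

#' 2x2 contingency table
#'
#' The positive prediction is the temporoparietal-variant (or
#' marker-present) call; the positive reference is amyloid (PIB) positivity.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (true/false
#'   positives/negatives).
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("contingency table is empty", call. = FALSE)
  out <- as.list(as.integer(cells))
  names(out) <- names(cells)
  class(out) <- "contingency_2x2"
  out
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- as.matrix(x)
  cat("2x2 contingency table (rows: prediction, cols: reference)\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
         dimnames = list(prediction = c("positive", "negative"),
                         reference = c("positive", "negative")))
}

total_2x2 <- function(x) x$tp + x$fp + x$fn + x$tn

align_labels <- function(predictions, reference, what = "prediction") {
  if (is.null(names(predictions)) || is.null(names(reference))) {
    stop("predictions and reference must be named by patient id",
         call. = FALSE)
  }
  only_pred <- setdiff(names(predictions), names(reference))
  only_ref <- setdiff(names(reference), names(predictions))
  if (length(only_pred) || length(only_ref)) {
    stop("patient id mismatch between ", what, " and reference; only in ",
         what, ": ", paste(only_pred, collapse = ", "),
         "; only in reference: ", paste(only_ref, collapse = ", "),
         call. = FALSE)
  }
  if (length(predictions) == 0L) {
    stop("empty ", what, " set", call. = FALSE)
  }
  if (anyNA(predictions) || anyNA(reference)) {
    stop("missing labels must be dropped upstream, not passed in",
         call. = FALSE)
  }
  reference[names(predictions)]
}

#' Cross-tabulate predictions against a reference standard
#'
#' @param predictions Named logical vector (names are patient ids; `TRUE` =
#'   positive call, e.g. tpv).
#' @param reference Named logical vector over the same patient ids (`TRUE` =
#'   reference positive, e.g. PIB+).
#' @return A [contingency_2x2()].
#' @export
build_contingency <- function(predictions, reference) {
  reference <- align_labels(predictions, reference)
  stopifnot(is.logical(predictions), is.logical(reference))
  contingency_2x2(tp = sum(predictions & reference),
                  fp = sum(predictions & !reference),
                  fn = sum(!predictions & reference),
                  tn = sum(!predictions & !reference))
}

# Clopper-Pearson exact interval via the beta quantile form
clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

wald_ci <- function(x, n, conf_level = 0.95) {
  p <- x / n
  se <- sqrt(p * (1 - p) / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(lower = max(0, p - z * se), upper = min(1, p + z * se))
}

#' Diagnostic performance summary
#'
#' Point estimates and 95% binomial confidence intervals for sensitivity,
#' specificity, positive and negative predictive value, and accuracy. The
#' default interval is the Clopper-Pearson exact interval, which keeps
#' nominal coverage at the small denominators typical of single-center
#' cohorts; a Wald interval is available for comparison. A statistic whose
#' denominator is zero is returned as `NA` (undefined), never as 0.
#'
#' @param table A [contingency_2x2()].
#' @param conf_level Confidence level, default 0.95.
#' @param ci_method `"clopper-pearson"` (default) or `"wald"`.
#' @return Object of class `performance_summary`: data.frame with columns
#'   `statistic`, `estimate`, `lower`, `upper`, `x` (numerator), `n`
#'   (denominator).
#' @examples
#' performance(contingency_2x2(tp = 9, fp = 4, fn = 2, tn = 10))
#' @export
performance <- function(table, conf_level = 0.95,
                        ci_method = c("clopper-pearson", "wald")) {
  stopifnot(inherits(table, "contingency_2x2"))
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method, "clopper-pearson" = clopper_pearson,
                   wald = wald_ci)
  defs <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$tn + table$fp),
    ppv = c(table$tp, table$tp + table$fp),
    npv = c(table$tn, table$tn + table$fn),
    accuracy = c(table$tp + table$tn, total_2x2(table))
  )
  rows <- lapply(names(defs), function(nm) {
    x <- defs[[nm]][1]
    n <- defs[[nm]][2]
    if (n == 0) {
      data.frame(statistic = nm, estimate = NA_real_, lower = NA_real_,
                 upper = NA_real_, x = x, n = n, stringsAsFactors = FALSE)
    } else {
      ci <- ci_fun(x, n, conf_level)
      data.frame(statistic = nm, estimate = x / n, lower = ci[["lower"]],
                 upper = ci[["upper"]], x = x, n = n,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "conf_level") <- conf_level
  attr(out, "ci_method") <- ci_method
  class(out) <- c("performance_summary", "data.frame")
  out
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Diagnostic performance (%s %.0f%% CI)\n",
              attr(x, "ci_method"), 100 * attr(x, "conf_level")))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", x$statistic[i]))
    } else {
      cat(sprintf("  %-12s %5.1f%%  (%.1f%% - %.1f%%)  [%d/%d]\n",
                  x$statistic[i], 100 * x$estimate[i], 100 * x$lower[i],
                  100 * x$upper[i], x$x[i], x$n[i]))
    }
  }
  invisible(x)
}

#' Sample odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `(tp*tn)/(fp*fn)` with the Woolf log-normal 95%
#' interval. When any cell is zero the Haldane-Anscombe correction (+0.5 to
#' every cell) is applied, guaranteeing a finite estimate;
#' `correction_applied` records it.
#'
#' @param table A [contingency_2x2()].
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `odds_ratio_result`: list with `or_estimate`,
#'   `ci95` (lower, upper), `correction_applied`.
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$tp, table$fp, table$fn, table$tn)
  correction <- any(cells == 0)
  if (correction) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se_log <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(or_estimate = or,
              ci95 = c(lower = exp(log(or) - z * se_log),
                       upper = exp(log(or) + z * se_log)),
              correction_applied = correction)
  class(out) <- "odds_ratio_result"
  out
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("Odds ratio %.2f (95%% CI %.2f - %.2f)%s\n", x$or_estimate,
              x$ci95[["lower"]], x$ci95[["upper"]],
              if (x$correction_applied) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional exact test by hypergeometric enumeration. The two-sided
#' p-value uses the probability-mass criterion: the sum of probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one. One-sided alternatives are upper (`"greater"`: association in the
#' tp/tn direction) or lower (`"less"`) tails.
#'
#' @param table A [contingency_2x2()].
#' @param sided `"two"` (default), `"greater"`, or `"less"`.
#' @return p-value in \[0, 1\].
#' @export
fisher_exact <- function(table, sided = c("two", "greater", "less")) {
  stopifnot(inherits(table, "contingency_2x2"))
  sided <- match.arg(sided)
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  unname(stats::fisher.test(as.matrix(table), alternative = alt)$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson statistic against the
#' 1-df chi-square reference distribution. Any zero margin makes the
#' statistic undefined; `NA` is returned for both fields.
#'
#' @param table A [contingency_2x2()].
#' @return List with `statistic` and `p_value`.
#' @export
chi_square <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Cohen's kappa for paired categorical ratings
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po` and expected agreement `pe` from the marginal products.
#' When `pe = 1` (both raters degenerate on the same single category) kappa
#' is defined as 1 if agreement is perfect, otherwise the marginals are
#' degenerate and an error is raised.
#'
#' @param ratings_a,ratings_b Equal-length vectors of paired labels.
#' @return Object of class `kappa_result`: list with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n`.
#' @examples
#' cohens_kappa(c("FV", "FV", "TPV"), c("FV", "TPV", "TPV"))
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 1L) {
    stop("ratings must be paired vectors of equal length >= 1", call. = FALSE)
  }
  if (anyNA(ratings_a) || anyNA(ratings_b)) {
    stop("missing ratings are not allowed", call. = FALSE)
  }
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  n <- length(a)
  tab <- table(a, b)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - .Machine$double.eps^0.5) {
    if (po >= 1 - .Machine$double.eps^0.5) {
      kappa <- 1
    } else {
      stop("degenerate marginals: expected agreement is 1 but observed is not",
           call. = FALSE)
    }
  } else {
    kappa <- (po - pe) / (1 - pe)
  }
  out <- list(kappa = kappa, observed_agreement = po, expected_agreement = pe,
              n = n)
  class(out) <- "kappa_result"
  out
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.2f (po = %.3f, pe = %.3f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' Count concordant binary calls
#'
#' Number of patients whose call matches the reference label.
#'
#' @param calls,reference Named logical vectors over the same patient ids.
#' @return Integer count of matches, with attribute `n` (number compared).
#' @export
concordance_count <- function(calls, reference) {
  reference <- align_labels(calls, reference, what = "calls")
  out <- sum(calls == reference)
  attr(out, "n") <- length(calls)
  out
}

#' Round half away from zero
#'
#' Reporting helper matching the conventional half-up rounding of printed
#' percentages (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 0.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
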