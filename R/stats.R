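# Diagnostic-accuracy and agreement statistics.

#' Confusion table
#'
#' @param tp,fp,fn,tn Non-negative counts (test vs gold standard).
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(as.list(v), class = "confusion_table")
}

#' Confusion table from per-case verdicts
#'
#' @param test,gold Logical vectors (test positivity vs gold-standard
#'   positivity).
#' @return A [confusion_table()].
#' @export
confusion_from_verdicts <- function(test, gold) {
  stopifnot(length(test) == length(gold))
  confusion_table(tp = sum(test & gold), fp = sum(test & !gold),
                  fn = sum(!test & gold), tn = sum(!test & !gold))
}

#' Sensitivity and specificity in percent
#'
#' @param ct A [confusion_table()].
#' @return List with `sensitivity` and `specificity` (exact percents) and
#'   their integer-rounded copies (`*_rounded`, half away from zero).
#' @export
sensitivity_specificity <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct$tp + ct$fn == 0 || ct$tn + ct$fp == 0)
    stop("undefined metric: empty positive or negative margin", call. = FALSE)
  sens <- 100 * ct$tp / (ct$tp + ct$fn)
  spec <- 100 * ct$tn / (ct$tn + ct$fp)
  list(sensitivity = sens, specificity = spec,
       sensitivity_rounded = as.integer(round_half_away(sens)),
       specificity_rounded = as.integer(round_half_away(spec)))
}

#' ROC area under the curve for an ordinal score
#'
#' The Mann-Whitney form `AUC = P(score+ > score-) + 0.5 P(tie)`, computed
#' with midranks; identical to the trapezoidal area under the empirical ROC
#' curve, and valid for binary, ordinal or continuous scores.
#'
#' @param scores Numeric (or ordered) score per case; higher means more
#'   test-positive.
#' @param gold Logical gold-standard status per case.
#' @return The AUC as a proportion in `[0, 1]`.
#' @export
roc_auc_ordinal <- function(scores, gold) {
  scores <- as.numeric(scores)
  gold <- as.logical(gold)
  stopifnot(length(scores) == length(gold))
  np <- sum(gold); nn <- sum(!gold)
  if (np == 0L || nn == 0L)
    stop("undefined metric: gold standard has a single class", call. = FALSE)
  r <- rank(scores)
  (sum(r[gold]) - np * (np + 1) / 2) / (np * nn)
}

#' Cohen's kappa and percent agreement
#'
#' @param t A k x k agreement matrix (rater A in rows, rater B in columns).
#' @return List with `kappa`, `agreement_percent` (observed agreement, in
#'   percent), `p_observed`, `p_expected`.
#' @export
cohens_kappa <- function(t) {
  t <- as.matrix(t)
  if (nrow(t) != ncol(t)) stop("agreement table must be square", call. = FALSE)
  if (any(t < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(t)
  if (n == 0) stop("empty agreement table", call. = FALSE)
  po <- sum(diag(t)) / n
  pe <- sum(rowSums(t) * colSums(t)) / n^2
  if (abs(1 - pe) < 1e-12)
    stop("undefined metric: degenerate marginals (chance agreement is 1)",
         call. = FALSE)
  list(kappa = (po - pe) / (1 - pe),
       agreement_percent = 100 * po,
       p_observed = po, p_expected = pe)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided; exact when both samples have at most 10 observations and no
#' ties, otherwise normal approximation with continuity and tie correction
#' (the standard `stats::wilcox.test` semantics, surfaced behind this
#' module's contract). Identical samples with zero spread return p = 1 with
#' a warning rather than an error.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (rank-sum W of `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be nonempty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples: p = 1", call. = FALSE)
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  ties <- any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided",
    exact = (length(x) <= 10L && length(y) <= 10L && !ties),
    correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; midranks on tied absolute differences;
#' exact p when at most 15 nonzero pairs without ties, otherwise normal
#' approximation with continuity correction. All-zero differences are an
#' error (the statistic is undefined).
#'
#' @param x,y Paired numeric samples of equal length.
#' @return List with `statistic` (V, the positive-rank sum) and `p`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  if (!length(d))
    stop("undefined statistic: all paired differences are zero",
         call. = FALSE)
  ties <- any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(
    d, alternative = "two.sided",
    exact = (length(d) <= 15L && !ties),
    correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Evaluate a per-case results table
#'
#' Computes the full diagnostic report for a cohort: detection rates of both
#' methods, sensitivity/specificity of the asymmetry method against the P-I
#' gold standard, ordinal ROC-AUC from the SD level, laterality and region
#' concordances, and the rank-sum test of scan delay against asymmetry
#' positivity (when delays are present).
#'
#' @param results A data frame (or CSV path) with columns `case_id`,
#'   `asym_positive`, `asym_level` (0, 1.5 or 2), `pi_positive`, and
#'   optionally `lat_asym`, `lat_semiology`, `lat_eeg`, `region_asym`,
#'   `region_eeg`, `t_seizure_to_spect_h`.
#' @return A list of metrics (class `perfusym_report`).
#' @export
evaluate_cohort <- function(results) {
  if (is.character(results))
    results <- utils::read.csv(results, stringsAsFactors = FALSE)
  stopifnot(all(c("asym_positive", "pi_positive") %in% names(results)))
  asym <- as.logical(results$asym_positive)
  gold <- as.logical(results$pi_positive)
  n <- length(asym)
  out <- list(n = n,
              detection_rate_asym_percent =
                round_half_away(100 * mean(asym)),
              detection_rate_pi_percent =
                round_half_away(100 * mean(gold)))
  ss <- tryCatch(sensitivity_specificity(confusion_from_verdicts(asym, gold)),
                 error = function(e) NULL)
  if (!is.null(ss)) {
    out$sensitivity_percent <- ss$sensitivity_rounded
    out$specificity_percent <- ss$specificity_rounded
  }
  if ("asym_level" %in% names(results)) {
    lev <- as.numeric(results$asym_level)
    out$roc_auc <- tryCatch(roc_auc_ordinal(lev, gold),
                            error = function(e) NA_real_)
  }
  conc <- function(a, b) tryCatch(concordance(a, b)$proportion_percent,
                                  error = function(e) NA_integer_)
  if (all(c("lat_asym", "lat_semiology") %in% names(results)))
    out$lateralization_concordance_semiology_percent <-
      conc(results$lat_asym, results$lat_semiology)
  if (all(c("lat_asym", "lat_eeg") %in% names(results)))
    out$lateralization_concordance_eeg_percent <-
      conc(results$lat_asym, results$lat_eeg)
  if (all(c("region_asym", "region_eeg") %in% names(results)))
    out$region_concordance_percent <-
      conc(results$region_asym, results$region_eeg)
  if ("t_seizure_to_spect_h" %in% names(results) &&
      length(unique(asym)) == 2L) {
    tt <- as.numeric(results$t_seizure_to_spect_h)
    w <- wilcoxon_rank_sum(tt[asym], tt[!asym])
    out$delay_ranksum_p <- w$p
  }
  class(out) <- "perfusym_report"
  out
}

#' @export
print.perfusym_report <- function(x, ...) {
  cat("<cohort evaluation report>\n")
  for (nm in setdiff(names(x), "n"))
    cat(sprintf("  %-44s %s\n", nm, format(x[[nm]], digits = 4)))
  cat(sprintf("  (n = %d cases)\n", x$n))
  invisible(x)
}
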