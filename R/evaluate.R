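# Borderline-aware contingency-table evaluation of membership predictions.
#
# OPLS-DA membership predictions are continuous on the 0/1 dummy scale.
# Values above 0.65 indicate class membership, below 0.35 non-membership,
# and the band in between is "borderline or uncertain".  The conservative
# evaluation counts borderline calls as wrong attributions; an alternative
# mode applies a single 0.5 cut with no borderline band.

#' Membership-threshold configuration
#'
#' @param member_above Membership threshold (strict; default 0.65).
#' @param nonmember_below Non-membership threshold (strict; default 0.35).
#' @param conservative Count borderline calls as wrong attributions
#'   (default `TRUE`): borderline affected samples go to FN, borderline
#'   unaffected to FP.  With `FALSE`, borderline samples are kept out of
#'   the four cells (raw borderline counts are always reported).
#' @param midpoint Apply a single 0.5 cut with no borderline band.
#' @return A `threshold_config`.
#' @export
threshold_config <- function(member_above = 0.65, nonmember_below = 0.35,
                             conservative = TRUE, midpoint = FALSE) {
  if (!(0 <= nonmember_below && nonmember_below < member_above &&
        member_above <= 1)) {
    stop("need 0 <= nonmember_below < member_above <= 1")
  }
  structure(list(member_above = member_above,
                 nonmember_below = nonmember_below,
                 conservative = isTRUE(conservative),
                 midpoint = isTRUE(midpoint)),
            class = "threshold_config")
}

#' Call class membership from prediction values
#'
#' Boundary values (exactly 0.65 or 0.35) are borderline: membership
#' requires strictly more than `member_above`, non-membership strictly less
#' than `nonmember_below`.  In midpoint mode there is no borderline band.
#'
#' @param yhat Numeric prediction values (finite).
#' @param cfg A [threshold_config()].
#' @return Factor with levels `member`, `borderline`, `nonmember`.
#' @export
call_membership <- function(yhat, cfg = threshold_config()) {
  if (!all(is.finite(yhat))) stop("prediction values must be finite")
  if (cfg$midpoint) {
    out <- ifelse(yhat > 0.5, "member", "nonmember")
  } else {
    out <- ifelse(yhat > cfg$member_above, "member",
                  ifelse(yhat < cfg$nonmember_below, "nonmember",
                         "borderline"))
  }
  factor(out, levels = c("member", "borderline", "nonmember"))
}

#' Build the borderline-aware contingency table
#'
#' The clinical evaluation is the gold standard: `truth` marks the samples
#' that belong to the predicted (affected) class.  Under the conservative
#' rule borderline calls are wrong attributions — borderline affected
#' samples count as false negatives, borderline unaffected as false
#' positives — and the raw borderline counts are preserved separately so
#' either reading can be audited.
#'
#' @param calls Factor from [call_membership()].
#' @param truth Logical (or 0/1) vector: sample truly belongs to the class.
#' @param cfg A [threshold_config()].
#' @param gold_standard Label describing the truth source.
#' @return A `contingency_table`: counts `TP`, `FP`, `TN`, `FN`,
#'   `borderline_affected`, `borderline_unaffected`, `n`.
#' @export
build_contingency <- function(calls, truth, cfg = threshold_config(),
                              gold_standard = "clinical evaluation") {
  if (length(calls) != length(truth)) {
    stop("`calls` and `truth` must have equal length")
  }
  truth <- as.logical(truth)
  member <- calls == "member"
  border <- calls == "borderline"
  tp <- sum(member & truth)
  fp <- sum(member & !truth)
  tn <- sum(calls == "nonmember" & !truth)
  fn <- sum(calls == "nonmember" & truth)
  ba <- sum(border & truth)
  bu <- sum(border & !truth)
  if (cfg$conservative) { # borderline = wrong attribution
    fn <- fn + ba
    fp <- fp + bu
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 borderline_affected = ba, borderline_unaffected = bu,
                 n = length(truth), gold_standard = gold_standard,
                 conservative = cfg$conservative),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table (gold standard: %s)\n", x$gold_standard))
  cat(sprintf("  TP %d  FN %d  (borderline affected %d)\n",
              x$TP, x$FN, x$borderline_affected))
  cat(sprintf("  FP %d  TN %d  (borderline unaffected %d)\n",
              x$FP, x$TN, x$borderline_unaffected))
  invisible(x)
}

#' Diagnostic metrics from a contingency table
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), accuracy = (TP+TN)/total.  Ratios with zero
#' denominator are reported as `NA`, never 0.  The Fisher p-value is the
#' exact two-tailed test on the 2x2 table.
#'
#' @param t A `contingency_table`.
#' @return A `diagnostic_metrics` list: `sensitivity`, `specificity`,
#'   `PPV`, `NPV`, `accuracy`, `fisher_p`.
#' @export
compute_metrics <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  total <- t$TP + t$FP + t$TN + t$FN
  structure(list(
    sensitivity = ratio(t$TP, t$TP + t$FN),
    specificity = ratio(t$TN, t$TN + t$FP),
    PPV = ratio(t$TP, t$TP + t$FP),
    NPV = ratio(t$TN, t$TN + t$FN),
    accuracy = ratio(t$TP + t$TN, total),
    fisher_p = if (total == 0) NA_real_ else fisher_exact_two_tailed(t)
  ), class = "diagnostic_metrics")
}

#' Exact two-tailed Fisher test
#'
#' Enumerates the full hypergeometric support with the observed margins
#' fixed and sums the probabilities of all tables no more probable than
#' the observed one (the standard "probability <= observed" two-sided
#' rule; `doubling = TRUE` instead doubles the smaller one-sided tail,
#' capped at 1).
#'
#' @param t A `contingency_table`, or a 2x2 matrix
#'   `rbind(c(TP, FN), c(FP, TN))`.
#' @param doubling Use the tail-doubling convention instead.
#' @return The p-value in (0, 1].
#' @export
fisher_exact_two_tailed <- function(t, doubling = FALSE) {
  if (inherits(t, "contingency_table")) {
    m <- rbind(c(t$TP, t$FN), c(t$FP, t$TN))
  } else {
    m <- as.matrix(t)
  }
  if (!all(dim(m) == 2) || any(m < 0)) stop("need a 2x2 table of counts >= 0")
  if (sum(m) == 0) stop("empty contingency table")
  # margins: row1 = affected (TP+FN), col1 = called positive (TP+FP)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  if (doubling) {
    lo <- sum(probs[support <= m[1, 1]])
    hi <- sum(probs[support >= m[1, 1]])
    return(min(1, 2 * min(lo, hi)))
  }
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
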