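#' ROC curve over observed score thresholds
#'
#' Candidate thresholds are the unique observed scores plus 0 and 1, and
#' the classification rule is `score >= threshold` implies positive
#' (threatened). Restricting thresholds to observed values keeps the
#' ranking finite and reproducible.
#'
#' @param scores Numeric scores in `[0, 1]` (e.g. fitted risk
#'   probabilities).
#' @param labels 0/1 vector, 1 = positive class.
#' @return Data frame of class `roc_points`, sorted by threshold:
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(c(0, scores, 1)))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  out <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg < t), numeric(1)))
  class(out) <- c("roc_points", class(out))
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area over (1 - specificity, sensitivity). With thresholds at
#' every observed score this equals the concordance probability that a
#' random positive outscores a random negative, ties counted one half.
#'
#' @param roc A [roc_curve()] result.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  # anchor at (0,0) and (1,1): the threshold grid stops at the extreme
  # observed scores, so the corner points may be absent from the curve
  fpr <- c(0, 1 - roc$specificity, 1)
  tpr <- c(0, roc$sensitivity, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Brute-force pairwise concordance (ties = 1/2); used as the independent
# check that the trapezoid equals the concordance probability.
auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

#' Rank ROC cutoffs by the Index of Union
#'
#' The Index of Union of a cutoff c is
#' `IU(c) = |Se(c) - AUC| + |Sp(c) - AUC|`: the best cutoff is the one
#' whose sensitivity and specificity are jointly closest to the AUC.
#' Ties are broken by the smaller `|Se - Sp|` gap, then by the lower
#' threshold.
#'
#' @param roc A [roc_curve()] result.
#' @param auc The AUC of the same classifier; computed from `roc` when
#'   omitted.
#' @return Data frame sorted ascending by IU (rank 1 = optimal):
#'   `rank`, `threshold`, `iu`, `sensitivity`, `specificity`.
#' @export
index_of_union <- function(roc, auc = auc_trapezoid(roc)) {
  iu <- abs(roc$sensitivity - auc) + abs(roc$specificity - auc)
  gap <- abs(roc$sensitivity - roc$specificity)
  ord <- order(iu, gap, roc$threshold)
  out <- data.frame(rank = seq_along(ord),
                    threshold = roc$threshold[ord],
                    iu = iu[ord],
                    sensitivity = roc$sensitivity[ord],
                    specificity = roc$specificity[ord])
  attr(out, "auc") <- auc
  out
}

#' Choose a classification cutoff with a sensitivity-priority override
#'
#' The aim of the risk models is to catch truly threatened species, so
#' sensitivity is prioritized over specificity: walking down the Index of
#' Union ranking from the optimum, the first cutoff whose sensitivity
#' reaches `min_sensitivity` is chosen. When the rank-1 cutoff already
#' qualifies the IU optimum is kept (`rule_applied = "iu_optimal"`);
#' otherwise a lower-ranked cutoff is accepted
#' (`rule_applied = "sensitivity_override"`). If no ranked cutoff
#' qualifies, the rank-1 cutoff is returned with a warning.
#'
#' @param ranking An [index_of_union()] ranking.
#' @param min_sensitivity Minimum acceptable sensitivity (default 0.70).
#' @return List of class `cutoff_selection`: `chosen_cutoff`,
#'   `rule_applied`, `rank`, `sensitivity`, `specificity`,
#'   `min_sensitivity`, `ranking`, and the `auc` carried by the ranking.
#' @export
select_cutoff <- function(ranking, min_sensitivity = 0.70) {
  stopifnot(nrow(ranking) > 0)
  ok <- which(ranking$sensitivity >= min_sensitivity)
  if (!length(ok)) {
    warning("no cutoff reaches sensitivity ", min_sensitivity,
            ": returning the IU-optimal cutoff", call. = FALSE)
    pick <- 1L
    rule <- "iu_optimal"
  } else {
    pick <- min(ok)
    rule <- if (pick == 1L) "iu_optimal" else "sensitivity_override"
  }
  structure(list(chosen_cutoff = ranking$threshold[pick],
                 rule_applied = rule,
                 rank = ranking$rank[pick],
                 sensitivity = ranking$sensitivity[pick],
                 specificity = ranking$specificity[pick],
                 min_sensitivity = min_sensitivity,
                 ranking = ranking,
                 auc = attr(ranking, "auc")),
            class = "cutoff_selection")
}

#' @export
print.cutoff_selection <- function(x, ...) {
  cat(sprintf("Cutoff %.3g (%s, rank %d): Se = %.2f, Sp = %.2f\n",
              x$chosen_cutoff, x$rule_applied, x$rank, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Two-graph ROC table
#'
#' Long-format table of sensitivity and specificity against threshold for
#' two-graph ROC plots, with the Se = Sp crossing threshold located by
#' linear interpolation (reported as `NA` when the curves do not cross
#' strictly inside the threshold range).
#'
#' @param roc A [roc_curve()] result.
#' @return Data frame `threshold`, `curve` (`"sensitivity"` /
#'   `"specificity"`), `value`; the crossing threshold is attached as
#'   attribute `crossing`.
#' @export
two_graph_roc <- function(roc) {
  long <- rbind(
    data.frame(threshold = roc$threshold, curve = "sensitivity",
               value = roc$sensitivity),
    data.frame(threshold = roc$threshold, curve = "specificity",
               value = roc$specificity))
  d <- roc$sensitivity - roc$specificity
  crossing <- NA_real_
  s <- which(d[-length(d)] * d[-1] <= 0 & d[-length(d)] != d[-1])
  if (length(s)) {
    i <- s[1]
    w <- d[i] / (d[i] - d[i + 1])
    crossing <- roc$threshold[i] + w * (roc$threshold[i + 1] - roc$threshold[i])
  } else if (any(d == 0)) {
    crossing <- roc$threshold[which(d == 0)[1]]
  }
  attr(long, "crossing") <- crossing
  long
}
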