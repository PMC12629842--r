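# Core statistics: rank test, FDR, ROC, cutpoints ----------------------------

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from mid-ranks, so ties contribute half-counts. For total
#' sample sizes up to `exact_max` (and under `method = "auto"`), the two-sided
#' p-value is computed by exhaustive enumeration of all label assignments of
#' the pooled observations, counting assignments whose U is at least as far
#' from its null mean as the observed U. Otherwise a normal approximation with
#' tie-corrected variance and a 0.5 continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param method `"auto"` (exact when `length(x) + length(y) <= exact_max`),
#'   `"exact"`, or `"normal"`.
#' @param exact_max Largest total sample size for which `"auto"` enumerates.
#' @return List with `U` (mid-rank U statistic for `x`) and `p` (two-sided).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal"),
                           exact_max = 10L) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("empty group")
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("NA values in input")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "auto") method <- if (n <= exact_max) "exact" else "normal"
  if (method == "exact") {
    if (n > 20L) stop("exact enumeration limited to total n <= 20")
    idx <- combn(n, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    tie <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- max(abs(U - mu) - 0.5, 0)
      # floor at the smallest positive double: extreme z underflows to 0,
      # which would violate the (0, 1] domain of downstream FDR adjustment
      p <- min(1, max(2 * pnorm(-d / sqrt(sigma2)), .Machine$double.xmin))
    }
  }
  list(U = U, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `adj_i = min over j with p_j >= p_i of p_j * n / rank_j`,
#' clipped at 1, returned in input order.
#'
#' @param pvals Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.5))  # 0.002, 0.5
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  n <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(n / seq(n, 1) * pvals[o]))
  adj[order(o)]
}

#' ROC curve for a score discriminating pathogenic from benign
#'
#' The classification rule is `score >= threshold` predicts pathogenic.
#' Candidate thresholds are the distinct observed scores in descending order
#' with a `+Inf` sentinel, so the curve starts at (0,0) and ends at (1,1).
#' The AUC is the trapezoidal integral of TPR over FPR, which equals the
#' tie-corrected concordance `(#\{p > n\} + 0.5 #\{p = n\}) / (|pos| |neg|)`.
#'
#' @param pos Scores of the positive (pathogenic) class.
#' @param neg Scores of the negative (benign) class.
#' @return Object of class `"roc_curve"`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("empty group")
  pos <- as.numeric(pos)
  neg <- as.numeric(neg)
  if (anyNA(pos) || anyNA(neg)) stop("NA scores")
  n1 <- length(pos)
  n2 <- length(neg)
  s <- c(pos, neg)
  lab <- rep(c(TRUE, FALSE), c(n1, n2))
  o <- order(s, decreasing = TRUE)
  s <- s[o]
  lab <- lab[o]
  last <- c(diff(s) != 0, TRUE)  # last index of each distinct score
  tpr <- cumsum(lab)[last] / n1
  fpr <- cumsum(!lab)[last] / n2
  th <- c(Inf, s[last])
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n1, n_neg = n2),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", x$n_pos, " pos vs ", x$n_neg, " neg; AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "firebrick", ...) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "l", col = col,
         xlab = "False positive rate", ylab = "True positive rate",
         xlim = c(0, 1), ylim = c(0, 1), ...)
    abline(0, 1, lty = 3, col = "grey50")
  } else {
    lines(x$fpr, x$tpr, col = col, ...)
  }
  invisible(x)
}

new_cutpoint <- function(threshold, j, f1, objective, strategy) {
  structure(list(threshold = threshold, j = j, f1 = f1,
                 objective = objective, strategy = strategy),
            class = "cutpoint")
}

#' @export
print.cutpoint <- function(x, ...) {
  cat("<cutpoint> strategy=", x$strategy,
      " threshold=", format(x$threshold, digits = 6),
      " J=", format(x$j, digits = 4),
      " F1=", format(x$f1, digits = 4), "\n", sep = "")
  invisible(x)
}

# F1 along a roc_curve's threshold grid; no predicted positives gives F1 = 0.
curve_f1 <- function(curve) {
  tp <- curve$tpr * curve$n_pos
  fp <- curve$fpr * curve$n_neg
  fn <- curve$n_pos - tp
  denom <- 2 * tp + fp + fn
  ifelse(denom > 0 & tp + fp > 0, 2 * tp / denom, 0)
}

cutpoint_from_curve <- function(curve, strategy, w_youden = 0.4) {
  j <- curve$tpr - curve$fpr
  f1 <- curve_f1(curve)
  obj <- switch(strategy,
                youden = j,
                f1 = f1,
                weighted = w_youden * j + (1 - w_youden) * f1,
                stop("unknown strategy: ", strategy))
  # thresholds descend, so the first maximum is the higher threshold; the
  # tolerance absorbs ulp-level float noise in exactly tied objectives
  # (genuine differences are rational with denominator <= n_pos * n_neg)
  i <- which(obj >= max(obj) - 1e-12)[1]
  new_cutpoint(curve$thresholds[i], j[i], f1[i], obj[i], strategy)
}

#' Youden's J optimal cutpoint
#'
#' Returns the threshold maximizing J = sensitivity + specificity - 1
#' (equivalently TPR - FPR) over the curve's threshold grid; ties resolve to
#' the higher (more specific) threshold.
#'
#' @param curve A [roc_curve()], or the positive-class score vector (in which
#'   case `neg` must be given).
#' @param neg Negative-class scores when `curve` is a score vector.
#' @return Object of class `"cutpoint"`.
#' @export
youden_cutpoint <- function(curve, neg = NULL) {
  if (!inherits(curve, "roc_curve")) curve <- roc_curve(curve, neg)
  cutpoint_from_curve(curve, "youden")
}

#' F1-optimal cutpoint
#'
#' Threshold maximizing F1 = 2 * precision * recall / (precision + recall)
#' with pathogenic as the positive class; thresholds with no predicted
#' positives score F1 = 0; ties resolve to the higher threshold.
#'
#' @param pos,neg Scores of the positive / negative class.
#' @return Object of class `"cutpoint"`.
#' @export
f1_cutpoint <- function(pos, neg) {
  cutpoint_from_curve(roc_curve(pos, neg), "f1")
}

#' Weighted Youden/F1 cutpoint
#'
#' Threshold maximizing the convex blend
#' `w_youden * J(t) + (1 - w_youden) * F1(t)` over the shared candidate grid.
#' `w_youden = 1` reduces to [youden_cutpoint()], `w_youden = 0` to
#' [f1_cutpoint()].
#'
#' @param pos,neg Scores of the positive / negative class.
#' @param w_youden Weight on Youden's J, in \[0, 1\] (default 0.4).
#' @return Object of class `"cutpoint"`.
#' @export
weighted_cutpoint <- function(pos, neg, w_youden = 0.4) {
  stopifnot(w_youden >= 0, w_youden <= 1)
  cutpoint_from_curve(roc_curve(pos, neg), "weighted", w_youden)
}

#' Significance stars for an adjusted p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05 (strict inequalities),
#' otherwise `"ns"`.
#'
#' @param p_adj Adjusted p-value(s) in (0, 1].
#' @return Character vector of labels.
#' @export
significance_label <- function(p_adj) {
  if (anyNA(p_adj) || any(p_adj <= 0 | p_adj > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  ifelse(p_adj < 0.001, "***",
         ifelse(p_adj < 0.01, "**",
                ifelse(p_adj < 0.05, "*", "ns")))
}
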