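# Reference-threshold learning and intra/inter validation.
#
# Given pair distances labelled intra (same binding mode / same compound
# class) and inter (different), the reference threshold is the cut t that
# maximises discrimination accuracy
#   ( #{intra < t} + #{inter >= t} ) / (n_intra + n_inter),
# swept over midpoints of consecutive sorted pooled distances plus the two
# extremes. The t-test mirrors the intra-vs-inter validation tables of
# descriptor studies: a pooled-variance two-sample two-sided test.

#' Discrimination accuracy of a distance threshold
#'
#' Fraction of pairs classified correctly when every distance below `t` is
#' called intra (similar) and every distance at or above `t` inter
#' (non-similar). The two count terms share one denominator (unbalanced
#' accuracy).
#'
#' @param t threshold.
#' @param intra,inter numeric vectors of pair distances; both non-empty.
#' @return Accuracy in `[0, 1]`.
#' @export
discrimination_accuracy <- function(t, intra, inter) {
  if (!length(intra) || !length(inter))
    stop("intra and inter distance lists must be non-empty")
  (sum(intra < t) + sum(inter >= t)) / (length(intra) + length(inter))
}

#' Learn the reference threshold by maximum discrimination
#'
#' Evaluates [discrimination_accuracy()] at every candidate threshold —
#' the midpoints between consecutive sorted unique pooled distances, plus
#' one candidate below the minimum and one above the maximum — and returns
#' the smallest candidate attaining the maximum.
#'
#' @param intra,inter numeric vectors of pair distances; both non-empty.
#' @return An object of class `threshold_result`: list with `t_star`,
#'   `accuracy`, `n_intra`, `n_inter`, and the swept `candidates`.
#' @export
reference_threshold <- function(intra, inter) {
  if (!length(intra) || !length(inter))
    stop("intra and inter distance lists must be non-empty")
  u <- sort(unique(c(intra, inter)))
  K <- length(u)
  span <- if (K > 1L) u[K] - u[1] else 1
  cands <- c(u[1], if (K > 1L) (u[-1] + u[-K]) / 2, u[K] + span / (2 * K))
  acc <- vapply(cands, discrimination_accuracy, numeric(1),
                intra = intra, inter = inter)
  best <- which.max(acc)  # first maximum = smallest maximizing candidate
  structure(list(t_star = cands[best], accuracy = acc[best],
                 n_intra = length(intra), n_inter = length(inter),
                 candidates = cands),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> t* = %.4g, accuracy = %.4f (%d intra, %d inter)\n",
    x$t_star, x$accuracy, x$n_intra, x$n_inter))
  invisible(x)
}

#' Two-sample t-test of intra- vs inter-cluster distances
#'
#' Pooled-variance two-sided t-test that the mean intra-cluster distance
#' differs from the mean inter-cluster distance; reports the group means and
#' sample standard deviations alongside the statistic. Degenerate input
#' (zero pooled variance) yields t = 0, p = 1 when the means are equal.
#'
#' @param intra,inter numeric distance vectors, each of length >= 2.
#' @param alpha significance level for the reported reject decision.
#' @return An object of class `ttest_result`: list with `mean_intra`,
#'   `mean_inter`, `std_intra`, `std_inter`, `t_stat`, `df`, `p_value`,
#'   `reject`, `alpha`.
#' @export
intra_inter_ttest <- function(intra, inter, alpha = 0.01) {
  if (length(intra) < 2L || length(inter) < 2L)
    stop("each distance list must have length >= 2")
  res <- tryCatch(
    stats::t.test(intra, inter, var.equal = TRUE),
    error = function(e) NULL)  # "data are essentially constant"
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(intra), mean(inter)))) {
      t_stat <- 0; p <- 1; df <- length(intra) + length(inter) - 2L
    } else stop("zero pooled variance with unequal means")
  } else {
    t_stat <- unname(res$statistic); p <- res$p.value
    df <- unname(res$parameter)
  }
  structure(list(mean_intra = mean(intra), mean_inter = mean(inter),
                 std_intra = stats::sd(intra), std_inter = stats::sd(inter),
                 t_stat = t_stat, df = df, p_value = p,
                 reject = p < alpha, alpha = alpha),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    paste0("<ttest_result> intra %.3f (sd %.3f) vs inter %.3f (sd %.3f): ",
           "t = %.3f, p = %.3g, %s H0 at alpha = %g\n"),
    x$mean_intra, x$std_intra, x$mean_inter, x$std_inter,
    x$t_stat, x$p_value, if (x$reject) "reject" else "retain", x$alpha))
  invisible(x)
}
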