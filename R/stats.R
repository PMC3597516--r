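#' Scale normalized ratios by a class proportion
#'
#' To compare class efficiencies between strains, each strain's distribution
#' of per-transformation normalized ratios is multiplied elementwise by the
#' strain's fixed class proportion (CO, NCO, unidirectional or bidirectional),
#' yielding a distribution whose mean is the class efficiency.
#'
#' @param values Numeric vector of normalized His+:Leu+ ratios.
#' @param proportion Class proportion in `[0, 1]`.
#' @return Numeric vector of scaled ratios.
#' @export
scaled_ratio_distribution <- function(values, proportion) {
  stopifnot(proportion >= 0, proportion <= 1)
  values * proportion
}

#' Two-tailed Student's t-test (pooled variance)
#'
#' The classical equal-variance two-sample t statistic with
#' `n1 + n2 - 2` degrees of freedom. Welch's unequal-variance form is
#' available behind a flag. If both samples are constant: p = 1 when the
#' means agree (no evidence of difference), 0 otherwise.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param welch Use the Welch-Satterthwaite form instead of pooled variance.
#' @return Two-tailed p-value in `[0, 1]`.
#' @export
student_t_two_tailed <- function(a, b, welch = FALSE) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each sample needs >= 2 values", call. = FALSE)
  m1 <- mean(a)
  m2 <- mean(b)
  v1 <- stats::var(a)
  v2 <- stats::var(b)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      return(if (m1 == m2) 1 else 0)
    }
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) {
      return(if (m1 == m2) 1 else 0)
    }
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  2 * stats::pt(-abs(tstat), df)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p by the point-probability rule: with margins fixed, the
#' p-value is the sum of hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 guards against floating-point ties). Two-sided
#' conventions for 2x2 tables differ between tools; this is the definition
#' used by standard contingency-table calculators and by
#' `stats::fisher.test`.
#'
#' @param a1,a2 First row of the table (e.g. CO and NCO counts in strain A).
#' @param b1,b2 Second row (same categories in strain B).
#' @return Two-sided p-value in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(a1, a2, b1, b2) {
  x <- c(a1, a2, b1, b2)
  if (any(x < 0) || any(x != floor(x))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(x) == 0) stop("all-zero table", call. = FALSE)
  m1 <- a1 + a2 # row 1 margin
  m2 <- b1 + b2 # row 2 margin
  k <- a1 + b1 # column 1 margin
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a1, m1, m2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Compare a metric between two strains
#'
#' Convenience wrapper producing one comparison row: scales each strain's
#' normalized ratios by its class proportion and applies the two-tailed
#' Student's t-test, flagging significance at p < 0.05.
#'
#' @param values_a,values_b Normalized ratios for the two strains.
#' @param prop_a,prop_b The class proportion applied to each.
#' @param metric Label for the comparison row.
#' @param welch Use Welch's t instead of pooled variance.
#' @return One-row data.frame: `metric`, `p`, `significant`.
#' @export
compare_strains <- function(values_a, values_b, prop_a, prop_b,
                            metric = "efficiency", welch = FALSE) {
  p <- student_t_two_tailed(
    scaled_ratio_distribution(values_a, prop_a),
    scaled_ratio_distribution(values_b, prop_b),
    welch = welch
  )
  data.frame(metric = metric, p = p, significant = p < 0.05)
}
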