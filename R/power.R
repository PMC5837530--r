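#' Cohen's d with pooled standard deviation
#'
#' d = (m1 - m2) / s_pooled with
#' s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)).
#' The 95\% CI uses the normal approximation
#' SE(d) = sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2))).
#'
#' @param m1,s1,n1 first group mean, SD, size.
#' @param m2,s2,n2 second group mean, SD, size.
#' @return object of class \code{EffectSize}: d, pooledSd, ci (length 2),
#'   the inputs.
#' @export
cohensD <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) stop("pooled SD is zero")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled SD is zero")
  d <- (m1 - m2) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  out <- list(d = d, pooledSd = sp, ci = d + c(-1, 1) * 1.96 * se,
              m1 = m1, s1 = s1, n1 = n1, m2 = m2, s2 = s2, n2 = n2)
  class(out) <- "EffectSize"
  out
}

#' @export
print.EffectSize <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (95%% CI %.3f to %.3f), pooled SD = %.3f\n",
              x$d, x$ci[1], x$ci[2], x$pooledSd))
  invisible(x)
}

#' Per-arm sample size for an atrophy-slowing trial
#'
#' N = ceiling(2 * ((1.96 + 0.842) / (TE * ES))^2): the per-arm size giving
#' 80\% power at two-sided alpha = 0.05 to detect a treatment that reduces
#' the case-control atrophy-rate difference by the fraction TE, when the
#' untreated difference has effect size ES (Cohen's d). The z constants are
#' fixed at their conventional printed precision.
#'
#' @param te treatment effectiveness in (0, 1].
#' @param es effect size (Cohen's d, > 0).
#' @return integer sample size per arm.
#' @export
sampleSizePerArm <- function(te, es) {
  if (any(te <= 0) || any(es <= 0)) stop("te and es must be > 0")
  as.integer(ceiling(2 * ((1.96 + 0.842) / (te * es))^2))
}

#' Sample size as a function of treatment effectiveness
#'
#' @param es effect size (Cohen's d).
#' @param teGrid vector of treatment-effectiveness values in (0, 1].
#' @return data.frame(te, n_per_arm), non-increasing in te.
#' @export
powerCurve <- function(es, teGrid = seq(0.05, 1, by = 0.05)) {
  if (any(teGrid <= 0 | teGrid > 1)) stop("teGrid values must be in (0, 1]")
  data.frame(te = teGrid,
             n_per_arm = vapply(teGrid, sampleSizePerArm, integer(1),
                                es = es))
}
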