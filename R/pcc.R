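#' Pearson correlation of two expression profiles
#'
#' Computes the Pearson correlation coefficient (PCC) between the expression
#' profiles of two genes over the same `m` sampling points,
#' \deqn{PCC(u,v) = \frac{1}{m-1}\sum_{i=1}^{m}
#'   \frac{p_u(i)-\bar p_u}{\sigma_u}\,\frac{p_v(i)-\bar p_v}{\sigma_v},}
#' where \eqn{\sigma} is the sample standard deviation (divisor `m - 1`,
#' consistent with the `1/(m-1)` prefactor, so identical profiles score
#' exactly 1).
#'
#' A profile with zero variance carries no co-expression evidence, so the
#' result is defined as 0 in that case rather than `NaN`.
#'
#' @param x,y Numeric vectors of equal length `m >= 2`.
#' @return A number in `[-1, 1]`.
#' @examples
#' compute_pcc(c(1, 2, 3), c(1, 2, 3))  # 1
#' compute_pcc(c(1, 2, 3), c(3, 2, 1))  # -1
#' compute_pcc(c(5, 5, 5), c(1, 2, 3))  # 0 (zero-variance policy)
#' @export
compute_pcc <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("expression profiles must be numeric vectors")
  }
  if (length(x) != length(y)) {
    stop("expression profiles have different numbers of sampling points (",
         length(x), " vs ", length(y), ")")
  }
  m <- length(x)
  if (m < 2) stop("at least 2 sampling points are required (m >= 2)")
  if (anyNA(x) || anyNA(y)) stop("expression profiles contain missing values")
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (m - 1)
}

# PCC post-processing before it enters an edge weight. Negative correlations
# would produce negative influence mass under the cascade model, so the
# default clamps them to 0; "absolute" treats anti-correlation as evidence of
# association; "raw" keeps the signed value.
apply_pcc_policy <- function(pcc, policy = c("clamp", "absolute", "raw")) {
  policy <- match.arg(policy)
  switch(policy,
    clamp    = max(pcc, 0),
    absolute = abs(pcc),
    raw      = pcc
  )
}
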