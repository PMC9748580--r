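## Eight-component normal-scale-mixture approximation to the logistic
## function: expit(x) ~= sum_k p_k Phi(s_k x).  The weights/scales below
## were obtained once by least-squares fitting on a dense grid over
## [0, 10] (symmetry gives the negative axis for free since sum p_k = 1)
## and are frozen; the sup-norm gap to expit on [-10, 10] is < 1e-5,
## well inside the 1e-3 contract checked by the test suite.
.ms_p <- c(0.076513745054343052,
           0.1244733300493187,
           0.13982936361979875,
           0.14742937403595416,
           0.13103666699364572,
           0.14432084063688813,
           0.1499928195391077,
           0.086403860070943792)
.ms_s <- c(0.33024293805236477,
           0.47826771192332418,
           0.488804254633325,
           0.51039281388019253,
           0.7197432288016995,
           0.72383782090776838,
           0.7256714118366856,
           1.0486827840395967)

#' Normal-scale-mixture basis for the logistic function
#'
#' Returns the eight weights \eqn{p_k \ge 0} (summing to one) and scales
#' \eqn{s_k > 0} such that \eqn{\mathrm{expit}(x) \approx \sum_k p_k
#' \Phi(s_k x)} uniformly on \eqn{[-10, 10]}.  Because each component is
#' a probit, Gaussian expectations of the logistic mean and its
#' derivative are available in closed form, which is what makes binary
#' markers tractable inside the variational updates.
#'
#' @return List with numeric vectors `p` and `s` (length 8 each).
#' @examples
#' b <- ms_basis()
#' sum(b$p * pnorm(b$s * 0))  # 0.5
#' @export
ms_basis <- function() list(p = .ms_p, s = .ms_s)

#' Evaluate the mixture-of-probits approximation to expit
#'
#' @param x Numeric vector.
#' @param basis Basis from [ms_basis()].
#' @return `sum_k p_k Phi(s_k x)`, elementwise in `x`.
#' @keywords internal
#' @export
ms_logistic <- function(x, basis = ms_basis()) {
  drop(stats::pnorm(outer(x, basis$s)) %*% basis$p)
}
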