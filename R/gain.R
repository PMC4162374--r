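#' Optimal divisive rescaling between two f-I curves
#'
#' Tests the divisive-gain hypothesis: can the excitatory f-I curve of a
#' heterogeneous-inhibition network be obtained from the homogeneous
#' (`w_I = 0`) curve by a single multiplicative factor? The squared
#' distance
#' \deqn{\Delta(\zeta) = \frac{1}{n}\sum_{i=1}^n [\zeta r_0(i) - r_w(i)]^2}
#' is minimized exactly in closed form,
#' \eqn{\zeta^* = \sum_i r_0(i) r_w(i) / \sum_i r_0(i)^2}.
#'
#' @param curve0 Reference [fI_curve()] (or any tibble with `mu` and
#'   `nu_E`): the `w_I = 0` curve `r_0`.
#' @param curve_w Target curve `r_w` on the same `mu` grid.
#' @return A list of class `gain_fit`: `zeta`, `delta` (mean squared
#'   residual, Hz^2), `n`, `residuals` (`zeta*r0 - rw`, Hz),
#'   `residual_std` (sd of the data around the fit, Hz), `mu`, `r0`, `rw`.
#' @export
#' @examples
#' spec <- update_spec(network_spec(), J_EI = -0.4)
#' g <- seq(9, 16, length.out = 25)
#' c0 <- fI_curve(update_spec(spec, w_I = 0), drive_spec(mu0 = 12), g)
#' cw <- fI_curve(update_spec(spec, w_I = 2), drive_spec(mu0 = 12), g)
#' fit <- optimal_rescaling(c0, cw)
#' fit$zeta
optimal_rescaling <- function(curve0, curve_w) {
  if (!isTRUE(all.equal(curve0$mu, curve_w$mu)))
    stop("the two curves must share the same mu grid")
  r0 <- curve0$nu_E
  rw <- curve_w$nu_E
  if (all(r0 == 0)) stop("reference curve is identically zero")
  zeta <- sum(r0 * rw) / sum(r0^2)
  resid <- zeta * r0 - rw
  structure(list(zeta = zeta, delta = mean(resid^2), n = length(r0),
                 residuals = resid, residual_std = stats::sd(resid),
                 mu = curve0$mu, r0 = r0, rw = rw),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("<gain_fit> zeta = %.4f, Delta = %.5g Hz^2 (n = %d)\n",
              x$zeta, x$delta, x$n))
  invisible(x)
}

#' @export
tidy.gain_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, r0 = x$r0, rw = x$rw,
                 rescaled = x$zeta * x$r0, residual = x$residuals)
}

#' @export
glance.gain_fit <- function(x, ...) {
  tibble::tibble(zeta = x$zeta, delta = x$delta, n = x$n,
                 residual_std = x$residual_std)
}

#' Residual diagnostics for a divisive-gain fit
#'
#' For a good purely multiplicative fit the residuals scatter around
#' zero, with about two thirds within one standard deviation (Gaussian
#' expectation). Reports the mean residual, that fraction, and a
#' two-sided sign-test p-value for zero-centring.
#'
#' @param fit A `gain_fit` with at least 5 points.
#' @return A one-row tibble: `mean_residual`, `frac_within_1sd`,
#'   `sign_test_p`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "gain_fit"), fit$n >= 5)
  r <- fit$residuals
  s <- stats::sd(r)
  n_pos <- sum(r > 0)
  n_nz <- sum(r != 0)
  p <- if (n_nz == 0) 1 else
    stats::binom.test(n_pos, n_nz, 0.5)$p.value
  tibble::tibble(mean_residual = mean(r),
                 frac_within_1sd = mean(abs(r - mean(r)) <= s),
                 sign_test_p = p)
}

#' Scale-invariant version of the squared distance
#'
#' `delta` divided by the squared mean of the target curve, making the
#' goodness-of-fit measure independent of the average firing rate (so
#' fits at different activity levels can be compared).
#'
#' @param fit A `gain_fit`.
#' @return Dimensionless scalar.
#' @export
normalized_delta <- function(fit) {
  m <- mean(fit$rw)
  if (m <= 0) stop("target curve has non-positive mean")
  fit$delta / m^2
}
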