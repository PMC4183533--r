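# Pharmacokinetic models: forward standard/extended Tofts curves, the SPGR
# signal-to-concentration conversion, nonlinear least-squares fitting, and
# percent parameterization error.

# exact-exponential trapezoidal convolution:
#   I(t_i) = int_0^{t_i} Cp(tau) exp(-kep (t_i - tau)) dtau
# computed by the O(n) recursion equivalent to the trapezoidal rule
.exp_conv <- function(t, cp, kep) {
  n <- length(t)
  out <- numeric(n)
  if (n < 2) return(out)
  for (i in 2:n) {
    d <- t[i] - t[i - 1]
    E <- exp(-kep * d)
    out[i] <- E * out[i - 1] + d / 2 * (cp[i] + E * cp[i - 1])
  }
  out
}

.cp_on_grid <- function(aif, t) {
  if (inherits(aif, "aif_model")) evaluate_aif(aif, t) else as.numeric(aif)
}

#' Standard Tofts model
#'
#' Two-compartment tissue concentration
#' `C_t(t) = Ktrans * int_0^t Cp(tau) exp(-(Ktrans/ve)(t - tau)) dtau`,
#' evaluated by trapezoidal convolution on the supplied grid.
#'
#' @param Ktrans volume transfer constant [1/min]
#' @param ve EES volume fraction
#' @param aif an `aif_model`, or a numeric vector of Cp already on `t` [mM]
#' @param t time grid [s]
#' @return tissue concentration `C_t(t)` [mM]
#' @export
standard_tofts <- function(Ktrans, ve, aif, t) {
  stopifnot(Ktrans >= 0, ve > 0, ve <= 1)
  cp <- .cp_on_grid(aif, t)
  kt <- Ktrans / 60
  kt * .exp_conv(t, cp, kt / ve)
}

#' Extended Tofts model
#'
#' Adds the intravascular term: `C_t(t) = standard + vp * Cp(t)`.
#' @inheritParams standard_tofts
#' @param vp plasma volume fraction
#' @return tissue concentration `C_t(t)` [mM]
#' @export
extended_tofts <- function(Ktrans, ve, vp, aif, t) {
  stopifnot(vp >= 0, vp < 1)
  cp <- .cp_on_grid(aif, t)
  standard_tofts(Ktrans, ve, cp, t) + vp * cp
}

#' Convert a signal time course to tissue concentration
#'
#' Standard conversion: invert the SPGR equation for `R1(t)`, then
#' `C_t(t) = (R1(t) - R10) / r1` with the voxel baseline rate `R10`.
#'
#' @param stc a `signal_time_course`
#' @param scan a `scan_parameters` (defaults to the one stored in `stc`)
#' @param R10 voxel baseline relaxation rate [1/s]
#' @return tissue concentration [mM] on `stc$time`
#' @export
si_to_concentration <- function(stc, scan = NULL, R10 = 0.5) {
  if (is.null(scan)) scan <- stc$scan
  (invert_spgr(stc$SI, scan) - R10) / scan$r1
}

#' Fit the extended Tofts model
#'
#' Bounded Levenberg-Marquardt least squares on concentration-space
#' residuals, started from the conventional initial guess
#' `[0.1 /min, 0.1, 0.01]` for `(Ktrans, ve, vp)`.
#'
#' @param t sample times [s]
#' @param ct measured tissue concentration [mM]
#' @param aif an `aif_model` (evaluated on `t`) or Cp samples on `t`
#' @param init initial guess `c(Ktrans, ve, vp)`
#' @param lower,upper box bounds for the parameters
#' @param truth optional true `c(Ktrans, ve, vp)` for percent errors
#' @param temporal_resolution,D metadata stored in the result
#' @param supersample convolution refinement factor: the model is evaluated
#'   on a grid `supersample` times finer than the data (AIF models only) so
#'   that quadrature error does not masquerade as lack of fit at coarse scan
#'   resolutions; `1` evaluates everything on the sample grid itself
#' @return a `fit_result` with `Ktrans_est` [1/min], `ve_est`, `vp_est`,
#'   `chi2` (residual sum of squares, mM^2), `converged`, and percent errors
#'   when `truth` is given
#' @export
fit_extended_tofts <- function(t, ct, aif, init = c(0.1, 0.1, 0.01),
                               lower = c(0, 1e-6, 0), upper = c(10, 1, 1),
                               truth = NULL, temporal_resolution = NA_real_,
                               D = NA_real_, supersample = 10L) {
  if (length(t) < 4) stop("need at least 4 samples to fit three parameters")
  if (supersample > 1L && inherits(aif, "aif_model")) {
    tf <- sort(unique(c(t, seq(min(t), max(t),
                               length.out = supersample * (length(t) - 1) + 1))))
    sel <- match(t, tf)
    cpf <- .cp_on_grid(aif, tf)
    resid_fn <- function(par)
      ct - extended_tofts(par[1], par[2], par[3], cpf, tf)[sel]
  } else {
    cp <- .cp_on_grid(aif, t)
    resid_fn <- function(par)
      ct - extended_tofts(par[1], par[2], par[3], cp, t)
  }
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- fit$par
  r <- resid_fn(est)
  pe <- if (!is.null(truth)) {
    c(Ktrans = percent_error(est[1], truth[1]),
      ve = percent_error(est[2], truth[2]),
      vp = percent_error(est[3], truth[3]))
  } else c(Ktrans = NA_real_, ve = NA_real_, vp = NA_real_)
  structure(list(Ktrans_est = est[1], ve_est = est[2], vp_est = est[3],
                 chi2 = sum(r^2), percent_errors = pe,
                 converged = fit$info %in% 1:3, info = fit$info,
                 temporal_resolution = temporal_resolution, D = D),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result> Ktrans %.4g /min, ve %.4g, vp %.4g, ",
                     "chi2 %.3g%s\n"),
              x$Ktrans_est, x$ve_est, x$vp_est, x$chi2,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Percent parameterization error
#'
#' `100 * (opt - actual) / actual`.
#' @param opt fitted value
#' @param actual true (assigned) value
#' @return percent error
#' @export
#' @examples
#' percent_error(0.2, 0.4)   # -50
percent_error <- function(opt, actual) {
  if (any(actual == 0)) stop("actual value must be nonzero")
  100 * (opt - actual) / actual
}
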