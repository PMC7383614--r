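#' Enantiomeric excess from product concentrations
#'
#' `ee = 100 * (c_RR - c_SS) / (c_RR + c_SS)` percent: positive for
#' (R,R)-diol excess, negative for (S,S).  Antisymmetric under swapping its
#' arguments and bounded in \[-100, 100\].
#'
#' @param c_RR,c_SS Concentrations (any common unit) of the (R,R)- and
#'   (S,S)-product enantiomers; vectorised.
#' @return Signed percent.
#' @examples
#' ee_from_concentrations(0.985, 0.015)  # 97
#' @export
ee_from_concentrations <- function(c_RR, c_SS) {
  if (any(c_RR < 0 | c_SS < 0))
    stop("ee_from_concentrations(): concentrations must be non-negative",
         call. = FALSE)
  tot <- c_RR + c_SS
  if (any(tot == 0))
    stop("ee_from_concentrations(): undefined, both concentrations zero",
         call. = FALSE)
  100 * (c_RR - c_SS) / tot
}

#' Specificity constant kcat/KM
#'
#' KM is stored in mM (the table convention) and the specificity constant in
#' M^-1 s^-1, so `kcat / (KM * 1e-3)`.
#'
#' @param kcat Turnover number, s^-1 (vectorised).
#' @param KM_mM Michaelis constant, mM.
#' @return kcat/KM in M^-1 s^-1 (unrounded; tables print 2-3 significant
#'   digits).
#' @examples
#' specificity_constant(0.063, 225)  # 0.28
#' @export
specificity_constant <- function(kcat, KM_mM) {
  if (any(KM_mM <= 0))
    stop("specificity_constant(): KM must be positive", call. = FALSE)
  if (any(kcat < 0))
    stop("specificity_constant(): kcat must be non-negative", call. = FALSE)
  kcat / (KM_mM * 1e-3)
}

#' Check a reported kinetics row for internal consistency
#'
#' Recomputes kcat/KM from the printed kcat and KM and compares with the
#' printed specificity constant at a relative tolerance covering rounding of
#' the printed values; rows that disagree beyond that are flagged rather
#' than forced.
#'
#' @param kcat,KM_mM,kcat_over_KM Printed values (s^-1, mM, M^-1 s^-1).
#' @param rel_tol Relative tolerance (default 5 percent, generous for
#'   2-significant-digit tables).
#' @return `TRUE` when consistent, `FALSE` (flag) otherwise; vectorised.
#' @export
check_kinetics_consistency <- function(kcat, KM_mM, kcat_over_KM,
                                       rel_tol = 0.05) {
  recomputed <- specificity_constant(kcat, KM_mM)
  abs(recomputed - kcat_over_KM) <= rel_tol * pmax(abs(kcat_over_KM),
                                                   .Machine$double.eps)
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of `v = Vmax * S / (KM + S)` via
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]), initialised with
#' `Vmax0 = max(v)` and `KM0 = S` at half-maximal velocity.  `kcat` is
#' `Vmax / enzyme_conc`.  The fit warns when fewer than four concentration
#' points are supplied or when the points do not straddle the fitted KM, and
#' flags a poorly identified KM (wide confidence) when its relative standard
#' error exceeds 50 percent or the estimate falls below half the smallest
#' measured concentration - the classic symptom of `S >> KM` everywhere.
#'
#' @param S Substrate concentrations, mM.
#' @param v Initial velocities (same time base as `kcat`; e.g. s^-1 when
#'   expressed per enzyme).
#' @param enzyme_conc Enzyme concentration in the units that make
#'   `Vmax / enzyme_conc` a per-second turnover (default 1: `v` already
#'   normalised).
#' @return A `kinetics_params`: `kcat`, `KM` (mM), `kcat_over_KM`
#'   (M^-1 s^-1), `Vmax`, standard errors `se_kcat`/`se_KM`, `converged`,
#'   `km_poorly_identified`, and the `fit` object.
#' @export
fit_michaelis_menten <- function(S, v, enzyme_conc = 1) {
  S <- as.numeric(S); v <- as.numeric(v)
  if (length(S) != length(v) || length(S) < 2L)
    stop("fit_michaelis_menten(): need matching S and v of length >= 2",
         call. = FALSE)
  if (all(v == 0))
    stop("fit_michaelis_menten(): degenerate data, all velocities zero",
         call. = FALSE)
  if (length(S) < 4L)
    warning("fit_michaelis_menten(): fewer than 4 concentration points",
            call. = FALSE)
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- median(S)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(Vmax = vmax0, KM = km0),
                       fn = function(p) v - p[["Vmax"]] * S / (p[["KM"]] + S),
                       lower = c(Vmax = 0, KM = 1e-12),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit_michaelis_menten(): fit failed to converge: ",
           conditionMessage(e), call. = FALSE))
  if (!fit$info %in% 1:4)
    stop("fit_michaelis_menten(): fit failed to converge (",
         fit$message, ")", call. = FALSE)
  est <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, KM = NA_real_))
  km <- unname(est[["KM"]])
  vmax <- unname(est[["Vmax"]])
  kcat <- vmax / enzyme_conc
  poorly <- isTRUE(se[["KM"]] / km > 0.5) || km < min(S[S > 0]) / 2
  if (!any(S < km) || !any(S > km))
    warning("fit_michaelis_menten(): concentrations do not straddle the ",
            "fitted KM; KM is weakly constrained", call. = FALSE)
  structure(list(kcat = kcat, KM = km,
                 kcat_over_KM = specificity_constant(kcat, km),
                 Vmax = vmax,
                 se_kcat = unname(se[["Vmax"]]) / enzyme_conc,
                 se_KM = unname(se[["KM"]]),
                 converged = TRUE,
                 km_poorly_identified = poorly,
                 fit = fit),
            class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat(sprintf(
    "<kinetics_params> kcat = %.4g s^-1 (se %.2g), KM = %.4g mM (se %.2g), kcat/KM = %.4g M^-1 s^-1%s\n",
    x$kcat, x$se_kcat, x$KM, x$se_KM, x$kcat_over_KM,
    if (x$km_poorly_identified) " [KM poorly identified]" else ""))
  invisible(x)
}
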