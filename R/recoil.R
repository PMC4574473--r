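## Circular laser-ablation recoil analysis ------------------------------------

#' Velocity-gradient tensor of a circular-cut recoil
#'
#' After a circular laser cut, the cut boundary recoils into an ellipse.
#' From the initial normal recoil velocities along the ellipse axes and
#' the half-axis lengths, the velocity-gradient tensor in the tissue
#' (PD/AP) coordinate system is
#' \deqn{v^{cut} = R(\theta)\,diag(V_\parallel/r_\parallel,\;
#'   V_\perp/r_\perp)\,R(-\theta),}
#' decomposed into the isotropic expansion rate `2C = trace` and a
#' symmetric traceless part `(vxx, vxy)` measuring anisotropic tissue
#' stress.
#'
#' @param v_par,v_perp Initial normal recoil velocities along the major
#'   and minor axes (um/h).
#' @param r_par,r_perp Half lengths of the major/minor axes (um),
#'   `r_par >= r_perp > 0`.
#' @param theta Angle between the major axis and the PD (x) axis, rad.
#' @return A data frame of class `recoil_measurement` with columns `C`
#'   (half the isotropic expansion rate, 1/h), `vxx`, `vxy` (traceless
#'   part, 1/h), and the inputs.  Vectorized over measurements.
#' @examples
#' recoil_tensor(0.4, 0.08, 4, 4, 0)  # rates 0.10 and 0.02 at theta = 0
#' @export
recoil_tensor <- function(v_par, v_perp, r_par, r_perp, theta) {
  if (any(r_par <= 0) || any(r_perp <= 0)) stop("non-positive radii")
  if (any(r_par < r_perp)) stop("r_par must be the major (larger) half-axis")
  e1 <- v_par / r_par
  e2 <- v_perp / r_perp
  cc <- (e1 + e2) / 2
  amp <- (e1 - e2) / 2
  structure(data.frame(C = cc,
                       vxx = amp * cos(2 * theta),
                       vxy = amp * sin(2 * theta),
                       v_par = v_par, v_perp = v_perp,
                       r_par = r_par, r_perp = r_perp, theta = theta),
            class = c("recoil_measurement", "data.frame"))
}

#' Cell-autonomous stress over shear modulus from recoil-elongation fits
#'
#' Ordinary least squares of the PD-projected anisotropic recoil rate on
#' the PD-projected cell elongation,
#' `vxx_cut = slope * Q_xx + intercept`.  Under the linear constitutive
#' law `sigma~ = 2 K Q + zeta`, the recoil rate is proportional to the
#' local anisotropic stress, so the intercept/slope ratio satisfies
#' `intercept/slope = zeta_xx / (2 K)`, and the reported estimate is
#' `zeta_xx / K = 2 * intercept / slope` (dimensionless).  A positive
#' slope indicates a positive shear modulus.
#'
#' @param qxx Average cell elongation (PD projection) in the cut region.
#' @param vxx Anisotropic recoil rate `vxx_cut` (1/h), e.g. from
#'   [recoil_tensor()].
#' @return Object of class `recoil_fit`: the underlying `lm` fit plus
#'   `zeta_over_K` and its delta-method standard error.
#' @examples
#' fit <- fit_zeta_over_K(c(0.1, 0.2, 0.3), 0.018 * c(0.1, 0.2, 0.3) + 0.003)
#' coef(fit)["zeta_over_K"]  # 2 * 0.003 / 0.018 = 1/3
#' @export
fit_zeta_over_K <- function(qxx, vxx) {
  if (length(qxx) < 3) stop("need at least 3 ablation measurements")
  if (diff(range(qxx)) < 1e-12) stop("degenerate Q_xx spread")
  fit <- lm(vxx ~ qxx)
  b <- coef(fit)[["(Intercept)"]]
  s <- coef(fit)[["qxx"]]
  ratio <- 2 * b / s
  cv <- vcov(fit)
  grad <- c(2 / s, -2 * b / s^2)
  se <- sqrt(drop(t(grad) %*% cv %*% grad))
  structure(list(lm = fit, slope = s, intercept = b,
                 zeta_over_K = ratio, se = se,
                 positive_K = s > 0),
            class = "recoil_fit")
}

#' @export
coef.recoil_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept,
    zeta_over_K = object$zeta_over_K)
}

#' @export
print.recoil_fit <- function(x, ...) {
  cat("Recoil-elongation fit: vxx_cut = slope * Q_xx + intercept\n")
  cat(sprintf("  slope     = %.4g 1/h (%s shear modulus)\n", x$slope,
              if (x$positive_K) "positive" else "negative"))
  cat(sprintf("  intercept = %.4g 1/h\n", x$intercept))
  cat(sprintf("  zeta_xx/K = %.4g +- %.2g\n", x$zeta_over_K, x$se))
  invisible(x)
}

#' @export
summary.recoil_fit <- function(object, ...) {
  s <- summary(object$lm)
  s$zeta_over_K <- object$zeta_over_K
  s
}

#' @export
predict.recoil_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  stats::predict(object$lm, data.frame(qxx = newdata), ...)
}

#' Isotropic recoil versus cell area
#'
#' OLS of half the isotropic recoil expansion rate on the log cell area
#' ratio, following the pressure law `P = -Kbar ln(a / a0)`.  Only the
#' fitted line and the sign of the inferred pressure trend are reported;
#' the preferred area and the area modulus cannot be reliably separated
#' by this method, so no `a0` or `Kbar` estimate is returned.
#'
#' @param log_area Values of `ln(a_cell / a_ref)`; `a_ref` is an
#'   arbitrary reference area affecting only the intercept.
#' @param vkk_half Half the isotropic expansion rate `v_kk / 2 = C`
#'   (1/h).
#' @return Object of class `recoil_iso_fit` with the `lm` fit, `slope`,
#'   `intercept` and `pressure_sign` (sign of the mean fitted `C`).
#' @export
fit_isotropic <- function(log_area, vkk_half) {
  if (length(log_area) < 3) stop("need at least 3 measurements")
  if (diff(range(log_area)) < 1e-12) stop("degenerate area spread")
  fit <- lm(vkk_half ~ log_area)
  structure(list(lm = fit,
                 slope = coef(fit)[["log_area"]],
                 intercept = coef(fit)[["(Intercept)"]],
                 pressure_sign = sign(mean(stats::fitted(fit)))),
            class = "recoil_iso_fit")
}

#' @export
coef.recoil_iso_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
print.recoil_iso_fit <- function(x, ...) {
  cat("Isotropic recoil fit: v_kk/2 = slope * ln(a/a_ref) + intercept\n")
  cat(sprintf("  slope = %.4g 1/h, intercept = %.4g 1/h\n",
              x$slope, x$intercept))
  cat(sprintf("  fitted expansion on average %s (tissue under %s)\n",
              if (x$pressure_sign >= 0) "positive" else "negative",
              if (x$pressure_sign >= 0) "tension" else "compression"))
  invisible(x)
}
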