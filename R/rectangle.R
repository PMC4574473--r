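## Delayed rearrangement law and two-rectangle continuum model ----------------

#' Rectangle dimensions from area and shape nematic
#'
#' A region of area `A` whose shape nematic (PD projection) is `Q` is
#' represented by a rectangle of length `L = sqrt(A) exp(Q)` along x and
#' height `h = sqrt(A) exp(-Q)`, so that `h L = A` and the aspect ratio
#' is `L / h = exp(2 Q)`.
#'
#' @param area Region area (any squared length unit).
#' @param qt_xx Shape nematic PD projection.
#' @return List with `L` and `h`.
#' @export
rect_dims <- function(area, qt_xx) {
  if (any(area <= 0)) stop("area must be positive")
  list(L = sqrt(area) * exp(qt_xx), h = sqrt(area) * exp(-qt_xx))
}

#' One integration step of the delayed rearrangement law
#'
#' The shear rate due to topological changes responds to cell elongation
#' with relaxation time `tau_r`, autonomous drive `lambda` and delay
#' `tau_d`:
#' \deqn{(1 + \tau_d\, d/dt)\, R = Q/\tau_r + \lambda.}
#' The step is exact for `Q` varying linearly across the interval
#' (exponential integrator); with `tau_d = 0` the law degenerates to the
#' algebraic branch `R = Q/tau_r + lambda`.
#'
#' @param r Current shear rate due to topological changes (1/h).
#' @param q_now,q_next Cell elongation at the start and end of the step.
#' @param tau_r Relaxation time (h, > 0).
#' @param tau_d Delay time (h, >= 0).
#' @param lambda Autonomous topological-shear drive (1/h).
#' @param dt Step (h).
#' @return The shear rate at the end of the step.
#' @export
step_rearrangement <- function(r, q_now, q_next, tau_r, tau_d, lambda, dt) {
  f0 <- q_now / tau_r + lambda
  f1 <- q_next / tau_r + lambda
  if (tau_d <= 0) return(f1)
  a <- exp(-dt / tau_d)
  a * r + f0 * (1 - a) + (f1 - f0) * (1 - tau_d * (1 - a) / dt)
}

## Predicted R series for an observed Q series (exact discretization for
## the linear interpolant of Q), starting from r0.
.eq5_predict <- function(time, q, tau_r, tau_d, lambda, r0) {
  n <- length(time)
  r <- numeric(n)
  r[1] <- r0
  for (i in seq_len(n - 1))
    r[i + 1] <- step_rearrangement(r[i], q[i], q[i + 1], tau_r, tau_d,
                                   lambda, time[i + 1] - time[i])
  r
}

#' Integrate the delayed rearrangement law for a prescribed elongation
#'
#' Solves `(1 + tau_d d/dt) R = Q(t)/tau_r + lambda` with an adaptive ODE
#' solver, treating `Q(t)` as the linear interpolant of the supplied
#' series.
#'
#' @param time Output times (h).
#' @param q Cell elongation at those times.
#' @inheritParams step_rearrangement
#' @param r0 Initial shear rate; default the instantaneous (no-delay)
#'   value at `time[1]`.
#' @return Data frame `time`, `q`, `r`.
#' @export
simulate_eq5 <- function(time, q, tau_r, tau_d, lambda,
                         r0 = q[1] / tau_r + lambda) {
  qfun <- approxfun(time, q, rule = 2)
  if (tau_d <= 0)
    return(data.frame(time = time, q = q, r = q / tau_r + lambda))
  rhs <- function(t, y, p)
    list((qfun(t) / tau_r + lambda - y[1]) / tau_d)
  sol <- deSolve::ode(c(r = r0), time, rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  data.frame(time = time, q = q, r = sol[, "r"])
}

#' Fit the delayed rearrangement law to (Q, R) series
#'
#' Least-squares fit of `(1 + tau_d d/dt) R = Q/tau_r + lambda` to one or
#' several observed trajectories of cell elongation `Q_xx(t)` and shear
#' rate due to topological changes `R_xx(t)`.  The law is discretized
#' exactly for linear interpolants of `Q(t)` (no numerical derivative of
#' a noisy series is ever taken); the residual is the difference between
#' the observed `R` series and the recursive prediction started at the
#' first observed value.
#'
#' With several wings (a list of series), a joint fit is performed with
#' shared time scales `tau_r`, `tau_d` and one `lambda` per wing.
#'
#' A delay only leaves a clear signature when the `(Q, R)` trajectory is
#' non-monotonic (it then spirals toward the fixed point `R = 0`,
#' `Q = -tau_r * lambda`); monotone or short series are flagged as
#' weakly identifying `tau_d`.
#'
#' @param series A data frame with columns `time`, `q`, `r`, or a list of
#'   such data frames (joint fit).
#' @param start Optional named list of starting values (`tau_r`, `tau_d`,
#'   `lambda`).
#' @return Object of class `eq5_fit` with components `tau_r`, `tau_d`,
#'   `lambda` (vector for joint fits), `vcov` (on the internal scale
#'   `(log tau_r, log tau_d, lambda...)`), `se` (delta-method standard
#'   errors), `fitted`, `residuals`, `sigma`, `weak_delay` flag.
#' @examples
#' tt <- seq(0, 16, by = 1 / 6)
#' qq <- 0.2 * pmin(tt / 6, 1) # ramp
#' sim <- simulate_eq5(tt, qq, tau_r = 1.8, tau_d = 3.7, lambda = -0.10)
#' fit <- fit_eq5(sim)
#' coef(fit)
#' @export
fit_eq5 <- function(series, start = NULL) {
  single <- is.data.frame(series)
  slist <- if (single) list(series) else series
  for (s in slist)
    stopifnot(all(c("time", "q", "r") %in% names(s)))
  nw <- length(slist)
  ## starting values: no-delay OLS of r on q
  qall <- unlist(lapply(slist, `[[`, "q"))
  rall <- unlist(lapply(slist, `[[`, "r"))
  ols <- unname(coef(lm(rall ~ qall)))
  st <- list(tau_r = if (ols[2] > 0) 1 / ols[2] else 2,
             tau_d = 1, lambda = rep(ols[1], nw))
  if (!is.null(start)) st[names(start)] <- start
  st$lambda <- rep(st$lambda, length.out = nw)
  obj <- function(p) {
    tau_r <- exp(p[1]); tau_d <- exp(p[2]); lam <- p[3:(2 + nw)]
    sum(vapply(seq_len(nw), function(i) {
      s <- slist[[i]]
      pred <- .eq5_predict(s$time, s$q, tau_r, tau_d, lam[i], s$r[1])
      sum((s$r - pred)^2)
    }, numeric(1)))
  }
  p0 <- c(log(st$tau_r), log(max(st$tau_d, 1e-3)), st$lambda)
  opt <- nlminb(p0, obj, control = list(iter.max = 500))
  op <- optim(opt$par, obj, method = "BFGS", hessian = TRUE,
              control = list(maxit = 200, reltol = 1e-14))
  if (op$value > opt$objective + 1e-12) op$par <- opt$par
  op$par <- unname(op$par)
  tau_r <- exp(op$par[1]); tau_d <- exp(op$par[2])
  lambda <- op$par[3:(2 + nw)]
  ndata <- sum(vapply(slist, nrow, integer(1)))
  dof <- max(1, ndata - length(op$par))
  sigma2 <- op$value / dof
  vc <- tryCatch(2 * sigma2 * solve(op$hessian),
                 error = function(e) matrix(NA_real_, length(op$par),
                                            length(op$par)))
  ## delta method back to natural scale for the taus
  se <- sqrt(diag(vc)) * c(tau_r, tau_d, rep(1, nw))
  fitted <- lapply(seq_len(nw), function(i)
    .eq5_predict(slist[[i]]$time, slist[[i]]$q, tau_r, tau_d, lambda[i],
                 slist[[i]]$r[1]))
  resid <- lapply(seq_len(nw), function(i) slist[[i]]$r - fitted[[i]])
  ## identifiability: does Q turn around?
  weak <- all(vapply(slist, function(s) {
    dq <- diff(s$q)
    all(dq >= -1e-12) || all(dq <= 1e-12)
  }, logical(1)))
  structure(list(tau_r = tau_r, tau_d = tau_d, lambda = lambda,
                 vcov = vc, se = setNames(
                   se, c("tau_r", "tau_d", paste0("lambda", seq_len(nw)))),
                 fitted = if (single) fitted[[1]] else fitted,
                 residuals = if (single) resid[[1]] else resid,
                 sigma = sqrt(sigma2), series = slist, single = single,
                 weak_delay = weak, convergence = op$convergence),
            class = "eq5_fit")
}

#' @export
coef.eq5_fit <- function(object, ...) {
  lam <- object$lambda
  names(lam) <- if (length(lam) == 1) "lambda" else
    paste0("lambda", seq_along(lam))
  c(tau_r = object$tau_r, tau_d = object$tau_d, lam)
}

#' @export
print.eq5_fit <- function(x, ...) {
  cat("Delayed rearrangement law fit: (1 + tau_d d/dt) R = Q/tau_r + lambda\n")
  cat(sprintf("  tau_r  = %.3f h (se %.3g)\n", x$tau_r, x$se["tau_r"]))
  cat(sprintf("  tau_d  = %.3f h (se %.3g)\n", x$tau_d, x$se["tau_d"]))
  for (i in seq_along(x$lambda))
    cat(sprintf("  lambda%s = %+.4f 1/h\n",
                if (length(x$lambda) > 1) paste0("[", i, "]") else "",
                x$lambda[i]))
  cat(sprintf("  residual sd %.3g 1/h on %d series\n", x$sigma,
              length(x$series)))
  if (x$weak_delay)
    cat("  note: Q series monotone; tau_d weakly identified\n")
  invisible(x)
}

#' @export
summary.eq5_fit <- function(object, ...) {
  out <- data.frame(estimate = coef(object),
                    se = object$se[seq_along(coef(object))])
  rownames(out) <- names(coef(object))
  structure(list(coefficients = out, sigma = object$sigma,
                 weak_delay = object$weak_delay), class = "summary.eq5_fit")
}

#' @export
print.summary.eq5_fit <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("residual sd: %.4g\n", x$sigma))
  invisible(x)
}

#' @export
predict.eq5_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  .eq5_predict(newdata$time, newdata$q, object$tau_r, object$tau_d,
               object$lambda[1],
               if (!is.null(newdata$r)) newdata$r[1] else
                 newdata$q[1] / object$tau_r + object$lambda[1])
}

#' @export
residuals.eq5_fit <- function(object, ...) object$residuals

#' @export
plot.eq5_fit <- function(x, which = 1L, ...) {
  s <- if (x$single) x$series[[1]] else x$series[[which]]
  f <- if (x$single) x$fitted else x$fitted[[which]]
  graphics::plot(s$q, s$r, type = "p", pch = 16, cex = 0.6,
                 xlab = "Q_xx", ylab = "R_xx (1/h)", ...)
  graphics::lines(s$q, f, col = "black")
  graphics::points(-x$tau_r * x$lambda[min(which, length(x$lambda))], 0,
                   col = "red", pch = 3)
  invisible(x)
}

#' @export
simulate.eq5_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- if (is.null(newdata)) object$series[[1]] else newdata
  base <- simulate_eq5(s$time, s$q, object$tau_r, object$tau_d,
                       object$lambda[1], r0 = s$r[1])
  out <- replicate(nsim, base$r + rnorm(nrow(base), 0, object$sigma))
  as.data.frame(out)
}
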