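## Two-rectangle (hinge + blade) continuum model ------------------------------
##
## The wing is represented by two rectangles attached along the PD (x)
## axis: the hinge spans [0, x_BH], the blade [x_BH, x_D].  Each region
## carries cell elongation Q, rearrangement shear rate R, and (blade)
## cell area a with preferred area a0.  Internal stress:
##   anisotropic  sigma~_xx = 2 K Q + zeta_xx,
##   isotropic    -P, P = -Kbar ln(a/a0_eff) - etabar v  (blade),
## with the hinge pressure the Lagrange multiplier imposing the measured
## hinge area.  Quasi-static force balance at the moving boundaries
## against external AP/PD springs (rest dimensions = initial dimensions)
## and friction gamma times the boundary velocity.  All moduli are in
## units of the blade shear modulus K, lengths in units of the initial
## wing length L0, times in hours.

#' Material parameters of the two-rectangle model
#'
#' Defaults are representative wild-type values (moduli normalized by
#' the blade shear modulus, times in hours).
#'
#' @param zeta_xx Blade cell-autonomous anisotropic stress [K].
#' @param kbar Area elastic modulus [K].
#' @param zetabar Cell area contractility [K] (shifts the effective
#'   preferred area: `a0_eff = a0 (1 - zetabar/kbar)`).
#' @param etabar Area viscosity [K h].
#' @param tau_r,tau_d,lambda_xx Blade rearrangement law coefficients
#'   (h, h, 1/h).
#' @param k_hinge Hinge shear modulus [K] (0: anisotropic hinge stresses
#'   negligible).
#' @param zeta_xx_h Hinge autonomous anisotropic stress [K].
#' @param tau_r_h,tau_d_h,lambda_xx_h Hinge rearrangement coefficients.
#' @return List of class `rect_params`.
#' @export
rect_params <- function(zeta_xx = 0.333, kbar = 2.07, zetabar = 0.05,
                        etabar = 49, tau_r = 1.7, tau_d = 4.2,
                        lambda_xx = -0.11, k_hinge = 0, zeta_xx_h = 0,
                        tau_r_h = 4.6, tau_d_h = 2.4, lambda_xx_h = -0.05) {
  structure(as.list(environment()), class = "rect_params")
}

#' Boundary parameters of the two-rectangle model
#'
#' @param k_ap Blade effective AP spring constant [K / L0].
#' @param k_pd Blade effective PD spring constant [K / L0].
#' @param k_ap_h,k_pd_h Hinge spring constants.
#' @param gamma Friction coefficient [K h / L0].
#' @param distal_attachment `"fixed"` (wild type: blade firmly attached
#'   distally to the cuticle) or `"free"` (dumpy-like: distal
#'   connections lost).
#' @return List of class `rect_boundary`.
#' @export
rect_boundary <- function(k_ap = 0.5, k_pd = 4.91, k_ap_h = 67.8,
                          k_pd_h = 9.5, gamma = 21.3,
                          distal_attachment = c("fixed", "free")) {
  distal_attachment <- match.arg(distal_attachment)
  structure(list(k_ap = k_ap, k_pd = k_pd, k_ap_h = k_ap_h,
                 k_pd_h = k_pd_h, gamma = gamma,
                 distal_attachment = distal_attachment),
            class = "rect_boundary")
}

## Solve the quasi-static boundary-velocity system at one instant.
## Unknowns: u1 = dx_BH/dt, u2 = dx_D/dt, u3 = dh_B/dt, u4 = dh_H/dt, PH.
.rect_balance <- function(y, par, bnd, inp, t, geo0) {
  xbh <- y["xbh"]; xd <- y["xd"]; hb <- y["hb"]; hh <- y["hh"]
  lb <- xd - xbh; lh <- xbh
  ab <- lb * hb
  qb <- y["qb"]; qh <- y["qh"]
  a0eff <- y["a0b"] * (1 - par$zetabar / par$kbar)
  p_el <- -par$kbar * log(y["ab_cell"] / a0eff)
  sig_b <- 2 * qb + par$zeta_xx              # blade anisotropic stress / K
  sig_h <- 2 * par$k_hinge * qh + par$zeta_xx_h
  dah <- inp$dahdt(t)
  g <- bnd$gamma
  free_distal <- bnd$distal_attachment == "free"
  ## stress components: sigma_xx = sig~ - P, sigma_yy = -sig~ - P
  ## P_B = p_el - etabar * vB, vB = (hb*(u2-u1) + lb*u3)/ab  (linear in u)
  ## Assemble 5x5 linear system M u = rhs for (u1,u2,u3,u4,PH)
  m <- matrix(0, 5, 5); rhs <- numeric(5)
  eta <- par$etabar
  cB <- eta / ab                      # P_B = p_el - cB*(hb*(u2-u1)+lb*u3)
  ## (1) interface: g*u1 = [sig_b - P_B] - [sig_h - PH]
  ##                + k_pd*(lb - lb0) - k_pd_h*(lh - lh0)
  m[1, 1] <- g - cB * hb
  m[1, 2] <- cB * hb
  m[1, 3] <- cB * lb
  m[1, 5] <- -1
  rhs[1] <- sig_b - p_el - sig_h + bnd$k_pd * (lb - geo0$lb0) -
    bnd$k_pd_h * (lh - geo0$lh0)
  ## (2) distal end
  if (free_distal) {
    ## g*u2 = -[sig_b - P_B] - k_pd*(lb - lb0)
    m[2, 1] <- -cB * hb
    m[2, 2] <- g + cB * hb
    m[2, 3] <- cB * lb
    rhs[2] <- -(sig_b - p_el) - bnd$k_pd * (lb - geo0$lb0)
  } else {
    m[2, 2] <- 1; rhs[2] <- 0
  }
  ## (3) blade AP: g*u3 = -[-sig_b - P_B] - k_ap*(hb - hb0)
  m[3, 1] <- -cB * hb
  m[3, 2] <- cB * hb
  m[3, 3] <- g + cB * lb
  rhs[3] <- sig_b + p_el - bnd$k_ap * (hb - geo0$hb0)
  ## (4) hinge AP: g*u4 = sig_h + PH - k_ap_h*(hh - hh0)
  m[4, 4] <- g
  m[4, 5] <- -1
  rhs[4] <- sig_h - bnd$k_ap_h * (hh - geo0$hh0)
  ## (5) hinge area constraint: hh*u1 + lh*u4 = dA_H/dt
  m[5, 1] <- hh
  m[5, 4] <- lh
  rhs[5] <- dah
  sol <- solve(m, rhs)
  names(sol) <- c("u1", "u2", "u3", "u4", "ph")
  sol
}

#' Simulate the two-rectangle model
#'
#' Integrates the coupled cell- and tissue-scale equations in the hinge
#' and blade rectangles: the area balance with measured division and
#' extrusion rates, the decomposition of shear into elongation change
#' plus rearrangements, the elastic constitutive law with area viscosity,
#' the delayed rearrangement law in each region, quasi-static force
#' balance against boundary springs and friction, and the imposed hinge
#' area.
#'
#' @param params A [rect_params()].
#' @param boundary A [rect_boundary()].
#' @param inputs List with functions of time (h): `hinge_area(t)`
#'   (imposed hinge area, L0^2), `kd(t)`, `ke(t)` (blade division and
#'   extrusion rates, 1/h).  Constants are promoted to functions.
#' @param init List with initial `blade_area`, `hinge_area`, `qt_b`,
#'   `qt_h` (region shape nematics), `q_b`, `r_b`, `q_h`, `r_h` (cell
#'   elongation and rearrangement rates), `a_cell` and `a0` (blade cell
#'   areas, arbitrary common unit).
#' @param t_span `c(t0, t1)` in hours.
#' @param dt Output step (h, default 0.05); integration uses an adaptive
#'   solver between outputs.
#' @return Data frame of class `rect_trajectory` with geometry (`x_bh`,
#'   `x_d`, `L_b`, `h_b`, `L_h`, `h_h`, areas), cell state (`q_b`, `r_b`,
#'   `q_h`, `r_h`, `a_cell`, `a0`), rates (`v_b`, `shear_b`, `shear_h`)
#'   and hinge pressure `p_h`.
#' @export
simulate_rectangle_model <- function(params, boundary, inputs, init,
                                     t_span = c(16, 32), dt = 0.05) {
  fun_of <- function(x) if (is.function(x)) x else function(t) rep(x, length(t))
  inp <- list(ah = fun_of(inputs$hinge_area),
              kd = fun_of(inputs$kd), ke = fun_of(inputs$ke))
  eps <- 1e-4
  inp$dahdt <- function(t) (inp$ah(t + eps) - inp$ah(t - eps)) / (2 * eps)
  dim_b <- rect_dims(init$blade_area, init$qt_b)
  dim_h <- rect_dims(init$hinge_area, init$qt_h)
  geo0 <- list(lb0 = dim_b$L, hb0 = dim_b$h, lh0 = dim_h$L, hh0 = dim_h$h)
  y0 <- c(xbh = dim_h$L, xd = dim_h$L + dim_b$L,
          hb = dim_b$h, hh = dim_h$h,
          qb = init$q_b, rb = init$r_b, qh = init$q_h, rh = init$r_h,
          ab_cell = init$a_cell, a0b = init$a0)
  par <- params; bnd <- boundary
  rhs <- function(t, y, p) {
    u <- .rect_balance(y, par, bnd, inp, t, geo0)
    lb <- y["xd"] - y["xbh"]; lh <- y["xbh"]
    dlb <- u["u2"] - u["u1"]
    vb <- (y["hb"] * dlb + lb * u["u3"]) / (lb * y["hb"])
    shear_b <- (dlb / lb - u["u3"] / y["hb"]) / 2
    shear_h <- (u["u1"] / lh - u["u4"] / y["hh"]) / 2
    dqb <- shear_b - y["rb"]
    drb <- if (par$tau_d > 0)
      (y["qb"] / par$tau_r + par$lambda_xx - y["rb"]) / par$tau_d
    else 0
    dqh <- shear_h - y["rh"]
    drh <- if (par$tau_d_h > 0)
      (y["qh"] / par$tau_r_h + par$lambda_xx_h - y["rh"]) / par$tau_d_h
    else 0
    kd <- inp$kd(t); ke <- inp$ke(t)
    da <- y["ab_cell"] * (vb - kd + ke)
    da0 <- -y["a0b"] * kd
    list(c(u["u1"], u["u2"], u["u3"], u["u4"],
           dqb, drb, dqh, drh, da, da0))
  }
  times <- seq(t_span[1], t_span[2], by = dt)
  sol <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  lb <- out$xd - out$xbh; lh <- out$xbh
  res <- data.frame(
    time = out$time, x_bh = out$xbh, x_d = out$xd,
    L_b = lb, h_b = out$hb, L_h = lh, h_h = out$hh,
    blade_area = lb * out$hb, hinge_area = lh * out$hh,
    q_b = out$qb, r_b = out$rb, q_h = out$qh, r_h = out$rh,
    a_cell = out$ab_cell, a0 = out$a0b)
  ## recompute instantaneous rates and hinge pressure at outputs
  rates <- t(vapply(seq_len(nrow(out)), function(i) {
    y <- unlist(out[i, -1])
    u <- .rect_balance(y, par, bnd, inp, out$time[i], geo0)
    lbi <- y["xd"] - y["xbh"]
    dlb <- u["u2"] - u["u1"]
    c(v_b = unname((y["hb"] * dlb + lbi * u["u3"]) / (lbi * y["hb"])),
      shear_b = unname((dlb / lbi - u["u3"] / y["hb"]) / 2),
      shear_h = unname((u["u1"] / y["xbh"] - u["u4"] / y["hh"]) / 2),
      p_h = unname(u["ph"]))
  }, numeric(4)))
  res <- cbind(res, as.data.frame(rates))
  ## algebraic rearrangement branches if tau_d == 0
  if (par$tau_d <= 0) res$r_b <- res$q_b / par$tau_r + par$lambda_xx
  if (par$tau_d_h <= 0) res$r_h <- res$q_h / par$tau_r_h + par$lambda_xx_h
  class(res) <- c("rect_trajectory", "data.frame")
  attr(res, "params") <- par
  attr(res, "boundary") <- bnd
  res
}

#' @export
print.rect_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<rect_trajectory> t = %.1f..%.1f h (%d points)\n",
              x$time[1], x$time[n], n))
  cat(sprintf("  blade: Q %.3f -> %.3f, area %.3f -> %.3f\n",
              x$q_b[1], x$q_b[n], x$blade_area[1], x$blade_area[n]))
  cat(sprintf("  hinge: Q %.3f -> %.3f, area %.3f -> %.3f\n",
              x$q_h[1], x$q_h[n], x$hinge_area[1], x$hinge_area[n]))
  invisible(x)
}

#' Fit rectangle-model parameters to observed trajectories
#'
#' Least-squares fit of selected model parameters to one or more
#' condition datasets, each providing observed time series of blade
#' shear rate, cell elongation and blade area (any subset), together
#' with that condition's inputs and boundary type.  The parameter mask
#' selects which entries of [rect_params()] / [rect_boundary()] are
#' free; all others stay fixed, which encodes staged protocols (e.g.
#' fit tissue parameters on wild-type conditions first, then only the
#' boundary constants for a mutant).
#'
#' @param datasets List of conditions; each a list with `observed` (data
#'   frame with `time` and any of `shear_b`, `q_b`, `blade_area`),
#'   `inputs`, `init`, `boundary` (see [simulate_rectangle_model()]).
#' @param params Starting [rect_params()].
#' @param free Character vector naming the free parameters, from
#'   `names(rect_params())` and `names(rect_boundary())` (boundary
#'   parameters are shared across conditions).
#' @param dt Simulation output step used during fitting (h).
#' @param weights Named weights for the observable columns (default 1).
#' @return List of class `rect_fit` with fitted `params`, per-condition
#'   `boundary`, the objective value, convergence code, and the final
#'   simulated trajectories.
#' @export
fit_rectangle_model <- function(datasets, params = rect_params(),
                                free = character(0), dt = 0.2,
                                weights = NULL) {
  p_names <- names(params)
  b_proto <- datasets[[1]]$boundary
  b_names <- setdiff(names(b_proto), "distal_attachment")
  bad <- setdiff(free, c(p_names, b_names))
  if (length(bad)) stop("unknown free parameters: ",
                        paste(bad, collapse = ", "))
  get_val <- function(nm) if (nm %in% p_names) params[[nm]] else b_proto[[nm]]
  x0 <- unname(vapply(free, get_val, numeric(1)))
  build <- function(x) {
    p <- params; b_extra <- list()
    for (i in seq_along(free)) {
      nm <- free[i]
      if (nm %in% p_names) p[[nm]] <- x[i] else b_extra[[nm]] <- x[i]
    }
    list(p = p, b_extra = b_extra)
  }
  objective <- function(x) {
    pb <- build(x)
    tot <- 0
    for (d in datasets) {
      b <- d$boundary
      for (nm in names(pb$b_extra)) b[[nm]] <- pb$b_extra[[nm]]
      tr <- tryCatch(simulate_rectangle_model(
        pb$p, b, d$inputs, d$init,
        t_span = range(d$observed$time), dt = dt),
        error = function(e) NULL)
      if (is.null(tr)) return(1e6)
      for (col in intersect(c("shear_b", "q_b", "blade_area"),
                            names(d$observed))) {
        pred <- approxfun(tr$time, tr[[col]], rule = 2)(d$observed$time)
        w <- if (!is.null(weights) && col %in% names(weights))
          weights[[col]] else 1
        tot <- tot + w * sum((d$observed[[col]] - pred)^2)
      }
    }
    tot
  }
  if (!length(free)) {
    val <- objective(numeric(0))
    return(structure(list(params = params, value = val, convergence = 0L,
                          free = free), class = "rect_fit"))
  }
  ## optimize in units of the starting values so all parameters have
  ## comparable scale
  sc <- pmax(abs(x0), 0.1)
  lo <- vapply(free, function(nm)
    if (nm %in% b_names) 0 else -Inf, numeric(1))
  opt <- nlminb(x0 / sc, function(z) objective(z * sc), lower = lo / sc,
                control = list(iter.max = 200, rel.tol = 1e-12))
  opt$par <- opt$par * sc
  pb <- build(opt$par)
  fitted_traj <- lapply(datasets, function(d) {
    b <- d$boundary
    for (nm in names(pb$b_extra)) b[[nm]] <- pb$b_extra[[nm]]
    simulate_rectangle_model(pb$p, b, d$inputs, d$init,
                             t_span = range(d$observed$time), dt = dt)
  })
  structure(list(params = pb$p, boundary_overrides = pb$b_extra,
                 estimates = setNames(opt$par, free),
                 value = opt$objective, convergence = opt$convergence,
                 trajectories = fitted_traj, free = free),
            class = "rect_fit")
}

#' @export
print.rect_fit <- function(x, ...) {
  cat("Rectangle-model fit\n")
  if (length(x$free)) {
    cat("  free parameters:\n")
    for (nm in names(x$estimates))
      cat(sprintf("    %s = %.4g\n", nm, x$estimates[nm]))
  } else cat("  (all parameters fixed; forward residual only)\n")
  cat(sprintf("  objective: %.6g\n", x$value))
  invisible(x)
}
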