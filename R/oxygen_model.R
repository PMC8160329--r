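#' Radial oxygen diffusion-consumption model
#'
#' Defines a Krogh-type model of oxygen transport from a capillary into the
#' surrounding tissue: Fick diffusion in cylindrical geometry with
#' Michaelis-Menten consumption by oxidative phosphorylation,
#' \deqn{\frac{dC}{dt} = \frac{1}{r}\frac{\partial}{\partial r}
#'   \left(r D \frac{\partial C}{\partial r}\right)
#'   - \frac{V_{max} C}{C + K_m}.}
#' The capillary edge (`r_c`) carries a Dirichlet boundary fixed at the
#' capillary oxygen concentration; the outer boundary (`r_max`, the point
#' midway between two capillaries) is zero-flux. The effective diffusion
#' coefficient is reduced by a fixed factor across a thin capillary wall
#' adjacent to `r_c`, representing the basement-membrane diffusion barrier.
#'
#' Working units are micrometres, seconds and micromolar internally;
#' `D` is accepted in m^2/min and `Vmax` in mM/min, the units in which
#' brain oxygen diffusivity and consumption rates are usually quoted.
#'
#' @param C_cap Capillary-edge oxygen concentration, uM.
#' @param Vmax Maximum oxidative-phosphorylation rate, mM/min.
#' @param r_max Outer (midpoint-between-capillaries) radius, um.
#' @param r_c Capillary radius, um.
#' @param wall Capillary wall thickness, um.
#' @param wall_D_factor Multiplier applied to `D` within the wall
#'   (0.6 = a 40 percent reduction).
#' @param D Oxygen diffusion coefficient in brain at 37 C, m^2/min.
#' @param Km Michaelis constant for oxygen, uM.
#' @param n_cells Number of finite-volume cells outside the wall.
#' @param wall_cell Maximum cell width inside the wall layer, um.
#' @param horizon Default time horizon for transient solves, s.
#' @return An object of class `oxygen_model`.
#' @seealso [steady_profile()], [solve_radial()], [calibrate_rmax()],
#'   [centile_sweep()]
#' @export
#' @examples
#' m <- oxygen_model(C_cap = 14, Vmax = 2, r_max = 14.4)
#' p <- steady_profile(m)
#' p$midpoint
oxygen_model <- function(C_cap, Vmax, r_max,
                         r_c = 2.5, wall = 0.2, wall_D_factor = 0.6,
                         D = 9.24e-8, Km = 1,
                         n_cells = 400, wall_cell = 0.05, horizon = 20) {
  stopifnot(C_cap >= 0, Vmax >= 0, r_c > 0, wall >= 0,
            r_max > r_c + wall, wall_D_factor > 0, wall_D_factor <= 1,
            D > 0, Km > 0, n_cells >= 10, horizon > 0)
  m <- list(C_cap = C_cap, Vmax = Vmax, r_max = r_max, r_c = r_c,
            wall = wall, wall_D_factor = wall_D_factor, D = D, Km = Km,
            n_cells = n_cells, wall_cell = wall_cell, horizon = horizon)
  class(m) <- "oxygen_model"
  m
}

# Finite-volume grid: faces, cell centers, per-cell D and volumes.
# A face is placed exactly at the outer edge of the wall so the reduced-D
# layer is resolved by whole cells of width <= wall_cell.
.oxy_grid <- function(m) {
  D_um2_s <- m$D * 1e12 / 60           # m^2/min -> um^2/s
  Vmax_uM_s <- m$Vmax * 1000 / 60      # mM/min -> uM/s
  if (m$wall > 0) {
    n_w <- max(1L, ceiling(m$wall / m$wall_cell))
    f_wall <- seq(m$r_c, m$r_c + m$wall, length.out = n_w + 1)
  } else {
    f_wall <- m$r_c
  }
  f_out <- seq(m$r_c + m$wall, m$r_max, length.out = m$n_cells + 1)
  faces <- c(f_wall[-length(f_wall)], f_out)
  centers <- (faces[-1] + faces[-length(faces)]) / 2
  vol <- (faces[-1]^2 - faces[-length(faces)]^2) / 2  # per radian, per length
  Dcell <- ifelse(centers < m$r_c + m$wall, m$wall_D_factor * D_um2_s, D_um2_s)
  n <- length(centers)
  # harmonic-mean diffusivity at interior faces (distance-weighted)
  hl <- faces[2:n] - centers[1:(n - 1)]
  hr <- centers[2:n] - faces[2:n]
  Dface <- (hl + hr) / (hl / Dcell[1:(n - 1)] + hr / Dcell[2:n])
  list(faces = faces, centers = centers, vol = vol, n = n,
       Dcell = Dcell, Dface = Dface,
       Vmax = Vmax_uM_s, Km = m$Km,
       # left boundary: Dirichlet at faces[1]
       hleft = centers[1] - faces[1],
       dr = c(NA, centers[2:n] - centers[1:(n - 1)]))
}

# Time derivative of the finite-volume system (uM/s).
.oxy_rhs <- function(C, g, C_cap) {
  n <- g$n
  # fluxes (per radian, per unit length): positive = outward
  q_int <- -g$Dface * g$faces[2:n] * (C[2:n] - C[1:(n - 1)]) / g$dr[2:n]
  q_left <- -g$Dcell[1] * g$faces[1] * (C[1] - C_cap) / g$hleft
  q <- c(q_left, q_int, 0)  # zero flux at outer face
  (q[1:n] - q[2:(n + 1)]) / g$vol - g$Vmax * C / (C + g$Km)
}

# Steady state by Picard iteration on the linearized reaction term;
# tridiagonal solve (Thomas algorithm) per iteration.
.oxy_steady <- function(m, tol = 1e-12, max_iter = 200) {
  g <- .oxy_grid(m)
  n <- g$n
  aW <- c(g$Dcell[1] * g$faces[1] / g$hleft,
          g$Dface * g$faces[2:n] / g$dr[2:n]) / g$vol   # coupling west
  aE <- c(g$Dface * g$faces[2:n] / g$dr[2:n], 0) / g$vol # coupling east
  C <- rep(m$C_cap, n)
  for (it in seq_len(max_iter)) {
    k <- g$Vmax / (C + g$Km)
    lower <- -aW[2:n]
    upper <- -aE[1:(n - 1)]
    diagm <- aW + aE + k
    rhs <- c(aW[1] * m$C_cap, rep(0, n - 1))
    Cn <- .thomas(lower, diagm, upper, rhs)
    delta <- max(abs(Cn - C) / pmax(abs(Cn), 1e-12))
    C <- Cn
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("steady-state iteration did not fully converge (delta = ",
            signif(delta, 3), ")")
  list(grid = g, C = C, iterations = it)
}

# Tridiagonal solver.
.thomas <- function(lower, diagm, upper, rhs) {
  n <- length(diagm)
  cp <- numeric(n - 1); dp <- numeric(n)
  cp[1] <- upper[1] / diagm[1]
  dp[1] <- rhs[1] / diagm[1]
  for (i in 2:n) {
    denom <- diagm[i] - lower[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Steady-state oxygen profile
#'
#' Solves the radial model to steady state and returns the oxygen
#' concentration profile C(r) together with the local consumption rate as a
#' fraction of Vmax, \eqn{VO_2/V_{max} = C/(C + K_m)}. The "midpoint" values
#' are those at the outer boundary, i.e. in the tissue midway between two
#' capillaries, which is the tissue furthest from a vessel.
#'
#' @param m An [oxygen_model()].
#' @param method `"newton"` (damped Picard/Newton iteration on the
#'   discretized steady equations; fast, default) or `"march"` (stiff time
#'   integration until the relative change falls below 1e-6 per second;
#'   cross-checks the direct solve).
#' @return An object of class `oxygen_profile` with elements `r` (um),
#'   `C` (uM), `VO2_frac`, `midpoint` (list with `C` and `VO2_frac`),
#'   `influx`, `consumption` and `flux_imbalance` (relative mass-balance
#'   error), and the model `m`.
#' @export
steady_profile <- function(m, method = c("newton", "march")) {
  method <- match.arg(method)
  if (method == "newton") {
    s <- .oxy_steady(m)
    g <- s$grid; C <- s$C
  } else {
    sol <- solve_radial(m, times = seq(0, m$horizon, by = 0.25))
    g <- .oxy_grid(m)
    C <- as.numeric(sol$C[nrow(sol$C), ])
    rate <- max(abs(.oxy_rhs(C, g, m$C_cap)) / pmax(C, 1e-9))
    if (rate > 1e-6)
      warning("time march did not reach steady state (max dC/C = ",
              signif(rate, 3), " /s); increase horizon")
  }
  influx <- g$Dcell[1] * g$faces[1] * (m$C_cap - C[1]) / g$hleft
  consumption <- sum(g$Vmax * C / (C + g$Km) * g$vol)
  p <- list(r = g$centers, C = C, VO2_frac = C / (C + g$Km),
            midpoint = list(r = m$r_max, C = C[g$n],
                            VO2_frac = C[g$n] / (C[g$n] + g$Km)),
            influx = influx, consumption = consumption,
            flux_imbalance = abs(influx - consumption) /
              max(consumption, .Machine$double.eps),
            model = m, method = method)
  class(p) <- "oxygen_profile"
  p
}

#' Transient solution of the radial oxygen model
#'
#' Integrates the discretized model from zero initial oxygen with stiff
#' time integration (method of lines, `deSolve::ode.1D`).
#'
#' @param m An [oxygen_model()].
#' @param times Output times, s.
#' @param C0 Initial concentration (scalar or per-cell vector), uM.
#' @return A list with `times`, matrix `C` (time x radius), `r`, and
#'   `midpoint` (the outer-boundary concentration time course).
#' @export
solve_radial <- function(m, times = seq(0, m$horizon, by = 0.05), C0 = 0) {
  g <- .oxy_grid(m)
  y0 <- rep_len(C0, g$n)
  f <- function(t, y, parms) list(.oxy_rhs(y, g, m$C_cap))
  sol <- deSolve::ode.1D(y = y0, times = times, func = f, parms = NULL,
                         nspec = 1, method = "lsoda",
                         rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed; see deSolve diagnostics")
  Cmat <- unname(sol[, -1, drop = FALSE])
  list(times = times, C = Cmat, r = g$centers,
       midpoint = Cmat[, g$n], model = m)
}

#' Time to reach steady state
#'
#' First time after which the midpoint (outer boundary) concentration stays
#' within a relative tolerance of its steady-state value, starting from
#' zero oxygen everywhere.
#'
#' @param m An [oxygen_model()].
#' @param tol Relative tolerance (default 0.01, i.e. within 1 percent).
#' @param dt Sampling interval of the transient solution, s.
#' @return Time in seconds.
#' @export
time_to_steady <- function(m, tol = 0.01, dt = 0.02) {
  ps <- steady_profile(m)
  target <- ps$midpoint$C
  if (target <= 0) stop("steady midpoint concentration is not positive")
  sol <- solve_radial(m, times = seq(0, m$horizon, by = dt))
  ok <- abs(sol$midpoint - target) / target <= tol
  if (!ok[length(ok)])
    stop("horizon too short: midpoint not within tolerance at t = ",
         m$horizon, " s")
  # first index from which the condition holds for all later times
  idx <- max(which(!ok), 0) + 1
  sol$times[idx]
}

#' Calibrate the outer radius to a target midpoint consumption fraction
#'
#' Bisects on `r_max` so that the steady-state consumption fraction
#' VO2/Vmax at the midpoint between capillaries equals a target. The
#' midpoint fraction decreases monotonically with `r_max` (a larger tissue
#' territory per capillary lowers the far-field oxygen), so bisection on a
#' bracket is exact.
#'
#' @param m An [oxygen_model()]; its `r_max` is ignored.
#' @param target Target midpoint VO2/Vmax, strictly inside (0, 1).
#' @param bracket Search interval for `r_max`, um.
#' @param tol_r Absolute tolerance on `r_max`, um.
#' @return The calibrated `r_max` in um.
#' @export
calibrate_rmax <- function(m, target, bracket = c(m$r_c + m$wall + 1, 100),
                           tol_r = 0.05) {
  stopifnot(target > 0, target < 1, length(bracket) == 2,
            bracket[1] > m$r_c + m$wall, diff(bracket) > 0)
  fr <- function(r_max) {
    mm <- m; mm$r_max <- r_max
    class(mm) <- "oxygen_model"
    steady_profile(mm)$midpoint$VO2_frac - target
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- fr(lo); fhi <- fr(hi)
  if (flo < 0 || fhi > 0)
    stop("target VO2 fraction ", target, " not attainable for r_max in [",
         lo, ", ", hi, "] um")
  while (hi - lo > tol_r) {
    mid <- (lo + hi) / 2
    if (fr(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Steady profiles over a set of capillary spacings
#'
#' Solves the steady model once per capillary spacing (the domain extent,
#' i.e. twice the tissue-distance centile under the separation convention)
#' and tabulates the midpoint oxygen concentration and consumption
#' fraction.
#'
#' @param m Template [oxygen_model()]; `r_max` is replaced per row.
#' @param spacings Positive ascending spacings, um.
#' @param centiles Optional centile ranks labelling each spacing.
#' @return A data.frame with columns `spacing`, `centile`, `midpoint_C`,
#'   `midpoint_VO2_frac`, `inhibition` (1 - VO2/Vmax).
#' @export
centile_sweep <- function(m, spacings, centiles = NULL) {
  stopifnot(length(spacings) >= 1, all(diff(spacings) > 0),
            all(spacings > m$r_c + m$wall))
  if (is.null(centiles)) centiles <- rep(NA_real_, length(spacings))
  stopifnot(length(centiles) == length(spacings))
  rows <- lapply(seq_along(spacings), function(i) {
    mm <- m; mm$r_max <- spacings[i]; class(mm) <- "oxygen_model"
    p <- steady_profile(mm)
    data.frame(spacing = spacings[i], centile = centiles[i],
               midpoint_C = p$midpoint$C,
               midpoint_VO2_frac = p$midpoint$VO2_frac,
               inhibition = 1 - p$midpoint$VO2_frac)
  })
  do.call(rbind, rows)
}

#' Fraction of tissue with inhibited oxygen consumption
#'
#' Combines a [centile_sweep()] table (midpoint consumption fraction per
#' capillary-spacing centile) with a tissue-distance distribution: tissue
#' at the p-th centile distance from a vessel experiences the midpoint
#' conditions of capillaries spaced at twice that centile distance, so the
#' fraction of tissue whose consumption is inhibited by at least a
#' threshold is one minus the centile rank at which the inhibition curve
#' crosses that threshold (linear interpolation between solved centiles).
#'
#' @param sweep Output of [centile_sweep()] with non-missing `centile`.
#' @param thresholds Inhibition thresholds (fractions of Vmax).
#' @return Named vector of tissue fractions in \[0, 1\].
#' @export
inhibition_fractions <- function(sweep, thresholds = c(0.10, 0.20)) {
  stopifnot(is.data.frame(sweep), all(is.finite(sweep$centile)))
  p <- sweep$centile; inh <- sweep$inhibition
  o <- order(p); p <- p[o]; inh <- inh[o]
  if (is.unsorted(inh))  # inhibition must grow with spacing centile
    inh <- cummax(inh)
  out <- vapply(thresholds, function(thr) {
    if (thr > max(inh)) return(0)
    if (thr <= min(inh)) return(1 - min(p) / 100)
    pc <- stats::approx(inh, p, xout = thr, ties = "ordered")$y
    1 - pc / 100
  }, numeric(1))
  names(out) <- paste0(">=", thresholds * 100, "%")
  out
}

#' @export
print.oxygen_model <- function(x, ...) {
  cat("Radial oxygen diffusion-consumption model\n")
  cat(sprintf("  capillary: r_c %.2f um, wall %.2f um (D x %.2f), C_cap %.3g uM\n",
              x$r_c, x$wall, x$wall_D_factor, x$C_cap))
  cat(sprintf("  tissue:    r_max %.2f um, D %.3g m^2/min, Vmax %.3g mM/min, Km %.3g uM\n",
              x$r_max, x$D, x$Vmax, x$Km))
  cat(sprintf("  grid:      %d cells (+wall refinement <= %.0f nm)\n",
              x$n_cells, x$wall_cell * 1000))
  invisible(x)
}

#' @export
coef.oxygen_model <- function(object, ...) {
  unlist(object[c("C_cap", "Vmax", "r_max", "r_c", "wall",
                  "wall_D_factor", "D", "Km")])
}

#' @export
print.oxygen_profile <- function(x, ...) {
  cat("Steady-state oxygen profile (", x$method, " solve)\n", sep = "")
  print(x$model)
  cat(sprintf("  midpoint [O2] %.3g uM, VO2/Vmax %.1f%%, mass-balance error %.2g%%\n",
              x$midpoint$C, 100 * x$midpoint$VO2_frac,
              100 * x$flux_imbalance))
  invisible(x)
}

#' @export
summary.oxygen_profile <- function(object, ...) {
  out <- list(midpoint = object$midpoint,
              range_C = range(object$C),
              flux_imbalance = object$flux_imbalance,
              model = coef(object$model))
  class(out) <- "summary.oxygen_profile"
  out
}

#' @export
print.summary.oxygen_profile <- function(x, ...) {
  cat("Oxygen profile summary\n")
  cat(sprintf("  [O2] range %.3g - %.3g uM\n", x$range_C[1], x$range_C[2]))
  cat(sprintf("  midpoint (r = %.2f um): [O2] %.3g uM, VO2/Vmax %.1f%%\n",
              x$midpoint$r, x$midpoint$C, 100 * x$midpoint$VO2_frac))
  cat(sprintf("  steady-state mass-balance error %.3g%%\n",
              100 * x$flux_imbalance))
  invisible(x)
}

#' @export
predict.oxygen_profile <- function(object, r, ...) {
  if (missing(r)) return(object$C)
  stats::approx(object$r, object$C, xout = r, rule = 2)$y
}

#' @export
plot.oxygen_profile <- function(x, which = c("C", "VO2"), ...) {
  which <- match.arg(which)
  if (which == "C") {
    graphics::plot(x$r, x$C, type = "l", xlab = "r (um)",
                   ylab = "[O2] (uM)", ...)
  } else {
    graphics::plot(x$r, 100 * x$VO2_frac, type = "l", xlab = "r (um)",
                   ylab = "VO2 (% of Vmax)", ...)
  }
  invisible(x)
}
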