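#' Radially symmetric tumor zonation state
#'
#' The radially symmetric reduction of the model describes the tumor by three
#' interface radii: `r_n` (necrotic/quiescent), `r_q` (quiescent/proliferative)
#' and `r_p` (the outer rim), with `0 <= r_n <= r_q <= r_p < 1` in units of the
#' oxygen-source radius.
#'
#' @param r_n,r_q,r_p interface radii (nondimensional).
#' @return An object of class `"radial_state"`.
#' @export
#' @examples
#' radial_state(0.1, 0.2, 0.3)
radial_state <- function(r_n, r_q, r_p) {
  stopifnot(is.numeric(r_n), is.numeric(r_q), is.numeric(r_p))
  tol <- 1e-12
  if (r_n < -tol || r_n > r_q + tol || r_q > r_p + tol || r_p >= 1)
    stop("radii must satisfy 0 <= r_n <= r_q <= r_p < 1", call. = FALSE)
  structure(list(r_n = max(r_n, 0), r_q = max(r_q, r_n, 0), r_p = r_p),
            class = "radial_state")
}

#' @export
print.radial_state <- function(x, ...) {
  cat(sprintf("radial tumor state: r_n = %.6g, r_q = %.6g, r_p = %.6g\n",
              x$r_n, x$r_q, x$r_p))
  invisible(x)
}

#' Closed-form radial oxygen profile
#'
#' Oxygen obeys a quasi-stationary diffusion equation with a constant sink of
#' strength `lambda` on the living annulus `r_n <= r <= r_p`, far-field value 1
#' at the source radius `r = 1`, and a flat profile inside the necrotic core
#' (no consumption there). The solution is C1 across the rim and logarithmic in
#' between.
#'
#' @param r radii at which to evaluate (vectorized), in `[0, 1]`.
#' @param state a [radial_state()].
#' @param lambda oxygen consumption/diffusion ratio.
#' @return Oxygen concentrations at `r` (far-field units).
#' @export
#' @examples
#' oxygen_profile(c(0, 0.3, 1), radial_state(0, 0, 0.3), lambda = 1.15)
oxygen_profile <- function(r, state, lambda) {
  stopifnot(inherits(state, "radial_state"), lambda >= 0)
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]", call. = FALSE)
  rn <- state$r_n; rp <- state$r_p
  mid <- function(r) {
    # guard rn = 0: rn^2 * log r -> 0 even as r -> 0
    lg <- ifelse(r > 0, log(r), 0)
    1 + lambda / 2 * (rp^2 * log(rp) - rn^2 * lg + (r^2 - rp^2) / 2)
  }
  out <- numeric(length(r))
  o <- r >= rp
  out[o] <- 1 + lambda / 2 * (rp^2 - rn^2) * ifelse(r[o] > 0, log(r[o]), 0)
  m <- r < rp & r >= rn
  out[m] <- mid(r[m])
  i <- r < rn
  if (any(i)) out[i] <- mid(rn)   # flat core; equals kappa_death for consistent states
  out
}

#' Reduced oxygen-threshold parameters
#'
#' The zonation of a radially symmetric tumor depends on the oxygen thresholds
#' only through `K_prol = 4 (1 - kappa_prol) / lambda` and
#' `K_death = 4 (1 - kappa_death) / lambda`.
#'
#' @param kappa_prol,kappa_death oxygen thresholds.
#' @param lambda consumption/diffusion ratio, positive.
#' @return A list with `K_prol` and `K_death` (`K_death >= K_prol`).
#' @export
reduced_params <- function(kappa_prol, kappa_death, lambda) {
  stopifnot(lambda > 0, kappa_death <= kappa_prol)
  list(K_prol = 4 * (1 - kappa_prol) / lambda,
       K_death = 4 * (1 - kappa_death) / lambda)
}

# right-hand sides of the two algebraic zonation relations
.relation_prol <- function(rn, rq, rp)
  -rp^2 * log(rp^2) + (if (rn > 0 && rq > 0) rn^2 * log(rq^2) else 0) - rq^2 + rp^2
.relation_death <- function(rn, rp)
  -rp^2 * log(rp^2) + (if (rn > 0) rn^2 * log(rn^2) else 0) - rn^2 + rp^2

#' Residuals of the zonation relations
#'
#' For a radially symmetric tumor the interior interface radii are tied to the
#' rim radius by two algebraic relations obtained from evaluating the oxygen
#' profile at the thresholds. This returns their residuals (zero for a
#' consistent state).
#'
#' @param state a [radial_state()].
#' @param lambda,kappa_prol,kappa_death oxygen parameters.
#' @return Named numeric vector with components `prol` and `death`.
#' @seealso [solve_regions()] for the inverse problem.
#' @export
region_relations <- function(state, lambda, kappa_prol, kappa_death) {
  K <- reduced_params(kappa_prol, kappa_death, lambda)
  c(prol = .relation_prol(state$r_n, state$r_q, state$r_p) - K$K_prol,
    death = .relation_death(state$r_n, state$r_p) - K$K_death)
}

#' Solve for the interior zonation radii given the rim radius
#'
#' Inverts the zonation relations: given `K_prol`, `K_death` (see
#' [reduced_params()]) and the rim radius `r_p`, finds `r_n` and `r_q` by
#' bracketed root finding. Both relations are monotone in the unknown radius,
#' so the roots are unique when they exist. Tumors too small to starve their
#' center return the `r_n = 0` (and possibly `r_q = 0`) branch; a tumor whose
#' rim oxygen is already below the proliferation threshold returns
#' `r_q = r_p`.
#'
#' @param K_prol,K_death reduced parameters, `K_death >= K_prol`.
#' @param r_p rim radius in `(0, 1)`.
#' @return A [radial_state()] with attributes `necrotic_core` and
#'   `proliferative_rim` (logical flags for the active branches).
#' @export
#' @examples
#' K <- reduced_params(0.94, 0.93, 1.15)
#' solve_regions(K$K_prol, K$K_death, 0.3)
solve_regions <- function(K_prol, K_death, r_p) {
  stopifnot(r_p > 0, r_p < 1, K_death >= K_prol, K_prol >= 0)
  rtol <- 1e-13
  # necrotic interface: relation_death(rn) - K_death = 0, decreasing in rn
  f_n <- function(rn) .relation_death(rn, r_p) - K_death
  has_core <- f_n(0) > 0
  r_n <- if (has_core)
    uniroot(f_n, c(1e-14, r_p * (1 - 1e-14)), tol = rtol)$root else 0
  # quiescent interface: relation_prol(rq) - K_prol = 0, decreasing in rq
  f_q <- function(rq) .relation_prol(r_n, rq, r_p) - K_prol
  if (f_q(r_p) > 0) {
    r_q <- r_p; prol_rim <- FALSE          # rim oxygen below kappa_prol
  } else {
    prol_rim <- TRUE
    lo <- max(r_n, 1e-14)
    r_q <- if (f_q(lo) <= 0) r_n else uniroot(f_q, c(lo, r_p), tol = rtol)$root
  }
  st <- radial_state(r_n, r_q, r_p)
  attr(st, "necrotic_core") <- has_core
  attr(st, "proliferative_rim") <- prol_rim
  st
}

#' Growth rate of the squared rim radius
#'
#' Mass balance of the constant-density tumor gives
#' `d(r_p^2)/dt = -mu_death r_n^2 - r_q^2 + r_p^2`: the proliferative annulus
#' adds volume at the (unit) proliferation rate and the necrotic core loses it
#' at rate `mu_death`.
#'
#' @param state a [radial_state()].
#' @param mu_death death rate.
#' @return `d(r_p^2)/dt` (nondimensional).
#' @export
radial_rhs <- function(state, mu_death) {
  stopifnot(inherits(state, "radial_state"), mu_death >= 0)
  -mu_death * state$r_n^2 - state$r_q^2 + state$r_p^2
}

#' Integrate the radially symmetric tumor dynamics
#'
#' Solves the scalar ODE for `r_p^2` with the interior radii slaved to the rim
#' through the zonation relations at every step (the oxygen field is
#' quasi-stationary, so zonation adapts instantaneously). Produces the
#' characteristic sigmoidal volume curve: exponential early growth followed by
#' a plateau at the stationary state.
#'
#' @param r_p0 initial rim radius in `(0, 1)`.
#' @param params a [model_params()] (or list coercible to one).
#' @param t_end final time (proliferation times).
#' @param dt_out output spacing.
#' @return A data frame with columns `t, r_n, r_q, r_p, V_p, V_q, V_n`, where
#'   the volumes are the cumulative disc areas `pi r^2` of the respective
#'   interfaces. If the rim approaches the oxygen source (`r_p -> 1`,
#'   avascularity breakdown) integration stops early and the result carries
#'   attribute `breakdown = TRUE`.
#' @export
#' @examples
#' tr <- integrate_radial(0.05, preset("table2_pde"), t_end = 5)
#' tail(tr, 1)
integrate_radial <- function(r_p0, params, t_end, dt_out = 0.1) {
  params <- as_model_params(params)
  stopifnot(r_p0 > 0, r_p0 < 1, t_end > 0)
  K <- reduced_params(params$kappa_prol, params$kappa_death, params$lambda)
  rhs_ode <- function(t, y, p) {
    rp <- sqrt(min(max(y[1], 1e-16), 1 - 1e-12))
    st <- solve_regions(K$K_prol, K$K_death, rp)
    list(radial_rhs(st, params$mu_death))
  }
  rootfun <- function(t, y, p) y[1] - (1 - 1e-6)^2   # stop before breakdown
  times <- unique(c(seq(0, t_end, by = dt_out), t_end))
  sol <- deSolve::ode(y = c(V = r_p0^2), times = times, func = rhs_ode,
                      parms = NULL, method = "lsoda",
                      rootfunc = rootfun, events = list(root = TRUE, terminalroot = 1),
                      rtol = 1e-10, atol = 1e-12)
  V <- pmax(sol[, "V"], 0)
  rp <- sqrt(V)
  zon <- t(vapply(rp, function(r) {
    s <- solve_regions(K$K_prol, K$K_death, max(r, 1e-8))
    c(s$r_n, s$r_q)
  }, numeric(2)))
  out <- data.frame(t = sol[, "time"], r_n = zon[, 1], r_q = zon[, 2], r_p = rp,
                    V_p = pi * rp^2, V_q = pi * zon[, 2]^2, V_n = pi * zon[, 1]^2)
  attr(out, "breakdown") <- max(rp) >= 1 - 2e-6
  out
}

#' Find the nontrivial stationary zonation
#'
#' Locates the radially symmetric equilibrium: the rim radius at which the
#' volume gained by proliferation balances the volume lost in the necrotic
#' core, with the interior radii satisfying the zonation relations.
#'
#' @param params a [model_params()].
#' @param r_p_max largest rim radius scanned (default just below 1).
#' @return A [radial_state()] at equilibrium (residuals below 1e-10).
#' @export
#' @examples
#' find_stationary(preset("table2_pde"))
find_stationary <- function(params, r_p_max = 0.995) {
  params <- as_model_params(params)
  K <- reduced_params(params$kappa_prol, params$kappa_death, params$lambda)
  g <- function(rp) radial_rhs(solve_regions(K$K_prol, K$K_death, rp),
                               params$mu_death)
  grid <- seq(0.01, r_p_max, length.out = 400)
  vals <- vapply(grid, g, numeric(1))
  sgn <- which(vals[-1] <= 0 & vals[-length(vals)] > 0)
  if (!length(sgn))
    stop("no nontrivial stationary state: tumor either collapses or grows to ",
         "the oxygen source (avascularity breakdown)", call. = FALSE)
  i <- sgn[1]
  rp <- uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  solve_regions(K$K_prol, K$K_death, rp)
}

#' Eigenvalue of the radially symmetric dynamics at equilibrium
#'
#' Linearizing the rim dynamics around a stationary zonation (with the
#' interior radii slaved to the rim) yields a single eigenvalue
#' `Lambda_r = 1 - (log r_p / log r_n) (mu_death + 2 log(r_q/r_n) /
#' (r_q^2 - r_n^2) * r_q^2)`. Negative values mean the equilibrium tumor
#' volume is stable. The degenerate cases `r_n -> 0` and `r_q -> r_n` are
#' evaluated through their analytic limits.
#'
#' @param state a stationary [radial_state()].
#' @param mu_death death rate.
#' @return The eigenvalue (1/time).
#' @seealso [prop31_guaranteed_stable()] for the size-only sufficient
#'   condition.
#' @export
eigenvalue_radial <- function(state, mu_death) {
  stopifnot(inherits(state, "radial_state"), mu_death >= 0)
  rn <- state$r_n; rq <- state$r_q; rp <- state$r_p
  if (rp <= 0) stop("degenerate state: r_p must be positive", call. = FALSE)
  if (rn < 1e-300) return(1 + 2 * log(rp))          # limit r_n -> 0
  a <- rn^2; b <- rq^2
  # Q = b * log(b/a) / (b - a), with series for b -> a
  x <- (b - a) / a
  Q <- if (abs(x) < 1e-6) (b / a) * (1 - x / 2 + x^2 / 3) else b * log(b / a) / (b - a)
  1 - log(rp) / log(rn) * (mu_death + Q)
}

#' Size-only sufficient condition for radial stability
#'
#' A stationary radially symmetric tumor is guaranteed to have a negative
#' radial eigenvalue whenever its rim radius does not exceed `exp(-1)`,
#' irrespective of the interior zonation or the death rate. The condition is
#' sufficient only: larger tumors may still be stable for particular
#' zonations.
#'
#' @param state a stationary [radial_state()].
#' @return `TRUE` iff `r_p <= exp(-1)`.
#' @export
prop31_guaranteed_stable <- function(state) {
  stopifnot(inherits(state, "radial_state"))
  state$r_p <= exp(-1)
}

#' Closed-form radial pressure profile
#'
#' The quasi-stationary pressure of a radially symmetric tumor with constant
#' density: sources of unit strength in the proliferative annulus, sinks of
#' strength `mu_death` in the necrotic core, a harmonic external field scaled
#' by `1/D_ext`, and a Young-Laplace curvature pressure `sigma / r_p` added
#' at the rim. The
#' negative radial pressure gradient at the rim equals the rim velocity
#' (Darcy's law).
#'
#' @param r radii at which to evaluate (vectorized), `r >= 0`.
#' @param state a [radial_state()].
#' @param mu_death death rate.
#' @param D_ext external Darcy ratio (may be `Inf`).
#' @param sigma surface tension.
#' @param p_ext_const ambient pressure constant added throughout.
#' @return Pressure values at `r`.
#' @export
pressure_profile <- function(r, state, mu_death, D_ext = Inf, sigma = 0,
                             p_ext_const = 0) {
  stopifnot(inherits(state, "radial_state"), all(r >= 0))
  rn <- state$r_n; rq <- state$r_q; rp <- state$r_p
  Mtot <- mu_death * rn^2 + rq^2 - rp^2        # net source strength / pi... (2x)
  p_ext_at <- function(r) {
    if (is.infinite(D_ext)) rep(0, length(r))
    else Mtot / (2 * D_ext) * ifelse(r > 0, log(r), 0)
  }
  base <- p_ext_at(rp) + sigma / rp + p_ext_const
  logterm <- function(coef, num, den) {
    # coef * log(num/den), with the 0 * log(0) limit evaluated as 0
    if (coef == 0) rep(0, length(num)) else coef * log(num / den)
  }
  p_p <- function(r) logterm((mu_death * rn^2 + rq^2) / 2, r, rp) -
    (r^2 - rp^2) / 4 + base
  p_q_at_rq <- if (rq < rp) p_p(rq) else base
  p_q <- function(r) p_q_at_rq + logterm(rn^2 / 2, r, rq)
  p_n_at_rn <- if (rn > 0) p_q(rn) else p_q_at_rq
  p_n <- function(r) p_n_at_rn + mu_death / 4 * (r^2 - rn^2)
  out <- numeric(length(r))
  sel <- r > rp
  out[sel] <- p_ext_at(r[sel]) + p_ext_const
  sel <- r <= rp & r >= rq
  out[sel] <- p_p(r[sel])
  sel <- r < rq & r >= rn
  out[sel] <- p_q(pmax(r[sel], 1e-300))
  sel <- r < rn
  out[sel] <- p_n(r[sel])
  out
}
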