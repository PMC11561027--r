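#' Mean-field cell density state
#'
#' The deterministic counterpart of the lattice population: a cell density
#' `rho` in `[0, 1]` per node, advected by the Darcy velocity `-grad p` and
#' grown/shrunk by the oxygen-dependent source. The tumor domain is the
#' region where `rho >= 0.5` (sharp interface by threshold, which keeps the
#' comparison with the lattice model grid-identical).
#'
#' @param grid a [build_lattice()] grid.
#' @param rho density vector over all lattice nodes, in `[0, 1]`.
#' @param t simulation time.
#' @return An object of class `"density_state"`.
#' @export
density_state <- function(grid, rho, t = 0) {
  stopifnot(inherits(grid, "lattice_grid"), length(rho) == grid$n^2)
  if (any(rho < -1e-12 | rho > 1 + 1e-12))
    stop("density must lie in [0, 1]", call. = FALSE)
  structure(list(grid = grid, rho = pmin(pmax(rho, 0), 1), t = t),
            class = "density_state")
}

#' @export
print.density_state <- function(x, ...) {
  cat(sprintf("density state at t = %.4g: mass %.5g, tumor area %.5g\n",
              x$t, sum(x$rho) * x$grid$h^2, sum(x$rho >= 0.5) * x$grid$h^2))
  invisible(x)
}

#' Oxygen-dependent growth source
#'
#' The mean-field source: `+rho` (unit proliferation rate) where oxygen is
#' above the proliferation threshold, `0` in the quiescent band, and
#' `-mu_death rho` where oxygen is below the death threshold (necrotic
#' material loses mass directly; the lattice degradation step has no
#' mean-field counterpart). The source acts on the tumor domain only and at
#' the saturated density `rho = 1` the sharp-interface model carries there:
#' with unit-rate growth, pressure sources and oxygen sinks all evaluated on
#' the domain, a saturated cell is an exact fixed point of the combined
#' advection-reaction update (`-rho div v + Gamma = 0`), so the interior
#' stays at density 1 and the interface self-sharpens. The partial-density
#' fringe outside the domain is pure interface: it carries no source and is
#' only advected.
#'
#' @param state a [density_state()].
#' @param c oxygen `scalar_field` for this state.
#' @param params a [model_params()].
#' @param domain optional logical tumor-domain mask (defaults to
#'   `rho >= 0.5`); the driver passes a sub-cell-smoothed mask.
#' @return Source vector over all lattice nodes (1/time).
#' @export
growth_source <- function(state, c, params, domain = NULL) {
  params <- as_model_params(params)
  stopifnot(inherits(state, "density_state"))
  lab <- .density_labels(state, c, params, domain)
  g <- numeric(state$grid$n^2)
  g[lab$prolif] <- 1
  g[lab$necrotic] <- -params$mu_death
  g
}

#' One conservative advection-reaction step of the density
#'
#' Finite-volume advection of `rho` with face velocities from the pressure
#' gradient (`v = -grad p`; faces with undefined pressure on either side
#' carry no flux), then the explicit growth/death update `dt * Gamma`, then
#' optional zero-mean Gaussian noise of standard deviation
#' `noise_amp * sqrt(dt)` on interface nodes (`0 < rho < 1`), mimicking the
#' number fluctuations of the stochastic model. The upwind fluxes use a
#' superbee-limited linear reconstruction: the scheme stays monotone (TVD,
#' so `rho` remains in `[0, 1]` up to the reaction term) while keeping the
#' tumor interface a few cells wide; plain first-order upwind smears the
#' rim anisotropically along the lattice axes, which visibly squares off
#' the contour. The result is clipped to `[0, 1]` after the noise. The
#' advective CFL condition `max|v| dt / h <= 0.5` per direction is
#' enforced.
#'
#' @param state a [density_state()].
#' @param p pressure `scalar_field` from [solve_pressure()].
#' @param Gamma source vector from [growth_source()].
#' @param dt time step.
#' @param noise_amp noise amplitude (0 disables; uses the current RNG
#'   stream).
#' @return The advanced `density_state` (time incremented by `dt`).
#' @export
step_density <- function(state, p, Gamma, dt, noise_amp = 0) {
  stopifnot(inherits(state, "density_state"), dt > 0)
  grid <- state$grid
  h <- grid$h
  rho <- state$rho
  pv <- p$values
  n2 <- grid$n^2
  superbee <- function(r) pmax(0, pmin(2 * r, 1), pmin(r, 2))
  take <- function(v, idx) {
    out <- numeric(n2)
    ok <- !is.na(idx)
    out[ok] <- v[idx[ok]]
    out
  }
  flux_dir <- function(d, dopp) {
    # face velocity and limited upwind flux towards the d-neighbor
    fwd <- grid$nbr[, d]
    ok <- !is.na(fwd)
    v <- numeric(n2)
    v[ok] <- -(pv[fwd[ok]] - pv[ok]) / h
    v[!is.finite(v)] <- 0       # no flux across faces with undefined pressure
    rho_F <- take(rho, fwd)
    rho_B <- take(rho, grid$nbr[, dopp])          # second-upwind for v > 0
    ff <- rep(NA_integer_, n2)                    # neighbor beyond the face
    ff[ok] <- grid$nbr[fwd[ok], d]
    rho_FF <- take(rho, ff)                       # second-upwind for v < 0
    drho <- rho_F - rho
    # v > 0: upwind cell is i
    rpos <- ifelse(abs(drho) > 0, (rho - rho_B) / drho, 0)
    face_pos <- rho + 0.5 * superbee(rpos) * drho
    # v < 0: upwind cell is the forward neighbor
    rneg <- ifelse(abs(drho) > 0, (rho_FF - rho_F) / (-drho), 0)
    face_neg <- rho_F + 0.5 * superbee(rneg) * (-drho)
    f <- ifelse(v > 0, v * face_pos, v * face_neg)
    f[!ok] <- 0
    list(v = v, f = f)
  }
  E <- flux_dir(2L, 1L); N <- flux_dir(4L, 3L)
  vmax <- max(abs(E$v), abs(N$v))
  if (vmax * dt / h > 0.5 + 1e-12)
    stop(sprintf("CFL violation: dt = %.3g exceeds the advective bound; use dt <= %.3g",
                 dt, 0.5 * h / vmax), call. = FALSE)
  # divergence in conservative form: western/southern face flux is the
  # eastern/northern flux of the neighbor
  FW <- numeric(n2)
  W <- grid$nbr[, 1L]; okW <- !is.na(W)
  FW[okW] <- E$f[W[okW]]
  FS <- numeric(n2)
  S <- grid$nbr[, 3L]; okS <- !is.na(S)
  FS[okS] <- N$f[S[okS]]
  div <- (E$f - FW + N$f - FS) / h
  rho_new <- rho + dt * (-div + Gamma)
  if (noise_amp > 0) {
    iface <- which(rho_new > 0 & rho_new < 1)
    rho_new[iface] <- rho_new[iface] +
      noise_amp * sqrt(dt) * stats::rnorm(length(iface))
  }
  # saturated cells next to the interface can overfill (the limited face
  # reconstruction exports less than the saturated flux while the growth
  # source keeps feeding them); push the excess into neighboring
  # unsaturated cells instead of clipping it away
  for (pass in 1:2) {
    over <- rho_new - 1
    donors <- which(over > 1e-14)
    if (!length(donors)) break
    caps <- matrix(0, length(donors), 4)
    for (d in 1:4) {
      j <- grid$nbr[donors, d]
      ok <- !is.na(j)
      caps[ok, d] <- pmax(0, 1 - rho_new[j[ok]])
    }
    tot <- rowSums(caps)
    give <- over[donors] * (tot > 0)
    rho_new[donors] <- rho_new[donors] - give
    for (d in 1:4) {
      j <- grid$nbr[donors, d]
      sel <- !is.na(j) & tot > 0 & caps[, d] > 0
      jj <- j[sel]
      rho_new[jj] <- rho_new[jj] + give[sel] * caps[sel, d] / tot[sel]
    }
  }
  density_state(grid, pmin(pmax(rho_new, 0), 1), state$t + dt)
}

#' Run the mean-field tumor model
#'
#' Time loop of the deterministic model: solve the conditional-sink oxygen
#' problem, classify regions, solve the pressure with the Young-Laplace rim
#' condition, then advance the density by one conservative upwind step (CFL
#' safety factor 0.5, capped by `dt_max`). Records the same trajectory
#' summaries as [simulate_dlcm()].
#'
#' @param initial a [density_state()].
#' @param params a [model_params()].
#' @param t_end final time.
#' @param seed integer seed (used by the noise injection).
#' @param noise_amp density-update noise amplitude (the stochastic model's
#'   counterpart of number fluctuations; 0 gives a deterministic run).
#' @param dt_max largest allowed step.
#' @param output_times recording times.
#' @param record_states if `TRUE`, keep the density vector at each output
#'   time (in `attr(, "states")`).
#' @param curvature_window passed to [estimate_curvature()].
#' @return Trajectory data frame with columns `t, mass, V_p, V_q, V_n,
#'   roundness, com_x, com_y`; attribute `final` holds the final state;
#'   attribute `vanished` flags early termination on a vanished tumor.
#' @export
# region labels for a density state: necrotic is the deactivated-sink region
# of the conditional oxygen solve (where the converged field sits at the
# death threshold and a strict c < kappa_death test is boundary-sensitive);
# fields without sink metadata fall back to threshold classification
.density_labels <- function(state, c, params, domain = NULL) {
  grid <- state$grid
  if (is.null(domain)) domain <- state$rho >= 0.5
  cv <- c$values
  supp <- attr(c, "sink_support")
  necro <- if (!is.null(supp)) {
    insupp <- logical(grid$n^2)
    insupp[supp] <- TRUE
    domain & !insupp
  } else domain & !is.na(cv) & cv < params$kappa_death
  prolif <- domain & !necro & !is.na(cv) & cv >= params$kappa_prol
  list(domain = domain, prolif = prolif, necrotic = necro,
       quiescent = domain & !necro & !prolif)
}

# 5-point local average; sub-cell interface positioning for domain masks so
# the free boundary moves continuously as density accumulates
.smooth_rho <- function(grid, rho) {
  acc <- 4 * rho
  wt <- rep(4, grid$n^2)
  for (d in 1:4) {
    j <- grid$nbr[, d]
    ok <- !is.na(j)
    acc[ok] <- acc[ok] + rho[j[ok]]
    wt[ok] <- wt[ok] + 1
  }
  acc / wt
}

run_pde <- function(initial, params, t_end, seed = 1, noise_amp = 1e-3,
                    dt_max = 0.02, output_times = NULL, record_states = FALSE,
                    curvature_window = 7) {
  params <- as_model_params(params)
  stopifnot(inherits(initial, "density_state"), t_end > initial$t)
  set.seed(as.integer(seed))
  grid <- initial$grid
  state <- initial
  if (is.null(output_times))
    output_times <- seq(initial$t, t_end, length.out = 121)
  output_times <- sort(unique(c(output_times, t_end)))
  recs <- vector("list", length(output_times))
  states <- if (record_states) vector("list", length(output_times)) else NULL
  next_out <- 1L
  vanished <- FALSE
  c_prev <- NULL
  repeat {
    if (!any(state$rho >= 0.5)) { vanished <- TRUE; break }
    oxy <- solve_oxygen(state, params, c_init = c_prev)
    c_prev <- oxy$values
    rho_s <- .smooth_rho(grid, state$rho)
    contour <- tryCatch(extract_boundary(grid, rho_s),
                        error = function(e) NULL)
    if (!is.null(contour) && length(contour$x) < 3) contour <- NULL
    curv <- if (!is.null(contour) && params$sigma > 0)
      estimate_curvature(contour, curvature_window) else NULL
    p <- solve_pressure(state, params, contour = contour, curvature = curv,
                        oxygen = oxy, domain = rho_s >= 0.5)
    while (next_out <= length(output_times) &&
           output_times[next_out] <= state$t + 1e-12) {
      recs[[next_out]] <- .pde_summary(state, oxy, params, contour,
                                       output_times[next_out])
      if (record_states) states[[next_out]] <- state$rho
      next_out <- next_out + 1L
    }
    if (state$t >= t_end - 1e-12) break
    g <- growth_source(state, oxy, params, domain = rho_s >= 0.5)
    # combined-CFL step (sum of the two face speeds per node stays below
    # half a cell per step, preserving positivity), aligned to recording
    pv <- p$values
    vsum <- numeric(grid$n^2)
    for (d in c(2L, 4L)) {
      j <- grid$nbr[, d]; ok <- !is.na(j)
      dv <- abs(pv[j[ok]] - pv[ok]) / grid$h
      dv[!is.finite(dv)] <- 0
      vsum[ok] <- vsum[ok] + dv
    }
    dmax <- max(vsum, 0)
    dt <- min(dt_max, if (dmax > 0) 0.5 * grid$h / dmax else dt_max,
              t_end - state$t)
    if (next_out <= length(output_times))
      dt <- min(dt, max(output_times[next_out] - state$t, 1e-9))
    state <- step_density(state, p, g, dt, noise_amp)
  }
  while (next_out <= length(output_times)) {
    oxy <- solve_oxygen(state, params)
    recs[[next_out]] <- .pde_summary(state, oxy, params, NULL,
                                     output_times[next_out])
    if (record_states) states[[next_out]] <- state$rho
    next_out <- next_out + 1L
  }
  out <- do.call(rbind, recs)
  attr(out, "final") <- state
  attr(out, "vanished") <- vanished
  if (record_states) attr(out, "states") <- states
  out
}

.pde_summary <- function(state, oxy, params, contour, t) {
  vols <- region_volumes(state, oxy, params)
  if (is.null(contour))
    contour <- tryCatch(extract_boundary(state$grid,
                                         .smooth_rho(state$grid, state$rho)),
                        error = function(e) NULL)
  rnd <- if (!is.null(contour))
    tryCatch(roundness(contour), error = function(e) NA_real_) else NA_real_
  w <- state$rho
  com <- if (sum(w) > 0)
    c(sum(state$grid$x * w), sum(state$grid$y * w)) / sum(w)
  else c(NA_real_, NA_real_)
  data.frame(t = t, mass = sum(state$rho) * state$grid$h^2,
             V_p = vols[["V_p"]], V_q = vols[["V_q"]], V_n = vols[["V_n"]],
             roundness = rnd, com_x = com[1], com_y = com[2])
}
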