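#' @title Quasi-stationary pressure and oxygen fields
#' @description Both the stochastic lattice model and the mean-field PDE treat
#'   pressure and oxygen as quasi-stationary: mechanical relaxation and oxygen
#'   diffusion are much faster than cell migration, growth and death, so each
#'   field solves a Poisson problem for the current cell configuration.
#' @name fields
NULL

# scalar field container shared by both solvers
scalar_field <- function(grid, values, active, dirichlet, residual) {
  structure(list(grid = grid, values = values, active = active,
                 dirichlet = dirichlet, residual = residual),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  v <- x$values[x$active]
  cat(sprintf("scalar field on %d nodes: range [%.5g, %.5g], solve residual %.3g\n",
              length(x$active), min(v), max(v), x$residual))
  invisible(x)
}

.tumor_indicator <- function(state) {
  if (inherits(state, "population_state")) as.numeric(state$u != 0)
  else if (inherits(state, "density_state")) state$rho
  else stop("state must be a population_state or density_state", call. = FALSE)
}

#' Solve the oxygen field
#'
#' Oxygen obeys `-Laplacian(c) = -lambda a` with `c = 1` on the domain
#' boundary (the radius-1 circle, imposed on all lattice nodes at or outside
#' that radius). For a lattice population the per-voxel sink is
#' `lambda * max(u, 0)` (the number of living cells), active
#' unconditionally. For a mean-field density the sink `lambda * rho` is
#' only active where `c >= kappa_death`, so the field solves an obstacle
#' problem: `c >= kappa_death` everywhere, with full consumption wherever
#' the constraint is slack and the deficit acting as a nonnegative
#' multiplier on the contact (necrotic) set. The solver is projected
#' red-black SOR, warm-startable from a previous field; the converged
#' contact set defines the necrotic region robustly (the field sits exactly
#' at the death threshold there, so a strict threshold test on the values
#' would be boundary-sensitive).
#'
#' @param state a `population_state` or `density_state`.
#' @param params a [model_params()].
#' @param max_iter relaxation sweep cap (mean-field only).
#' @param c_init optional warm start (full-lattice oxygen values from a
#'   previous solve).
#' @return A `scalar_field` with the oxygen values (Dirichlet nodes hold 1);
#'   for the mean-field variant, attribute `sink_support` holds the indices
#'   of the active-sink nodes.
#' @export
solve_oxygen <- function(state, params, max_iter = 20000, c_init = NULL) {
  params <- as_model_params(params)
  grid <- state$grid
  sys <- .oxygen_system(grid)
  active <- sys$active
  dir_nodes <- sys$dir_nodes
  vals <- rep(NA_real_, grid$n^2)
  vals[dir_nodes] <- 1
  if (inherits(state, "population_state")) {
    a <- pmax(state$u, 0)
    sol <- .oxygen_cached_solve(sys, -params$lambda * a[active])
    vals[active] <- as.numeric(sol)
    res <- attr(sol, "residual")
    supp <- NULL
  } else if (inherits(state, "density_state")) {
    # consumption density: saturated on the tumor domain (the sharp-interface
    # model carries rho = 1 there; numerically diluted cells would otherwise
    # under-consume and feed an oxygen surplus), partial on the fringe
    rho <- pmax(state$rho, as.numeric(state$rho >= 0.5))
    if (is.null(c_init)) {
      # initial iterate: unconstrained full-consumption solve, projected up
      sol0 <- .oxygen_cached_solve(sys, -params$lambda * rho[active])
      c_init <- vals
      c_init[active] <- pmax(as.numeric(sol0), params$kappa_death)
    }
    ob <- .oxygen_obstacle_psor(grid, sys, rho, params$lambda,
                                params$kappa_death, c_init, max_iter)
    vals <- ob$c
    res <- ob$residual
    supp <- ob$support
  } else stop("state must be a population_state or density_state", call. = FALSE)
  f <- scalar_field(grid, vals, active,
                    list(nodes = dir_nodes, values = 1), res)
  attr(f, "sink_support") <- supp
  f
}

# projected red-black SOR for the oxygen obstacle problem: c >= kappa on
# cell-bearing nodes, full sink -lambda*rho where the constraint is slack.
# The projection is applied only where rho > 0 (elsewhere there is no
# consumption to suppress, and the plain equation holds).
.oxygen_obstacle_psor <- function(grid, sys, rho, lambda, kappa, c_init,
                                  max_sweeps = 20000, tol = 1e-10, omega = 1.7) {
  n2 <- grid$n^2
  active <- sys$active
  cache <- grid$cache
  if (is.null(cache$psor)) {
    # disc-interior unknowns always have 4 on-lattice neighbors (the
    # Dirichlet ring covers the rest), so the sweeps need no masking
    parity <- (round(grid$x / grid$h) + round(grid$y / grid$h)) %% 2
    cache$psor <- lapply(0:1, function(pp) {
      idx <- active[parity[active] == pp]
      list(idx = idx, W = grid$nbr[idx, 1], E = grid$nbr[idx, 2],
           S = grid$nbr[idx, 3], N = grid$nbr[idx, 4])
    })
  }
  cols <- cache$psor
  cvals <- c_init
  cvals[sys$dir_nodes] <- 1
  f <- numeric(n2)
  f[active] <- -lambda * rho[active]
  h2f4 <- grid$h^2 * f / 4
  canbind <- rho > 0
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (col in cols) {
      idx <- col$idx
      gs <- (cvals[col$W] + cvals[col$E] + cvals[col$S] + cvals[col$N]) / 4 +
        h2f4[idx]
      newv <- (1 - omega) * cvals[idx] + omega * gs
      bind <- canbind[idx]
      newv[bind] <- pmax(newv[bind], kappa)
      delta <- max(delta, max(abs(newv - cvals[idx])))
      cvals[idx] <- newv
    }
    if (delta < tol) break
    if (sweep == max_sweeps)
      stop("oxygen obstacle solve did not converge in ", max_sweeps, " sweeps",
           call. = FALSE)
  }
  contact <- canbind & !is.na(cvals) & cvals <= kappa + 1e-9
  support <- active[rho[active] > 0 & !contact[active]]
  list(c = cvals, support = support, residual = delta)
}

#' Solve the pressure field
#'
#' Pressure obeys `-Laplacian(p) = s` on the tumor domain. For a lattice
#' population the source is 1 on voxels above carrying capacity (`u = 2`)
#' and 0 elsewhere; for a mean-field density it is the relative growth rate
#' of each region (`+1` proliferative, `0` quiescent, `-mu_death` necrotic),
#' which requires the oxygen field. The solvers operate in the free-flowing
#' external medium regime (`D_ext = Inf`): the ambient pressure is spatially
#' constant, so the rim condition reduces to the Dirichlet value
#' `p_ext + sigma C` imposed on the empty nodes bordering the tumor, with the
#' curvature `C` (positive for a convex tumor) taken from the nearest vertex
#' of the tumor contour. The curvature pressure raises the rim value on
#' bulges, which redistributes flow towards indentations and damps shape
#' perturbations of every mode `k >= 2`.
#'
#' @param state a `population_state` or `density_state`.
#' @param params a [model_params()].
#' @param contour optional precomputed [extract_boundary()] contour of the
#'   tumor (recomputed if `NULL` and `sigma > 0`).
#' @param curvature optional per-vertex curvatures matching `contour`.
#' @param oxygen a `scalar_field` from [solve_oxygen()]; required for a
#'   `density_state`.
#' @param domain optional logical tumor-domain mask for a `density_state`
#'   (defaults to `rho >= 0.5`).
#' @return A `scalar_field` with the pressure (rim Dirichlet nodes hold their
#'   boundary value).
#' @export
solve_pressure <- function(state, params, contour = NULL, curvature = NULL,
                           oxygen = NULL, domain = NULL) {
  params <- as_model_params(params)
  grid <- state$grid
  if (inherits(state, "population_state")) {
    in_tumor <- state$u != 0
    src_full <- as.numeric(state$u > 1)
  } else if (inherits(state, "density_state")) {
    in_tumor <- if (is.null(domain)) state$rho >= 0.5 else domain
    if (is.null(oxygen))
      stop("the mean-field pressure source requires the oxygen field", call. = FALSE)
    lab <- .density_labels(state, oxygen, params, in_tumor)
    # unit class rates on the (saturated) tumor domain, matching the growth
    # source so that div v balances Gamma exactly at density 1
    src_full <- numeric(grid$n^2)
    src_full[lab$prolif] <- 1
    src_full[lab$necrotic] <- -params$mu_death
  } else stop("state must be a population_state or density_state", call. = FALSE)
  active <- which(in_tumor)
  if (!length(active)) stop("empty tumor domain", call. = FALSE)
  nb <- grid$nbr[active, , drop = FALSE]
  cand <- unique(nb[!is.na(nb)])
  rim <- cand[!in_tumor[cand]]
  if (!length(rim)) stop("tumor domain has no boundary (fills the lattice)",
                         call. = FALSE)
  bc <- rep(params$p_ext, length(rim))
  if (params$sigma > 0) {
    if (is.null(contour))
      contour <- extract_boundary(grid, .tumor_indicator(state))
    if (is.null(curvature)) curvature <- estimate_curvature(contour)
    bc <- params$p_ext + params$sigma * .nearest_curvature(grid, rim, contour, curvature)
  }
  sys <- assemble_laplacian(grid, active, list(nodes = rim, values = bc))
  sol <- solve_masked_poisson(sys, src_full[active])
  vals <- rep(NA_real_, grid$n^2)
  vals[rim] <- bc
  vals[active] <- as.numeric(sol)
  scalar_field(grid, vals, active, list(nodes = rim, values = bc),
               attr(sol, "residual"))
}

# curvature seen by a rim node: kernel-weighted average over nearby contour
# vertices (bandwidth ~ one cell). Raw nearest-vertex lookup gives adjacent
# rim nodes jumpy Dirichlet values, which injects spurious tangential
# pressure gradients of order sigma*dC/h at the rim
.nearest_curvature <- function(grid, nodes, contour, curvature) {
  bw2 <- (1.5 * grid$h)^2
  cmax <- 1 / (3 * grid$h)    # curvature beyond the lattice scale is noise
  curvature <- pmin(pmax(curvature, -cmax), cmax)
  vapply(nodes, function(i) {
    d2 <- (contour$x - grid$x[i])^2 + (contour$y - grid$y[i])^2
    w <- exp(-d2 / (2 * bw2))
    if (sum(w) < 1e-12) curvature[which.min(d2)]
    else sum(w * curvature) / sum(w)
  }, numeric(1))
}

#' Pressure flux across a shared voxel edge
#'
#' The movement rate between two adjacent voxels is proportional to the
#' pressure gradient integrated over their shared edge. On the square lattice
#' the gradient `(p_i - p_j)/h` times the edge length `h` is simply
#' `p_i - p_j`.
#'
#' @param p a `scalar_field` (pressure).
#' @param i,j adjacent node indices.
#' @return The flux from `i` to `j` (antisymmetric in its arguments).
#' @export
edge_flux <- function(p, i, j) {
  stopifnot(inherits(p, "scalar_field"))
  if (!j %in% p$grid$nbr[i, ])
    stop("nodes ", i, " and ", j, " are not lattice neighbors", call. = FALSE)
  p$values[i] - p$values[j]
}

#' Export a scalar field as a delimited table
#'
#' @param field a `scalar_field`.
#' @param file output path (tab-separated with a header row).
#' @return The written data frame, invisibly.
#' @export
write_field <- function(field, file) {
  keep <- which(!is.na(field$values))
  df <- data.frame(node = keep, x = field$grid$x[keep], y = field$grid$y[keep],
                   value = field$values[keep])
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

# the oxygen system (disc interior unknowns, unit Dirichlet ring) depends
# only on the grid, so its Cholesky factor is computed once and cached
.oxygen_system <- function(grid) {
  cache <- grid$cache
  if (is.null(cache$oxy_sys)) {
    inside <- grid$r < grid$radius - 1e-12
    active <- which(inside)
    dir_nodes <- which(!inside)
    sys <- assemble_laplacian(grid, active, list(nodes = dir_nodes, values = 1))
    sys$dir_nodes <- dir_nodes
    sys$chol <- Matrix::Cholesky(Matrix::forceSymmetric(sys$A), LDL = FALSE)
    cache$oxy_sys <- sys
  }
  cache$oxy_sys
}

.oxygen_cached_solve <- function(sys, source) {
  rhs <- source + sys$b
  sol <- as.numeric(Matrix::solve(sys$chol, rhs, system = "A"))
  res <- sqrt(sum((as.numeric(sys$A %*% sol) - rhs)^2))
  attr(sol, "residual") <- res
  sol
}
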