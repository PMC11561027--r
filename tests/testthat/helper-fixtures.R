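# shared fixtures: small grids are expensive to rebuild per test, reuse them
grid_cache <- new.env()

test_grid <- function(h, radius = 1) {
  key <- paste0("g", h, "_", radius)
  if (is.null(grid_cache[[key]])) grid_cache[[key]] <- build_lattice(h, radius)
  grid_cache[[key]]
}

# a synthetic oxygen scalar_field with prescribed values (bypasses the solver,
# used to pin region labels in fixtures)
synthetic_oxygen <- function(grid, values) {
  structure(list(grid = grid, values = values, active = seq_len(grid$n^2),
                 dirichlet = list(nodes = integer(), values = numeric()),
                 residual = 0),
            class = "scalar_field")
}

# random stationary zonation: draw (eta, mu_death, r_p), slave r_q, r_n via the
# stationarity identity r_p^2 = (1 + mu_death * eta) * r_q^2, r_n^2 = eta r_q^2
random_stationary <- function(n, seed = 1, rp_range = c(0.05, 0.9)) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    eta <- runif(1, 0.01, 0.99)
    mu <- exp(runif(1, log(0.05), log(20)))
    rp <- runif(1, rp_range[1], rp_range[2])
    rq <- rp / sqrt(1 + mu * eta)
    rn <- sqrt(eta) * rq
    out[[i]] <- list(state = radial_state(rn, rq, rp), mu_death = mu, eta = eta)
  }
  out
}

# analytic circle contour (not lattice-extracted)
circle_contour <- function(r, n = 512, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- center[1] + r * cos(th); y <- center[2] + r * sin(th)
  structure(list(x = x, y = y, area = abs(avtumor:::.shoelace(x, y)),
                 perimeter = sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))),
            class = "boundary_contour", n_components = 1L)
}

# --- local oracles -----------------------------------------------------------

# forward relations recomputed independently from the oxygen closed form:
# K values defined by evaluating the profile at the stated thresholds
.relation_prol_pub <- function(st, lam) {
  kp <- oxygen_profile(st$r_q, st, lam)
  list(K = 4 * (1 - kp) / lam, kappa = kp)
}
.relation_death_pub <- function(st, lam) {
  kd <- oxygen_profile(max(st$r_n, 1e-12), st, lam)
  list(K = 4 * (1 - kd) / lam, kappa = kd)
}

# centered finite difference of the slaved rim dynamics in V = r_p^2
.fd_eigenvalue <- function(st, mu_death, rel = 1e-6) {
  Kp <- .relation_prol_pub(st, 1)$K
  Kd <- .relation_death_pub(st, 1)$K
  g <- function(V) {
    s <- solve_regions(Kp, Kd, sqrt(V))
    radial_rhs(s, mu_death)
  }
  V0 <- st$r_p^2
  dV <- rel * V0
  (g(V0 + dV) - g(V0 - dV)) / (2 * dV)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

state_key <- function(u) {
  nz <- which(u != 0L)
  if (!length(nz)) return("empty")
  paste(nz, u[nz], sep = ":", collapse = ",")
}

# exhaustive CTMC: breadth-first enumeration of the reachable state space,
# generator assembled from the package's rate functions, then exponentiated;
# independent of the Gillespie sampling path it is used to check
enumerate_master_equation <- function(init, pp, t,
                                      channels = c("move", "die", "degrade"),
                                      max_states = 500) {
  grid <- init$grid
  states <- list(init$u)
  index <- new.env()
  index[[state_key(init$u)]] <- 1L
  trans <- list()
  qi <- 1L
  while (qi <= length(states)) {
    u <- states[[qi]]
    st <- population_state(grid, u)
    sched <- NULL
    if ("move" %in% channels && any(u == 1L | u == 2L) && any(u != 0L)) {
      p <- solve_pressure(st, pp)
      mv <- movement_rates(st, p, pp)
      if (nrow(mv)) sched <- mv
    }
    if (any(c("proliferate", "die", "degrade") %in% channels) && any(u != 0L)) {
      oxy <- solve_oxygen(st, pp)
      cl <- cell_event_rates(st, oxy, pp)
      cl <- cl[cl$kind %in% channels, , drop = FALSE]
      if (nrow(cl)) sched <- rbind(sched, cl)
    }
    if (!is.null(sched) && nrow(sched)) {
      for (k in seq_len(nrow(sched))) {
        u2 <- apply_event(st, sched[k, ])$u
        key <- state_key(u2)
        j <- index[[key]]
        if (is.null(j)) {
          j <- length(states) + 1L
          states[[j]] <- u2
          index[[key]] <- j
          if (j > max_states) stop("toy state space exceeded max_states")
        }
        trans[[length(trans) + 1L]] <- c(qi, j, sched$rate[k])
      }
    }
    qi <- qi + 1L
  }
  n <- length(states)
  Q <- matrix(0, n, n)
  for (tr in trans) Q[tr[1], tr[2]] <- Q[tr[1], tr[2]] + tr[3]
  diag(Q) <- diag(Q) - rowSums(Q)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  pt <- P[1, ]
  names(pt) <- vapply(states, state_key, character(1))
  list(prob = as.list(pt), states = states, n = n)
}

# perturbed disc carrying the equilibrium zonation: living annulus around a
# necrotic core, both interfaces displaced by the same relative cosine mode
zonated_disc <- function(grid, st, eps, k, phase = 0) {
  th <- atan2(grid$y, grid$x)
  mod <- 1 + eps * cos(k * (th - phase))
  u <- integer(grid$n^2)
  u[grid$r <= st$r_p * mod] <- 1L
  u[grid$r <= st$r_n * mod] <- -1L
  population_state(grid, u)
}
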