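test_that("oxygen solve honors the far-field condition and trivial cases", {
  g <- test_grid(0.05)
  empty <- population_state(g, integer(g$n^2) + 1L * (g$r <= 0.2))
  pp <- model_params(lambda = 0)
  f <- solve_oxygen(empty, pp)
  expect_equal(f$values[f$active], rep(1, length(f$active)))
  # Dirichlet ring holds exactly 1 also with a sink present
  pp1 <- model_params(lambda = 1)
  f1 <- solve_oxygen(empty, pp1)
  expect_true(all(f1$values[f1$dirichlet$nodes] == 1))
  expect_true(all(f1$values[f1$active] <= 1 + 1e-12))
  expect_lt(f1$residual, 1e-8)
})

test_that("2D oxygen matches the radial closed form on a uniform disc", {
  pp <- model_params(mu_death = 1.35, lambda = 1.15)
  ref <- oxygen_profile(0.3, radial_state(0, 0, 0.3), 1.15)
  errs <- vapply(c(0.04, 0.02), function(h) {
    g <- test_grid(h)
    st <- make_initial_disc(g, 0.3)$population
    f <- solve_oxygen(st, pp)
    idx <- which(g$r <= 0.3)
    max(abs(f$values[idx] - oxygen_profile(g$r[idx], radial_state(0, 0, 0.3), 1.15)))
  }, numeric(1))
  expect_lt(errs[2], errs[1])                 # shrinks with refinement
  expect_lt(errs[2], 5e-3)
  # rim value reproduces 1 + (lambda/2) r_p^2 log r_p within O(h)
  g <- test_grid(0.02)
  st <- make_initial_disc(g, 0.3)$population
  f <- solve_oxygen(st, pp)
  sel <- abs(g$r - 0.3) < g$h / 2
  expect_equal(mean(f$values[sel]), ref, tolerance = 5e-3)
  # radial monotonicity of the symmetric solution
  ord <- order(g$r[f$active])
  vals <- f$values[f$active][ord]
  rr <- g$r[f$active][ord]
  bins <- cut(rr, seq(0, 1, 0.05))
  profile <- tapply(vals, bins, mean)
  expect_true(all(diff(profile[!is.na(profile)]) > -1e-6))
})

test_that("mean-field conditional sink deactivates below the death threshold", {
  g <- test_grid(0.02)
  ds <- make_initial_disc(g, 0.32)$density
  pp <- model_params(lambda = 1.15, kappa_death = 0.93, kappa_prol = 0.94)
  f <- solve_oxygen(ds, pp)
  supp <- attr(f, "sink_support")
  expect_gt(length(supp), 0)
  expect_true(all(f$values[supp] >= pp$kappa_death - 1e-9))
  # deactivated interior: some starved nodes exist for this large tumor
  tum <- which(ds$rho > 0 & g$r < g$radius - 1e-12)
  expect_gt(length(setdiff(tum, supp)), 0)
  # without starvation the fixed point is the plain solve
  small <- make_initial_disc(g, 0.1)$density
  fs <- solve_oxygen(small, pp)
  expect_equal(length(attr(fs, "sink_support")), sum(small$rho[fs$active] > 0))
})

test_that("pressure is zero for a source-free tumor without surface tension", {
  g <- test_grid(0.05)
  st <- make_initial_disc(g, 0.3)$population   # all singly occupied
  pp <- model_params(sigma = 0, p_ext = 0)
  f <- solve_pressure(st, pp)
  expect_lt(max(abs(f$values[f$active])), 1e-12)
  expect_error(solve_pressure(population_state(g, integer(g$n^2)), pp), "empty")
})

test_that("2D pressure matches the radial piecewise closed form", {
  # prescribed zonation (0.1, 0.2, 0.3) through a synthetic oxygen field;
  # the piecewise profile is matched at fixed resolution (the threshold
  # quantization of the source regions adds a bounded O(h) error)
  stz <- radial_state(0.1, 0.2, 0.3)
  mu <- 1.35
  g <- test_grid(0.02)
  ds <- density_state(g, as.numeric(g$r <= 0.3))
  cv <- 0.93 + 0.05 * (g$r - 0.1)     # crosses 0.93 at r_n and 0.935 at r_q
  oxy <- synthetic_oxygen(g, cv)
  pp <- model_params(mu_death = mu, kappa_prol = 0.935, kappa_death = 0.93,
                     sigma = 0)
  f <- solve_pressure(ds, pp, oxygen = oxy)
  ref <- pressure_profile(g$r[f$active], stz, mu)
  expect_lt(max(abs(f$values[f$active] - ref)), 2e-3)
})

test_that("pressure converges to the closed form at first order", {
  # all-proliferative disc (quadratic profile): the max-norm error is pure
  # boundary fitting; averaging over fixture radii removes the
  # lattice-alignment oscillation of the error constant
  hs <- c(0.04, 0.02, 0.01)
  rps <- c(0.27, 0.3)
  perr <- function(h, rp) {
    g <- test_grid(h)
    ds <- density_state(g, as.numeric(g$r <= rp))
    oxy <- synthetic_oxygen(g, rep(1, g$n^2))
    f <- solve_pressure(ds, model_params(mu_death = 1.35, sigma = 0),
                        oxygen = oxy)
    ref <- pressure_profile(g$r[f$active], radial_state(0, 0, rp), 1.35)
    max(abs(f$values[f$active] - ref))
  }
  errs <- vapply(hs, function(h) mean(vapply(rps, perr, numeric(1), h = h)),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  fit <- stats::lm(log(errs) ~ log(hs))
  expect_gte(unname(stats::coef(fit)[2]), 0.9)
})

test_that("surface tension enters the rim condition as a curvature pressure", {
  g <- test_grid(0.01)
  st <- make_initial_disc(g, 0.3)$population
  pp <- model_params(sigma = 5e-3)
  f <- solve_pressure(st, pp)
  # source-free: constant at p_ext + sigma / r within discretization error
  expect_equal(mean(f$values[f$active]), 5e-3 / 0.3, tolerance = 0.06)
  expect_lt(stats::sd(f$values[f$active]), 5e-4)
})

test_that("edge fluxes are antisymmetric and sum to the source strength", {
  g <- test_grid(0.05)
  u <- integer(g$n^2)
  u[g$r <= 0.3] <- 1L
  set.seed(8)
  doubles <- sample(which(g$r <= 0.2), 12)
  u[doubles] <- 2L
  st <- population_state(g, u)
  pp <- model_params(sigma = 0)
  f <- solve_pressure(st, pp)
  # antisymmetry on sampled adjacent pairs
  idx <- sample(f$active, 50)
  for (i in idx) {
    for (j in g$nbr[i, ]) {
      if (!is.na(j) && !is.na(f$values[j]))
        expect_equal(edge_flux(f, i, j), -edge_flux(f, j, i))
    }
  }
  expect_error(edge_flux(f, f$active[1], f$active[1] + 5 * g$n), "neighbors")
  # discrete divergence theorem: rim outflux equals total source
  rim <- f$dirichlet$nodes
  out <- 0
  for (i in f$active) {
    for (j in g$nbr[i, ]) {
      if (!is.na(j) && j %in% rim) out <- out + edge_flux(f, i, j)
    }
  }
  expect_equal(out, length(doubles) * g$h^2, tolerance = 1e-8)
})

test_that("field export writes a well-formed table", {
  g <- test_grid(0.1)
  st <- make_initial_disc(g, 0.3)$population
  f <- solve_oxygen(st, model_params())
  path <- tempfile(fileext = ".tsv")
  df <- write_field(f, path)
  back <- utils::read.table(path, header = TRUE)
  expect_equal(names(back), c("node", "x", "y", "value"))
  expect_equal(nrow(back), nrow(df))
  unlink(path)
})
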