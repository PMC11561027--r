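test_that("oxygen profile satisfies its boundary data and closed-form values", {
  st <- radial_state(0, 0, 0.3)
  expect_equal(oxygen_profile(1, st, 1.15), 1)
  # direct evaluation of the annulus branch at the rim
  expect_equal(oxygen_profile(0.3, st, 1.15),
               1 + 1.15 / 2 * 0.3^2 * log(0.3), tolerance = 1e-12)
  expect_equal(oxygen_profile(c(0, 0.2, 0.7), st, 0), rep(1, 3))
  expect_error(oxygen_profile(1.2, st, 1), "0, 1")
})

test_that("oxygen profile is continuous, C1 at the rim, and flat in the core", {
  st <- radial_state(0.12, 0.2, 0.32)
  lam <- 1.3
  eps <- 1e-7
  for (ri in c(st$r_n, st$r_p)) {
    expect_equal(oxygen_profile(ri - eps, st, lam), oxygen_profile(ri + eps, st, lam),
                 tolerance = 1e-5)
  }
  d_in <- (oxygen_profile(st$r_p, st, lam) - oxygen_profile(st$r_p - eps, st, lam)) / eps
  d_out <- (oxygen_profile(st$r_p + eps, st, lam) - oxygen_profile(st$r_p, st, lam)) / eps
  expect_equal(d_in, d_out, tolerance = 1e-4)
  expect_equal(oxygen_profile(0, st, lam), oxygen_profile(st$r_n, st, lam))
  # monotone nonincreasing inward
  r <- seq(0, 1, by = 0.01)
  expect_true(all(diff(oxygen_profile(r, st, lam)) >= -1e-12))
})

test_that("reduced parameters and forward/inverse zonation relations agree", {
  K <- reduced_params(0.94, 0.93, 1.15)
  expect_equal(K$K_prol, 4 * 0.06 / 1.15, tolerance = 1e-12)
  expect_equal(K$K_death, 4 * 0.07 / 1.15, tolerance = 1e-12)
  st <- solve_regions(K$K_prol, K$K_death, 0.3)
  res <- region_relations(st, 1.15, 0.94, 0.93)
  expect_lt(max(abs(res)), 1e-10)
  # the interior interfaces sit exactly at the oxygen thresholds
  expect_equal(oxygen_profile(st$r_q, st, 1.15), 0.94, tolerance = 1e-9)
  expect_equal(oxygen_profile(st$r_n, st, 1.15), 0.93, tolerance = 1e-9)
})

test_that("solve_regions handles the branch structure of small tumors", {
  K <- reduced_params(0.94, 0.93, 1.15)
  tiny <- solve_regions(K$K_prol, K$K_death, 0.05)
  expect_identical(tiny$r_n, 0)
  expect_identical(tiny$r_q, 0)      # fully proliferative
  expect_false(attr(tiny, "necrotic_core"))
  mid <- solve_regions(K$K_prol, K$K_death, 0.24)
  expect_identical(mid$r_n, 0)
  expect_gt(mid$r_q, 0)              # quiescent band, no necrotic core yet
  big <- solve_regions(K$K_prol, K$K_death, 0.4)
  expect_gt(big$r_n, 0)
})

test_that("forward/inverse round trips close over random states", {
  set.seed(11)
  for (i in 1:50) {
    rp <- runif(1, 0.1, 0.9)
    rq <- runif(1, 0.3, 0.95) * rp
    rn <- runif(1, 0.05, 0.95) * rq
    st <- radial_state(rn, rq, rp)
    lam <- runif(1, 0.3, 3)
    Kp <- .relation_prol_pub(st, lam)
    Kd <- .relation_death_pub(st, lam)
    back <- solve_regions(Kp$K, Kd$K, rp)
    expect_equal(back$r_n, rn, tolerance = 1e-8)
    expect_equal(back$r_q, rq, tolerance = 1e-8)
  }
})

test_that("volume balance has the stated closed form", {
  expect_equal(radial_rhs(radial_state(0, 0, 0.3), 1), 0.09)
  expect_equal(radial_rhs(radial_state(0.1, 0.2, 0.3), 1.35),
               -1.35 * 0.01 - 0.04 + 0.09, tolerance = 1e-14)
})

test_that("radial integration has the exponential limit and reaches the fixed point", {
  pp <- preset("table2_pde")
  tr <- integrate_radial(0.03, pp, t_end = 0.5, dt_out = 0.05)
  expect_equal(tr$V_p, pi * 0.03^2 * exp(tr$t), tolerance = 0.02)
  long <- integrate_radial(0.05, pp, t_end = 60, dt_out = 1)
  st <- find_stationary(pp)
  expect_equal(tail(long$r_p, 1), st$r_p, tolerance = 1e-6)
  # sigmoid: monotone growth towards the plateau
  expect_true(all(diff(long$V_p) > -1e-8))
  expect_lt(abs(tail(long$V_p, 1) - pi * st$r_p^2), 1e-4)
})

test_that("the stationary state solves both relation sets to tight residuals", {
  pp <- preset("table2_pde")
  st <- find_stationary(pp)
  expect_lt(abs(radial_rhs(st, pp$mu_death)), 1e-10)
  expect_lt(max(abs(region_relations(st, pp$lambda, pp$kappa_prol, pp$kappa_death))),
            1e-10)
  # comparative statics: heavier death shrinks the equilibrium tumor
  rps <- vapply(c(0.8, 1.35, 2, 4), function(mu) {
    p <- pp; p$mu_death <- mu
    find_stationary(p)$r_p
  }, numeric(1))
  expect_true(all(diff(rps) <= 1e-10))
})

test_that("radial eigenvalue matches a finite-difference linearization", {
  cases <- random_stationary(30, seed = 5, rp_range = c(0.08, 0.85))
  for (cs in cases) {
    st <- cs$state
    lam_closed <- eigenvalue_radial(st, cs$mu_death)
    lam_fd <- .fd_eigenvalue(st, cs$mu_death)
    expect_equal(lam_closed, lam_fd, tolerance = 1e-6)
  }
})

test_that("eigenvalue limit branches agree with nearby interior values", {
  # r_n -> 0 limit branch
  lim <- eigenvalue_radial(radial_state(0, 0.3, 0.4), 1)
  expect_equal(lim, 1 + 2 * log(0.4), tolerance = 1e-12)
  near <- eigenvalue_radial(radial_state(1e-60, 0.3, 0.4), 1)
  expect_equal(near, lim, tolerance = 2e-2)
  # r_q -> r_n limit branch continuous
  a <- eigenvalue_radial(radial_state(0.2, 0.2, 0.4), 0.7)
  b <- eigenvalue_radial(radial_state(0.2, 0.2 + 1e-9, 0.4), 0.7)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("documented stationary example is stable with the expected eigenvalue", {
  st <- radial_state(0.1, 0.2, sqrt(1.35 * 0.01 + 0.04))
  expect_lt(abs(radial_rhs(st, 1.35)), 1e-14)
  expect_equal(eigenvalue_radial(st, 1.35), -1.0338, tolerance = 1e-3)
  expect_true(prop31_guaranteed_stable(st))
  expect_false(prop31_guaranteed_stable(radial_state(0.1, 0.3, 0.5)))
  expect_true(prop31_guaranteed_stable(radial_state(0.1, 0.2, exp(-1))))
})

test_that("radial pressure profile is continuous with the mass-balance rim gradient", {
  st <- radial_state(0.1, 0.2, 0.3)
  mu <- 1.35
  eps <- 1e-7
  for (ri in c(st$r_n, st$r_q)) {
    expect_equal(pressure_profile(ri - eps, st, mu), pressure_profile(ri + eps, st, mu),
                 tolerance = 1e-5)
  }
  dp <- (pressure_profile(st$r_p, st, mu) - pressure_profile(st$r_p - eps, st, mu)) / eps
  expect_equal(-dp, radial_rhs(st, mu) / (2 * st$r_p), tolerance = 1e-5)
  expect_equal(-dp, 0.06083, tolerance = 1e-3)
  # Young-Laplace curvature pressure enters the rim value
  expect_equal(pressure_profile(st$r_p, st, mu, sigma = 0.01) -
                 pressure_profile(st$r_p, st, mu, sigma = 0),
               0.01 / st$r_p, tolerance = 1e-10)
})
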