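exact_on <- function(grid) {
  function(pot, temperature, seed) {
    exact_boltzmann_sampler(pot, temperature, seed, grid)
  }
}

test_that("the potential-of-mean-force difference vanishes at the fixed point", {
  g <- grid6()
  P <- single_gauss_dist(c(-66, 145), c(14, 12), g)
  dv <- delta_v_surface(P, P, 300, 1e-8)
  expect_equal(max(abs(dv$delta_v[dv$mask])), 0)
  U <- uniform_dist(g)
  dvu <- delta_v_surface(U, U, 300)
  expect_true(all(dvu$mask))
  expect_equal(unique(as.vector(dvu$delta_v)), 0)
})

test_that("the log-ratio surface has the suppressive sign convention and units", {
  g <- grid6()
  U <- uniform_dist(g)
  p <- matrix(1, g$n_phi, g$n_psi)
  p[1, 1] <- exp(1)                       # sampler over-populates one bin
  S <- rama_distribution(p, g)
  ## temperature such that kB T = 1 kJ/mol
  temp <- 1 / 0.0083144621
  dv <- delta_v_surface(U, S, temp)
  ## both renormalized: difference of logs shifts by a constant; bin ratios
  ## carry the signal exactly
  expect_equal(dv$delta_v[1, 1] - dv$delta_v[2, 2], 1, tolerance = 1e-12)
  expect_gt(dv$delta_v[1, 1], 0)
  tiny <- matrix(1e-12, g$n_phi, g$n_psi); tiny[5, 5] <- 1
  T2 <- rama_distribution(tiny, g)
  expect_error(delta_v_surface(T2, T2, 300, floor = 1), "below the probability floor")
})

test_that("clamp mode keeps a bounded signal where one distribution is empty", {
  g <- grid6()
  d1 <- delta_dist(-63, 141, g); d2 <- delta_dist(63, -141, g)
  dv <- delta_v_surface(d1, d2, 300, floor = 1e-4, floor_mode = "clamp")
  expect_equal(sum(dv$mask), 2L)
  kT <- 0.0083144621 * 300
  expect_equal(dv$delta_v[d2$p > 0], kT * log(1 / 1e-4))
  expect_equal(dv$delta_v[d1$p > 0], -kT * log(1 / 1e-4))
})

test_that("an IBI step at the fixed point leaves the parameters unchanged", {
  g <- grid6()
  pot0 <- random_potential(5, kmax = 2)
  target <- boltzmann_distribution(pot0, 300, g)
  cfg <- ibi_config(grid = g, seed = 1)
  st <- ibi_step(pot0, target, exact_on(g), cfg)
  expect_potentials_equal(st$potential, pot0, tol = 1e-8)
  expect_lt(st$fit_residual, 1e-9)
  ## lambda-independence of the zero update
  cfg2 <- ibi_config(grid = g, lambda = 0.3, seed = 1)
  st2 <- ibi_step(pot0, target, exact_on(g), cfg2)
  expect_potentials_equal(st2$potential, pot0, tol = 1e-8)
})

test_that("one exact-sampler step recovers an in-span target from a flat start", {
  g <- grid2()
  truth <- random_potential(41)
  target <- boltzmann_distribution(truth, 300, g)
  cfg <- ibi_config(grid = g, seed = 2)
  st <- ibi_step(fourier_potential(numeric(5), numeric(5)), target,
                 exact_on(g), cfg)
  expect_equal(st$potential$k_phi, truth$k_phi, tolerance = 1e-6)
  expect_equal(st$potential$k_psi, truth$k_psi, tolerance = 1e-6)
})

test_that("a gauge shift of the potential changes neither sample nor update", {
  g <- grid6()
  pot <- random_potential(55, kmax = 2)
  lifted <- fourier_potential(pot$k_phi, pot$k_psi, offset = pot$offset + 42)
  target <- single_gauss_dist(c(-66, 145), c(20, 16), g)
  cfg <- ibi_config(grid = g, seed = 3)
  s1 <- ibi_step(pot, target, exact_on(g), cfg)
  s2 <- ibi_step(lifted, target, exact_on(g), cfg)
  expect_equal(s1$sampled$p, s2$sampled$p, tolerance = 1e-12)
  expect_equal(s1$potential$k_phi, s2$potential$k_phi, tolerance = 1e-8)
  expect_equal(s1$potential$k_psi, s2$potential$k_psi, tolerance = 1e-8)
})

test_that("exact-sampler inversion recovers random in-span potentials", {
  g <- grid2()
  for (r in 1:5) {
    truth <- random_potential(500 + r)
    target <- boltzmann_distribution(truth, 300, g)
    res <- run_ibi(target, exact_on(g),
                   ibi_config(tol = 1e-6, max_iterations = 3, grid = g,
                              seed = 600 + r))
    expect_true(res$converged)
    expect_lte(res$iterations, 3L)
    expect_lt(max(abs(c(res$potential$k_phi - truth$k_phi,
                        res$potential$k_psi - truth$k_psi))), 1e-5)
    ## Hellinger trace non-increasing for in-span targets at lambda = 1
    expect_true(all(diff(res$hellinger) <= 1e-12))
  }
})

test_that("a uniform target converges at iteration zero from a flat start", {
  g <- grid6()
  res <- run_ibi(uniform_dist(g), exact_on(g),
                 ibi_config(tol = 1e-9, grid = g, seed = 1))
  expect_true(res$converged)
  expect_equal(res$iterations, 0L)
  expect_equal(res$best_hellinger, 0)
})

test_that("out-of-span targets settle at the best separable approximation", {
  g <- grid6()
  ## two diagonal modes: not a product distribution, broad enough that no
  ## bin falls below the floor
  m <- gaussian_rama_model(list(
    gaussian_component("a", 0.5, c(-70, 120), c(35, 35)),
    gaussian_component("b", 0.5, c(60, -60), c(35, 35))))
  target <- evaluate_model(m, g)
  expect_gt(min(target$p), 1e-8)
  cfg <- ibi_config(tol = 1e-4, max_iterations = 6, grid = g,
                    phases = "free", seed = 9)
  res <- run_ibi(target, exact_on(g), cfg)
  expect_false(res$converged)
  expect_equal(res$iterations, 6L)
  ## best-so-far Hellinger trace is non-increasing by construction, and the
  ## run settles: the last update is negligible
  expect_true(all(diff(cummin(res$hellinger)) <= 0))
  ## direct best-approximation oracle: LS fit of the target PMF in the span
  kT <- 0.0083144621 * 300
  pmf <- -kT * log(target$p)
  direct <- fit_fourier_to_surface(pmf, g, phases = "free")
  h_direct <- hellinger_distance(
    boltzmann_distribution(direct$potential, 300, g), target)
  expect_equal(res$best_hellinger, h_direct, tolerance = 0.02)
})

test_that("the Metropolis sampler is deterministic and exact for a flat potential", {
  g <- grid2()
  flat <- fourier_potential(numeric(5), numeric(5))
  P1 <- metropolis_sampler(flat, 300, 1e6, 60, seed = 21, grid = g)
  P2 <- metropolis_sampler(flat, 300, 1e6, 60, seed = 21, grid = g)
  expect_identical(P1$p, P2$p)
  ## flat potential: every proposal accepted; histogram noise floor for
  ## n = 1e6 over 32400 bins gives E[H] ~ sqrt(B/(8n)) = 0.064
  expect_lt(hellinger_distance(P1, uniform_dist(g)), 0.08)
  expect_error(metropolis_sampler(flat, 300, 0), ">= 1")
})

test_that("Metropolis occupancies follow Boltzmann weights within sampling error", {
  g <- grid6()
  pot <- fourier_potential(c(2, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  S <- metropolis_sampler(pot, 300, 5e5, 60, seed = 8, grid = g)
  B <- boltzmann_distribution(pot, 300, g)
  ## coarse regions beat per-bin noise: quadrant occupancies
  quad <- function(P) {
    half <- g$n_phi / 2
    c(sum(P$p[1:half, 1:half]), sum(P$p[1:half, -(1:half)]),
      sum(P$p[-(1:half), 1:half]), sum(P$p[-(1:half), -(1:half)]))
  }
  expect_lt(max(abs(quad(S) - quad(B))), 0.02)
})

test_that("a trapped walker reports zero acceptance instead of spinning", {
  g <- grid6()
  ## a well this deep leaves an acceptance window of ~1e-3 degrees: once the
  ## walker falls in, essentially every proposal is rejected
  spike <- fourier_potential(c(1e10, 0, 0, 0, 0), numeric(5))
  expect_error(metropolis_sampler(spike, 300, 2e5, 180, seed = 4, grid = g),
               "consecutive Metropolis rejections")
})

test_that("stochastic inversion tracks an in-span target within its noise envelope", {
  g <- grid2()
  truth <- fourier_potential(c(1.5, -0.8, 0.4, 0, 0), c(-1, 0.5, 0, 0, 0))
  target <- boltzmann_distribution(truth, 300, g)
  sampler <- make_metropolis_sampler(1e6, 90, g)
  st <- ibi_step(fourier_potential(numeric(5), numeric(5)), target, sampler,
                 ibi_config(grid = g, seed = 100))
  ## empirical noise envelope: repeat the one-step recovery over 5 seeds and
  ## bound each coefficient error by 3x the spread
  errs <- sapply(1:5, function(r) {
    s <- ibi_step(fourier_potential(numeric(5), numeric(5)), target, sampler,
                  ibi_config(grid = g, seed = 200 + 10 * r))
    max(abs(c(s$potential$k_phi - truth$k_phi,
              s$potential$k_psi - truth$k_psi)))
  })
  expect_lt(max(abs(c(st$potential$k_phi - truth$k_phi,
                      st$potential$k_psi - truth$k_psi))),
            3 * max(errs))
  expect_lt(max(errs), 0.5)  # the fit sees through 1e6-step sampling noise
})
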