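hb_params <- function() {
  karplus_parameters("3J(HN,HA)", A = 7.09, B = -1.42, C = 1.55,
                     theta0 = -60, depends_on = "phi",
                     s_A = 0.12, s_B = 0.09, s_C = 0.08)
}

test_that("the Karplus equation hits its cosine extrema and is periodic", {
  p <- hb_params()
  expect_equal(karplus_value(-p$theta0, p), p$A + p$B + p$C)
  expect_equal(karplus_value(180 - p$theta0, p), p$A - p$B + p$C)
  expect_equal(karplus_value(90 - p$theta0, p), p$C)
  th <- seq(-180, 180, by = 7)
  expect_equal(karplus_value(th, p), karplus_value(th + 360, p),
               tolerance = 1e-12)
  expect_error(karplus_value(NaN, p), "finite")
})

test_that("ensemble averages are exact for constants and deltas and match fine quadrature", {
  g <- grid2()
  P <- single_gauss_dist(c(-70, 140), c(18, 14), g)
  expect_equal(ensemble_average(P, function(phi, psi) 3.7), 3.7)
  d <- delta_dist(-60, 150, g)
  p <- hb_params()
  ## the delta occupies the bin centered (-59, 151)
  expect_equal(ensemble_average(d, function(phi, psi) karplus_value(phi, p)),
               karplus_value(-59, p))
  ## independent 0.25-degree quadrature oracle
  fine <- angle_grid(0.25)
  Pf <- single_gauss_dist(c(-70, 140), c(18, 14), fine)
  q <- function(phi, psi) karplus_value(phi, p)
  expect_equal(ensemble_average(P, q), ensemble_average(Pf, q),
               tolerance = 1e-4)
  expect_error(ensemble_average(P, function(phi, psi) phi / 0 * 0), "non-finite")
})

test_that("ensemble averaging is linear and monotone", {
  g <- grid6()
  P <- single_gauss_dist(c(-66, 145), c(14, 12), g)
  q1 <- function(phi, psi) cos(phi * pi / 180)
  q2 <- function(phi, psi) cos(phi * pi / 180) + 0.5
  expect_equal(ensemble_average(P, function(phi, psi) 2 * q1(phi, psi) + 1),
               2 * ensemble_average(P, q1) + 1, tolerance = 1e-12)
  expect_lte(ensemble_average(P, q1), ensemble_average(P, q2))
})

test_that("coupling uncertainties propagate Karplus errors in quadrature", {
  g <- grid2()
  obs <- jcoupling_observation("3J(HN,HA)", 5.5, s_J = 0.3)
  p0 <- karplus_parameters("3J(HN,HA)", 7.09, -1.42, 1.55, -60, "phi",
                           s_A = 0, s_B = 0, s_C = 0)
  P <- single_gauss_dist(c(-70, 140), c(18, 14), g)
  expect_equal(coupling_uncertainty(P, p0, obs), 0.3)
  ## delta at the zero of cos(theta + theta0): only s_C and s_J survive
  ## (theta0 chosen so a bin center sits exactly at 90 - theta0)
  p59 <- karplus_parameters("3J(HN,HA)", 7.09, -1.42, 1.55, -59, "phi",
                            s_A = 0.12, s_B = 0.09, s_C = 0.08)
  d <- delta_dist(149, 0, g)
  expect_equal(coupling_uncertainty(d, p59, obs),
               sqrt(p59$s_C^2 + obs$s_J^2), tolerance = 1e-12)
  p <- hb_params()
  expect_gte(coupling_uncertainty(P, p, obs), obs$s_J)
  ## fine-grid quadrature oracle
  fine <- angle_grid(0.25)
  Pf <- single_gauss_dist(c(-70, 140), c(18, 14), fine)
  expect_equal(coupling_uncertainty(P, p, obs),
               coupling_uncertainty(Pf, p, obs), tolerance = 1e-6)
  pna <- karplus_parameters("1J(N,CA)", 0.8, -0.66, 10.7, 0, "psi")
  expect_error(coupling_uncertainty(P, pna, obs), "s_J alone")
})

test_that("reduced chi-squared matches direct summation and scales as 1/s^2", {
  expect_equal(chi2_j(c(5, 6), c(5, 6), c(0.3, 0.4)), 0)
  expect_equal(chi2_j(5.3, 5.0, 0.3), 1)
  jc <- c(5.2, 6.9, 1.1, 10.8, 2.4); je <- c(5.0, 7.3, 1.4, 10.5, 2.0)
  s <- c(0.3, 0.25, 0.4, 0.5, 0.35)
  oracle <- sum(((jc - je) / s)^2) / 5
  expect_equal(chi2_j(jc, je, s), oracle, tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(chi2_j(jc[perm], je[perm], s[perm]), oracle)
  expect_equal(chi2_j(jc, je, 2 * s), oracle / 4)
  tags <- c("phi", "phi", "psi", "phi", "phi")
  both <- chi2_j(jc, je, s, tags)
  expect_equal(both$chi2_J, oracle)
  expect_equal(both$chi2_Jphi, mean((((jc - je) / s)^2)[tags == "phi"]))
  expect_error(chi2_j(numeric(0), numeric(0), numeric(0)), "no couplings")
})

test_that("a distribution scores zero against its own forward-computed couplings", {
  g <- grid6()
  P <- single_gauss_dist(c(-66, 145), c(14, 12), g)
  kt <- default_karplus_table()
  kl <- ramaibi:::as_karplus_list(kt)
  obs <- data.frame(coupling_name = kt$coupling_name,
                    J_exp = vapply(kl, function(p) {
                      ensemble_average(P, ramaibi:::karplus_q(p))
                    }, numeric(1)),
                    s_J = 0.3, stringsAsFactors = FALSE)
  rep <- jcoupling_report(P, kt, obs)
  expect_equal(rep$chi2_J, 0, tolerance = 1e-20)
  expect_equal(rep$chi2_Jphi, 0, tolerance = 1e-20)
  expect_equal(nrow(rep$couplings), 5L)
  ## the psi-dependent 1J is excluded from the phi subset
  expect_equal(sum(rep$couplings$depends_on == "phi"), 4L)
})

test_that("each conformer contributes a conservative VCD couplet", {
  g <- grid2()
  cfg <- oscillator_config()
  d <- delta_dist(-66, 145, g)
  prof <- vcd_profile(d, cfg)
  ## integrated dichroism of the couplet vanishes
  expect_lt(abs(sum(prof$delta_epsilon)), 1e-12 * max(abs(prof$delta_epsilon)))
  ## parallel-dipole geometry: zero couplet, not an error
  d0 <- delta_dist(1, 1, g)  # sin(phi) ~ 0 at the bin center
  prof0 <- vcd_profile(d0, cfg)
  expect_lt(max(abs(prof0$delta_epsilon)),
            0.1 * max(abs(prof$delta_epsilon)))
})

test_that("VCD profiles are linear in the conformer populations", {
  g <- grid2()
  cfg <- oscillator_config()
  d1 <- delta_dist(-66, 145, g); d2 <- delta_dist(-120, 130, g)
  mix <- rama_distribution(0.7 * d1$p + 0.3 * d2$p, g)
  pm <- vcd_profile(mix, cfg)
  p1 <- vcd_profile(d1, cfg); p2 <- vcd_profile(d2, cfg)
  expect_equal(pm$delta_epsilon, 0.7 * p1$delta_epsilon + 0.3 * p2$delta_epsilon,
               tolerance = 1e-12)
})

test_that("inversion-symmetric ensembles give an identically zero VCD signal", {
  g <- grid2()
  cfg <- oscillator_config()
  P <- make_target("glycine_like", g)$distribution
  prof <- vcd_profile(P, cfg)
  scale <- max(abs(vcd_profile(delta_dist(-66, 145, g), cfg)$delta_epsilon))
  expect_lt(max(abs(prof$delta_epsilon)), 1e-10 * scale)
})

test_that("VCD chi-squared reduces deviations by the per-point errors", {
  wn <- seq(1600, 1690, by = 10)
  a <- vcd_profile_object(wn, sin(wn / 30), s_k = 0.1)
  expect_equal(chi2_vcd(a, a), 0)
  one <- vcd_profile_object(1650, 0.25, s_k = 0.1)
  ref <- vcd_profile_object(1650, 0.15, s_k = 0.1)
  expect_equal(chi2_vcd(one, ref), 1)
  dev <- c(0.01, -0.02, 0.03, 0, 0.005, -0.015, 0.02, -0.01, 0, 0.01)
  b <- vcd_profile_object(wn, a$delta_epsilon + dev, s_k = 0.1)
  expect_equal(chi2_vcd(b, a), mean((dev / 0.1)^2), tolerance = 1e-12)
  short <- vcd_profile_object(wn + 5, a$delta_epsilon, s_k = 0.1)
  expect_error(chi2_vcd(short, a), "wavenumber grids")
})
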