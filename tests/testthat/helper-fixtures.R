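## Shared fixtures.  Coarse grids keep unit tests fast; anything tied to the
## default 2-degree discretization uses grid2().

grid2 <- function() angle_grid(2)
grid6 <- function() angle_grid(6)

uniform_dist <- function(grid = grid2()) {
  rama_distribution(matrix(1, grid$n_phi, grid$n_psi), grid)
}

delta_dist <- function(phi, psi, grid = grid2()) {
  histogram_from_angles(cbind(phi, psi), grid)
}

## single wrapped-Gaussian distribution evaluated on a grid
single_gauss_dist <- function(center, sigma, grid = grid2()) {
  evaluate_model(gaussian_rama_model(
    list(gaussian_component("g", 1, center, sigma))), grid)
}

random_potential <- function(seed, kmax = 3, n = 5) {
  set.seed(seed)
  fourier_potential(stats::runif(n, -kmax, kmax), stats::runif(n, -kmax, kmax))
}

expect_potentials_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$k_phi, b$k_phi, tolerance = tol)
  expect_equal(a$k_psi, b$k_psi, tolerance = tol)
  expect_equal(a$gamma_phi, b$gamma_phi, tolerance = tol)
  expect_equal(a$gamma_psi, b$gamma_psi, tolerance = tol)
}

## well-separated Gaussian model: every center >= 3 sigma inside its region
well_separated_model <- function() {
  gaussian_rama_model(list(
    gaussian_component("pPII", 0.6, c(-66, 140), c(8, 12)),
    gaussian_component("abeta", 0.25, c(-155, 155), c(8, 8)),
    gaussian_component("alpha", 0.15, c(-61, -37), c(7, 7))))
}
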