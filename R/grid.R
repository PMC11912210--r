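#' Physical constants
#'
#' Boltzmann constant in kJ/(mol K), the unit system used throughout the
#' package (energies kJ/mol, temperatures K, angles degrees at the API).
#' @keywords internal
KB_KJ_MOL_K <- 0.0083144621

#' Construct a uniform (phi, psi) bin grid
#'
#' Discretizes Ramachandran space into square bins of `bin_width` degrees.
#' With the default 2 degree width the bin centers run -179, -177, ..., 177,
#' 179 along each axis, giving 180 x 180 = 32400 bins.
#'
#' @param bin_width Bin width in degrees; must divide 360 evenly.
#' @return An object of class `angle_grid` with fields `bin_width`,
#'   `centers_phi`, `centers_psi`, `n_phi`, `n_psi`.
#' @examples
#' g <- angle_grid()
#' g$n_phi * g$n_psi  # 32400
#' @export
angle_grid <- function(bin_width = 2) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || !is.finite(bin_width) ||
      bin_width <= 0) {
    stop("'bin_width' must be a single positive number")
  }
  n <- 360 / bin_width
  if (abs(n - round(n)) > 1e-9) {
    stop("'bin_width' must divide 360 evenly, got ", bin_width)
  }
  n <- as.integer(round(n))
  centers <- -180 + bin_width / 2 + bin_width * (seq_len(n) - 1)
  structure(
    list(bin_width = bin_width,
         centers_phi = centers, centers_psi = centers,
         n_phi = n, n_psi = n),
    class = "angle_grid")
}

#' @export
print.angle_grid <- function(x, ...) {
  cat(sprintf("angle_grid: %g deg bins, %d x %d = %d bins\n",
              x$bin_width, x$n_phi, x$n_psi, x$n_phi * x$n_psi))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$bin_width, b$bin_width)) &&
    a$n_phi == b$n_phi && a$n_psi == b$n_psi
}

#' Wrap angles into (-180, 180]
#'
#' @param a Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

## Bin index along one axis; values exactly on a bin edge fall in the upper
## bin, and +180 wraps onto the -180 side (the bin centered at -179 for the
## default grid), so every angle lands in exactly one bin.
bin_index_1d <- function(a, grid) {
  idx <- floor((a + 180) / grid$bin_width)
  (idx %% grid$n_phi) + 1L
}

#' Construct a binned Ramachandran distribution
#'
#' @param p Matrix of non-negative values, `n_phi` rows (phi) by `n_psi`
#'   columns (psi).  Normalized to unit total mass.
#' @param grid An [angle_grid()].
#' @param meta Provenance tag, one of `"histogram"`, `"gaussian_model"`,
#'   `"boltzmann"`, `"file"`.
#' @return Object of class `rama_distribution`.
#' @export
rama_distribution <- function(p, grid = angle_grid(),
                              meta = c("histogram", "gaussian_model",
                                       "boltzmann", "file")) {
  meta <- match.arg(meta)
  if (!inherits(grid, "angle_grid")) stop("'grid' must be an angle_grid")
  p <- as.matrix(p)
  if (nrow(p) != grid$n_phi || ncol(p) != grid$n_psi) {
    stop(sprintf("probability matrix must be %d x %d, got %d x %d",
                 grid$n_phi, grid$n_psi, nrow(p), ncol(p)))
  }
  if (any(!is.finite(p))) stop("probabilities must be finite")
  if (any(p < 0)) stop("probabilities must be non-negative")
  tot <- sum(p)
  if (tot <= 0) stop("total probability mass must be positive")
  structure(list(grid = grid, p = p / tot, meta = meta),
            class = "rama_distribution")
}

#' @export
print.rama_distribution <- function(x, ...) {
  cat(sprintf("rama_distribution (%s): %d x %d bins, max p = %.3g\n",
              x$meta, x$grid$n_phi, x$grid$n_psi, max(x$p)))
  invisible(x)
}

#' Histogram (phi, psi) angle pairs onto a grid
#'
#' Each sample is wrapped periodically and counted in exactly one bin; the
#' result is normalized to a probability distribution.
#'
#' @param angles Two-column matrix or data frame of (phi, psi) pairs in
#'   degrees, or a list with components `phi` and `psi`.
#' @param grid An [angle_grid()].
#' @return A [rama_distribution()] with `meta = "histogram"`.
#' @export
histogram_from_angles <- function(angles, grid = angle_grid()) {
  if (is.list(angles) && !is.data.frame(angles) &&
      all(c("phi", "psi") %in% names(angles))) {
    angles <- cbind(angles$phi, angles$psi)
  }
  angles <- as.matrix(angles)
  if (nrow(angles) == 0) stop("'angles' must contain at least one (phi, psi) pair")
  if (ncol(angles) < 2) stop("'angles' must have phi and psi columns")
  phi <- as.numeric(angles[, 1]); psi <- as.numeric(angles[, 2])
  bad <- which(!is.finite(phi) | !is.finite(psi))
  if (length(bad)) {
    stop("non-finite angle at index ", bad[1])
  }
  ip <- bin_index_1d(phi, grid)
  is <- bin_index_1d(psi, grid)
  counts <- tabulate((is - 1L) * grid$n_phi + ip, nbins = grid$n_phi * grid$n_psi)
  p <- matrix(counts, nrow = grid$n_phi, ncol = grid$n_psi)
  rama_distribution(p, grid, meta = "histogram")
}

#' Hellinger distance between two binned distributions
#'
#' H(P, Q) = sqrt( (1/2) * sum_ij (sqrt(P_ij) - sqrt(Q_ij))^2 ), the standard
#' form bounded in \[0, 1\]: 0 for identical distributions, 1 for disjoint
#' supports.
#'
#' @param P,Q [rama_distribution()] objects on identical grids.
#' @return Unitless distance in \[0, 1\].
#' @export
hellinger_distance <- function(P, Q) {
  stopifnot(inherits(P, "rama_distribution"), inherits(Q, "rama_distribution"))
  if (!grids_identical(P$grid, Q$grid)) {
    stop("distributions are on different grids")
  }
  h2 <- 0.5 * sum((sqrt(P$p) - sqrt(Q$p))^2)
  sqrt(min(max(h2, 0), 1))
}

#' Classify a Hellinger distance into similarity categories
#'
#' Uses the conventional four-way banding for Ramachandran distribution
#' comparisons: H in \[0, 0.1\] very similar, (0.1, 0.25\] moderately similar,
#' (0.25, 0.4\] moderately dissimilar, above 0.4 very dissimilar.  Intervals
#' are closed on the right.
#'
#' @param h Hellinger distance(s) in \[0, 1\].
#' @return Character vector of labels.
#' @export
classify_hellinger <- function(h) {
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1)) {
    stop("'h' must lie in [0, 1]")
  }
  labs <- c("very similar", "moderately similar",
            "moderately dissimilar", "very dissimilar")
  labs[findInterval(h, c(0.1, 0.25, 0.4), left.open = TRUE) + 1L]
}

#' Default mesostate region definitions
#'
#' Seven rectangular (phi, psi) regions commonly used to coarse-grain peptide
#' conformational ensembles: polyproline II (pPII), antiparallel beta strand
#' (abeta), the transitional beta region (betat), right-handed helix (alpha),
#' two turn-supporting beta_(i+2) regions, and asx.  All boundaries are open
#' intervals (strict inequalities on bin centers).
#'
#' @return Data frame with columns `name`, `phi_min`, `phi_max`, `psi_min`,
#'   `psi_max`, `chirality`.
#' @export
default_mesostates <- function() {
  data.frame(
    name = c("pPII", "abeta", "betat", "alpha",
             "typeI/II'beta_i+2", "typeI'/IIbeta_i+2", "asx"),
    phi_min = c(-90, -180, -130, -90, -110, 50, 70),
    phi_max = c(-42, -130, -90, -32, -30, 110, 110),
    psi_min = c(100, 130, 130, -60, -20, -20, 75),
    psi_max = c(180, 180, 180, -14, 20, 20, 170),
    chirality = c("right", "right", "right", "right", "right", "left", "n/a"),
    stringsAsFactors = FALSE)
}

region_mask <- function(grid, phi_min, phi_max, psi_min, psi_max) {
  lim <- c(phi_min, phi_max, psi_min, psi_max)
  if (any(!is.finite(lim)) || any(lim < -180) || any(lim > 180) ||
      phi_min >= phi_max || psi_min >= psi_max) {
    stop("mesostate region outside the angular domain or empty")
  }
  inphi <- grid$centers_phi > phi_min & grid$centers_phi < phi_max
  inpsi <- grid$centers_psi > psi_min & grid$centers_psi < psi_max
  outer(inphi, inpsi, `&`)
}

#' Mesostate populations and free energies of a distribution
#'
#' Populations are probability sums over bins whose centers fall strictly
#' inside each region.  The free energy of a region is the population-weighted
#' mean of the per-bin potential of mean force -kB*T*log(p / p_ref) over its
#' occupied bins, with p_ref = 1/(number of bins), so that unoccupied regions
#' sit at zero free energy by convention.  Overlapping regions each receive
#' the full population of shared bins; `other_fraction` is measured against
#' the union of all regions.
#'
#' @param P A [rama_distribution()].
#' @param defs Region definitions as from [default_mesostates()].
#' @param temperature Temperature in K.
#' @return Object of class `mesostate_report`: a list with `populations`,
#'   `free_energies` (kJ/mol), and `other_fraction`.
#' @export
mesostate_report <- function(P, defs = default_mesostates(), temperature = 300) {
  stopifnot(inherits(P, "rama_distribution"), temperature > 0)
  grid <- P$grid
  nbins <- grid$n_phi * grid$n_psi
  p_ref <- 1 / nbins
  kT <- KB_KJ_MOL_K * temperature
  pop <- g <- stats::setNames(numeric(nrow(defs)), defs$name)
  union_mask <- matrix(FALSE, grid$n_phi, grid$n_psi)
  for (i in seq_len(nrow(defs))) {
    m <- region_mask(grid, defs$phi_min[i], defs$phi_max[i],
                     defs$psi_min[i], defs$psi_max[i])
    union_mask <- union_mask | m
    pr <- P$p[m]
    pop[i] <- sum(pr)
    occ <- pr > 0
    if (any(occ)) {
      pmf <- -kT * log(pr[occ] / p_ref)
      g[i] <- sum(pr[occ] * pmf) / pop[i]
    }
  }
  structure(
    list(populations = pop, free_energies = g,
         other_fraction = 1 - sum(P$p[union_mask]),
         temperature = temperature),
    class = "mesostate_report")
}

#' @export
print.mesostate_report <- function(x, ...) {
  cat(sprintf("mesostate_report (T = %g K)\n", x$temperature))
  df <- data.frame(population = round(x$populations, 4),
                   free_energy_kJ_mol = round(x$free_energies, 3))
  print(df)
  cat(sprintf("other fraction: %.4f\n", x$other_fraction))
  invisible(x)
}
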