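#' Separable Fourier-series backbone dihedral potential
#'
#' V(phi, psi) = sum_n k_phi\[n\] (1 + cos(n phi - gamma_phi\[n\])) +
#'               sum_m k_psi\[m\] (1 + cos(m psi - gamma_psi\[m\])) + offset,
#' the Amber proper-dihedral functional form with one term per multiplicity.
#' Energies are kJ/mol, angles and phases degrees.  The additive offset is
#' physically irrelevant (it cancels in Boltzmann weights) and is never
#' exported to topology files.
#'
#' @param k_phi,k_psi Coefficient vectors (kJ/mol), term n = 1..N / m = 1..M.
#' @param gamma_phi,gamma_psi Per-term phases in degrees (default all 0).
#' @param offset Additive constant (kJ/mol).
#' @return Object of class `fourier_potential`.
#' @export
fourier_potential <- function(k_phi = numeric(5), k_psi = numeric(5),
                              gamma_phi = NULL, gamma_psi = NULL, offset = 0) {
  k_phi <- as.numeric(k_phi); k_psi <- as.numeric(k_psi)
  if (length(k_phi) < 1 || length(k_psi) < 1) {
    stop("at least one Fourier term per angle is required")
  }
  if (is.null(gamma_phi)) gamma_phi <- numeric(length(k_phi))
  if (is.null(gamma_psi)) gamma_psi <- numeric(length(k_psi))
  stopifnot(length(gamma_phi) == length(k_phi),
            length(gamma_psi) == length(k_psi))
  if (any(!is.finite(c(k_phi, k_psi, gamma_phi, gamma_psi, offset)))) {
    stop("potential parameters must be finite")
  }
  structure(list(k_phi = k_phi, k_psi = k_psi,
                 gamma_phi = as.numeric(gamma_phi),
                 gamma_psi = as.numeric(gamma_psi),
                 offset = as.numeric(offset)),
            class = "fourier_potential")
}

#' @export
print.fourier_potential <- function(x, ...) {
  cat(sprintf("fourier_potential: N = %d phi terms, M = %d psi terms, offset = %.4g kJ/mol\n",
              length(x$k_phi), length(x$k_psi), x$offset))
  cat("  k_phi:", paste(sprintf("%.4g", x$k_phi), collapse = " "), "\n")
  cat("  k_psi:", paste(sprintf("%.4g", x$k_psi), collapse = " "), "\n")
  if (any(x$gamma_phi != 0) || any(x$gamma_psi != 0)) {
    cat("  gamma_phi:", paste(sprintf("%.4g", x$gamma_phi), collapse = " "), "\n")
    cat("  gamma_psi:", paste(sprintf("%.4g", x$gamma_psi), collapse = " "), "\n")
  }
  invisible(x)
}

## 1-D series sum_n k_n (1 + cos(n theta - gamma_n)) at angles in degrees
fourier_series_1d <- function(angles_deg, k, gamma_deg) {
  th <- angles_deg * pi / 180
  v <- numeric(length(angles_deg))
  for (n in seq_along(k)) {
    v <- v + k[n] * (1 + cos(n * th - gamma_deg[n] * pi / 180))
  }
  v
}

#' Evaluate a dihedral potential on a bin grid
#'
#' @param pot A [fourier_potential()].
#' @param grid An [angle_grid()].
#' @return `n_phi` x `n_psi` matrix of energies (kJ/mol) at the bin centers.
#' @export
evaluate_potential <- function(pot, grid = angle_grid()) {
  stopifnot(inherits(pot, "fourier_potential"), inherits(grid, "angle_grid"))
  vphi <- fourier_series_1d(grid$centers_phi, pot$k_phi, pot$gamma_phi)
  vpsi <- fourier_series_1d(grid$centers_psi, pot$k_psi, pot$gamma_psi)
  outer(vphi, vpsi, `+`) + pot$offset
}

#' Boltzmann distribution of a dihedral potential
#'
#' p(phi, psi) proportional to exp(-V / (kB T)) on the grid, normalized.
#' Overflow-safe (the surface is shifted by its minimum before
#' exponentiation), hence invariant to the additive offset.
#'
#' @param pot A [fourier_potential()].
#' @param temperature Temperature in K, > 0.
#' @param grid An [angle_grid()].
#' @return A [rama_distribution()] with `meta = "boltzmann"`.
#' @export
boltzmann_distribution <- function(pot, temperature = 300, grid = angle_grid()) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("'temperature' must be positive")
  }
  v <- evaluate_potential(pot, grid)
  w <- exp(-(v - min(v)) / (KB_KJ_MOL_K * temperature))
  rama_distribution(w, grid, meta = "boltzmann")
}

## Design matrix for the separable Fourier fit on a grid: intercept, then
## cos(n phi) (and sin(n phi) for free phases), then the psi block.
fourier_design <- function(grid, n_phi_terms, n_psi_terms, phases) {
  phi <- grid$centers_phi * pi / 180
  psi <- grid$centers_psi * pi / 180
  nb_phi <- grid$n_phi; nb_psi <- grid$n_psi
  one_phi <- rep(1, nb_phi); one_psi <- rep(1, nb_psi)
  cols <- list(as.vector(outer(one_phi, one_psi)))
  names(cols) <- "intercept"
  for (n in seq_len(n_phi_terms)) {
    cols[[paste0("cos_phi_", n)]] <- as.vector(outer(cos(n * phi), one_psi))
  }
  if (phases == "free") {
    for (n in seq_len(n_phi_terms)) {
      cols[[paste0("sin_phi_", n)]] <- as.vector(outer(sin(n * phi), one_psi))
    }
  }
  for (m in seq_len(n_psi_terms)) {
    cols[[paste0("cos_psi_", m)]] <- as.vector(outer(one_phi, cos(m * psi)))
  }
  if (phases == "free") {
    for (m in seq_len(n_psi_terms)) {
      cols[[paste0("sin_psi_", m)]] <- as.vector(outer(one_phi, sin(m * psi)))
    }
  }
  do.call(cbind, cols)
}

## Convert (a, b) coefficients of a*cos(n t) + b*sin(n t) into the
## k*cos(n t - gamma) form.  Canonicalized with gamma in (-90, 90] and
## signed k, so cosine-only series keep signed coefficients with gamma = 0.
ab_to_kgamma <- function(a, b) {
  k <- sqrt(a^2 + b^2)
  g <- atan2(b, a) * 180 / pi
  flip <- g > 90 | g <= -90
  k[flip] <- -k[flip]
  g[flip] <- g[flip] - sign(g[flip]) * 180
  list(k = k, gamma = g)
}

#' Fit a separable Fourier potential to an energy surface
#'
#' Least-squares fit of the [fourier_potential()] functional form to an
#' energy surface on the grid, optionally restricted to a mask of valid bins
#' (e.g. bins where a potential-of-mean-force difference is defined).  With
#' `phases = "fixed"` only cosine terms (gamma = 0) are fit; `"free"` adds
#' sine terms, solved in the linear cos/sin parametrization and converted
#' back to amplitude/phase form.
#'
#' @param delta_v `n_phi` x `n_psi` energy surface (kJ/mol); may contain NA
#'   outside the mask.
#' @param grid An [angle_grid()].
#' @param n_phi_terms,n_psi_terms Number of Fourier terms per angle.
#' @param phases `"fixed"` (cosine-only) or `"free"` (cosine and sine).
#' @param mask Logical matrix of bins to include; defaults to all finite
#'   bins of `delta_v`.
#' @param weights Optional non-negative weight matrix for the squared-error
#'   loss (default unweighted).  Weighting by a sampled probability acts as
#'   inverse-variance weighting for log-histogram noise.
#' @return Object of class `fourier_fit`: list with `potential` (the fitted
#'   [fourier_potential()], coefficient increments), `residual_rms` (kJ/mol)
#'   and `n_bins_used`.
#' @export
fit_fourier_to_surface <- function(delta_v, grid = angle_grid(),
                                   n_phi_terms = 5, n_psi_terms = 5,
                                   phases = c("fixed", "free"), mask = NULL,
                                   weights = NULL) {
  phases <- match.arg(phases)
  delta_v <- as.matrix(delta_v)
  stopifnot(nrow(delta_v) == grid$n_phi, ncol(delta_v) == grid$n_psi)
  if (is.null(mask)) mask <- is.finite(delta_v)
  mask <- mask & is.finite(delta_v)
  keep <- as.vector(mask)
  if (!any(keep)) stop("all bins are masked; nothing to fit")
  X <- fourier_design(grid, n_phi_terms, n_psi_terms, phases)
  y <- as.vector(delta_v)[keep]
  fit <- if (is.null(weights)) {
    stats::lm.fit(X[keep, , drop = FALSE], y)
  } else {
    w <- as.vector(as.matrix(weights))[keep]
    if (any(!is.finite(w)) || any(w < 0)) stop("'weights' must be non-negative")
    stats::lm.wfit(X[keep, , drop = FALSE], y, pmax(w, .Machine$double.xmin))
  }
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  cn <- colnames(X)
  a_phi <- beta[match(paste0("cos_phi_", seq_len(n_phi_terms)), cn)]
  a_psi <- beta[match(paste0("cos_psi_", seq_len(n_psi_terms)), cn)]
  if (phases == "free") {
    b_phi <- beta[match(paste0("sin_phi_", seq_len(n_phi_terms)), cn)]
    b_psi <- beta[match(paste0("sin_psi_", seq_len(n_psi_terms)), cn)]
    kp <- ab_to_kgamma(a_phi, b_phi); ks <- ab_to_kgamma(a_psi, b_psi)
  } else {
    kp <- list(k = a_phi, gamma = numeric(n_phi_terms))
    ks <- list(k = a_psi, gamma = numeric(n_psi_terms))
  }
  ## each k (1 + cos) term carries a constant k; the fitted intercept absorbs
  ## them, so the stored offset compensates to reproduce the fit exactly
  offset <- unname(beta[match("intercept", cn)]) - sum(kp$k) - sum(ks$k)
  pot <- fourier_potential(kp$k, ks$k, kp$gamma, ks$gamma, offset)
  structure(list(potential = pot,
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 n_bins_used = sum(keep)),
            class = "fourier_fit")
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf("fourier_fit: residual RMS %.4g kJ/mol over %d bins\n",
              x$residual_rms, x$n_bins_used))
  print(x$potential)
  invisible(x)
}

#' Rescale the periodic terms of a potential
#'
#' Multiplies every periodic coefficient by `factor`, leaving the offset
#' unchanged; the manual-rescaling step used to shrink dihedral potential
#' magnitudes after inversion.
#'
#' @param pot A [fourier_potential()].
#' @param factor Finite scale factor.
#' @return Rescaled [fourier_potential()].
#' @export
rescale_potential <- function(pot, factor) {
  stopifnot(inherits(pot, "fourier_potential"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor)) {
    stop("'factor' must be a single finite number")
  }
  fourier_potential(pot$k_phi * factor, pot$k_psi * factor,
                    pot$gamma_phi, pot$gamma_psi, pot$offset)
}

## Sum of two potentials (pot1 + lambda * pot2), combining matching-order
## terms through the linear cos/sin representation so arbitrary phases add
## correctly.
add_potentials <- function(pot1, pot2, lambda = 1) {
  combine <- function(k1, g1, k2, g2) {
    nmax <- max(length(k1), length(k2))
    a <- b <- numeric(nmax)
    idx1 <- seq_along(k1); idx2 <- seq_along(k2)
    a[idx1] <- k1 * cos(g1 * pi / 180)
    b[idx1] <- k1 * sin(g1 * pi / 180)
    a[idx2] <- a[idx2] + lambda * k2 * cos(g2 * pi / 180)
    b[idx2] <- b[idx2] + lambda * k2 * sin(g2 * pi / 180)
    ab_to_kgamma(a, b)
  }
  p <- combine(pot1$k_phi, pot1$gamma_phi, pot2$k_phi, pot2$gamma_phi)
  s <- combine(pot1$k_psi, pot1$gamma_psi, pot2$k_psi, pot2$gamma_psi)
  ## keep the evaluated surface exactly equal to V1 + lambda*V2: the (1+cos)
  ## form ties a constant sum(k) to the periodic part, so re-balance offset
  off <- pot1$offset + lambda * pot2$offset +
    (sum(pot1$k_phi) + sum(pot1$k_psi) +
       lambda * (sum(pot2$k_phi) + sum(pot2$k_psi))) -
    (sum(p$k) + sum(s$k))
  fourier_potential(p$k, s$k, p$gamma, s$gamma, off)
}
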