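#' Karplus parameters for one coupling
#'
#' J(theta) = A cos^2(theta + theta0) + B cos(theta + theta0) + C, with the
#' phase theta0 tabulated per coupling and the relevant backbone dihedral
#' (phi or psi) carried as data, not code.  Parameter uncertainties
#' (s_A, s_B, s_C) may be absent, as for 1J(N,CA).
#'
#' @param coupling_name Label, e.g. `"3J(HN,HA)"`.
#' @param A,B,C Karplus coefficients in Hz.
#' @param theta0 Phase in degrees.
#' @param depends_on `"phi"` or `"psi"`.
#' @param s_A,s_B,s_C Parameter uncertainties in Hz, or NA when unavailable.
#' @return Object of class `karplus_parameters`.
#' @export
karplus_parameters <- function(coupling_name, A, B, C, theta0,
                               depends_on = c("phi", "psi"),
                               s_A = NA_real_, s_B = NA_real_, s_C = NA_real_) {
  depends_on <- match.arg(depends_on)
  stopifnot(is.character(coupling_name), length(coupling_name) == 1)
  num <- c(A = A, B = B, C = C, theta0 = theta0)
  if (any(!is.finite(num))) stop("Karplus coefficients must be finite")
  s <- c(s_A, s_B, s_C)
  if (any(!is.na(s) & s < 0)) stop("parameter uncertainties must be >= 0")
  structure(list(coupling_name = coupling_name, A = A, B = B, C = C,
                 theta0 = theta0, depends_on = depends_on,
                 s_A = s_A, s_B = s_B, s_C = s_C),
            class = "karplus_parameters")
}

#' Karplus equation
#'
#' @param theta Dihedral angle(s) in degrees.
#' @param params A [karplus_parameters()].
#' @return Coupling constant(s) in Hz.
#' @export
karplus_value <- function(theta, params) {
  stopifnot(inherits(params, "karplus_parameters"))
  if (any(!is.finite(theta))) stop("'theta' must be finite")
  ct <- cos((theta + params$theta0) * pi / 180)
  params$A * ct^2 + params$B * ct + params$C
}

## bin-center function of (phi, psi) for one coupling
karplus_q <- function(params) {
  if (params$depends_on == "phi") {
    function(phi, psi) karplus_value(phi, params)
  } else {
    function(phi, psi) karplus_value(psi, params)
  }
}

#' Ensemble average of an observable over a distribution
#'
#' <Q> = sum over bins of q(phi_center, psi_center) * p(bin); linear in q.
#'
#' @param P A [rama_distribution()].
#' @param q Vectorized `function(phi, psi)` of bin-center angles in degrees.
#' @return The ensemble-averaged value.
#' @export
ensemble_average <- function(P, q) {
  stopifnot(inherits(P, "rama_distribution"), is.function(q))
  g <- P$grid
  PHI <- matrix(g$centers_phi, g$n_phi, g$n_psi)
  PSI <- matrix(g$centers_psi, g$n_phi, g$n_psi, byrow = TRUE)
  Q <- q(PHI, PSI)
  if (length(Q) == 1) Q <- rep(Q, length(PHI))
  Q <- matrix(Q, g$n_phi, g$n_psi)
  if (any(!is.finite(Q) & P$p > 0)) {
    stop("observable is non-finite at an occupied bin")
  }
  sum(Q * P$p, na.rm = TRUE)
}

#' Experimental J-coupling observation
#'
#' @param coupling_name Label matching a [karplus_parameters()] entry.
#' @param J_exp Experimental coupling in Hz.
#' @param s_J Experimental uncertainty in Hz, > 0.
#' @return Object of class `jcoupling_observation`.
#' @export
jcoupling_observation <- function(coupling_name, J_exp, s_J) {
  stopifnot(is.character(coupling_name), length(coupling_name) == 1,
            is.finite(J_exp))
  if (!is.finite(s_J) || s_J <= 0) stop("'s_J' must be positive")
  structure(list(coupling_name = coupling_name, J_exp = J_exp, s_J = s_J),
            class = "jcoupling_observation")
}

#' Total uncertainty of an ensemble-averaged J-coupling
#'
#' Propagates the Karplus-parameter uncertainties together with the
#' experimental one: the pointwise uncertainty
#' s_bar(theta) = sqrt( (s_A cos^2)^2 + (s_B cos)^2 + s_C^2 + s_J^2 )
#' (quadrature combination of independent error sources, with
#' cos = cos(theta + theta0)) is ensemble-averaged over the distribution.
#' The result is always >= s_J.
#'
#' @param P A [rama_distribution()].
#' @param params A [karplus_parameters()]; its `s_A`, `s_B`, `s_C` must be
#'   present (not NA).
#' @param obs A [jcoupling_observation()].
#' @return Total uncertainty s_i in Hz.
#' @export
coupling_uncertainty <- function(P, params, obs) {
  stopifnot(inherits(params, "karplus_parameters"),
            inherits(obs, "jcoupling_observation"))
  if (any(is.na(c(params$s_A, params$s_B, params$s_C)))) {
    stop(sprintf(paste("Karplus parameter uncertainties are unavailable for %s;",
                       "use the experimental uncertainty s_J alone"),
                 params$coupling_name))
  }
  sbar <- function(theta) {
    ct <- cos((theta + params$theta0) * pi / 180)
    sqrt((params$s_A * ct^2)^2 + (params$s_B * ct)^2 +
           params$s_C^2 + obs$s_J^2)
  }
  q <- if (params$depends_on == "phi") {
    function(phi, psi) sbar(phi)
  } else {
    function(phi, psi) sbar(psi)
  }
  ensemble_average(P, q)
}

#' Reduced chi-squared over a set of J-couplings
#'
#' chi2 = (1/N) sum_i ((J_calc_i - J_exp_i) / s_i)^2.  When `depends_on`
#' tags are supplied, the phi-dependent subset statistic `chi2_Jphi` is also
#' returned.
#'
#' @param J_calc,J_exp Equal-length vectors of calculated and experimental
#'   couplings (Hz).
#' @param s Per-coupling total uncertainties (Hz), > 0.
#' @param depends_on Optional character vector of `"phi"`/`"psi"` tags.
#' @return If `depends_on` is NULL, the reduced chi-squared (numeric);
#'   otherwise a list with `chi2_J` and `chi2_Jphi`.
#' @export
chi2_j <- function(J_calc, J_exp, s, depends_on = NULL) {
  n <- length(J_calc)
  if (n == 0) stop("no couplings supplied")
  if (length(J_exp) != n || length(s) != n) {
    stop("'J_calc', 'J_exp' and 's' must have equal length")
  }
  if (any(!is.finite(s)) || any(s <= 0)) stop("uncertainties must be positive")
  z2 <- ((J_calc - J_exp) / s)^2
  if (is.null(depends_on)) return(mean(z2))
  phi_set <- depends_on == "phi"
  list(chi2_J = mean(z2),
       chi2_Jphi = if (any(phi_set)) mean(z2[phi_set]) else NA_real_)
}

#' Score a distribution against J-coupling observations
#'
#' Forward-computes every observed coupling as an ensemble average under the
#' distribution, propagates uncertainties, and aggregates the reduced
#' chi-squared over all couplings and over the phi-dependent subset.
#'
#' @param P A [rama_distribution()].
#' @param karplus Named list of [karplus_parameters()] (names = coupling
#'   names), or the data frame from [read_karplus_table()].
#' @param observations List of [jcoupling_observation()]s, or the data frame
#'   from [read_observations_table()].
#' @return Object of class `jcoupling_report`: data frame `couplings` with
#'   columns `coupling_name`, `depends_on`, `J_calc`, `J_exp`, `abs_dev`,
#'   `s_i`, plus scalars `chi2_J` and `chi2_Jphi`.
#' @export
jcoupling_report <- function(P, karplus, observations) {
  karplus <- as_karplus_list(karplus)
  observations <- as_observation_list(observations)
  rows <- lapply(observations, function(obs) {
    par <- karplus[[obs$coupling_name]]
    if (is.null(par)) {
      stop("no Karplus parameters for coupling ", obs$coupling_name)
    }
    jc <- ensemble_average(P, karplus_q(par))
    si <- if (any(is.na(c(par$s_A, par$s_B, par$s_C)))) obs$s_J
          else coupling_uncertainty(P, par, obs)
    data.frame(coupling_name = obs$coupling_name,
               depends_on = par$depends_on,
               J_calc = jc, J_exp = obs$J_exp,
               abs_dev = abs(jc - obs$J_exp), s_i = si,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  agg <- chi2_j(df$J_calc, df$J_exp, df$s_i, df$depends_on)
  structure(list(couplings = df,
                 chi2_J = agg$chi2_J, chi2_Jphi = agg$chi2_Jphi),
            class = "jcoupling_report")
}

#' @export
print.jcoupling_report <- function(x, ...) {
  df <- x$couplings
  df$J_calc <- round(df$J_calc, 3); df$abs_dev <- round(df$abs_dev, 3)
  df$s_i <- round(df$s_i, 3)
  print(df, row.names = FALSE)
  cat(sprintf("reduced chi2_J = %.4g, chi2_Jphi = %.4g\n",
              x$chi2_J, x$chi2_Jphi))
  invisible(x)
}

as_karplus_list <- function(x) {
  if (is.data.frame(x)) {
    x <- lapply(seq_len(nrow(x)), function(i) {
      karplus_parameters(x$coupling_name[i], x$A[i], x$B[i], x$C[i],
                         x$theta0[i], x$depends_on[i],
                         x$s_A[i], x$s_B[i], x$s_C[i])
    })
  }
  if (inherits(x, "karplus_parameters")) x <- list(x)
  stats::setNames(x, vapply(x, `[[`, character(1), "coupling_name"))
}

as_observation_list <- function(x) {
  if (is.data.frame(x)) {
    x <- lapply(seq_len(nrow(x)), function(i) {
      jcoupling_observation(x$coupling_name[i], x$J_exp[i], x$s_J[i])
    })
  }
  if (inherits(x, "jcoupling_observation")) x <- list(x)
  x
}

#' Two-oscillator exciton model configuration for amide I' VCD
#'
#' Degenerate coupled-oscillator model of the two amide I' chromophores
#' flanking the central residue.  Dipole 1 lies along the laboratory x axis;
#' dipole 2 is its image rotated by phi about z and psi about y; the
#' inter-dipole separation vector points along z.  This geometry yields an
#' excitonic splitting even in (phi, psi) and a rotational strength odd in
#' (phi, psi), so inversion-symmetric (achiral, glycine-like) ensembles give
#' an identically zero VCD signal.  All constants are configurable; the
#' model is a simple, conservative-couplet approximation, not a quantitative
#' transition-dipole-coupling parametrization.
#'
#' @param nu0 Intrinsic oscillator wavenumber in 1/cm (amide I' in D2O,
#'   default 1650).
#' @param coupling_strength Splitting scale in 1/cm: the excitonic coupling
#'   is `coupling_strength * cos(phi) * cos(psi)` (default 5).
#' @param rotational_scale Rotational-strength scale of the couplet (sets
#'   the molar-dichroism units of the output; default 1).
#' @param half_width Band half-width at half-maximum in 1/cm (default 12).
#' @param shape `"gaussian"` or `"lorentzian"` band shape.
#' @param wavenumbers Output wavenumber grid in 1/cm.
#' @return Object of class `oscillator_config`.
#' @export
oscillator_config <- function(nu0 = 1650, coupling_strength = 5,
                              rotational_scale = 1, half_width = 12,
                              shape = c("gaussian", "lorentzian"),
                              wavenumbers = NULL) {
  shape <- match.arg(shape)
  stopifnot(nu0 > 0, half_width > 0, is.finite(coupling_strength),
            is.finite(rotational_scale))
  if (is.null(wavenumbers)) wavenumbers <- seq(nu0 - 60, nu0 + 60, by = 1)
  structure(list(nu0 = nu0, coupling_strength = coupling_strength,
                 rotational_scale = rotational_scale,
                 half_width = half_width, shape = shape,
                 wavenumbers = wavenumbers),
            class = "oscillator_config")
}

#' Construct a VCD amide I' profile object
#'
#' @param wavenumbers Wavenumber grid in 1/cm.
#' @param delta_epsilon Molar dichroism per wavenumber.
#' @param s_k Per-point standard error (> 0); recycled if scalar.
#' @return Object of class `vcd_profile`.
#' @export
vcd_profile_object <- function(wavenumbers, delta_epsilon, s_k = 1) {
  stopifnot(length(wavenumbers) == length(delta_epsilon))
  s_k <- rep_len(s_k, length(wavenumbers))
  if (any(!is.finite(s_k)) || any(s_k <= 0)) stop("'s_k' must be positive")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 delta_epsilon = as.numeric(delta_epsilon),
                 s_k = as.numeric(s_k)),
            class = "vcd_profile")
}

band_shape <- function(x, half_width, shape) {
  if (shape == "gaussian") {
    ## half-width at half-maximum -> sigma
    sigma <- half_width / sqrt(2 * log(2))
    exp(-0.5 * (x / sigma)^2) / (sigma * sqrt(2 * pi))
  } else {
    (half_width / pi) / (x^2 + half_width^2)
  }
}

#' Forward-compute the VCD amide I' profile of an ensemble
#'
#' For each (phi, psi) bin the two-oscillator exciton model produces two
#' bands at nu0 +/- J(phi, psi) with rotational strengths of opposite sign
#' (a conservative couplet, sum exactly zero per conformer); the per-bin
#' couplets are population-averaged over the distribution and convolved with
#' the configured band shape.  Parallel-dipole geometries give a zero
#' couplet, not an error.
#'
#' @param P A [rama_distribution()].
#' @param cfg An [oscillator_config()].
#' @param s_k Standard error attached to the returned profile (placeholder
#'   for calculated profiles; default 1).
#' @return A [vcd_profile_object()].
#' @export
vcd_profile <- function(P, cfg = oscillator_config(), s_k = 1) {
  stopifnot(inherits(P, "rama_distribution"), inherits(cfg, "oscillator_config"))
  grid <- P$grid
  phi <- grid$centers_phi * pi / 180
  psi <- grid$centers_psi * pi / 180
  ## excitonic splitting (even in phi, psi) and rotational strength
  ## (odd: R ~ r12 . (mu1 x mu2) = sin(phi) cos(psi) for this geometry)
  Jmat <- cfg$coupling_strength * outer(cos(phi), cos(psi))
  Rmat <- cfg$rotational_scale * outer(sin(phi), cos(psi))
  pw <- as.vector(P$p)
  keep <- pw > 0
  pR <- (pw * as.vector(Rmat))[keep]
  Jv <- as.vector(Jmat)[keep]
  wn <- cfg$wavenumbers
  de <- vapply(wn, function(nu) {
    sum(pR * (band_shape(nu - (cfg$nu0 + Jv), cfg$half_width, cfg$shape) -
                band_shape(nu - (cfg$nu0 - Jv), cfg$half_width, cfg$shape)))
  }, numeric(1))
  vcd_profile_object(wn, de, s_k)
}

#' Reduced chi-squared between two VCD profiles
#'
#' chi2_VCD = (1/N') sum_k ((de_calc_k - de_exp_k) / s_k)^2 using the
#' experimental per-point standard errors.
#'
#' @param calc,exp [vcd_profile_object()]s on identical wavenumber grids.
#' @return Reduced chi-squared (unitless).
#' @export
chi2_vcd <- function(calc, exp) {
  stopifnot(inherits(calc, "vcd_profile"), inherits(exp, "vcd_profile"))
  if (length(calc$wavenumbers) != length(exp$wavenumbers) ||
      any(abs(calc$wavenumbers - exp$wavenumbers) > 1e-9)) {
    stop("VCD profiles are on different wavenumber grids")
  }
  mean(((calc$delta_epsilon - exp$delta_epsilon) / exp$s_k)^2)
}
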