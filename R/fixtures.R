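#' Built-in Karplus parameter defaults
#'
#' Loads the editable table shipped in `inst/extdata/karplus_default.tsv`:
#' representative literature-style parameters for the five couplings used to
#' constrain guest-residue ensembles (the Hu-Bax-style phi-dependent 3J set
#' and a psi-dependent 1J(N,CA) without tabulated parameter uncertainties).
#' Replace the file or pass your own table wherever Karplus parameters are
#' accepted.
#'
#' @return Data frame in [read_karplus_table()] layout.
#' @export
default_karplus_table <- function() {
  read_karplus_table(system.file("extdata", "karplus_default.tsv",
                                 package = "ramaibi", mustWork = TRUE))
}

#' Synthetic target ensembles with known ground truth
#'
#' Builds a Gaussian superposition model and its binned distribution for one
#' of three scenarios:
#' \describe{
#'   \item{glycine_like}{Inversion-symmetric about (0, 0): components come in
#'     +/- center pairs with equal weights, emulating the achiral backbone
#'     of a glycine guest residue.}
#'   \item{alanine_like}{Chiral, with a dominant polyproline II basin.  The
#'     component layout is a product of a phi-mode mixture (pPII/helical
#'     column near -66 deg, beta column near -125 deg) and a psi-mode
#'     mixture (extended band near 145 deg, helical band near -40 deg), the
#'     class of distributions a separable backbone dihedral potential can
#'     generate.}
#'   \item{custom}{A single component (delta-like for small sigma), for
#'     fixed-point tests.}
#' }
#'
#' @param scenario `"glycine_like"`, `"alanine_like"` or `"custom"`.
#' @param grid An [angle_grid()].
#' @param weights Optional named weight overrides (by component name);
#'   remaining weights are rescaled to keep the total at 1.
#' @param center,sigma Component center/half-widths for `scenario = "custom"`.
#' @return List with `model` (the [gaussian_rama_model()] ground truth) and
#'   `distribution` (its [rama_distribution()] on `grid`).
#' @export
make_target <- function(scenario = c("glycine_like", "alanine_like", "custom"),
                        grid = angle_grid(), weights = NULL,
                        center = c(-60, 150), sigma = c(12, 12)) {
  scenario <- match.arg(scenario)
  comps <- switch(scenario,
    glycine_like = {
      half <- list(
        list(name = "pPII+", w = 0.30, c = c(-80, 150), s = c(14, 14)),
        list(name = "beta+", w = 0.15, c = c(-150, 155), s = c(15, 13)),
        list(name = "alpha+", w = 0.05, c = c(-65, -40), s = c(11, 11)))
      mirrored <- lapply(half, function(x) {
        list(name = paste0(sub("\\+$", "", x$name), "-"),
             w = x$w, c = -x$c, s = x$s)
      })
      c(half, mirrored)
    },
    alanine_like = {
      ## the two extended basins that dominate alanine ensembles, sharing
      ## the high-psi band so a single Monte Carlo walk equilibrates them
      list(
        list(name = "pPII", w = 0.78, c = c(-66, 145), s = c(14, 12)),
        list(name = "betat", w = 0.22, c = c(-125, 145), s = c(16, 12)))
    },
    custom = list(list(name = "custom", w = 1, c = center, s = sigma)))
  if (!is.null(weights)) {
    nm <- vapply(comps, `[[`, character(1), "name")
    if (!all(names(weights) %in% nm)) {
      stop("unknown component in weight overrides: ",
           paste(setdiff(names(weights), nm), collapse = ", "))
    }
    w <- vapply(comps, `[[`, numeric(1), "w")
    fixed <- nm %in% names(weights)
    w[fixed] <- weights[nm[fixed]]
    if (sum(w[fixed]) > 1) stop("overridden weights exceed 1")
    if (any(!fixed)) {
      w[!fixed] <- w[!fixed] / sum(w[!fixed]) * (1 - sum(w[fixed]))
    }
    for (i in seq_along(comps)) comps[[i]]$w <- w[i]
  }
  w <- vapply(comps, `[[`, numeric(1), "w")
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("component weights sum to %.12g, not 1", sum(w)))
  }
  model <- gaussian_rama_model(lapply(comps, function(x) {
    gaussian_component(x$name, x$w, x$c, x$s)
  }))
  list(model = model, distribution = evaluate_model(model, grid))
}

#' Generate a synthetic spectroscopic experiment from a model
#'
#' Forward-computes the noiseless ensemble-averaged J-couplings (and
#' optionally the VCD amide I' profile) of the model, then adds Gaussian
#' noise matched to the scoring uncertainties: each J observation is drawn
#' with the total per-coupling uncertainty s_i (experimental plus propagated
#' Karplus-parameter error), so the reduced chi-squared of the generating
#' model against its own synthetic experiment is calibrated to 1 in
#' expectation.  Noiseless ground-truth values are recorded alongside.
#'
#' @param model A [gaussian_rama_model()].
#' @param karplus Karplus table (data frame) or list of
#'   [karplus_parameters()]; defaults to [default_karplus_table()].
#' @param seed Integer random seed.
#' @param s_J Experimental uncertainty per coupling in Hz (recycled).
#' @param grid An [angle_grid()].
#' @param include_vcd Also generate a noisy VCD profile?
#' @param vcd_cfg An [oscillator_config()] for the VCD forward model.
#' @param vcd_noise Per-point VCD standard error s_k.
#' @return List with `observations` (data frame `coupling_name`, `J_exp`,
#'   `s_J`), `truth` (data frame with noiseless `J_true` and the total
#'   uncertainty `s_i` used as noise sd), `vcd` (noisy
#'   [vcd_profile_object()] or NULL) and `vcd_truth`.
#' @export
make_synthetic_experiment <- function(model, karplus = default_karplus_table(),
                                      seed = 1, s_J = 0.3,
                                      grid = angle_grid(),
                                      include_vcd = TRUE,
                                      vcd_cfg = oscillator_config(),
                                      vcd_noise = NULL) {
  stopifnot(inherits(model, "gaussian_rama_model"))
  P <- evaluate_model(model, grid)
  kl <- as_karplus_list(karplus)
  nms <- names(kl)
  s_J <- rep_len(s_J, length(kl))
  set.seed(seed)
  j_true <- s_tot <- numeric(length(kl))
  for (i in seq_along(kl)) {
    par <- kl[[i]]
    j_true[i] <- ensemble_average(P, karplus_q(par))
    obs0 <- jcoupling_observation(par$coupling_name, j_true[i], s_J[i])
    s_tot[i] <- if (any(is.na(c(par$s_A, par$s_B, par$s_C)))) s_J[i]
                else coupling_uncertainty(P, par, obs0)
  }
  j_exp <- j_true + stats::rnorm(length(kl), 0, s_tot)
  vcd <- vcd_true <- NULL
  if (include_vcd) {
    vcd_true <- vcd_profile(P, vcd_cfg)
    if (is.null(vcd_noise)) {
      vcd_noise <- max(abs(vcd_true$delta_epsilon), .Machine$double.eps) * 0.05
    }
    noisy <- vcd_true$delta_epsilon +
      stats::rnorm(length(vcd_true$wavenumbers), 0, vcd_noise)
    vcd <- vcd_profile_object(vcd_true$wavenumbers, noisy, vcd_noise)
  }
  list(observations = data.frame(coupling_name = nms, J_exp = j_exp,
                                 s_J = s_J, stringsAsFactors = FALSE),
       truth = data.frame(coupling_name = nms, J_true = j_true, s_i = s_tot,
                          stringsAsFactors = FALSE),
       vcd = vcd, vcd_truth = vcd_true, seed = seed)
}
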