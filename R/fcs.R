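#' FCS model parameters
#'
#' Parameters of the autocorrelation model for translational diffusion
#' through a 3D Gaussian confocal volume with triplet dynamics:
#' \deqn{G(\tau) = 1 + \frac{1}{\langle N\rangle}
#'   \left(1 + \tau/\tau_D\right)^{-1}
#'   \left(1 + s^2 \tau/\tau_D\right)^{-1/2}
#'   \left(1 + c_T e^{-\tau/\tau_T}\right)}
#'
#' @param N_mean mean number of molecules in the confocal volume, > 0.
#' @param tau_D diffusion time (s), > 0.
#' @param s aspect ratio of the confocal volume (default 0.27).
#' @param c_T triplet amplitude, >= 0.
#' @param tau_T triplet time (s), > 0.
#' @return An `fcs_params` list.
#' @export
fcs_params <- function(N_mean, tau_D, s = 0.27, c_T = 0, tau_T = 1e-6) {
  stopifnot(N_mean > 0, tau_D > 0, s >= 0, c_T >= 0, tau_T > 0)
  structure(list(N_mean = N_mean, tau_D = tau_D, s = s, c_T = c_T,
                 tau_T = tau_T), class = "fcs_params")
}

#' Evaluate the FCS correlation model
#'
#' @param params an [fcs_params()].
#' @param lags lag times (s), positive.
#' @return Correlation values G(tau).
#' @export
fcs_model <- function(params, lags) {
  stopifnot(all(lags > 0))
  with(params,
       1 + (1 / N_mean) * (1 + lags / tau_D)^-1 *
         (1 + s^2 * lags / tau_D)^-0.5 *
         (1 + c_T * exp(-lags / tau_T)))
}

#' Simulate a synthetic FCS curve
#'
#' Evaluates the correlation model on a lag grid and applies multiplicative
#' Gaussian noise of relative magnitude `noise_level` to the correlation
#' amplitude G - 1 (correlator noise scales with the correlation, so the
#' baseline G -> 1 stays clean at the same relative level).
#'
#' @param params an [fcs_params()].
#' @param lags lag grid (s); default 140 log-spaced points between 1e-7 and
#'   1 s, the span of a typical multi-tau correlator.
#' @param noise_level relative noise SD (0 for a noiseless curve).
#' @return An `fcs_curve` tibble with columns `lag`, `G`.
#' @export
simulate_fcs_curve <- function(params, lags = 10^seq(-7, 0, length.out = 140),
                               noise_level = 0) {
  G <- fcs_model(params, lags)
  if (noise_level > 0)
    G <- 1 + (G - 1) * (1 + stats::rnorm(length(G), 0, noise_level))
  out <- tibble::tibble(lag = lags, G = G)
  class(out) <- c("fcs_curve", class(out))
  out
}

#' Fit the FCS model to a correlation curve
#'
#' Weighted least-squares fit (Levenberg-Marquardt) of the diffusion +
#' triplet model. The aspect-ratio parameter `s` is fixed at 0.27 by
#' default; any parameter listed in `fixed` is held at the supplied value.
#' Weights default to 1/G^2, matching multiplicative noise.
#'
#' @param curve an `fcs_curve` (or tibble with `lag`, `G`), >= 10 points.
#' @param fixed named list of parameters to fix, e.g.
#'   `list(s = 0.27, c_T = 0.15, tau_T = 2e-6)`.
#' @param start optional named list of starting values; defaults derived
#'   from the curve (amplitude -> N_mean, half-decay lag -> tau_D).
#' @param weights optional weights; default `1/G^2`.
#' @return An `fcs_fit` list: `params` ([fcs_params()]), `fitted`,
#'   `residuals`, `converged`, `fixed`.
#' @export
fit_fcs <- function(curve, fixed = list(s = 0.27), start = NULL,
                    weights = NULL) {
  stopifnot(nrow(curve) >= 10)
  lag <- curve$lag; G <- curve$G
  if (is.null(weights)) weights <- 1 / G^2
  amp <- max(mean(G[seq_len(3)]) - 1, 1e-6)
  N0 <- 1 / amp
  half <- 1 + amp / 2
  tauD0 <- lag[which.min(abs(G - half))]
  defaults <- list(N_mean = N0, tau_D = max(tauD0, min(lag)), s = 0.27,
                   c_T = 0.05, tau_T = 2e-6)
  if (!is.null(start)) defaults[names(start)] <- start
  defaults[names(fixed)] <- fixed
  free <- setdiff(c("N_mean", "tau_D", "s", "c_T", "tau_T"), names(fixed))
  if (!length(free)) stop("no free parameters", call. = FALSE)

  par0 <- log(pmax(unlist(defaults[free]), 1e-12))
  fn <- function(th) {
    p <- defaults
    p[free] <- as.list(exp(th))
    sqrt(weights) * (G - fcs_model(structure(p, class = "fcs_params"), lag))
  }
  fit <- minpack.lm::nls.lm(par0, fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  p <- defaults
  p[free] <- as.list(exp(fit$par))
  params <- structure(p, class = "fcs_params")
  fitted <- fcs_model(params, lag)
  structure(list(params = params, fitted = fitted,
                 residuals = G - fitted,
                 converged = fit$info %in% 1:4,
                 fixed = fixed, lags = lag, G = G),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf(
    "<fcs_fit> <N> = %.4g, tau_D = %.3g s, s = %.2f, c_T = %.3g, tau_T = %.3g s%s\n",
    x$params$N_mean, x$params$tau_D, x$params$s, x$params$c_T,
    x$params$tau_T, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Two-pass FCS fitting across replicate curves
#'
#' First pass: each curve is fitted with the triplet amplitude and triplet
#' time free. The triplet parameters are then averaged over all fits and
#' fixed; in the second pass only the diffusion time and the mean occupancy
#' \eqn{\langle N\rangle} remain free.
#'
#' @param curves list of `fcs_curve` objects.
#' @param s fixed aspect-ratio parameter.
#' @return A list: `fits` (second-pass `fcs_fit` per curve), `N_mean`
#'   (average over curves), `c_T`, `tau_T` (the averaged triplet
#'   parameters).
#' @export
fit_fcs_two_pass <- function(curves, s = 0.27) {
  if (inherits(curves, "fcs_curve")) curves <- list(curves)
  pass1 <- lapply(curves, fit_fcs, fixed = list(s = s))
  c_T <- mean(vapply(pass1, function(f) f$params$c_T, 0))
  tau_T <- mean(vapply(pass1, function(f) f$params$tau_T, 0))
  pass2 <- lapply(curves, fit_fcs,
                  fixed = list(s = s, c_T = c_T, tau_T = tau_T))
  list(fits = pass2,
       N_mean = mean(vapply(pass2, function(f) f$params$N_mean, 0)),
       c_T = c_T, tau_T = tau_T)
}

#' Convert a fitted mean occupancy to a ligand concentration
#'
#' Linear conversion through an instrument calibration factor (mol/L per
#' molecule in the confocal volume), which must be supplied explicitly:
#' the effective confocal volume is instrument-specific and is obtained
#' from a calibration measurement.
#'
#' @param N_mean fitted mean number of molecules.
#' @param calibration_factor mol/L per molecule, > 0.
#' @param N_sd optional uncertainty of `N_mean`, propagated linearly.
#' @return A one-row tibble with `concentration` (mol/L) and
#'   `concentration_sd`.
#' @export
concentration_from_N <- function(N_mean, calibration_factor, N_sd = NULL) {
  if (missing(calibration_factor) || is.null(calibration_factor) ||
      !is.numeric(calibration_factor) || calibration_factor <= 0)
    stop("a positive `calibration_factor` must be supplied", call. = FALSE)
  stopifnot(N_mean >= 0)
  tibble::tibble(concentration = N_mean * calibration_factor,
                 concentration_sd = if (is.null(N_sd)) NA_real_ else
                   N_sd * calibration_factor)
}

#' Write / read an FCS curve as TSV
#'
#' @param curve an `fcs_curve`.
#' @param path file path.
#' @return `write_fcs_tsv()`: `path` invisibly; `read_fcs_tsv()`: an
#'   `fcs_curve`.
#' @export
write_fcs_tsv <- function(curve, path) {
  utils::write.table(data.frame(lag_s = curve$lag, G = curve$G), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fcs_tsv
#' @export
read_fcs_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- tibble::tibble(lag = tab$lag_s, G = tab$G)
  class(out) <- c("fcs_curve", class(out))
  out
}
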