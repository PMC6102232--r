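#' Log-likelihood of a binned photon trace under a kinetic model
#'
#' Evaluates the binned-photon hidden-Markov likelihood
#' \deqn{L = 1^T \left[\prod_{t=1}^{T} F_t e^{\Delta K}\right] p_{eq}}
#' where \eqn{F_t} is diagonal with per-state Poisson factors for the donor
#' and acceptor counts of bin t, by the forward recursion
#' \eqn{\alpha_t = F_t e^{\Delta K} \alpha_{t-1}}, \eqn{\alpha_0 = p_{eq}},
#' rescaled every bin. The result is independent of the rescaling schedule
#' up to floating point.
#'
#' @param trace a [photon_trace()].
#' @param model a `kinetic_model` (must be irreducible up to transient
#'   states).
#' @param emissions an [emission_rates()] covering the model's classes.
#' @param p0 optional start distribution; default the stationary one.
#' @return The log-likelihood (scalar; `-Inf` for traces impossible under a
#'   degenerate model, e.g. zero photon rate with nonzero counts).
#' @export
trace_log_likelihood <- function(trace, model, emissions, p0 = NULL) {
  stopifnot(inherits(trace, "photon_trace"),
            inherits(model, "kinetic_model"))
  delta <- attr(trace, "delta")
  P <- propagator(model, delta)
  if (is.null(p0)) p0 <- equilibrium_distribution(model)$p_eq
  mus <- state_bin_means(model, emissions, delta)
  forward_loglik_cpp(trace$donor, trace$acceptor, P, mus$mu_d, mus$mu_a,
                     unname(p0))
}

# ---- internal fitting machinery -------------------------------------------

model_builder <- function(type) {
  switch(type,
         two_state = build_two_state,
         two_state_blink = build_two_state_blink,
         three_state_blink = build_three_state_blink,
         four_state_blink = build_four_state_blink,
         stop("unknown model type: ", type, call. = FALSE))
}

RATE_LOWER <- 1e-4
RATE_UPPER <- 1e4
EMIS_LOWER <- 1e-2
EMIS_UPPER <- 1e6

# pack/unpack free parameters on the log scale
pack_params <- function(rates, emissions, free_rates, free_emissions) {
  th <- numeric(0); nm <- character(0)
  for (f in free_rates) {
    v <- rates[[f]]
    th <- c(th, log(max(min(v, RATE_UPPER), RATE_LOWER)))
    nm <- c(nm, f)
  }
  if (length(free_emissions)) {
    for (f in free_emissions) {
      p <- strsplit(f, "\\.")[[1]]  # "class.channel"
      v <- emissions[[paste0("rate_", p[2])]][emissions$class == p[1]]
      th <- c(th, log(max(min(v, EMIS_UPPER), EMIS_LOWER)))
      nm <- c(nm, f)
    }
  }
  stats::setNames(th, nm)
}

unpack_params <- function(theta, rates, emissions, free_rates,
                          free_emissions) {
  i <- 0L
  for (f in free_rates) {
    i <- i + 1L
    rates[[f]] <- unname(exp(theta[i]))
  }
  for (f in free_emissions) {
    i <- i + 1L
    p <- strsplit(f, "\\.")[[1]]
    emissions[[paste0("rate_", p[2])]][emissions$class == p[1]] <-
      unname(exp(theta[i]))
  }
  list(rates = rates, emissions = emissions)
}

# apply "class.channel" photon-rate overrides to an emissions object
patch_emissions <- function(emissions, free_emissions, values) {
  for (i in seq_along(free_emissions)) {
    p <- strsplit(free_emissions[i], "\\.")[[1]]
    emissions[[paste0("rate_", p[2])]][emissions$class == p[1]] <- values[i]
  }
  emissions
}

# negative summed log-likelihood over traces (shared kinetics, per-trace
# emissions allowed via emissions_list; free emission rates are shared
# across traces)
make_objective <- function(traces, type, rates, emissions_list, free_rates,
                           free_emissions) {
  build <- model_builder(type)
  delta <- attr(traces[[1]], "delta")
  same_emis <- length(emissions_list) == 1L
  nk <- length(free_rates)
  ne <- length(free_emissions)
  function(theta) {
    if (any(!is.finite(theta))) return(1e300)
    thk <- theta[seq_len(nk)]
    the <- theta[nk + seq_len(ne)]
    if (any(thk < log(RATE_LOWER)) || any(thk > log(RATE_UPPER)))
      return(1e300)
    if (ne && (any(the < log(EMIS_LOWER)) || any(the > log(EMIS_UPPER))))
      return(1e300)
    up <- unpack_params(theta, rates, emissions_list[[1]], free_rates,
                        free_emissions)
    model <- tryCatch(build(up$rates), error = function(e) NULL)
    if (is.null(model)) return(1e300)
    P <- propagator(model, delta)
    p0 <- tryCatch(unname(equilibrium_distribution(model)$p_eq),
                   error = function(e) NULL)
    if (is.null(p0)) return(1e300)
    emis_vals <- exp(theta[length(free_rates) + seq_along(free_emissions)])
    ll <- 0
    for (m in seq_along(traces)) {
      emis <- if (same_emis) up$emissions else
        patch_emissions(emissions_list[[m]], free_emissions, emis_vals)
      mus <- state_bin_means(model, emis, delta)
      lm <- forward_loglik_cpp(traces[[m]]$donor, traces[[m]]$acceptor, P,
                               mus$mu_d, mus$mu_a, p0)
      if (!is.finite(lm)) return(1e300)
      ll <- ll + lm
    }
    -ll
  }
}

new_fit_result <- function(estimates, loglik, converged, n_traces, n_bins,
                           type, rates, emissions, free_rates,
                           free_emissions, delta, se = NULL) {
  structure(list(estimates = estimates, log_likelihood = loglik,
                 converged = converged, n_traces = n_traces,
                 n_bins = n_bins, model_type = type, rates = rates,
                 emissions = emissions, free_rates = free_rates,
                 free_emissions = free_emissions, delta = delta,
                 bootstrap_sd = se),
            class = "photonhmm_fit")
}

#' @export
print.photonhmm_fit <- function(x, ...) {
  cat(sprintf("<photonhmm_fit> %s, %d trace(s), %d bins, ln L = %.2f%s\n",
              x$model_type, x$n_traces, x$n_bins, x$log_likelihood,
              if (x$converged) "" else " (NOT converged)"))
  est <- x$estimates
  df <- data.frame(estimate = unlist(est))
  if (!is.null(x$bootstrap_sd))
    df$bootstrap_sd <- x$bootstrap_sd[rownames(df)]
  print(df)
  invisible(x)
}

mlh_fit <- function(traces, type, rates_init, emissions_init,
                    free_rates, free_emissions = character(0),
                    maxit = 2000, reltol = 1e-10) {
  if (inherits(traces, "photon_trace")) traces <- list(traces)
  if (!length(free_rates) && !length(free_emissions))
    stop("at least one free parameter is required", call. = FALSE)
  if (!inherits(rates_init, "rate_spec"))
    rates_init <- do.call(rate_spec, rates_init)
  rates <- unclass(rates_init)
  # second-order rates are derived quantities; drop them so optimizing the
  # pseudo-first-order rates cannot leave the spec inconsistent
  rates$kon1 <- NULL
  rates$kon2 <- NULL
  emissions_list <- if (inherits(emissions_init, "emission_rates"))
    list(emissions_init) else emissions_init
  obj <- make_objective(traces, type, rates, emissions_list, free_rates,
                        free_emissions)
  th0 <- pack_params(rates, emissions_list[[1]], free_rates, free_emissions)
  opt <- if (length(th0) == 1L) {
    o <- stats::optim(th0, obj, method = "Brent",
                      lower = log(RATE_LOWER), upper = log(RATE_UPPER))
    o
  } else {
    stats::optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  }
  up <- unpack_params(stats::setNames(opt$par, names(th0)), rates,
                      emissions_list[[1]], free_rates, free_emissions)
  est <- c(up$rates[free_rates],
           as.list(stats::setNames(exp(opt$par[length(free_rates) +
                                                 seq_along(free_emissions)]),
                                   free_emissions)))
  n_bins <- sum(vapply(traces, nrow, 0L))
  # a free rate pinned near its box edge means that direction is not
  # identified by the data (e.g. no transitions observed)
  kest <- exp(opt$par[seq_along(free_rates)])
  at_bound <- length(kest) && (any(kest <= 2 * RATE_LOWER) ||
                                 any(kest >= RATE_UPPER / 2))
  new_fit_result(est, -opt$value, opt$convergence == 0 && !at_bound,
                 length(traces), n_bins, type, up$rates,
                 if (length(emissions_list) == 1L) up$emissions else
                   emissions_list,
                 free_rates, free_emissions, attr(traces[[1]], "delta"))
}

default_free_rates <- function(type) {
  switch(type,
         two_state = c("kon1_prime", "koff1"),
         two_state_blink = c("kon1_prime", "koff1", "kb_plus", "kb_minus"),
         three_state_blink = c("kon1_prime", "kon2_prime", "koff1", "koff2",
                               "kb_plus", "kb_minus"),
         four_state_blink = c("kon1_prime", "kon2_prime", "koff1", "koff2",
                              "k12", "k21", "kb_plus", "kb_minus"))
}

#' Maximum-likelihood fit of a single photon trace
#'
#' Maximizes the binned-photon log-likelihood of one trace over the free
#' rate coefficients and (optionally) the per-class photon rates. Free
#' parameters are optimized on a log scale (bounds 1e-4 to 1e4 s^-1 for
#' rates), by Nelder-Mead from the supplied initial values; convergence is
#' declared when the relative change in ln L falls below `reltol`. By
#' default the trace is rebinned to 20 ms, the bin width used for per-trace
#' photon-rate estimation.
#'
#' @param trace a [photon_trace()].
#' @param type model type: `"two_state"`, `"two_state_blink"`,
#'   `"three_state_blink"` or `"four_state_blink"`.
#' @param rates_init initial [rate_spec()] (all required rates set; fixed
#'   rates keep these values).
#' @param emissions_init initial [emission_rates()].
#' @param free_rates names of rate fields to optimize; default all rates of
#'   the model type.
#' @param free_emissions character vector like `"bound.D"` naming
#'   class/channel photon rates to optimize; default all classes/channels
#'   of `emissions_init`.
#' @param rebin_to analysis bin width (s); `NULL` keeps the trace binning.
#' @param maxit,reltol optimizer control.
#' @return A `photonhmm_fit` object; see [tidy.photonhmm_fit()].
#' @export
fit_trace <- function(trace, type, rates_init, emissions_init,
                      free_rates = default_free_rates(type),
                      free_emissions = NULL,
                      rebin_to = 0.02, maxit = 2000, reltol = 1e-10) {
  if (!is.null(rebin_to)) trace <- rebin_trace(trace, rebin_to)
  if (is.null(free_emissions))
    free_emissions <- as.vector(outer(emissions_init$class, c("D", "A"),
                                      paste, sep = "."))
  mlh_fit(list(trace), type, rates_init, emissions_init, free_rates,
          free_emissions, maxit = maxit, reltol = reltol)
}

#' Global maximum-likelihood fit across traces
#'
#' Maximizes the summed log-likelihood \eqn{\sum_m \ln L_m} over rate
#' coefficients shared by all traces, with per-trace photon rates held
#' fixed (as estimated beforehand by [fit_trace()] at 20 ms). The default
#' analysis bin width is the traces' own (typically 1 ms, fine enough not
#' to average over fast events).
#'
#' @param traces list of [photon_trace()] at a common bin width.
#' @param type model type (see [fit_trace()]).
#' @param rates_init initial/fixed [rate_spec()].
#' @param emissions one [emission_rates()] shared by all traces, or a list
#'   with one element per trace.
#' @param free_rates names of the shared rate coefficients to optimize.
#' @param free_emissions optional `"class.channel"` names of photon rates
#'   shared across traces to optimize (e.g. the dark-state rates).
#' @param maxit,reltol optimizer control.
#' @return A `photonhmm_fit`.
#' @export
fit_global <- function(traces, type, rates_init, emissions,
                       free_rates = default_free_rates(type),
                       free_emissions = character(0),
                       maxit = 2000, reltol = 1e-10) {
  if (inherits(traces, "photon_trace")) traces <- list(traces)
  deltas <- vapply(traces, attr, 0, "delta")
  if (diff(range(deltas)) > 1e-12)
    stop("all traces must share one bin width", call. = FALSE)
  mlh_fit(traces, type, rates_init, emissions, free_rates,
          free_emissions, maxit = maxit, reltol = reltol)
}

#' Bootstrap standard errors for a global fit
#'
#' Resamples traces with replacement `n_boot` times (default ten trials),
#' refits the global model on each resample starting from the full-data
#' optimum, and reports the per-parameter standard deviation. Failed
#' resample fits are dropped with a warning when they exceed 20%.
#'
#' @param traces list of [photon_trace()].
#' @param fit a `photonhmm_fit` from [fit_global()] on the same traces.
#' @param n_boot number of bootstrap trials (>= 2).
#' @param seed integer seed for the resampling.
#' @return The input `fit` with `bootstrap_sd` filled in (named vector) and
#'   an attribute `boot_estimates` (matrix of per-trial estimates).
#' @export
bootstrap_errors <- function(traces, fit, n_boot = 10, seed = 1L) {
  stopifnot(inherits(fit, "photonhmm_fit"), n_boot >= 2)
  set.seed(seed)
  emis <- fit$emissions
  per_trace_emis <- !inherits(emis, "emission_rates")
  est <- matrix(NA_real_, n_boot, length(fit$free_rates),
                dimnames = list(NULL, fit$free_rates))
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(traces), replace = TRUE)
    e_b <- if (per_trace_emis) emis[idx] else emis
    f <- tryCatch(
      fit_global(traces[idx], fit$model_type,
                 do.call(rate_spec, Filter(Negate(is.null), fit$rates)),
                 e_b, free_rates = fit$free_rates),
      error = function(e) NULL)
    if (is.null(f) || !is.finite(f$log_likelihood)) {
      n_fail <- n_fail + 1L
    } else {
      est[b, ] <- unlist(f$estimates[fit$free_rates])
    }
  }
  if (n_fail > 0.2 * n_boot)
    warning(n_fail, " of ", n_boot, " bootstrap fits failed")
  fit$bootstrap_sd <- apply(est, 2, stats::sd, na.rm = TRUE)
  attr(fit, "boot_estimates") <- est
  fit
}

#' Serialize a fit result as JSON
#'
#' @param fit a `photonhmm_fit`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(model_type = fit$model_type,
              estimates = fit$estimates,
              units = "rates: s^-1; photon rates: counts s^-1",
              bootstrap_sd = as.list(fit$bootstrap_sd),
              log_likelihood = fit$log_likelihood,
              converged = fit$converged,
              n_traces = fit$n_traces, n_bins = fit$n_bins,
              delta = fit$delta, free_rates = fit$free_rates)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
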