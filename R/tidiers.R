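#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a maximum-likelihood fit
#'
#' @param x a `photonhmm_fit`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error` (bootstrap
#'   SD when available) and `unit`.
#' @method tidy photonhmm_fit
#' @export
tidy.photonhmm_fit <- function(x, ...) {
  terms <- names(x$estimates)
  unit <- ifelse(grepl("\\.", terms), "counts/s", "1/s")
  se <- rep(NA_real_, length(terms))
  if (!is.null(x$bootstrap_sd)) {
    idx <- match(names(x$bootstrap_sd), terms)
    se[idx[!is.na(idx)]] <- x$bootstrap_sd[!is.na(idx)]
  }
  tibble::tibble(term = terms, estimate = unlist(x$estimates),
                 std.error = se, unit = unit)
}

#' @rdname tidy.photonhmm_fit
#' @method glance photonhmm_fit
#' @export
glance.photonhmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, n_traces = x$n_traces,
                 n_bins = x$n_bins, converged = x$converged,
                 model_type = x$model_type, delta = x$delta)
}

#' Tidy a dwell-time exponential fit
#'
#' @param x an `exp_fit`.
#' @param ... unused.
#' @return One row per component: `component`, `rate`, `amplitude`,
#'   `mean_dwell`.
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$rates), rate = x$rates,
                 amplitude = x$amplitudes, mean_dwell = 1 / x$rates)
}

#' @rdname tidy.exp_fit
#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, logLik = x$log_likelihood,
                 n = x$n, truncation_bound = x$truncation_bound,
                 collapsed = x$collapsed)
}

#' Tidy an FCS fit
#'
#' @param x an `fcs_fit`.
#' @param ... unused.
#' @return A tibble with `term`, `estimate`, `fixed`.
#' @method tidy fcs_fit
#' @export
tidy.fcs_fit <- function(x, ...) {
  terms <- c("N_mean", "tau_D", "s", "c_T", "tau_T")
  tibble::tibble(term = terms,
                 estimate = unlist(x$params[terms]),
                 fixed = terms %in% names(x$fixed))
}

#' @rdname tidy.fcs_fit
#' @method glance fcs_fit
#' @export
glance.fcs_fit <- function(x, ...) {
  tibble::tibble(rss = sum(x$residuals^2), n = length(x$residuals),
                 converged = x$converged)
}

#' Plot a photon trace
#'
#' Donor and acceptor counts per bin as step lines (donor up, acceptor
#' mirrored down, the usual two-channel display).
#'
#' @param object a [photon_trace()].
#' @param max_time show only the first `max_time` seconds (default 10).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot photon_trace
#' @export
autoplot.photon_trace <- function(object, max_time = 10, ...) {
  delta <- attr(object, "delta")
  df <- tibble::tibble(time = (object$bin - 0.5) * delta,
                       donor = object$donor,
                       acceptor = -object$acceptor)
  df <- df[df$time <= max_time, ]
  long <- tidyr::pivot_longer(df, c("donor", "acceptor"),
                              names_to = "channel", values_to = "counts")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$counts,
                                     colour = .data$channel)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(donor = "#2e8b57",
                                            acceptor = "#c23b22")) +
    ggplot2::labs(x = "time (s)", y = "photon counts per bin",
                  title = attr(object, "trace_id")) +
    ggplot2::theme_minimal()
}

#' Plot a photon-count-ratio histogram
#'
#' @param object a [count_ratio_histogram()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot count_ratio_histogram
#' @export
autoplot.count_ratio_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = object$bin_right[1] - object$bin_left[1],
                      fill = "grey40") +
    ggplot2::labs(x = "acceptor / total photon-count ratio", y = "bins") +
    ggplot2::theme_minimal()
}

#' Plot a 2D dwell map
#'
#' Mean bound versus mean unbound dwell time per 4-s segment on log axes;
#' coexisting kinetic regimes appear as separate clusters.
#'
#' @param object result of [segment_dwell_map()] (optionally clustered).
#' @param bins hexbin resolution.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dwell_map
#' @export
autoplot.dwell_map <- function(object, bins = 40, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$mean_off, .data$mean_on))
  p <- if (!is.null(object$cluster))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster),
                            alpha = 0.5, size = 0.8)
  else p + ggplot2::geom_bin2d(bins = bins)
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean unbound dwell (s)",
                  y = "mean bound dwell (s)") +
    ggplot2::theme_minimal()
}

#' Plot an FCS fit
#'
#' @param object an `fcs_fit`.
#' @param ... unused.
#' @return A ggplot object (curve, fit and residuals).
#' @method autoplot fcs_fit
#' @export
autoplot.fcs_fit <- function(object, ...) {
  df <- tibble::tibble(lag = object$lags, G = object$G,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$G)) +
    ggplot2::geom_point(size = 0.6, colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#c23b22") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"),
                  y = expression(G(tau))) +
    ggplot2::theme_minimal()
}

#' Plot the dwell-time distribution with its exponential fit(s)
#'
#' @param object an `exp_fit`.
#' @param dwells the dwell durations the fit was computed from.
#' @param ... unused.
#' @return A ggplot object: log-spaced dwell histogram with the fitted
#'   (truncated) density overlaid.
#' @export
plot_dwell_fit <- function(object, dwells, ...) {
  x <- dwells[dwells >= object$truncation_bound]
  edges <- 10^seq(log10(min(x)), log10(max(x) * 1.001), length.out = 30)
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  dens <- function(t) {
    den <- sum(object$amplitudes * exp(-object$rates *
                                         object$truncation_bound))
    rowSums(vapply(seq_along(object$rates), function(i)
      object$amplitudes[i] * object$rates[i] * exp(-object$rates[i] * t),
      numeric(length(t)))) / den
  }
  df <- tibble::tibble(mid = h$mids, density = h$density)
  fitdf <- tibble::tibble(t = 10^seq(log10(min(x)), log10(max(x)),
                                     length.out = 200))
  fitdf$density <- dens(fitdf$t)
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_col(fill = "grey60", width = diff(edges)[1]) +
    ggplot2::geom_line(data = fitdf, ggplot2::aes(.data$t, .data$density),
                       colour = "#c23b22") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (s)", y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
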