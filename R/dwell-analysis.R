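#' Truncated single- or double-exponential fit of dwell times
#'
#' Maximum-likelihood fit of dwell-time durations with a left-truncated
#' exponential (`n_components = 1`) or a left-truncated mixture of two
#' exponentials (`n_components = 2`). The truncation bound reflects the
#' shortest dwell the decoder identifies reliably (12 ms by default
#' elsewhere in the package); dwells below it are excluded from the
#' likelihood rather than silently dropped from the data. For the
#' single-component model the MLE is closed form (shifted mean); the
#' mixture is fitted by Nelder-Mead on (log rate1, log rate2, logit
#' amplitude). Rates are reported sorted descending (fast first); a mixture
#' whose two rates collapse (within 1%) is flagged and the
#' single-component result returned.
#'
#' @param dwells numeric dwell durations (s).
#' @param n_components 1 or 2.
#' @param truncation_bound left-truncation bound (s); durations below it
#'   are discarded before fitting.
#' @return An `exp_fit` list: `n_components`, `rates` (s^-1, descending),
#'   `amplitudes` (sum 1), `log_likelihood`, `n`, `truncation_bound`,
#'   `collapsed`.
#' @export
fit_dwell_exponentials <- function(dwells, n_components = 1,
                                   truncation_bound = 0) {
  stopifnot(n_components %in% c(1, 2), truncation_bound >= 0)
  x <- dwells[dwells >= truncation_bound & is.finite(dwells)]
  if (length(x) < 10)
    stop("need at least 10 dwells above the truncation bound", call. = FALSE)
  t0 <- truncation_bound
  # single exponential: memorylessness shifts the MLE to 1/(mean - t0)
  r1 <- 1 / (mean(x) - t0)
  ll1 <- sum(log(r1) - r1 * (x - t0))
  single <- structure(list(n_components = 1L, rates = r1, amplitudes = 1,
                           log_likelihood = ll1, n = length(x),
                           truncation_bound = t0, collapsed = FALSE),
                      class = "exp_fit")
  if (n_components == 1) return(single)

  nll <- function(th) {
    ra <- exp(th[1]); rb <- exp(th[2]); a <- stats::plogis(th[3])
    if (!all(is.finite(c(ra, rb, a)))) return(1e300)
    num <- a * ra * exp(-ra * x) + (1 - a) * rb * exp(-rb * x)
    den <- a * exp(-ra * t0) + (1 - a) * exp(-rb * t0)
    if (any(num <= 0) || den <= 0) return(1e300)
    -sum(log(num)) + length(x) * log(den)
  }
  # start from a split around the single-rate estimate
  th0 <- c(log(r1 * 3), log(r1 / 3), 0)
  opt <- stats::optim(th0, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  ra <- exp(opt$par[1]); rb <- exp(opt$par[2]); a <- stats::plogis(opt$par[3])
  rates <- c(ra, rb); amps <- c(a, 1 - a)
  ord <- order(rates, decreasing = TRUE)
  rates <- rates[ord]; amps <- amps[ord]
  collapsed <- abs(diff(log(rates))) < 0.01 || min(amps) < 1e-4
  if (collapsed) {
    single$collapsed <- TRUE
    return(single)
  }
  structure(list(n_components = 2L, rates = rates, amplitudes = amps,
                 log_likelihood = -opt$value, n = length(x),
                 truncation_bound = t0, collapsed = FALSE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %d component(s), n = %d, truncation %.3g s%s\n",
              x$n_components, x$n, x$truncation_bound,
              if (x$collapsed) " (mixture collapsed)" else ""))
  for (i in seq_along(x$rates))
    cat(sprintf("  rate %.4g s^-1 (amplitude %.3f)\n", x$rates[i],
                x$amplitudes[i]))
  invisible(x)
}

# log-spaced histogram of dwells with bins merged up to a minimum expected
# count; returns observed counts and model-expected counts
dwell_histogram_chi2 <- function(x, fit, bins_per_decade = 15,
                                 min_expected = 5) {
  t0 <- fit$truncation_bound
  lo <- max(t0, min(x)); hi <- max(x) * 1.0001
  edges <- 10^seq(log10(lo), log10(hi),
                  length.out = max(4, ceiling(log10(hi / lo) *
                                                bins_per_decade) + 1))
  edges[1] <- lo; edges[length(edges)] <- hi
  obs <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  cdf <- function(t) {
    # truncated mixture CDF above t0
    num <- sum(fit$amplitudes * exp(-fit$rates * pmax(t, t0)))
    den <- sum(fit$amplitudes * exp(-fit$rates * t0))
    1 - num / den
  }
  expd <- length(x) * diff(vapply(edges, cdf, 0))
  # merge bins rightward until each has min_expected expected counts
  O <- integer(0); E <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expd[i]
    if (ce >= min_expected) {
      O <- c(O, co); E <- c(E, ce); co <- 0; ce <- 0
    }
  }
  if (ce > 0 && length(E)) {
    O[length(O)] <- O[length(O)] + co
    E[length(E)] <- E[length(E)] + ce
  }
  list(observed = O, expected = E)
}

chi2_of <- function(x, fit, bins_per_decade = 15) {
  h <- dwell_histogram_chi2(x, fit, bins_per_decade)
  sum((h$observed - h$expected)^2 / h$expected)
}

#' Chi-squared ratio diagnostic for bi-exponential dwell kinetics
#'
#' Fits the dwell distribution with one and with two truncated exponential
#' components, computes Poisson-weighted chi-squared values on a log-spaced
#' dwell histogram, and reports the normalized ratio
#' chi2(single)/chi2(double). The raw ratio is normalized by its null
#' expectation, estimated from parametric-bootstrap replicates drawn from
#' the best single-exponential fit, so that values near 1 indicate
#' single-exponential kinetics and substantially larger values flag a
#' second kinetic component.
#'
#' @param dwells numeric dwell durations (s).
#' @param truncation_bound left-truncation bound (s).
#' @param bins_per_decade histogram resolution for the chi-squared.
#' @param n_null parametric-bootstrap replicates for the normalization
#'   (set 0 to skip normalization).
#' @param seed seed for the bootstrap replicates.
#' @return A list: `ratio` (normalized), `raw_ratio`, `null_mean`,
#'   `chi2_single`, `chi2_double`, `fit_single`, `fit_double`.
#' @export
chi2_ratio <- function(dwells, truncation_bound = 0, bins_per_decade = 15,
                       n_null = 20, seed = 1L) {
  f1 <- fit_dwell_exponentials(dwells, 1, truncation_bound)
  f2 <- fit_dwell_exponentials(dwells, 2, truncation_bound)
  x <- dwells[dwells >= truncation_bound]
  c1 <- chi2_of(x, f1, bins_per_decade)
  c2 <- chi2_of(x, if (f2$collapsed) f1 else f2, bins_per_decade)
  raw <- c1 / c2
  null_mean <- 1
  if (n_null > 0) {
    set.seed(seed)
    null_ratios <- vapply(seq_len(n_null), function(b) {
      xb <- truncation_bound + stats::rexp(length(x), f1$rates[1])
      g1 <- fit_dwell_exponentials(xb, 1, truncation_bound)
      g2 <- tryCatch(fit_dwell_exponentials(xb, 2, truncation_bound),
                     error = function(e) g1)
      chi2_of(xb, g1, bins_per_decade) /
        chi2_of(xb, if (g2$collapsed) g1 else g2, bins_per_decade)
    }, 0)
    null_mean <- mean(null_ratios)
  }
  list(ratio = raw / null_mean, raw_ratio = raw, null_mean = null_mean,
       chi2_single = c1, chi2_double = c2, fit_single = f1, fit_double = f2)
}

#' Photon-count-ratio histogram of a trace
#'
#' For every time bin of width `bin_width` (the trace is rebinned when
#' needed) the ratio of acceptor counts over total counts,
#' \eqn{N_A / (N_A + N_D)}, is computed; empty time bins are skipped. The
#' ratio is an uncorrected proxy for the FRET efficiency, so a trace
#' visiting unbound (low ratio) and bound (high ratio) states gives a
#' bimodal histogram.
#'
#' @param trace a [photon_trace()].
#' @param bin_width time-bin width for the ratios (s); default 20 ms.
#' @param breaks number of histogram bins over the ratio support of 0 to 1.
#' @return A `count_ratio_histogram` tibble with columns `bin_left`,
#'   `bin_right`, `count`; attributes `ratios` (the per-bin values),
#'   `bin_width` and `n_empty`.
#' @export
count_ratio_histogram <- function(trace, bin_width = 0.02, breaks = 50) {
  tr <- rebin_trace(trace, bin_width)
  tot <- tr$donor + tr$acceptor
  keep <- tot > 0
  ratios <- tr$acceptor[keep] / tot[keep]
  edges <- seq(0, 1, length.out = breaks + 1)
  h <- graphics::hist(ratios, breaks = edges, plot = FALSE,
                      include.lowest = TRUE)
  out <- tibble::tibble(bin_left = edges[-length(edges)],
                        bin_right = edges[-1], count = h$counts)
  attr(out, "ratios") <- ratios
  attr(out, "bin_width") <- bin_width
  attr(out, "n_empty") <- sum(!keep)
  class(out) <- c("count_ratio_histogram", class(out))
  out
}

#' Write a histogram as TSV
#'
#' @param hist a tibble with `bin_left`, `bin_right`, `count`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_histogram_tsv <- function(hist, file) {
  utils::write.table(
    data.frame(bin_left = hist$bin_left, bin_right = hist$bin_right,
               count = hist$count),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
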