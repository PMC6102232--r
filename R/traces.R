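#' Per-class photon detection rates
#'
#' Mean donor/acceptor photon detection rates for each emission class of a
#' kinetic model. States sharing an emission class share rates (the two
#' bound states of the isomerization schemes have identical photon rates).
#' Channel backgrounds are additive rates applied to every state.
#'
#' @param class character vector of emission-class labels.
#' @param rate_D,rate_A donor/acceptor detection rates (counts/s), >= 0.
#' @param background_D,background_A additive channel backgrounds (counts/s).
#' @return An `emission_rates` object (a tibble with attributes).
#' @examples
#' emission_rates(c("unbound", "bound", "dark"),
#'                rate_D = c(2000, 500, 80), rate_A = c(100, 1200, 80))
#' @export
emission_rates <- function(class, rate_D, rate_A,
                           background_D = 0, background_A = 0) {
  stopifnot(length(class) == length(rate_D),
            length(class) == length(rate_A),
            all(rate_D >= 0), all(rate_A >= 0),
            background_D >= 0, background_A >= 0)
  out <- tibble::tibble(class = as.character(class),
                        rate_D = as.numeric(rate_D),
                        rate_A = as.numeric(rate_A))
  attr(out, "background_D") <- background_D
  attr(out, "background_A") <- background_A
  class(out) <- c("emission_rates", class(out))
  out
}

#' Default experiment-like emission rates
#'
#' Donor-only unbound state, FRET-shifted bound state with a lower total
#' rate (the acceptor dye has the lower quantum yield), and a near-dark
#' blink state; roughly 40 counts per 20-ms bin, giving two well-separated
#' photon-count-ratio populations.
#'
#' @return An `emission_rates` object covering classes unbound/bound/dark.
#' @export
default_emission_rates <- function() {
  emission_rates(c("unbound", "bound", "dark"),
                 rate_D = c(2000, 500, 80),
                 rate_A = c(100, 1200, 80))
}

# per-state expected counts per bin (rate + background) * delta
state_bin_means <- function(model, emissions, delta) {
  cls <- model$emission_class[model$states]
  idx <- match(cls, emissions$class)
  if (anyNA(idx))
    stop("emission_rates is missing class(es): ",
         paste(setdiff(cls, emissions$class), collapse = ", "), call. = FALSE)
  bd <- attr(emissions, "background_D") %||% 0
  ba <- attr(emissions, "background_A") %||% 0
  list(mu_d = (emissions$rate_D[idx] + bd) * delta,
       mu_a = (emissions$rate_A[idx] + ba) * delta)
}

#' Construct a two-channel binned photon trace
#'
#' The unit of all inference: donor and acceptor photon counts per time bin
#' of width `delta`, as a tibble with columns `bin`, `donor`, `acceptor` and
#' attributes `delta`, `trace_id`, `meta`.
#'
#' @param donor,acceptor non-negative integer counts per bin (equal length).
#' @param delta bin width (s), > 0.
#' @param trace_id identifier string.
#' @param meta optional list of metadata (seed, generating parameters, ...).
#' @return A `photon_trace` tibble.
#' @export
photon_trace <- function(donor, acceptor, delta, trace_id = "trace",
                         meta = list()) {
  stopifnot(length(donor) == length(acceptor), delta > 0,
            all(donor >= 0), all(acceptor >= 0))
  if (any(donor != round(donor)) || any(acceptor != round(acceptor)))
    stop("photon counts must be integers", call. = FALSE)
  out <- tibble::tibble(bin = seq_along(donor),
                        donor = as.integer(donor),
                        acceptor = as.integer(acceptor))
  attr(out, "delta") <- delta
  attr(out, "trace_id") <- trace_id
  attr(out, "meta") <- meta
  class(out) <- c("photon_trace", class(out))
  out
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("<photon_trace> %s: %d bins of %.4g s (%.3g s total)\n",
              attr(x, "trace_id"), nrow(x), attr(x, "delta"),
              nrow(x) * attr(x, "delta")))
  NextMethod()
}

#' Rebin a photon trace to a coarser bin width
#'
#' Sums counts over consecutive groups of bins. The new width must be an
#' integer multiple of the current one; a trailing partial group is dropped.
#'
#' @param trace a [photon_trace()].
#' @param new_delta target bin width (s).
#' @return A `photon_trace` at the new bin width.
#' @export
rebin_trace <- function(trace, new_delta) {
  delta <- attr(trace, "delta")
  k <- new_delta / delta
  if (abs(k - round(k)) > 1e-9 * k)
    stop("new_delta must be an integer multiple of the trace bin width",
         call. = FALSE)
  k <- as.integer(round(k))
  if (k == 1L) return(trace)
  n <- (nrow(trace) %/% k) * k
  if (n == 0L) stop("trace shorter than one new bin", call. = FALSE)
  grp <- rep(seq_len(n %/% k), each = k)
  photon_trace(
    donor = as.integer(rowsum(trace$donor[seq_len(n)], grp)),
    acceptor = as.integer(rowsum(trace$acceptor[seq_len(n)], grp)),
    delta = delta * k,
    trace_id = attr(trace, "trace_id"),
    meta = attr(trace, "meta"))
}

#' Write / read a photon trace as TSV
#'
#' Plain-text interchange format: comment header lines `#delta`, `#trace_id`
#' and `#seed` (when present in the metadata), then tab-separated columns
#' `bin_index`, `donor_counts`, `acceptor_counts`.
#'
#' @param trace a [photon_trace()].
#' @param path file path.
#' @return `write_trace_tsv()` returns `path` invisibly; `read_trace_tsv()`
#'   returns a `photon_trace`.
#' @export
write_trace_tsv <- function(trace, path) {
  hdr <- c(sprintf("#delta\t%.12g", attr(trace, "delta")),
           sprintf("#trace_id\t%s", attr(trace, "trace_id")))
  seed <- attr(trace, "meta")$seed
  if (!is.null(seed)) hdr <- c(hdr, sprintf("#seed\t%d", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("bin_index\tdonor_counts\tacceptor_counts", con)
  utils::write.table(
    data.frame(trace$bin, trace$donor, trace$acceptor), con,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "\t")
  meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  m <- list()
  if (!is.null(meta$seed)) m$seed <- as.integer(meta$seed)
  photon_trace(tab$donor_counts, tab$acceptor_counts,
               delta = as.numeric(meta$delta),
               trace_id = meta$trace_id %||% "trace", meta = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
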