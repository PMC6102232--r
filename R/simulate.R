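#' Simulate an exact continuous-time Markov state path
#'
#' Exact stochastic simulation of the jump process defined by a generator
#' matrix: holding times are exponential with rate \eqn{-K_{ii}}, jumps go
#' to state j with probability \eqn{K_{ji}/(-K_{ii})}. An absorbing state
#' (zero exit rate) yields a single segment covering the remaining duration.
#'
#' @param model a `kinetic_model`.
#' @param duration total simulated time (s), > 0.
#' @param start starting state label, or `NULL` to draw from the stationary
#'   distribution.
#' @return A `ground_truth_path`: a tibble with columns `t_start`, `t_end`,
#'   `state` (one row per constant-state segment) and attribute `duration`.
#' @export
simulate_state_path <- function(model, duration, start = NULL) {
  stopifnot(inherits(model, "kinetic_model"), duration > 0)
  K <- model$K; states <- model$states; S <- length(states)
  exit <- -diag(K)
  if (is.null(start)) {
    p0 <- equilibrium_distribution(model)$p_eq
    cur <- sample.int(S, 1L, prob = p0)
  } else {
    cur <- match(start, states)
    if (is.na(cur)) stop("unknown start state", call. = FALSE)
  }
  cap <- 256L
  t_start <- numeric(cap); t_end <- numeric(cap); st <- integer(cap)
  n <- 0L
  t <- 0
  while (t < duration) {
    if (n == cap) {  # grow geometrically
      cap <- cap * 2L
      length(t_start) <- cap; length(t_end) <- cap; length(st) <- cap
    }
    n <- n + 1L
    if (exit[cur] <= 0) {
      t_start[n] <- t; t_end[n] <- duration; st[n] <- cur
      break
    }
    dt <- stats::rexp(1L, exit[cur])
    t2 <- min(t + dt, duration)
    t_start[n] <- t; t_end[n] <- t2; st[n] <- cur
    if (t + dt >= duration) break
    p <- K[, cur]; p[cur] <- 0
    cur <- sample.int(S, 1L, prob = p)
    t <- t2
  }
  out <- tibble::tibble(t_start = t_start[seq_len(n)],
                        t_end = t_end[seq_len(n)],
                        state = states[st[seq_len(n)]])
  attr(out, "duration") <- duration
  attr(out, "states") <- states
  class(out) <- c("ground_truth_path", class(out))
  out
}

# fractional occupancy of each state within each bin (T x S matrix)
bin_occupancy <- function(path, states, delta, n_bins) {
  S <- length(states)
  occ <- matrix(0, n_bins, S)
  si <- match(path$state, states)
  for (seg in seq_len(nrow(path))) {
    a <- path$t_start[seg]; b <- min(path$t_end[seg], n_bins * delta)
    if (b <= a) next
    b0 <- floor(a / delta); b1 <- min(ceiling(b / delta) - 1, n_bins - 1)
    bi <- b0:b1
    frac <- (pmin(b, (bi + 1) * delta) - pmax(a, bi * delta)) / delta
    idx <- bi + 1L + (si[seg] - 1L) * n_bins
    occ[idx] <- occ[idx] + pmax(frac, 0)
  }
  occ
}

#' Emit binned photon counts along a state path
#'
#' For each time bin the donor and acceptor counts are Poisson with mean
#' equal to the time-weighted average of the per-state photon rates over the
#' bin (bins straddling a transition mix the adjacent states' rates), plus
#' the channel background, times the bin width.
#'
#' @param path a `ground_truth_path` from [simulate_state_path()].
#' @param model the `kinetic_model` that generated the path (for the
#'   state -> emission-class mapping).
#' @param emissions an [emission_rates()] object.
#' @param delta bin width (s).
#' @param trace_id identifier for the resulting trace.
#' @return A [photon_trace()] covering `floor(duration / delta)` bins.
#' @export
emit_photons <- function(path, model, emissions, delta,
                         trace_id = "trace") {
  duration <- attr(path, "duration")
  n_bins <- floor(duration / delta + 1e-9)
  if (n_bins < 1) stop("path covers less than one bin", call. = FALSE)
  mus <- state_bin_means(model, emissions, delta)
  occ <- bin_occupancy(path, model$states, delta, n_bins)
  mu_d <- as.numeric(occ %*% mus$mu_d)
  mu_a <- as.numeric(occ %*% mus$mu_a)
  photon_trace(stats::rpois(n_bins, mu_d), stats::rpois(n_bins, mu_a),
               delta = delta, trace_id = trace_id)
}

#' Simulate a dataset of photon traces with exact ground truth
#'
#' Generates `n_traces` independent traces. Trace durations are exponential
#' with mean `mean_duration` (donor photobleaching truncates each trace;
#' default mean ~1 min as in typical surface experiments), floored at one
#' bin width. A single root seed spawns one sub-seed per trace, recorded in
#' the manifest, so the dataset is reproducible trace by trace.
#'
#' @param model a `kinetic_model`.
#' @param emissions an [emission_rates()].
#' @param n_traces number of traces (>= 1).
#' @param mean_duration mean trace duration before photobleaching (s).
#' @param delta bin width of the generated traces (s); default 1 ms.
#' @param seed integer root seed.
#' @param fixed_duration when `TRUE` every trace lasts exactly
#'   `mean_duration` instead of an exponential draw.
#' @return A list with elements `traces` (list of [photon_trace()]),
#'   `truths` (list of ground-truth paths) and `manifest` (a tibble with
#'   trace ids, seeds and durations; the generating configuration is in its
#'   attributes).
#' @export
simulate_dataset <- function(model, emissions, n_traces, mean_duration = 60,
                             delta = 0.001, seed = 1L,
                             fixed_duration = FALSE) {
  stopifnot(n_traces >= 1, mean_duration > 0, delta > 0)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_traces)
  traces <- vector("list", n_traces)
  truths <- vector("list", n_traces)
  ids <- sprintf("trace%03d", seq_len(n_traces))
  durations <- numeric(n_traces)
  for (i in seq_len(n_traces)) {
    set.seed(sub_seeds[i])
    dur <- if (fixed_duration) mean_duration else
      stats::rexp(1L, 1 / mean_duration)
    dur <- max(dur, delta)
    path <- simulate_state_path(model, dur)
    tr <- emit_photons(path, model, emissions, delta, trace_id = ids[i])
    attr(tr, "meta") <- list(seed = sub_seeds[i])
    truths[[i]] <- path
    traces[[i]] <- tr
    durations[i] <- nrow(tr) * delta
  }
  empty <- vapply(traces, nrow, 0L) == 0L
  if (any(empty)) warning(sum(empty), " empty trace(s) dropped")
  manifest <- tibble::tibble(trace_id = ids, seed = sub_seeds,
                             duration = durations,
                             n_bins = vapply(traces, nrow, 0L))
  attr(manifest, "config") <- list(seed = seed, n_traces = n_traces,
                                   mean_duration = mean_duration,
                                   delta = delta,
                                   rates = Filter(Negate(is.null),
                                                  unclass(model$rates)),
                                   emissions = as.data.frame(emissions))
  list(traces = traces[!empty], truths = truths[!empty],
       manifest = manifest[!empty, ])
}

#' Write / read a simulated dataset on disk
#'
#' Each trace is a TSV (see [write_trace_tsv()]); each ground truth a TSV
#' sidecar with columns `t_start`, `t_end`, `state_label`; a JSON manifest
#' lists the files, the seed, and an echo of the generating configuration.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `write_dataset()`: the manifest path, invisibly.
#'   `read_dataset()`: a list with `traces` and `manifest` (ground truths
#'   are reloaded when present).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  trace_files <- paste0(man$trace_id, ".tsv")
  truth_files <- paste0(man$trace_id, "_truth.tsv")
  for (i in seq_len(nrow(man))) {
    write_trace_tsv(dataset$traces[[i]], file.path(dir, trace_files[i]))
    tt <- dataset$truths[[i]]
    utils::write.table(
      data.frame(t_start = tt$t_start, t_end = tt$t_end,
                 state_label = tt$state),
      file.path(dir, truth_files[i]),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  obj <- list(config = attr(man, "config"),
              traces = data.frame(trace_id = man$trace_id, file = trace_files,
                                  truth_file = truth_files, seed = man$seed,
                                  duration = man$duration))
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  traces <- lapply(file.path(dir, man$traces$file), read_trace_tsv)
  truths <- lapply(seq_len(nrow(man$traces)), function(i) {
    f <- file.path(dir, man$traces$truth_file[i])
    if (!file.exists(f)) return(NULL)
    tab <- utils::read.table(f, header = TRUE, sep = "\t")
    out <- tibble::tibble(t_start = tab$t_start, t_end = tab$t_end,
                          state = tab$state_label)
    attr(out, "duration") <- max(tab$t_end)
    class(out) <- c("ground_truth_path", class(out))
    out
  })
  list(traces = traces, truths = truths, manifest = man)
}
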