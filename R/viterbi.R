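#' Most likely state trajectory of a photon trace
#'
#' Viterbi decoding of the binned-photon hidden Markov model: transition
#' probabilities are \eqn{e^{\Delta K}}, emissions are per-bin Poisson
#' factors in both channels, and the chain starts from the stationary
#' distribution. Ties in the backtrack resolve to the lowest state index,
#' so decodes are reproducible. Traces are typically decoded at 1-ms bins
#' to avoid averaging over fast events, with a model that includes the dark
#' state so that blink events are not misread as binding.
#'
#' @inheritParams trace_log_likelihood
#' @return A `state_path` tibble with columns `bin`, `state` (model state
#'   label) and `class` (emission class, i.e. unbound/bound/dark);
#'   attributes `delta` and `trace_id`.
#' @export
viterbi_path <- function(trace, model, emissions, p0 = NULL) {
  stopifnot(inherits(trace, "photon_trace"),
            inherits(model, "kinetic_model"))
  delta <- attr(trace, "delta")
  mus <- state_bin_means(model, emissions, delta)
  spread_d <- diff(range(mus$mu_d)); spread_a <- diff(range(mus$mu_a))
  flagged <- (spread_d + spread_a) < 1e-12
  if (flagged)
    warning("all states share identical emission rates; decode is ",
            "uninformative")
  P <- propagator(model, delta)
  if (is.null(p0)) p0 <- equilibrium_distribution(model)$p_eq
  idx <- viterbi_cpp(trace$donor, trace$acceptor, P, mus$mu_d, mus$mu_a,
                     unname(p0))
  out <- tibble::tibble(bin = trace$bin,
                        state = model$states[idx],
                        class = unname(model$emission_class[idx]))
  attr(out, "delta") <- delta
  attr(out, "trace_id") <- attr(trace, "trace_id")
  attr(out, "states") <- model$states
  attr(out, "uninformative") <- flagged
  class(out) <- c("state_path", class(out))
  out
}

fold_dark <- function(class) ifelse(class == "dark", "unbound", class)

#' Dwell times from a decoded state path
#'
#' Converts contiguous runs of the bound/unbound class labels into dwell
#' durations. Dark (blink) intervals are folded into the unbound class:
#' blinking is a photophysical artifact of the fluorophore, not a binding
#' event. The first and last dwell of a trace are truncated by the
#' observation window and flagged so they can be excluded from dwell-time
#' fits.
#'
#' @param path a `state_path` from [viterbi_path()], or any tibble with a
#'   `class` column on a regular bin grid.
#' @param delta bin width (s); default taken from the path attributes.
#' @return A `dwell_set` tibble with columns `class` (`"bound"` or
#'   `"unbound"`), `t_start`, `duration` (s) and `truncated`.
#' @export
extract_dwells <- function(path, delta = attr(path, "delta")) {
  stopifnot(!is.null(delta))
  cls <- fold_dark(path$class)
  r <- rle(cls)
  n <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- tibble::tibble(
    class = r$values,
    t_start = starts * delta,
    duration = r$lengths * delta,
    truncated = seq_len(n) %in% c(1L, n))
  attr(out, "delta") <- delta
  attr(out, "trace_id") <- attr(path, "trace_id")
  class(out) <- c("dwell_set", class(out))
  out
}

# class-level dwells of a ground-truth path (exact transition times)
truth_dwells <- function(truth, model) {
  cls <- fold_dark(unname(model$emission_class[truth$state]))
  keep <- c(TRUE, cls[-1] != cls[-length(cls)])
  t0 <- truth$t_start[keep]
  cls <- cls[keep]
  t1 <- c(t0[-1], max(truth$t_end))
  tibble::tibble(class = cls, t_start = t0, duration = t1 - t0,
                 truncated = seq_along(t0) %in% c(1L, length(t0)))
}

# binding/unbinding transition times and directions from class dwells
class_transitions <- function(dwells) {
  if (nrow(dwells) < 2L)
    return(tibble::tibble(time = numeric(0), direction = character(0)))
  tibble::tibble(
    time = dwells$t_start[-1],
    direction = ifelse(dwells$class[-1] == "bound", "bind", "unbind"))
}

#' Fraction of true transitions recovered by a decode
#'
#' Matching rule: a true binding/unbinding transition counts as identified
#' when the decoded path contains a class change of the same direction
#' within `window_bins` bins of its true time; each decoded transition can
#' match at most one true transition (greedy nearest-neighbour matching).
#'
#' @param truth a ground-truth path from [simulate_state_path()].
#' @param path the decoded `state_path` for the corresponding trace.
#' @param model the `kinetic_model` (for the state -> class mapping).
#' @param window_bins matching window, in decoding bins (default 10).
#' @return A one-row tibble with `n_true`, `n_matched`, `recovered`
#'   (fraction).
#' @export
transition_recovery <- function(truth, path, model, window_bins = 10) {
  delta <- attr(path, "delta")
  tt <- class_transitions(truth_dwells(truth, model))
  # keep true transitions inside the decoded window
  tt <- tt[tt$time <= nrow(path) * delta, , drop = FALSE]
  dt <- class_transitions(extract_dwells(path))
  win <- window_bins * delta
  matched <- 0L
  used <- rep(FALSE, nrow(dt))
  for (i in seq_len(nrow(tt))) {
    cand <- which(!used & dt$direction == tt$direction[i] &
                    abs(dt$time - tt$time[i]) <= win)
    if (length(cand)) {
      j <- cand[which.min(abs(dt$time[cand] - tt$time[i]))]
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  tibble::tibble(n_true = nrow(tt), n_matched = matched,
                 recovered = if (nrow(tt)) matched / nrow(tt) else NA_real_)
}

#' Per-segment mean dwell times (2D dwell map)
#'
#' Splits each trace into consecutive segments of `segment_length` seconds
#' and computes the mean bound dwell time and mean unbound dwell time per
#' segment (dwells are assigned to the segment containing their start;
#' truncated first/last dwells are excluded). Segments lacking a completed
#' dwell of either class are dropped and counted. The resulting
#' (mean tau_on, mean tau_off) table is the 2D dwell map whose clusters
#' reveal coexisting kinetic regimes; the number of clusters is a user
#' decision, not computed here.
#'
#' @param dwells a `dwell_set`, or a list of them (one per trace).
#' @param segment_length segment length (s), default 4.
#' @return A tibble with columns `trace_id`, `segment`, `mean_on`,
#'   `mean_off`, `n_on`, `n_off`; attribute `n_dropped` counts excluded
#'   segments.
#' @export
segment_dwell_map <- function(dwells, segment_length = 4) {
  stopifnot(segment_length > 0)
  if (inherits(dwells, "dwell_set")) dwells <- list(dwells)
  per_trace <- lapply(seq_along(dwells), function(i) {
    d <- dwells[[i]]
    id <- attr(d, "trace_id") %||% as.character(i)
    d <- d[!d$truncated, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d$segment <- floor(d$t_start / segment_length)
    d$trace_id <- id
    d
  })
  all <- dplyr::bind_rows(per_trace)
  if (!nrow(all))
    return(tibble::tibble(trace_id = character(0), segment = integer(0),
                          mean_on = numeric(0), mean_off = numeric(0),
                          n_on = integer(0), n_off = integer(0)))
  wide <- all |>
    dplyr::group_by(.data$trace_id, .data$segment, .data$class) |>
    dplyr::summarise(mean = mean(.data$duration), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class",
                       values_from = c("mean", "n"))
  for (col in c("mean_bound", "mean_unbound", "n_bound", "n_unbound"))
    if (is.null(wide[[col]])) wide[[col]] <- NA
  ok <- !is.na(wide$mean_bound) & !is.na(wide$mean_unbound)
  out <- tibble::tibble(trace_id = wide$trace_id, segment = wide$segment,
                        mean_on = wide$mean_bound,
                        mean_off = wide$mean_unbound,
                        n_on = wide$n_bound, n_off = wide$n_unbound)[ok, ]
  attr(out, "n_dropped") <- sum(!ok)
  attr(out, "segment_length") <- segment_length
  class(out) <- c("dwell_map", class(out))
  out
}

#' Split a trace into cis and trans segments from a four-state decode
#'
#' Maximal intervals in which the decoded path stays within the trans block
#' (unbound1/bound1/dark1) or the cis block (unbound2/bound2/dark2) are cut
#' out as sub-traces for separate two-state (plus blink) refitting. Traces
#' that never switch yield a single segment.
#'
#' @param trace the decoded [photon_trace()].
#' @param path its `state_path` under the four-state model.
#' @param min_duration segments shorter than this (s) are dropped (too few
#'   bins to constrain a refit); default 1 s.
#' @return A tibble with columns `isomer` (`"trans"`/`"cis"`), `t_start`,
#'   `t_end`, and `trace` (list column of [photon_trace()] sub-traces).
#' @export
split_cis_trans_segments <- function(trace, path, min_duration = 1) {
  delta <- attr(trace, "delta")
  block <- ifelse(grepl("1$", path$state), "trans", "cis")
  r <- rle(block)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- tibble::tibble(isomer = r$values,
                         start_bin = starts, end_bin = ends)
  segs$t_start <- (segs$start_bin - 1L) * delta
  segs$t_end <- segs$end_bin * delta
  segs <- segs[(segs$end_bin - segs$start_bin + 1L) * delta >= min_duration, ]
  segs$trace <- lapply(seq_len(nrow(segs)), function(i) {
    rows <- segs$start_bin[i]:segs$end_bin[i]
    photon_trace(trace$donor[rows], trace$acceptor[rows], delta,
                 trace_id = paste0(attr(trace, "trace_id"), "_",
                                   segs$isomer[i], "_", i))
  })
  segs[, c("isomer", "t_start", "t_end", "trace")]
}

#' Write a decoded path / dwell set as TSV
#'
#' @param path a `state_path`; `dwells` a `dwell_set`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_path_tsv <- function(path, file) {
  utils::write.table(
    data.frame(bin_index = path$bin, state_label = path$state,
               class_label = path$class),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_path_tsv
#' @param dwells a `dwell_set`.
#' @export
write_dwells_tsv <- function(dwells, file) {
  utils::write.table(
    data.frame(trace_id = attr(dwells, "trace_id") %||% "trace",
               class = dwells$class, t_start = dwells$t_start,
               duration = dwells$duration,
               truncated_flag = dwells$truncated),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
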