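#' Analysis configuration
#'
#' Bundles the tunable settings of the analysis pipelines with their
#' defaults: 20-ms bins for per-trace photon-rate estimation, the traces'
#' native (typically 1-ms) bins for global rate fitting and Viterbi
#' decoding, 4-s segments for the 2D dwell map, a 12-ms dwell truncation
#' bound, and ten bootstrap trials.
#'
#' @param delta_estimation bin width for per-trace photon-rate fits (s).
#' @param segment_length dwell-map segment length (s).
#' @param truncation_bound left truncation for dwell-time fits (s).
#' @param n_boot bootstrap trials for the final global fit (0 disables).
#' @param n_blink_traces number of traces used for the global blink-rate
#'   estimation stage (blinking is fast and abundantly sampled, so a subset
#'   suffices and keeps the stage cheap).
#' @param min_segment_duration shortest cis/trans segment refitted (s).
#' @param blink_init initial (blink-on, blink-off) rates (s^-1).
#' @param iso_init initial (k12, k21) isomerization rates (s^-1).
#' @param dark_init initial dark-state (donor, acceptor) photon rates
#'   (counts/s); refined by likelihood maximization.
#' @param seed integer seed recorded in every report.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(delta_estimation = 0.02, segment_length = 4,
                            truncation_bound = 0.012, n_boot = 10,
                            n_blink_traces = 50, min_segment_duration = 2,
                            blink_init = c(2, 50), iso_init = c(0.05, 0.05),
                            dark_init = c(100, 100), seed = 1L) {
  structure(list(delta_estimation = delta_estimation,
                 segment_length = segment_length,
                 truncation_bound = truncation_bound, n_boot = n_boot,
                 n_blink_traces = n_blink_traces,
                 min_segment_duration = min_segment_duration,
                 blink_init = blink_init, iso_init = iso_init,
                 dark_init = dark_init, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Initial photon rates and kinetics from the count-ratio histogram
#'
#' Two-component split of the per-bin photon-count ratios at the
#' estimation bin width: bins are assigned to the unbound (low-ratio) or
#' bound (high-ratio) population by 1D k-means, per-class photon rates are
#' the class-mean counts, and initial association/dissociation rates come
#' from the mean run lengths of the classified bins.
#'
#' @param trace a [photon_trace()].
#' @param delta estimation bin width (s).
#' @return A list with `emissions` (an [emission_rates()] for
#'   unbound/bound) and `rates` (named kon1_prime, koff1 initial values).
#' @export
estimate_emissions <- function(trace, delta = 0.02) {
  tr <- rebin_trace(trace, delta)
  tot <- tr$donor + tr$acceptor
  keep <- tot > 0
  ratio <- tr$acceptor[keep] / tot[keep]
  if (length(unique(round(ratio, 6))) < 2L)
    stop("count-ratio histogram is degenerate; cannot split populations",
         call. = FALSE)
  km <- stats::kmeans(matrix(ratio, ncol = 1),
                      centers = matrix(range(ratio), ncol = 1))
  low <- which.min(km$centers)
  assign_unbound <- km$cluster == low
  mk <- function(sel, ch) mean(ch[keep][sel]) / delta
  emis <- emission_rates(
    c("unbound", "bound"),
    rate_D = c(mk(assign_unbound, tr$donor), mk(!assign_unbound, tr$donor)),
    rate_A = c(mk(assign_unbound, tr$acceptor),
               mk(!assign_unbound, tr$acceptor)))
  cls <- rep(NA, nrow(tr)); cls[keep] <- ifelse(assign_unbound, "u", "b")
  cls[is.na(cls)] <- "u"
  r <- rle(cls)
  mean_run <- function(v) mean(r$lengths[r$values == v]) * delta
  tu <- mean_run("u"); tb <- mean_run("b")
  rates <- c(kon1_prime = if (is.finite(tu)) 1 / tu else 1,
             koff1 = if (is.finite(tb)) 1 / tb else 10)
  list(emissions = emis, rates = rates)
}

add_dark_class <- function(emissions, rate_D, rate_A) {
  if ("dark" %in% emissions$class) return(emissions)
  out <- emission_rates(c(emissions$class, "dark"),
                        c(emissions$rate_D, rate_D),
                        c(emissions$rate_A, rate_A),
                        background_D = attr(emissions, "background_D") %||% 0,
                        background_A = attr(emissions, "background_A") %||% 0)
  out
}

# per-trace 20-ms estimation of photon rates (stage shared by all
# pipelines); returns per-trace emissions + rates
estimate_all_emissions <- function(traces, config) {
  res <- lapply(traces, function(tr) {
    init <- tryCatch(estimate_emissions(tr, config$delta_estimation),
                     error = function(e) NULL)
    if (is.null(init)) return(NULL)
    fit <- tryCatch(
      fit_trace(tr, "two_state",
                rate_spec(kon1_prime = init$rates[["kon1_prime"]],
                          koff1 = init$rates[["koff1"]]),
                init$emissions, rebin_to = config$delta_estimation,
                maxit = 800, reltol = 1e-8),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    e <- fit$emissions
    list(emissions = add_dark_class(e, config$dark_init[1],
                                    config$dark_init[2]),
         kon = fit$rates$kon1_prime, koff = fit$rates$koff1)
  })
  ok <- !vapply(res, is.null, TRUE)
  list(ok = ok,
       emissions = lapply(res[ok], `[[`, "emissions"),
       kon = vapply(res[ok], `[[`, 0, "kon"),
       koff = vapply(res[ok], `[[`, 0, "koff"))
}

#' Two-state pipeline: per-trace rates, global fit, decode, dwells
#'
#' The full analysis for kinetically homogeneous data (e.g. a binding
#' partner without the proline switch): per-trace photon-rate estimation
#' at 20 ms, global maximum-likelihood fit of the association/dissociation
#' and blink rates at the native bin width with emissions fixed, Viterbi
#' decoding, dwell-time statistics, and bootstrap errors.
#'
#' @param traces list of [photon_trace()] (native binning, typically 1 ms).
#' @param config an [analysis_config()].
#' @return A `photonhmm_report` list: `fit` (global `photonhmm_fit` with
#'   bootstrap SDs), `dwells`, `dwell_map`, `on_fit`/`off_fit` (truncated
#'   exponential fits), `config` echo and `seed`.
#' @export
run_two_state_analysis <- function(traces, config = analysis_config()) {
  if (!length(traces)) stop("empty dataset", call. = FALSE)
  est <- estimate_all_emissions(traces, config)
  if (!any(est$ok)) stop("no usable traces", call. = FALSE)
  traces <- traces[est$ok]
  rates0 <- rate_spec(kon1_prime = stats::median(est$kon),
                      koff1 = stats::median(est$koff),
                      kb_plus = config$blink_init[1],
                      kb_minus = config$blink_init[2])
  fit <- fit_global(traces, "two_state_blink", rates0, est$emissions,
                    free_rates = c("kon1_prime", "koff1", "kb_plus",
                                   "kb_minus"),
                    free_emissions = c("dark.D", "dark.A"))
  model <- build_two_state_blink(do.call(rate_spec,
                                         Filter(Negate(is.null), fit$rates)))
  emis_fitted <- lapply(est$emissions, patch_emissions,
                        free_emissions = fit$free_emissions,
                        values = unlist(fit$estimates[fit$free_emissions]))
  paths <- purrr::map2(traces, emis_fitted,
                       ~viterbi_path(.x, model, .y))
  dwells <- lapply(paths, extract_dwells)
  dmap <- segment_dwell_map(dwells, config$segment_length)
  all_d <- dplyr::bind_rows(dwells)
  on_fit <- tryCatch(fit_dwell_exponentials(
    all_d$duration[all_d$class == "bound" & !all_d$truncated], 1,
    config$truncation_bound), error = function(e) NULL)
  off_fit <- tryCatch(fit_dwell_exponentials(
    all_d$duration[all_d$class == "unbound" & !all_d$truncated], 1,
    config$truncation_bound), error = function(e) NULL)
  if (config$n_boot > 0)
    fit <- bootstrap_errors(traces, fit, n_boot = config$n_boot,
                            seed = config$seed)
  structure(list(fit = fit, dwells = dwells, dwell_map = dmap,
                 on_fit = on_fit, off_fit = off_fit,
                 emissions = emis_fitted, paths = paths,
                 config = config, seed = config$seed),
            class = "photonhmm_report")
}

#' Three-state pipeline for a homogeneous host binding two ligand forms
#'
#' Analysis for the inverted geometry in which the immobilized molecule is
#' kinetically homogeneous but the freely diffusing partner interconverts
#' between a high- and a low-affinity form: the host is observed unbound,
#' bound to form 1, or bound to form 2 (plus a dark state), with both
#' bound states sharing photon rates. Reports the four binding rates, the
#' blink rates, and the fraction of fast (low-affinity) binding
#' transitions `kon2'/(kon1' + kon2')`.
#'
#' @inheritParams run_two_state_analysis
#' @return A `photonhmm_report` with elements as in
#'   [run_two_state_analysis()] plus `frac_fast` and the dwell mixture fit
#'   `on_fit` (two components).
#' @export
run_three_state_analysis <- function(traces, config = analysis_config()) {
  if (!length(traces)) stop("empty dataset", call. = FALSE)
  est <- estimate_all_emissions(traces, config)
  if (!any(est$ok)) stop("no usable traces", call. = FALSE)
  traces <- traces[est$ok]
  # provisional decode with the blink model to harvest dwell statistics
  rates_bl <- rate_spec(kon1_prime = stats::median(est$kon),
                        koff1 = stats::median(est$koff),
                        kb_plus = config$blink_init[1],
                        kb_minus = config$blink_init[2])
  sub <- seq_len(min(config$n_blink_traces, length(traces)))
  fit_bl <- fit_global(traces[sub], "two_state_blink", rates_bl,
                       est$emissions[sub],
                       free_rates = c("kon1_prime", "koff1", "kb_plus",
                                      "kb_minus"),
                       free_emissions = c("dark.D", "dark.A"))
  emis_fitted <- lapply(est$emissions, patch_emissions,
                        free_emissions = fit_bl$free_emissions,
                        values = unlist(fit_bl$estimates[
                          fit_bl$free_emissions]))
  model_bl <- build_two_state_blink(do.call(
    rate_spec, Filter(Negate(is.null), fit_bl$rates)))
  paths0 <- purrr::map2(traces, emis_fitted, ~viterbi_path(.x, model_bl, .y))
  dwells0 <- lapply(paths0, extract_dwells)
  all_d <- dplyr::bind_rows(dwells0)
  on_mix <- fit_dwell_exponentials(
    all_d$duration[all_d$class == "bound" & !all_d$truncated], 2,
    config$truncation_bound)
  kon_tot <- fit_bl$estimates$kon1_prime
  if (on_mix$n_components == 2L) {
    koff2_0 <- on_mix$rates[1]; koff1_0 <- on_mix$rates[2]
    afast <- on_mix$amplitudes[1]
  } else {
    koff2_0 <- on_mix$rates * 3; koff1_0 <- on_mix$rates; afast <- 0.3
  }
  rates0 <- rate_spec(kon1_prime = kon_tot * (1 - afast),
                      kon2_prime = kon_tot * afast,
                      koff1 = koff1_0, koff2 = koff2_0,
                      kb_plus = fit_bl$rates$kb_plus,
                      kb_minus = fit_bl$rates$kb_minus)
  fit <- fit_global(traces, "three_state_blink", rates0, emis_fitted,
                    free_rates = c("kon1_prime", "kon2_prime", "koff1",
                                   "koff2"))
  model <- build_three_state_blink(do.call(
    rate_spec, Filter(Negate(is.null), fit$rates)))
  paths <- purrr::map2(traces, emis_fitted, ~viterbi_path(.x, model, .y))
  dwells <- lapply(paths, extract_dwells)
  dmap <- segment_dwell_map(dwells, config$segment_length)
  if (config$n_boot > 0)
    fit <- bootstrap_errors(traces, fit, n_boot = config$n_boot,
                            seed = config$seed)
  e <- fit$estimates
  frac_fast <- e$kon2_prime / (e$kon1_prime + e$kon2_prime)
  structure(list(fit = fit, blink_fit = fit_bl, dwells = dwells,
                 dwell_map = dmap, on_fit = on_mix,
                 frac_fast = frac_fast, emissions = emis_fitted,
                 paths = paths, config = config, seed = config$seed),
            class = "photonhmm_report")
}

# two-cluster split of the dwell map on log mean bound dwell: threshold at
# the density minimum between the two dominant modes; k-means fallback
cluster_dwell_map <- function(dmap, threshold = NULL) {
  lx <- log10(dmap$mean_on)
  if (is.null(threshold)) {
    d <- stats::density(lx, n = 512)
    y <- d$y
    locmax <- which(diff(sign(diff(y))) == -2) + 1L
    if (length(locmax) >= 2L) {
      # two highest modes, then the lowest point of the valley between them
      top2 <- sort(locmax[order(y[locmax], decreasing = TRUE)][1:2])
      valley <- top2[1]:top2[2]
      threshold <- d$x[valley[which.min(y[valley])]]
    } else {
      km <- stats::kmeans(matrix(lx, ncol = 1), centers = 2)
      threshold <- mean(km$centers)
    }
  }
  dmap$cluster <- ifelse(lx > threshold, "slow_off", "fast_off")
  attr(dmap, "threshold_log10_tau_on") <- threshold
  dmap
}

#' Iterative four-state analysis of switching binding kinetics
#'
#' The full iterative procedure for traces in which the immobilized
#' molecule interconverts slowly between a high-affinity (trans) and a
#' low-affinity (cis) form:
#' \enumerate{
#'   \item estimate the blink rate coefficients (and dark-state photon
#'     rates) by a global two-state-plus-blink fit, and fix them;
#'   \item fix the four binding rates to values read off the two clusters
#'     of the 4-s segment dwell map, and estimate the isomerization rates
#'     k12, k21 per trace (used as initializers);
#'   \item decode the most likely state path under the four-state model
#'     and split every trace into cis and trans segments;
#'   \item refit the trans segments and the cis segments separately with
#'     the two-state-plus-blink model to refine the binding rates;
#'   \item fit k12 and k21 globally over all traces with the four-state
#'     model, everything else fixed at the refined values.
#' }
#'
#' @inheritParams run_two_state_analysis
#' @return A `photonhmm_report` with `fit` (final global k12/k21 fit;
#'   `rates` holds the complete refined rate set), `binding_fits`
#'   (trans/cis segment refits), `blink_fit`, `dwell_map` (clustered),
#'   `per_trace_iso` (stage-2 estimates), `segments`, `paths`, and
#'   bootstrap SDs for k12/k21 when `config$n_boot > 0`. Traces without
#'   any decoded isomerization switch are counted in `n_no_switch`; when
#'   no switches are seen at all the isomerization rates are flagged
#'   non-identifiable.
#' @export
run_four_state_iterative <- function(traces, config = analysis_config()) {
  if (!length(traces)) stop("empty dataset", call. = FALSE)
  ## stage 0: per-trace photon rates at 20 ms
  est <- estimate_all_emissions(traces, config)
  if (!any(est$ok)) stop("no usable traces", call. = FALSE)
  traces <- traces[est$ok]

  ## stage 1: blink rates from a two-state-plus-blink global fit (subset)
  rates_bl <- rate_spec(kon1_prime = stats::median(est$kon),
                        koff1 = stats::median(est$koff),
                        kb_plus = config$blink_init[1],
                        kb_minus = config$blink_init[2])
  sub <- seq_len(min(config$n_blink_traces, length(traces)))
  fit_bl <- fit_global(traces[sub], "two_state_blink", rates_bl,
                       est$emissions[sub],
                       free_rates = c("kon1_prime", "koff1", "kb_plus",
                                      "kb_minus"),
                       free_emissions = c("dark.D", "dark.A"))
  kb_plus <- fit_bl$estimates$kb_plus
  kb_minus <- fit_bl$estimates$kb_minus
  emis_fitted <- lapply(est$emissions, patch_emissions,
                        free_emissions = fit_bl$free_emissions,
                        values = unlist(fit_bl$estimates[
                          fit_bl$free_emissions]))

  ## stage 2a: dwell map from a blink-model decode, split into 2 clusters
  model_bl <- build_two_state_blink(do.call(
    rate_spec, Filter(Negate(is.null), fit_bl$rates)))
  paths0 <- purrr::map2(traces, emis_fitted, ~viterbi_path(.x, model_bl, .y))
  dwells0 <- lapply(paths0, extract_dwells)
  dmap <- cluster_dwell_map(
    segment_dwell_map(dwells0, config$segment_length))
  cl_slow <- dmap[dmap$cluster == "slow_off", ]
  cl_fast <- dmap[dmap$cluster == "fast_off", ]
  if (!nrow(cl_slow) || !nrow(cl_fast))
    stop("dwell map does not separate into two clusters", call. = FALSE)
  rates_init <- rate_spec(
    kon1_prime = 1 / mean(cl_slow$mean_off),
    koff1 = 1 / mean(cl_slow$mean_on),
    kon2_prime = 1 / mean(cl_fast$mean_off),
    koff2 = 1 / mean(cl_fast$mean_on),
    k12 = config$iso_init[1], k21 = config$iso_init[2],
    kb_plus = kb_plus, kb_minus = kb_minus)

  ## stage 2b: per-trace isomerization-rate estimates (initializers)
  per_trace_iso <- purrr::map2(traces, emis_fitted, function(tr, em) {
    f <- tryCatch(
      fit_global(tr, "four_state_blink", rates_init, em,
                 free_rates = c("k12", "k21"), maxit = 200, reltol = 1e-8),
      error = function(e) NULL)
    if (is.null(f)) c(k12 = NA_real_, k21 = NA_real_) else
      c(k12 = f$estimates$k12, k21 = f$estimates$k21)
  })
  iso_mat <- do.call(rbind, per_trace_iso)
  iso_med <- apply(iso_mat, 2, stats::median, na.rm = TRUE)
  if (all(is.na(iso_mat))) iso_med <- config$iso_init

  ## stage 3: four-state Viterbi decode and cis/trans splitting
  rates_dec <- rates_init
  rates_dec$k12 <- iso_med[["k12"]]; rates_dec$k21 <- iso_med[["k21"]]
  model4 <- build_four_state_blink(rates_dec)
  paths <- purrr::map2(traces, emis_fitted, ~viterbi_path(.x, model4, .y))
  segments <- purrr::pmap(list(traces, paths), split_cis_trans_segments,
                          min_duration = config$min_segment_duration)
  n_switch <- vapply(segments, nrow, 0L) - 1L
  seg_tbl <- dplyr::bind_rows(
    purrr::imap(segments, ~dplyr::mutate(.x, trace_index = .y)))

  ## stage 4: refit trans and cis segments with the blink model
  refit_block <- function(isomer) {
    rows <- which(seg_tbl$isomer == isomer)
    if (!length(rows)) return(NULL)
    segs <- seg_tbl$trace[rows]
    emis <- emis_fitted[seg_tbl$trace_index[rows]]
    init <- if (isomer == "trans")
      rate_spec(kon1_prime = rates_init$kon1_prime,
                koff1 = rates_init$koff1,
                kb_plus = kb_plus, kb_minus = kb_minus)
    else
      rate_spec(kon1_prime = rates_init$kon2_prime,
                koff1 = rates_init$koff2,
                kb_plus = kb_plus, kb_minus = kb_minus)
    fit_global(segs, "two_state_blink", init, emis,
               free_rates = c("kon1_prime", "koff1"))
  }
  fit_trans <- refit_block("trans")
  fit_cis <- refit_block("cis")
  # an isomer never visited in the decode keeps its dwell-map estimate;
  # with no switches at all the isomerization rates are not identifiable
  # and the final fit is flagged below
  if (is.null(fit_trans) && is.null(fit_cis))
    stop("cis/trans splitting produced no usable segments", call. = FALSE)

  ## stage 5: global isomerization fit with everything else fixed
  rates_ref <- rate_spec(
    kon1_prime = if (is.null(fit_trans)) rates_init$kon1_prime else
      fit_trans$estimates$kon1_prime,
    koff1 = if (is.null(fit_trans)) rates_init$koff1 else
      fit_trans$estimates$koff1,
    kon2_prime = if (is.null(fit_cis)) rates_init$kon2_prime else
      fit_cis$estimates$kon1_prime,
    koff2 = if (is.null(fit_cis)) rates_init$koff2 else
      fit_cis$estimates$koff1,
    k12 = iso_med[["k12"]], k21 = iso_med[["k21"]],
    kb_plus = kb_plus, kb_minus = kb_minus)
  fit <- fit_global(traces, "four_state_blink", rates_ref, emis_fitted,
                    free_rates = c("k12", "k21"))
  if (config$n_boot > 0)
    fit <- bootstrap_errors(traces, fit, n_boot = config$n_boot,
                            seed = config$seed)
  iso_identifiable <- sum(n_switch, na.rm = TRUE) > 0
  if (!iso_identifiable)
    warning("no isomerization switches decoded; k12/k21 are not ",
            "identifiable")
  structure(list(fit = fit, binding_fits = list(trans = fit_trans,
                                                cis = fit_cis),
                 blink_fit = fit_bl, dwell_map = dmap,
                 per_trace_iso = iso_mat, segments = seg_tbl,
                 paths = paths, emissions = emis_fitted,
                 n_no_switch = sum(n_switch == 0L),
                 iso_identifiable = iso_identifiable,
                 config = config, seed = config$seed),
            class = "photonhmm_report")
}

#' @export
print.photonhmm_report <- function(x, ...) {
  cat("<photonhmm_report>\n")
  print(x$fit)
  invisible(x)
}

#' Simulate a dataset to disk
#'
#' Thin wrapper over [simulate_dataset()] and [write_dataset()] that builds
#' the kinetic model from a [rate_spec()] and records the seed and
#' configuration in the manifest.
#'
#' @param rates a [rate_spec()].
#' @param type model type (see [fit_trace()]).
#' @param emissions an [emission_rates()]; default
#'   [default_emission_rates()].
#' @param n_traces,mean_duration,delta,seed see [simulate_dataset()].
#' @param dir optional output directory; when `NULL` nothing is written.
#' @return The in-memory dataset (invisibly the manifest path attribute is
#'   set when written).
#' @export
run_simulation <- function(rates, type = "four_state_blink",
                           emissions = default_emission_rates(),
                           n_traces = 163, mean_duration = 60,
                           delta = 0.001, seed = 1L, dir = NULL) {
  model <- model_builder(type)(rates)
  ds <- simulate_dataset(model, emissions, n_traces = n_traces,
                         mean_duration = mean_duration, delta = delta,
                         seed = seed)
  if (!is.null(dir)) {
    path <- write_dataset(ds, dir)
    attr(ds, "manifest_path") <- path
  }
  ds
}

#' Serialize a pipeline report as JSON
#'
#' @param report a `photonhmm_report`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    seed = report$seed,
    config = unclass(report$config),
    estimates = report$fit$estimates,
    bootstrap_sd = as.list(report$fit$bootstrap_sd),
    log_likelihood = report$fit$log_likelihood,
    converged = report$fit$converged,
    rates = Filter(Negate(is.null), report$fit$rates),
    frac_fast = report$frac_fast,
    version = as.character(utils::packageVersion("photonhmm")))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
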