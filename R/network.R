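#' Configuration of the four-population decision circuit
#'
#' Collects every knob of the spiking network: population sizes, the
#' potentiated recurrent weight, external drive, integration settings and
#' an optional down-scaling factor for desk-sized runs.
#'
#' @param N_E Number of excitatory neurons before scaling (default 1600).
#' @param N_I Number of inhibitory interneurons before scaling (default 400).
#' @param f Fraction of excitatory neurons in each selective population
#'   (default 0.15).
#' @param w_plus Potentiated weight within each selective population
#'   (dimensionless, >= 1). `w_minus` is derived via [derive_w_minus()].
#' @param v_ext Background Poisson rate per neuron in kHz (default 2.4).
#' @param dt Integration step in ms (default 0.02).
#' @param duration Simulated time in seconds.
#' @param seed Master RNG seed; every neuron gets an independent stream
#'   derived from it, so rasters are reproducible and iteration-order free.
#' @param scale Network reduction factor k: population counts are divided by
#'   k and the recurrent conductances multiplied by k, preserving the mean
#'   recurrent drive per neuron at the cost of larger finite-size
#'   fluctuations. k = 1 is the full published circuit.
#' @param I_inject Constant injected current in nA applied to every neuron
#'   (positive values depolarize); used for single-neuron calibration runs.
#' @param inj_window Length-2 vector (ms) during which `I_inject` applies.
#' @param synapse_override Named list replacing individual entries of the
#'   [synapse_params()] presets, e.g. `list(excitatory = list(g_rec_AMPA = 0))`.
#' @return An object of class `network_config`.
#' @export
network_config <- function(N_E = 1600, N_I = 400, f = 0.15, w_plus = 1.61,
                           v_ext = 2.4, dt = 0.02, duration = 1, seed = 1,
                           scale = 1, I_inject = 0, inj_window = c(0, Inf),
                           synapse_override = NULL) {
  stopifnot(N_E > 0, N_I > 0, f > 0, f < 0.5, w_plus >= 1, v_ext >= 0,
            dt > 0, duration > 0, scale >= 1)
  N_E_s <- N_E / scale
  N_I_s <- N_I / scale
  N_sel <- f * N_E_s
  if (abs(N_sel - round(N_sel)) > 1e-9 || abs(N_E_s - round(N_E_s)) > 1e-9 ||
      abs(N_I_s - round(N_I_s)) > 1e-9)
    stop("population sizes must be integers after scaling: got N_E = ", N_E_s,
         ", N_I = ", N_I_s, ", f*N_E = ", N_sel)
  syn_e <- synapse_params("excitatory")
  syn_i <- synapse_params("inhibitory")
  if (!is.null(synapse_override)) {
    for (cls in names(synapse_override)) {
      tgt <- if (cls == "excitatory") "syn_e" else "syn_i"
      cur <- get(tgt)
      cur[names(synapse_override[[cls]])] <- synapse_override[[cls]]
      assign(tgt, cur)
    }
  }
  # scaling multiplies recurrent conductances so N * g stays constant
  for (nm in c("g_rec_AMPA", "g_NMDA", "g_GABA")) {
    syn_e[[nm]] <- syn_e[[nm]] * scale
    syn_i[[nm]] <- syn_i[[nm]] * scale
  }
  structure(list(
    N_E = as.integer(round(N_E_s)), N_I = as.integer(round(N_I_s)), f = f,
    w_plus = w_plus, w_minus = derive_w_minus(w_plus, f),
    v_ext = v_ext, dt = dt, duration = duration, seed = as.integer(seed),
    scale = scale, I_inject = I_inject, inj_window = inj_window,
    neuron = list(excitatory = neuron_params("excitatory"),
                  inhibitory = neuron_params("inhibitory")),
    synapse = list(excitatory = syn_e, inhibitory = syn_i)
  ), class = "network_config")
}

#' Stimulus specification for the motion-discrimination task
#'
#' The two selective populations receive independent Poisson spike trains at
#' `mu1 = mu (1 + c)` and `mu2 = mu (1 - c)`, where `c` is the motion
#' coherence, through the external AMPA channel, on top of the background
#' drive, during the window `[t_on, t_off)`.
#'
#' @param mu Stimulus strength in Hz (>= 0).
#' @param c Motion coherence as a fraction in `[-1, 1]` (e.g. 0.032 for 3.2%).
#' @param t_on,t_off Stimulus window in ms (default: the whole trial).
#' @return An object of class `stimulus_spec` with derived `mu1`, `mu2`.
#' @export
stimulus_spec <- function(mu = 0, c = 0, t_on = 0, t_off = Inf) {
  stopifnot(mu >= 0, abs(c) <= 1, t_off >= t_on)
  structure(list(mu = mu, c = c, mu1 = mu * (1 + c), mu2 = mu * (1 - c),
                 t_on = t_on, t_off = t_off), class = "stimulus_spec")
}

#' Population sizes and the connection weight matrix
#'
#' The circuit is fully connected. Weights are population-wise: `w_plus`
#' within S1 and within S2; `w_minus` between S1 and S2 and from NS onto
#' S1/S2; all remaining weights 1. The weight matrix applies to the AMPA and
#' NMDA recurrent sums; GABA synapses are unweighted (their inhibitory sign
#' is carried by the driving force `V - V_I` in the current equation).
#'
#' @param config A [network_config()].
#' @return List with `sizes` (named S1, S2, NS, I) and `W`, the 4x4
#'   pre-by-post weight matrix.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  N_S1 <- as.integer(round(config$f * config$N_E))
  N_NS <- config$N_E - 2L * N_S1
  sizes <- c(S1 = N_S1, S2 = N_S1, NS = N_NS, I = config$N_I)
  wp <- config$w_plus
  wm <- config$w_minus
  W <- matrix(1, 4, 4, dimnames = list(pre = names(sizes), post = names(sizes)))
  W["S1", "S1"] <- wp
  W["S2", "S2"] <- wp
  W["S1", "S2"] <- wm
  W["S2", "S1"] <- wm
  W["NS", "S1"] <- wm
  W["NS", "S2"] <- wm
  list(sizes = sizes, W = W)
}

#' Simulate one trial of the spiking network
#'
#' Integrates the full circuit with a second-order Runge-Kutta (Heun) step
#' at `config$dt`; Poisson arrivals and recurrent spikes enter as unit jumps
#' of the gating variables between steps. Deterministic for a given
#' `config$seed`.
#'
#' @param config A [network_config()].
#' @param stimulus A [stimulus_spec()] or `NULL` for spontaneous activity.
#' @param record `"spikes"` for the full raster, `"counts"` for per-
#'   population spike counts in `count_bin` ms bins (memory-light for long
#'   runs), or `"both"`.
#' @param count_bin Bin width in ms for `record = "counts"` (default 5).
#' @param gating_stride If > 0, per-population gating-variable sums are
#'   recorded every `gating_stride` integration steps (diagnostics).
#' @return A `spike_raster` object: `spikes` data frame (`neuron`,
#'   `time_ms`), `population` factor over neuron indices, `sizes`,
#'   `duration_ms`, optional `counts` matrix, and gating diagnostics
#'   (`gating_min`, `snmda_max`).
#' @export
run_trial <- function(config, stimulus = NULL,
                      record = c("spikes", "counts", "both"),
                      count_bin = 5, gating_stride = 0) {
  stopifnot(inherits(config, "network_config"))
  record <- match.arg(record)
  if (is.null(stimulus)) stimulus <- stimulus_spec(0, 0)
  stopifnot(inherits(stimulus, "stimulus_spec"))
  dur_ms <- config$duration * 1000
  sched <- rbind(
    if (stimulus$t_on > 0) c(0, 0, 0),
    c(stimulus$t_on, stimulus$mu1, stimulus$mu2),
    if (stimulus$t_off < dur_ms) c(stimulus$t_off, 0, 0))
  run_schedule(config, sched, record = record, count_bin = count_bin,
               gating_stride = gating_stride, stimulus = stimulus)
}

#' Simulate a trial under a piecewise-constant stimulus schedule
#'
#' Generalizes [run_trial()] to staircase stimulus protocols (e.g. ramped
#' inputs): each schedule row gives the onset time and the Poisson rates to
#' the two selective populations that hold from that time until the next row.
#'
#' @param config A [network_config()].
#' @param schedule Numeric matrix/data frame with columns `t_from` (ms),
#'   `mu1`, `mu2` (Hz), rows in ascending onset order.
#' @inheritParams run_trial
#' @param stimulus Optional [stimulus_spec()] stored as metadata.
#' @return A `spike_raster`, as for [run_trial()].
#' @export
run_schedule <- function(config, schedule,
                         record = c("spikes", "counts", "both"),
                         count_bin = 5, gating_stride = 0, stimulus = NULL) {
  stopifnot(inherits(config, "network_config"))
  record <- match.arg(record)
  schedule <- as.matrix(schedule)
  stopifnot(ncol(schedule) == 3, !is.unsorted(schedule[, 1]))
  net <- build_network(config)
  sz <- net$sizes
  ne <- config$neuron$excitatory
  ni <- config$neuron$inhibitory
  se <- config$synapse$excitatory
  si <- config$synapse$inhibitory
  dur_ms <- config$duration * 1000
  inj <- config$inj_window
  res <- sim_network_cpp(
    sz[["S1"]], sz[["S2"]], sz[["NS"]], sz[["I"]],
    net$W,
    unlist(ne[c("C_m", "g_L", "V_L", "V_th", "V_reset", "tau_ref")]),
    unlist(ni[c("C_m", "g_L", "V_L", "V_th", "V_reset", "tau_ref")]),
    unlist(se[c("g_ext_AMPA", "g_rec_AMPA", "g_NMDA", "g_GABA")]),
    unlist(si[c("g_ext_AMPA", "g_rec_AMPA", "g_NMDA", "g_GABA")]),
    se$tau_AMPA, se$tau_NMDA_decay, se$tau_NMDA_rise, se$tau_GABA,
    se$alpha, se$Mg, se$V_E, se$V_I,
    config$v_ext, schedule,
    -config$I_inject, inj[1], min(inj[2], dur_ms),
    config$dt, dur_ms, config$seed,
    record %in% c("spikes", "both"),
    if (record %in% c("counts", "both")) count_bin else 0,
    as.integer(gating_stride))
  pop <- factor(rep(names(sz), sz), levels = names(sz))
  out <- list(
    spikes = data.frame(neuron = res$neuron, time_ms = res$time_ms),
    population = pop, sizes = sz, duration_ms = res$duration_ms,
    counts = if (record %in% c("counts", "both")) {
      m <- res$counts; colnames(m) <- names(sz); m
    },
    count_bin_ms = if (record %in% c("counts", "both")) count_bin,
    gating = res$gating,
    gating_min = res$gating_min, snmda_max = res$snmda_max,
    config = config, stimulus = stimulus, schedule = schedule)
  class(out) <- "spike_raster"
  out
}

#' @export
print.spike_raster <- function(x, ...) {
  cat("<spike_raster> ", sum(x$sizes), " neurons (",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), "), ",
      x$duration_ms, " ms, ", nrow(x$spikes), " spikes\n", sep = "")
  invisible(x)
}

#' Mean firing rate per population over a raster
#'
#' @param raster A `spike_raster`.
#' @param from Start of the averaging window in ms (default 0).
#' @return Named numeric vector of rates in spikes/s.
#' @export
mean_rates <- function(raster, from = 0) {
  stopifnot(inherits(raster, "spike_raster"))
  span_s <- (raster$duration_ms - from) / 1000
  if (nrow(raster$spikes) > 0) {
    sp <- raster$spikes[raster$spikes$time_ms > from, ]
    pop_of_spike <- raster$population[sp$neuron]
    cnt <- table(factor(pop_of_spike, levels = names(raster$sizes)))
  } else {
    cnt <- stats::setNames(rep(0, length(raster$sizes)), names(raster$sizes))
  }
  stats::setNames(as.numeric(cnt) / (as.numeric(raster$sizes) * span_s),
                  names(raster$sizes))
}
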