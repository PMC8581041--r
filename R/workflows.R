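#' Stationary landscape protocol
#'
#' End-to-end protocol at fixed circuit and stimulus parameters: simulate
#' (or accept) rate trajectories, pool them into the steady-state landscape
#' until the convergence statistic drops below a threshold or the trial
#' budget is exhausted, then locate attractors, compute the flux field and
#' (when two decision states coexist) barrier metrics and transition paths.
#'
#' @param config A [network_config()] (its `duration` is the per-trial
#'   length; trial seeds are `config$seed + 0:(n_trials-1)`).
#' @param stimulus A [stimulus_spec()].
#' @param n_trials Trial budget (default 10).
#' @param input Optional list of [rate_trajectory()] objects (e.g. Langevin
#'   surrogates); when given, no simulation is run.
#' @param bins Landscape bins per axis (default 40).
#' @param discard Transient dropped at the start of each trajectory, ms
#'   (default 500).
#' @param window,stride Rate-extraction window and stride, ms.
#' @param sigma_threshold Convergence threshold on the relative L2 distance
#'   between successive pooled distributions (default 6e-4, i.e. 0.06%).
#' @param check_every Number of trials pooled between convergence checks.
#' @param flux_boxes Coarse boxes per axis for the flux field (default 20).
#' @param region_semi Attractor-region semi-axis, spikes/s (default 5).
#' @param smooth,depth,high_rate Passed to [find_minima()].
#' @param paths If TRUE and both decision states are present, extract and
#'   average the DS1->DS2 and DS2->DS1 transition paths.
#' @return List: `trajectories`, `landscape`, `attractors`, `flux`,
#'   `barriers` (when computable), `paths`, `sigma_trace`, `converged`,
#'   `manifest`.
#' @export
run_stationary_landscape <- function(config, stimulus, n_trials = 10,
                                     input = NULL, bins = 40, discard = 500,
                                     window = 50, stride = 5,
                                     sigma_threshold = 6e-4, check_every = 4,
                                     flux_boxes = 20, region_semi = 5,
                                     smooth = 1, depth = 0.5, high_rate = 15,
                                     paths = FALSE) {
  manifest <- list(protocol = "stationary_landscape",
                   config = config, stimulus = stimulus,
                   n_trials = n_trials, bins = bins, discard = discard,
                   window = window, stride = stride,
                   sigma_threshold = sigma_threshold,
                   check_every = check_every, flux_boxes = flux_boxes,
                   region_semi = region_semi, smooth = smooth, depth = depth,
                   high_rate = high_rate, paths = paths,
                   external_input = !is.null(input),
                   package = as.character(utils::packageVersion("decisionscape")))
  trajs <- if (!is.null(input)) {
    if (is.data.frame(input)) list(input) else input
  } else {
    lapply(seq_len(n_trials) - 1L, function(k) {
      cfg <- config
      cfg$seed <- config$seed + k
      compute_population_rates(run_trial(cfg, stimulus, record = "counts",
                                         count_bin = stride),
                               window = window, stride = stride)
    })
  }
  # convergence: sigma between successive pooled distributions on a fixed grid
  rng <- pooled_range(trajs, discard, headroom = 1.05)
  sigma_trace <- numeric(0)
  converged <- FALSE
  prev <- NULL
  checkpoints <- if (check_every < length(trajs))
    unique(c(seq(check_every, length(trajs), by = check_every),
             length(trajs)))
  else length(trajs)
  for (ck in checkpoints) {
    cur <- estimate_pss(trajs[seq_len(ck)], bins = bins, range = rng,
                        discard = discard)
    if (!is.null(prev)) {
      sigma_trace <- c(sigma_trace, convergence_sigma(prev, cur))
      if (tail(sigma_trace, 1) < sigma_threshold) {
        converged <- TRUE
        trajs <- trajs[seq_len(ck)]
        prev <- cur
        break
      }
    }
    prev <- cur
  }
  land <- prev
  att <- find_minima(land, smooth = smooth, depth = depth,
                     high_rate = high_rate)
  flux <- estimate_flux(lapply(trajs, discard_transient, discard),
                        N1 = flux_boxes, N2 = flux_boxes)
  out <- list(trajectories = trajs, landscape = land, attractors = att,
              flux = flux, sigma_trace = sigma_trace, converged = converged,
              manifest = manifest)
  labs <- att$label
  if (all(c("DS1", "DS2") %in% labs))
    out$barriers <- barrier_metrics(land, att, "DS1", "DS2", smooth = smooth)
  if (all(c("SS", "DS1") %in% labs))
    out$barriers_ss <- barrier_metrics(land, att, "SS", "DS1", smooth = smooth)
  if (paths && all(c("DS1", "DS2") %in% labs)) {
    regs <- define_regions(att[att$label %in% c("DS1", "DS2"), ], region_semi)
    fw <- extract_transition_paths(trajs, regs$DS1, regs$DS2)
    bw <- extract_transition_paths(trajs, regs$DS2, regs$DS1)
    out$paths <- list(
      forward = if (fw$K > 0) average_path(fw) else fw,
      backward = if (bw$K > 0) average_path(bw) else bw)
    out$regions <- regs
  }
  out
}

#' Drop the initial transient of a trajectory
#'
#' @param traj A [rate_trajectory()].
#' @param discard Time to drop from the start, ms.
#' @return The truncated trajectory.
#' @export
discard_transient <- function(traj, discard) {
  out <- traj[traj$t > discard, , drop = FALSE]
  rownames(out) <- NULL
  rate_trajectory(as.data.frame(out), window = attr(traj, "window"),
                  stride = attr(traj, "stride"))
}

pooled_range <- function(trajs, discard = 0, headroom = 1.05) {
  x <- unlist(lapply(trajs, function(d) d$r1[d$t > discard]))
  y <- unlist(lapply(trajs, function(d) d$r2[d$t > discard]))
  list(r1 = c(min(0, min(x)), max(x) * headroom + 1e-6),
       r2 = c(min(0, min(y)), max(y) * headroom + 1e-6))
}

#' Replay a workflow manifest
#'
#' Re-runs a protocol from the manifest embedded in its output; with the
#' stored seeds this reproduces the outputs exactly.
#'
#' @param manifest A `manifest` element from a workflow result.
#' @param ... Overrides.
#' @return The workflow result.
#' @export
replay_manifest <- function(manifest, ...) {
  stopifnot(is.list(manifest), !is.null(manifest$protocol))
  if (isTRUE(manifest$external_input) && !("input" %in% names(list(...))))
    stop("this run used externally supplied trajectories; pass them via input=")
  args <- manifest[setdiff(names(manifest),
                           c("protocol", "package", "external_input"))]
  dots <- list(...)
  args[names(dots)] <- dots
  fn <- switch(manifest$protocol,
               stationary_landscape = run_stationary_landscape,
               ramp_hysteresis = run_ramp_hysteresis,
               coherence_sweep = run_coherence_sweep,
               parameter_census = run_parameter_census,
               stop("unknown protocol: ", manifest$protocol))
  do.call(fn, args)
}

classify_state <- function(r1, r2, high_rate = 15) {
  ifelse(r1 >= high_rate & r2 >= high_rate, "DU",
         ifelse(r1 >= high_rate, "DS1",
                ifelse(r2 >= high_rate, "DS2", "SS")))
}

#' Ramped-stimulus hysteresis protocol
#'
#' Drives the circuit with a staircase of stimulus strengths, increasing
#' and decreasing through the same levels, and reports which attractor
#' class the population state occupies at each level in each direction.
#' Hysteresis shows up as level-wise disagreement between the two
#' directions (e.g. dwelling in the spontaneous state on the way up but in
#' the double-up state on the way down).
#'
#' @param config A [network_config()]; `config$duration` is ignored (the
#'   schedule fixes the duration).
#' @param mu_levels Stimulus strengths of the staircase, Hz.
#' @param dwell Dwell time per level, seconds.
#' @param n_trials Trials per direction.
#' @param c Motion coherence (default 0).
#' @param discard_frac Fraction of each dwell discarded before averaging
#'   (default 0.4).
#' @param window,stride Rate extraction parameters, ms.
#' @param high_rate Cutoff for state classification, spikes/s.
#' @param simulate_fn Optional replacement simulator
#'   `function(config, schedule, seed)` returning a [rate_trajectory()];
#'   used to exercise the protocol on surrogate dynamics.
#' @return List: `occupancy` (data frame direction x level with modal state
#'   and mean rates), `hysteresis_layers` (number of levels whose modal
#'   state differs between directions), per-level pooled landscapes
#'   (`landscapes_up`, `landscapes_down`), `manifest`.
#' @export
run_ramp_hysteresis <- function(config, mu_levels = c(5, 16, 40, 76, 90),
                                dwell = 1.5, n_trials = 4, c = 0,
                                discard_frac = 0.4, window = 50, stride = 5,
                                high_rate = 15, simulate_fn = NULL) {
  manifest <- list(protocol = "ramp_hysteresis", config = config,
                   mu_levels = mu_levels, dwell = dwell, n_trials = n_trials,
                   c = c, discard_frac = discard_frac, window = window,
                   stride = stride, high_rate = high_rate,
                   package = as.character(utils::packageVersion("decisionscape")))
  dwell_ms <- dwell * 1000
  n_lev <- length(mu_levels)
  mk_sched <- function(levels)
    cbind(t_from = (seq_len(n_lev) - 1) * dwell_ms,
          mu1 = levels * (1 + c), mu2 = levels * (1 - c))
  default_sim <- function(cfg, schedule, seed) {
    cfg$seed <- seed
    cfg$duration <- n_lev * dwell
    compute_population_rates(run_schedule(cfg, schedule, record = "counts",
                                          count_bin = stride),
                             window = window, stride = stride)
  }
  sim <- if (is.null(simulate_fn)) default_sim else simulate_fn
  run_dir <- function(levels, seed_off) {
    sched <- mk_sched(levels)
    lapply(seq_len(n_trials), function(k)
      sim(config, sched, config$seed + seed_off + k - 1L))
  }
  up <- run_dir(mu_levels, 0L)
  down <- run_dir(rev(mu_levels), 1000L)
  layer_stats <- function(trajs, levels) {
    do.call(rbind, lapply(seq_len(n_lev), function(li) {
      t0 <- (li - 1) * dwell_ms + discard_frac * dwell_ms
      t1 <- li * dwell_ms
      sub <- lapply(trajs, function(d) d[d$t > t0 & d$t <= t1, ])
      m1 <- vapply(sub, function(d) mean(d$r1), numeric(1))
      m2 <- vapply(sub, function(d) mean(d$r2), numeric(1))
      states <- classify_state(m1, m2, high_rate)
      data.frame(mu = levels[li],
                 r1 = mean(m1), r2 = mean(m2),
                 state = names(sort(table(states), decreasing = TRUE))[1])
    }))
  }
  occ_up <- cbind(direction = "up", layer_stats(up, mu_levels))
  occ_down <- cbind(direction = "down", layer_stats(down, rev(mu_levels)))
  occ <- rbind(occ_up, occ_down)
  layer_land <- function(trajs, levels) {
    lapply(seq_len(n_lev), function(li) {
      t0 <- (li - 1) * dwell_ms + discard_frac * dwell_ms
      t1 <- li * dwell_ms
      sub <- lapply(trajs, function(d) {
        s <- d[d$t > t0 & d$t <= t1, ]
        rate_trajectory(as.data.frame(s))
      })
      estimate_pss(sub, bins = 30)
    })
  }
  m_up <- occ_up[order(occ_up$mu), "state"]
  m_down <- occ_down[order(occ_down$mu), "state"]
  list(occupancy = occ,
       hysteresis_layers = sum(m_up != m_down),
       landscapes_up = layer_land(up, mu_levels),
       landscapes_down = layer_land(down, rev(mu_levels)),
       manifest = manifest)
}

#' Coherence sweep: barrier asymmetry and switching kinetics
#'
#' For each motion coherence, pools trials at fixed circuit parameters,
#' computes the relative barrier RB between a pair of attractors from the
#' landscape, and the mean first-passage time between their elliptical
#' regions; summarizes the RB monotonicity in c and the rank correlation
#' between RB and log MFPT.
#'
#' @param config A [network_config()] (per-trial duration from
#'   `config$duration`).
#' @param mu Stimulus strength, Hz.
#' @param c_values Coherence fractions to sweep.
#' @param n_trials Trials pooled per coherence.
#' @param pair Ordered attractor pair, default `c("DS1", "DS2")` (use
#'   `c("SS", "DS1")` for the tristable decision barrier).
#' @param bins,discard,window,stride,smooth,depth,high_rate As in
#'   [run_stationary_landscape()].
#' @param region_semi Region semi-axis for the MFPT, spikes/s.
#' @param input Optional list (one element per coherence) of trajectory
#'   lists, bypassing simulation.
#' @return List: `table` (one row per c: RB, MFPT, K, n attractors),
#'   `spearman_rb_c`, `spearman_rb_logmfpt`, `manifest`.
#' @export
run_coherence_sweep <- function(config, mu = 58,
                                c_values = c(0.005, 0.01, 0.016, 0.024, 0.032),
                                n_trials = 10, pair = c("DS1", "DS2"),
                                bins = 40, discard = 500, window = 50,
                                stride = 5, region_semi = 5, smooth = 1,
                                depth = 0.5, high_rate = 15, input = NULL) {
  manifest <- list(protocol = "coherence_sweep", config = config, mu = mu,
                   c_values = c_values, n_trials = n_trials, pair = pair,
                   bins = bins, discard = discard, window = window,
                   stride = stride, region_semi = region_semi,
                   smooth = smooth, depth = depth, high_rate = high_rate,
                   package = as.character(utils::packageVersion("decisionscape")))
  rows <- list()
  for (ci in seq_along(c_values)) {
    cc <- c_values[ci]
    trajs <- if (!is.null(input)) input[[ci]] else {
      lapply(seq_len(n_trials) - 1L, function(k) {
        cfg <- config
        cfg$seed <- config$seed + 10000L * ci + k
        compute_population_rates(
          run_trial(cfg, stimulus_spec(mu, cc), record = "counts",
                    count_bin = stride),
          window = window, stride = stride)
      })
    }
    land <- estimate_pss(trajs, bins = bins, discard = discard)
    att <- find_minima(land, smooth = smooth, depth = depth,
                       high_rate = high_rate)
    row <- data.frame(c = cc, n_attractors = nrow(att), RB = NA_real_,
                      MFPT = NA_real_, K = 0L, censored = 0L)
    if (all(pair %in% att$label)) {
      bm <- barrier_metrics(land, att, pair[1], pair[2], smooth = smooth)
      row$RB <- bm$RB
      regs <- define_regions(att[att$label %in% pair, ], region_semi)
      fpt <- first_passage_times(lapply(trajs, discard_transient, discard),
                                 regs[[pair[1]]], regs[[pair[2]]])
      row$MFPT <- fpt$MFPT
      row$K <- fpt$K
      row$censored <- fpt$n_censored
    }
    rows[[ci]] <- row
  }
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$RB) & is.finite(tab$MFPT) & tab$MFPT > 0
  list(table = tab,
       spearman_rb_c = if (sum(is.finite(tab$RB)) > 2)
         cor(tab$c[is.finite(tab$RB)], tab$RB[is.finite(tab$RB)],
             method = "spearman") else NA_real_,
       spearman_rb_logmfpt = if (sum(ok) > 2)
         cor(tab$RB[ok], log(tab$MFPT[ok]), method = "spearman")
         else NA_real_,
       manifest = manifest)
}

#' Attractor census over the (w_plus, mu) plane
#'
#' Counts coexisting attractors per parameter cell from pooled
#' multi-trial landscapes and summarizes how the count changes with the
#' recurrent connectivity.
#'
#' @param config Base [network_config()] (its `w_plus` is overridden).
#' @param w_plus_values,mu_values Parameter grid.
#' @param n_trials Trials pooled per cell.
#' @param bins,discard,window,stride,smooth,depth,high_rate As elsewhere.
#' @param input Optional nested list `input[[wi]][[mi]]` of trajectory
#'   lists, bypassing simulation.
#' @return List: `table` (w_plus, mu, n_attractors, labels),
#'   `spearman_count_wplus` (rank correlation pooled over mu rows),
#'   `max_attractors`, `manifest`.
#' @export
run_parameter_census <- function(config, w_plus_values = c(1.61, 1.66),
                                 mu_values = c(5, 16, 58), n_trials = 5,
                                 bins = 40, discard = 500, window = 50,
                                 stride = 5, smooth = 1, depth = 0.5,
                                 high_rate = 15, input = NULL) {
  manifest <- list(protocol = "parameter_census", config = config,
                   w_plus_values = w_plus_values, mu_values = mu_values,
                   n_trials = n_trials, bins = bins, discard = discard,
                   window = window, stride = stride, smooth = smooth,
                   depth = depth, high_rate = high_rate,
                   package = as.character(utils::packageVersion("decisionscape")))
  rows <- list()
  for (wi in seq_along(w_plus_values)) for (mi in seq_along(mu_values)) {
    wp <- w_plus_values[wi]; mm <- mu_values[mi]
    trajs <- if (!is.null(input)) input[[wi]][[mi]] else {
      lapply(seq_len(n_trials) - 1L, function(k) {
        cfg <- network_config(
          N_E = config$N_E * config$scale, N_I = config$N_I * config$scale,
          f = config$f, w_plus = wp, v_ext = config$v_ext, dt = config$dt,
          duration = config$duration,
          seed = config$seed + 100000L * wi + 1000L * mi + k,
          scale = config$scale)
        compute_population_rates(
          run_trial(cfg, stimulus_spec(mm, 0), record = "counts",
                    count_bin = stride),
          window = window, stride = stride)
      })
    }
    land <- estimate_pss(trajs, bins = bins, discard = discard)
    att <- find_minima(land, smooth = smooth, depth = depth,
                       high_rate = high_rate)
    rows[[length(rows) + 1]] <-
      data.frame(w_plus = wp, mu = mm, n_attractors = nrow(att),
                 labels = paste(sort(att$label), collapse = "+"))
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       spearman_count_wplus = if (length(w_plus_values) > 1)
         cor(tab$w_plus, tab$n_attractors, method = "spearman") else NA_real_,
       max_attractors = max(tab$n_attractors),
       manifest = manifest)
}
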