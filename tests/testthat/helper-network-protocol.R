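# Desk-scale landscape protocol for the spiking circuit, shared by the
# acceptance checks. Scale factor 4; per-trial duration and trial count
# chosen so each parameter point gets a few hundred seconds-equivalent of
# usable samples while the whole suite stays desk-sized. Bins are widened
# to at least `aa_quanta` rate quanta (1/(N_S1 * window)) to avoid comb
# artifacts of the discrete spike-count rates.

net_bins <- function(trajs, discard, N_S1 = 60, window_s = 0.05,
                     aa_quanta = 3, max_bins = 40) {
  quant <- 1 / (N_S1 * window_s)
  xs <- unlist(lapply(trajs, function(d) d$r1[d$t > discard]))
  ys <- unlist(lapply(trajs, function(d) d$r2[d$t > discard]))
  span <- max(xs, ys) + 1
  list(bins = max(8, min(max_bins, floor(span / (aa_quanta * quant)))),
       range = list(r1 = c(0, span), r2 = c(0, span)))
}

net_trajectories <- function(w_plus, mu, seed, n_trials = 4, duration = 8,
                             scale = 4) {
  cached(sprintf("net_%s_%s_%s_%s_%s", w_plus, mu, seed, n_trials, duration), {
    cfg <- network_config(w_plus = w_plus, duration = duration, seed = seed,
                          scale = scale)
    lapply(seq_len(n_trials) - 1L, function(k) {
      c2 <- cfg
      c2$seed <- cfg$seed + k
      compute_population_rates(run_trial(c2, stimulus_spec(mu, 0),
                                         record = "counts"))
    })
  })
}

net_attractors <- function(w_plus, mu, seed, n_trials = 4, duration = 8,
                           discard = 2500) {
  trajs <- net_trajectories(w_plus, mu, seed, n_trials, duration)
  bs <- net_bins(trajs, discard)
  g <- estimate_pss(trajs, bins = bs$bins, range = bs$range,
                    discard = discard)
  list(trajs = trajs, grid = g, attractors = find_minima(g))
}

# Decision-state regions placed at the mean positions of the two decided
# quadrants (empirical "decision boundary" circles); used when kinetics are
# needed irrespective of whether the finite-sample landscape resolves the
# decision minima.
decided_regions <- function(trajs, discard = 2500, margin = 5, semi = 4) {
  xs <- unlist(lapply(trajs, function(d) d$r1[d$t > discard]))
  ys <- unlist(lapply(trajs, function(d) d$r2[d$t > discard]))
  d1 <- xs > ys + margin
  d2 <- ys > xs + margin
  att <- data.frame(label = c("DS1", "DS2"),
                    r1 = c(mean(xs[d1]), mean(xs[d2])),
                    r2 = c(mean(ys[d1]), mean(ys[d2])))
  define_regions(att, semi)
}
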