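# Shared fixtures: toy grids, hand-built trajectories, an exhaustive
# minimax-path oracle, and small cached network runs.

# landscape_grid with prescribed potential values (NA = unvisited)
toy_grid <- function(U, mid1 = seq_len(nrow(U)), mid2 = seq_len(ncol(U))) {
  P <- exp(-U)
  P[is.na(P)] <- 0
  P <- P / sum(P)
  bw1 <- if (length(mid1) > 1) diff(mid1[1:2]) else 1
  bw2 <- if (length(mid2) > 1) diff(mid2[1:2]) else 1
  structure(list(
    edges1 = c(mid1 - bw1 / 2, tail(mid1, 1) + bw1 / 2),
    edges2 = c(mid2 - bw2 / 2, tail(mid2, 1) + bw2 / 2),
    mid1 = mid1, mid2 = mid2,
    counts = ifelse(is.na(U), 0L, 1L), P = P, U = U,
    visited = !is.na(U), n = sum(!is.na(U))), class = "landscape_grid")
}

make_traj <- function(r1, r2, dt = 5) {
  rate_trajectory(data.frame(t = seq_along(r1) * dt, r1 = r1, r2 = r2),
                  window = 50, stride = dt)
}

make_raster <- function(neuron, time_ms, sizes, duration_ms) {
  structure(list(
    spikes = data.frame(neuron = neuron, time_ms = time_ms),
    population = factor(rep(names(sizes), sizes), levels = names(sizes)),
    sizes = sizes, duration_ms = duration_ms, counts = NULL,
    gating_min = 0, snmda_max = 0, config = NULL, stimulus = NULL),
    class = "spike_raster")
}

# Independent oracle: minimax saddle by exhaustive DFS over all simple
# 8-connected paths between two bins of a small grid.
brute_minimax <- function(U, a, b) {
  n1 <- nrow(U); n2 <- ncol(U)
  best <- Inf
  visited <- matrix(FALSE, n1, n2)
  rec <- function(i, j, cur) {
    cur <- max(cur, U[i, j])
    if (cur >= best) return(invisible())
    if (i == b[1] && j == b[2]) { best <<- cur; return(invisible()) }
    visited[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      if (is.na(U[ii, jj]) || visited[ii, jj]) next
      rec(ii, jj, cur)
    }
    visited[i, j] <<- FALSE
  }
  rec(a[1], a[2], -Inf)
  best
}

# Small cached network runs shared across tests (computed once per session).
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

spont_raster_s8 <- function() cached("spont_s8", {
  run_trial(network_config(duration = 1, seed = 101, scale = 8),
            record = "both")
})

# isolated-neuron config: all synaptic conductances zero, constant current
isolated_config <- function(I_nA, duration = 1, seed = 7,
                            inj_window = c(0, Inf)) {
  zero <- list(g_ext_AMPA = 0, g_rec_AMPA = 0, g_NMDA = 0, g_GABA = 0)
  network_config(N_E = 20, N_I = 5, f = 0.15, w_plus = 1, v_ext = 0,
                 duration = duration, seed = seed, I_inject = I_nA,
                 inj_window = inj_window,
                 synapse_override = list(excitatory = zero, inhibitory = zero))
}
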