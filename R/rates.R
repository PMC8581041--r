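#' Construct a rate trajectory
#'
#' The interchange container consumed by the landscape, flux and transition
#' modules: a data frame with a time column `t` (ms) and rate columns
#' (spikes/s), typically `r1` and `r2` for the two selective populations.
#'
#' @param df Data frame with columns `t`, `r1`, `r2` (and optionally
#'   `r_NS`, `r_I`).
#' @param window Counting-window length in ms (NA if not window-based).
#' @param stride Sample spacing in ms.
#' @return A `rate_trajectory` (data frame subclass).
#' @export
rate_trajectory <- function(df, window = NA_real_, stride = NA_real_) {
  stopifnot(is.data.frame(df), all(c("t", "r1", "r2") %in% names(df)))
  if (is.na(stride) && nrow(df) > 1) stride <- df$t[2] - df$t[1]
  structure(df, window = window, stride = stride,
            class = c("rate_trajectory", "data.frame"))
}

#' Population-averaged firing rates from a spike raster
#'
#' Counts the spikes of each population in a sliding time window and divides
#' by population size and window length. Windows are right-aligned: the
#' sample at time `t` summarizes the interval `(t - window, t]`. Partial
#' windows at the ends of the raster are dropped.
#'
#' @param raster A `spike_raster` from [run_trial()]. Works from the exact
#'   spike times when they were recorded, otherwise from the binned
#'   per-population counts (which requires `window` and `stride` to be
#'   multiples of the count bin).
#' @param window Window length in ms (default 50).
#' @param stride Window step in ms (default 5).
#' @return A [rate_trajectory()] with columns `t`, `r1`, `r2`, `r_NS`, `r_I`.
#' @export
compute_population_rates <- function(raster, window = 50, stride = 5) {
  stopifnot(inherits(raster, "spike_raster"), window > 0, stride > 0)
  if (raster$duration_ms <= 0) stop("zero-duration raster")
  if (raster$duration_ms < window)
    stop("raster shorter than one counting window")
  pops <- names(raster$sizes)
  t_samp <- seq(window, raster$duration_ms, by = stride)
  have_spikes <- nrow(raster$spikes) > 0 || is.null(raster$counts)
  if (have_spikes) {
    pop_of_spike <- raster$population[raster$spikes$neuron]
    cols <- lapply(pops, function(p) {
      tm <- sort(raster$spikes$time_ms[pop_of_spike == p])
      cnt <- findInterval(t_samp, tm) - findInterval(t_samp - window, tm)
      cnt / (raster$sizes[[p]] * window / 1000)
    })
  } else {
    cb <- raster$count_bin_ms
    if (window %% cb != 0 || stride %% cb != 0)
      stop("window and stride must be multiples of the count bin (", cb, " ms)")
    w <- window / cb
    n <- nrow(raster$counts)
    keep <- round((t_samp / cb))
    cols <- lapply(pops, function(p) {
      cs <- cumsum(raster$counts[, p])
      cnt <- cs[keep] - c(0, cs)[pmax(keep - w + 1, 1)]
      cnt / (raster$sizes[[p]] * window / 1000)
    })
  }
  names(cols) <- c("r1", "r2", "r_NS", "r_I")
  rate_trajectory(data.frame(t = t_samp, cols), window = window,
                  stride = stride)
}
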