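#' Write / read a rate trajectory as CSV
#'
#' Plain-text interchange format: `# key=value` comment headers carrying
#' the window and stride, then columns `t, r1, r2, ...`.
#'
#' @param traj A [rate_trajectory()].
#' @param path File path.
#' @return `write_rate_trajectory`: the path, invisibly;
#'   `read_rate_trajectory`: the trajectory.
#' @export
write_rate_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# window=", attr(traj, "window")),
               paste0("# stride=", attr(traj, "stride"))), con)
  write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_trajectory
#' @export
read_rate_trajectory <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "="))
  get_num <- function(k) {
    v <- kv[kv[, 1] == k, 2]
    if (!length(v) || v == "NA") NA_real_ else as.numeric(v)
  }
  df <- read.csv(path, comment.char = "#")
  rate_trajectory(df, window = get_num("window"), stride = get_num("stride"))
}

#' Write / read a spike raster as CSV
#'
#' Columns `neuron, time_ms`; population sizes and duration are stored in
#' `# key=value` headers so the raster (population membership included)
#' round-trips.
#'
#' @param raster A `spike_raster`.
#' @param path File path.
#' @return `write_spike_raster`: the path, invisibly; `read_spike_raster`:
#'   a `spike_raster` (simulation metadata such as the config is not
#'   persisted).
#' @export
write_spike_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sizes=", paste(names(raster$sizes),
                                        raster$sizes, sep = ":",
                                        collapse = ",")),
               paste0("# duration_ms=", raster$duration_ms)), con)
  write.csv(raster$spikes, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_raster
#' @export
read_spike_raster <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- sub("^# ", "", hdr)
  sizes_str <- sub("^sizes=", "", kv[startsWith(kv, "sizes=")])
  parts <- strsplit(strsplit(sizes_str, ",")[[1]], ":")
  sizes <- stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                           vapply(parts, `[`, "", 1))
  dur <- as.numeric(sub("^duration_ms=", "",
                        kv[startsWith(kv, "duration_ms=")]))
  spikes <- read.csv(path, comment.char = "#")
  structure(list(spikes = spikes,
                 population = factor(rep(names(sizes), sizes),
                                     levels = names(sizes)),
                 sizes = sizes, duration_ms = dur,
                 counts = NULL, gating_min = NA_real_, snmda_max = NA_real_,
                 config = NULL, stimulus = NULL),
            class = "spike_raster")
}

#' Export a landscape grid as long-format CSV
#'
#' One row per bin: indices, bin-centre coordinates, count, probability
#' and potential (`NA` on unvisited bins).
#'
#' @param grid A `landscape_grid`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_landscape <- function(grid, path) {
  stopifnot(inherits(grid, "landscape_grid"))
  n1 <- length(grid$mid1); n2 <- length(grid$mid2)
  df <- data.frame(i = rep(seq_len(n1), n2), j = rep(seq_len(n2), each = n1),
                   r1 = rep(grid$mid1, n2), r2 = rep(grid$mid2, each = n1),
                   count = as.vector(grid$counts), P = as.vector(grid$P),
                   U = as.vector(grid$U))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a flux field as quiver-style CSV
#'
#' One row per box: centre coordinates, flux vector, and block standard
#' errors when available.
#'
#' @param flux A `flux_field`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_flux <- function(flux, path) {
  stopifnot(inherits(flux, "flux_field"))
  df <- data.frame(r1 = rep(flux$mid1, flux$N2),
                   r2 = rep(flux$mid2, each = flux$N1),
                   Jx = as.vector(flux$Jx), Jy = as.vector(flux$Jy))
  if (!is.null(flux$SEx)) {
    df$SEx <- as.vector(flux$SEx)
    df$SEy <- as.vector(flux$SEy)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
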