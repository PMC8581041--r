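#' Steady-state probability and potential on the (r1, r2) plane
#'
#' Bins the pooled samples of one or more rate trajectories into a regular
#' 2D grid, normalizes to the joint probability `P_ss`, and maps the
#' potential `U = -ln(P_ss)`. `U` is defined only on visited bins; empty
#' bins are left `NA` rather than floored to a fabricated finite value.
#'
#' @param traj A [rate_trajectory()] or a list of them (pooled by
#'   concatenating samples, e.g. across trials).
#' @param bins Number of bins per axis (default 50) or length-2 vector.
#' @param range Optional list with `r1` and `r2` giving `c(lo, hi)` grid
#'   limits. Default: `[0, max + one bin]` per axis over the pooled samples.
#'   Samples outside the grid are clipped into the edge bins with a warning.
#' @param discard Initial transient to drop from every trajectory, in ms
#'   (default 0).
#' @param cols Names of the two coordinate columns (default `r1`, `r2`).
#' @return A `landscape_grid`: bin edges and midpoints, `counts`, `P`
#'   (sums to 1), `U`, logical `visited` mask, and total sample count `n`.
#' @export
estimate_pss <- function(traj, bins = 50, range = NULL, discard = 0,
                         cols = c("r1", "r2")) {
  trajs <- if (inherits(traj, "rate_trajectory") || is.data.frame(traj))
    list(traj) else traj
  stopifnot(length(trajs) >= 1)
  xs <- unlist(lapply(trajs, function(d) d[[cols[1]]][d$t > discard]))
  ys <- unlist(lapply(trajs, function(d) d[[cols[2]]][d$t > discard]))
  n <- length(xs)
  if (n < 1) stop("no samples (after discarding the transient)")
  if (length(bins) == 1) bins <- c(bins, bins)
  if (is.null(range)) {
    mk <- function(v) {
      hi <- max(v)
      lo <- min(0, min(v))
      bw <- if (hi > lo) (hi - lo) / (bins[1] - 1) else 1
      c(lo, hi + bw)
    }
    range <- list(r1 = mk(xs), r2 = mk(ys))
  }
  e1 <- seq(range$r1[1], range$r1[2], length.out = bins[1] + 1)
  e2 <- seq(range$r2[1], range$r2[2], length.out = bins[2] + 1)
  i1 <- findInterval(xs, e1, rightmost.closed = TRUE)
  i2 <- findInterval(ys, e2, rightmost.closed = TRUE)
  out_of_grid <- sum(i1 < 1 | i1 > bins[1] | i2 < 1 | i2 > bins[2])
  if (out_of_grid > 0)
    warning(out_of_grid, " samples outside the grid were clipped to edge bins")
  i1 <- pmin(pmax(i1, 1L), bins[1])
  i2 <- pmin(pmax(i2, 1L), bins[2])
  counts <- matrix(tabulate((i2 - 1L) * bins[1] + i1, nbins = bins[1] * bins[2]),
                   nrow = bins[1])
  P <- counts / n
  U <- ifelse(counts > 0, -log(P), NA_real_)
  structure(list(edges1 = e1, edges2 = e2,
                 mid1 = (e1[-1] + e1[-length(e1)]) / 2,
                 mid2 = (e2[-1] + e2[-length(e2)]) / 2,
                 counts = counts, P = P, U = U, visited = counts > 0, n = n),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat("<landscape_grid> ", length(x$mid1), "x", length(x$mid2), " bins, ",
      x$n, " samples, ", sum(x$visited), " visited bins\n", sep = "")
  invisible(x)
}

#' Relative Euclidean distance between two binned distributions
#'
#' The convergence statistic `sigma = ||P_b - P_a||_2 / ||P_a||_2` used to
#' decide whether the sampled distribution has stopped changing as the
#' trajectory is prolonged. Returned as a fraction (multiply by 100 for %).
#'
#' @param a,b Two `landscape_grid`s on identical grids.
#' @return Non-negative scalar; 0 for identical distributions.
#' @export
convergence_sigma <- function(a, b) {
  stopifnot(inherits(a, "landscape_grid"), inherits(b, "landscape_grid"))
  if (!isTRUE(all.equal(a$edges1, b$edges1)) ||
      !isTRUE(all.equal(a$edges2, b$edges2)))
    stop("grids differ: sigma requires identical bin edges")
  sqrt(sum((b$P - a$P)^2)) / sqrt(sum(a$P^2))
}

# 3x3 boxcar smoothing of U over visited bins (NA-aware, unvisited stay NA)
smooth_potential <- function(U, visited, passes = 1) {
  n1 <- nrow(U); n2 <- ncol(U)
  for (p in seq_len(passes)) {
    Upad <- matrix(NA_real_, n1 + 2, n2 + 2)
    Upad[2:(n1 + 1), 2:(n2 + 1)] <- U
    acc <- matrix(0, n1, n2); cnt <- matrix(0, n1, n2)
    for (di in -1:1) for (dj in -1:1) {
      blk <- Upad[(2 + di):(n1 + 1 + di), (2 + dj):(n2 + 1 + dj)]
      ok <- !is.na(blk)
      acc[ok] <- acc[ok] + blk[ok]
      cnt <- cnt + ok
    }
    U <- ifelse(visited & cnt > 0, acc / pmax(cnt, 1), NA_real_)
  }
  U
}

# union-find root lookup (no path compression; grids are small)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Watershed-style sweep over visited bins in order of increasing U.
# Returns the minima (bin indices) with their persistence (depth below the
# merge level at which their basin is absorbed by a deeper one), and a
# callback-ready structure for saddle queries.
sweep_basins <- function(U, visited) {
  n1 <- nrow(U); n2 <- ncol(U)
  ord <- order(U, na.last = NA)  # visited bins, ascending potential
  parent <- seq_len(n1 * n2)
  basin_min <- integer(n1 * n2)  # representative -> index of its minimum bin
  active <- logical(n1 * n2)
  minima <- integer(0)
  death <- numeric(0)    # persistence at absorption (Inf if never absorbed)
  saddle_of <- integer(0)  # bin where the absorbing merge happened
  neigh_off <- expand.grid(di = -1:1, dj = -1:1)
  neigh_off <- neigh_off[!(neigh_off$di == 0 & neigh_off$dj == 0), ]
  max_level <- numeric(n1 * n2)  # highest activated level per basin root
  for (b in ord) {
    i <- (b - 1L) %% n1 + 1L
    j <- (b - 1L) %/% n1 + 1L
    comps <- integer(0)
    for (k in seq_len(nrow(neigh_off))) {
      ii <- i + neigh_off$di[k]; jj <- j + neigh_off$dj[k]
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      nb <- (jj - 1L) * n1 + ii
      if (active[nb]) comps <- c(comps, uf_find(parent, nb))
    }
    comps <- unique(comps)
    active[b] <- TRUE
    if (length(comps) == 0) {
      # a fresh local minimum seeds a new basin
      minima <- c(minima, b)
      death <- c(death, Inf)
      saddle_of <- c(saddle_of, NA_integer_)
      basin_min[b] <- b
      max_level[b] <- U[b]
    } else {
      # attach to the deepest adjoining basin; other basins die here
      mins <- vapply(comps, function(cc) U[basin_min[cc]], numeric(1))
      winner <- comps[which.min(mins)]
      for (cc in comps) {
        if (cc != winner) {
          mb <- basin_min[cc]
          idx <- match(mb, minima)
          death[idx] <- U[b] - U[mb]
          saddle_of[idx] <- b
          parent[cc] <- winner
        }
      }
      parent[b] <- winner
      basin_min[uf_find(parent, b)] <- basin_min[winner]
      max_level[winner] <- U[b]
    }
  }
  # An unabsorbed minimum that is not the deepest point of the connected
  # region it lives in cannot exist (it would have been absorbed); but each
  # disconnected visited region contributes its own unabsorbed minimum.
  # Credit those with the relief of their region (max level - minimum), so
  # stray single-bin islands carry zero persistence; the minimum of the
  # region with the greatest relief keeps Inf (the global basin).
  unab <- which(!is.finite(death))
  if (length(unab) > 1) {
    relief <- vapply(unab, function(ix) {
      r <- uf_find(parent, minima[ix])
      max_level[r] - U[minima[ix]]
    }, numeric(1))
    keep_inf <- unab[which.max(relief)]
    for (ii in seq_along(unab))
      if (unab[ii] != keep_inf) death[unab[ii]] <- relief[ii]
  }
  list(minima = minima, persistence = death, saddle_of = saddle_of)
}

#' Locate attractor minima of the potential landscape
#'
#' Finds the local minima of `U` over the visited bins, after optional 3x3
#' boxcar smoothing, and prunes shallow minima by topographic persistence:
#' a minimum whose basin is absorbed by a deeper one at a level less than
#' `depth` above it is treated as sampling noise. Each surviving minimum is
#' labelled by position in the rate plane: `SS` (both rates low), `DS1`
#' (r1 high, r2 low), `DS2` (r2 high, r1 low), `DU` (both high).
#'
#' @param grid A `landscape_grid`.
#' @param smooth Number of smoothing passes (default 1; 0 disables).
#' @param depth Persistence threshold in dimensionless potential units
#'   (default 0.5).
#' @param high_rate Rate cutoff in spikes/s separating "low" from "high"
#'   coordinates for labelling (default 15, the conventional decision
#'   threshold for this circuit).
#' @return An `attractor_set` data frame: `label`, `r1`, `r2`, `U`,
#'   `persistence`, bin indices `i`, `j`. Zero rows if no minima survive.
#' @export
find_minima <- function(grid, smooth = 1, depth = 0.5, high_rate = 15) {
  stopifnot(inherits(grid, "landscape_grid"))
  U <- grid$U
  if (smooth > 0) U <- smooth_potential(U, grid$visited, smooth)
  sw <- sweep_basins(U, grid$visited)
  keep <- sw$persistence >= depth
  b <- sw$minima[keep]
  n1 <- nrow(U)
  i <- (b - 1L) %% n1 + 1L
  j <- (b - 1L) %/% n1 + 1L
  res <- data.frame(
    label = NA_character_,
    r1 = grid$mid1[i], r2 = grid$mid2[j],
    U = U[cbind(i, j)], persistence = sw$persistence[keep], i = i, j = j,
    stringsAsFactors = FALSE)
  if (nrow(res) > 0) {
    hi1 <- res$r1 >= high_rate; hi2 <- res$r2 >= high_rate
    res$label <- ifelse(hi1 & hi2, "DU",
                        ifelse(hi1, "DS1", ifelse(hi2, "DS2", "SS")))
    res <- res[order(res$U), ]
    dup <- duplicated(res$label)
    if (any(dup)) {
      warning("multiple minima share a position label; ",
              "keeping the label on the deepest, suffixing the rest")
      res$label[dup] <- paste0(res$label[dup], ".", seq_len(sum(dup)))
    }
    rownames(res) <- NULL
  }
  structure(res, class = c("attractor_set", "data.frame"),
            smoothed_U = U)
}

#' Minimax saddle between two minima
#'
#' The saddle value between minima `a` and `b` is the minimum over all
#' 8-connected paths through visited bins of the maximum potential along
#' the path. Computed by the sorted-bin union-find sweep (watershed), which
#' is equivalent to exhaustive path search. Unvisited bins cannot be
#' traversed.
#'
#' @param grid A `landscape_grid`.
#' @param a,b Rows of an `attractor_set` (or any list with bin indices
#'   `i`, `j`).
#' @param smooth Smoothing passes applied to `U` before the sweep; use the
#'   same value as in [find_minima()] so levels are comparable (default 1).
#' @return List with `U_saddle`, `position` (rate coordinates of the bin
#'   where the two basins meet), and `connected` (FALSE, with `U_saddle =
#'   Inf`, if the minima lie in disconnected visited regions).
#' @export
find_saddle <- function(grid, a, b, smooth = 1) {
  stopifnot(inherits(grid, "landscape_grid"))
  U <- grid$U
  if (smooth > 0) U <- smooth_potential(U, grid$visited, smooth)
  n1 <- nrow(U); n2 <- ncol(U)
  ba <- (a$j - 1L) * n1 + a$i
  bb <- (b$j - 1L) * n1 + b$i
  if (is.na(U[ba]) || is.na(U[bb])) stop("a and b must be visited bins")
  if (ba == bb)
    return(list(U_saddle = U[ba], position = c(grid$mid1[a$i], grid$mid2[a$j]),
                connected = TRUE))
  ord <- order(U, na.last = NA)
  parent <- seq_len(n1 * n2)
  active <- logical(n1 * n2)
  for (bin in ord) {
    i <- (bin - 1L) %% n1 + 1L
    j <- (bin - 1L) %/% n1 + 1L
    active[bin] <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      nb <- (jj - 1L) * n1 + ii
      if (active[nb]) {
        ra <- uf_find(parent, bin); rb <- uf_find(parent, nb)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (uf_find(parent, ba) == uf_find(parent, bb))
      return(list(U_saddle = U[bin],
                  position = c(grid$mid1[i], grid$mid2[j]), connected = TRUE))
  }
  list(U_saddle = Inf, position = c(NA_real_, NA_real_), connected = FALSE)
}

#' Barrier heights and relative barrier between two attractors
#'
#' For the transition `from -> to`, the barrier heights are
#' `BH_from = U_saddle - U_from` and `BH_to = U_saddle - U_to`, with
#' `U_saddle` the minimax saddle level between the two minima; the relative
#' barrier `RB = BH_from - BH_to` quantifies the stability of `from`
#' against `to` (positive: `from` has the deeper basin).
#'
#' @param grid A `landscape_grid`.
#' @param attractors An `attractor_set` from [find_minima()].
#' @param from,to Labels of the two attractors (e.g. `"DS1"`, `"DS2"`).
#' @param smooth Smoothing passes, as in [find_saddle()].
#' @return List with `U_from`, `U_to`, `U_saddle`, `BH_from`, `BH_to`,
#'   `RB` and the saddle `position`.
#' @export
barrier_metrics <- function(grid, attractors, from = "DS1", to = "DS2",
                            smooth = 1) {
  stopifnot(inherits(attractors, "data.frame"))
  for (lb in c(from, to))
    if (!lb %in% attractors$label)
      stop("attractor '", lb, "' not present in the attractor set")
  a <- attractors[attractors$label == from, ][1, ]
  b <- attractors[attractors$label == to, ][1, ]
  sd_ <- find_saddle(grid, a, b, smooth = smooth)
  list(U_from = a$U, U_to = b$U, U_saddle = sd_$U_saddle,
       BH_from = sd_$U_saddle - a$U, BH_to = sd_$U_saddle - b$U,
       RB = (sd_$U_saddle - a$U) - (sd_$U_saddle - b$U),
       position = sd_$position, connected = sd_$connected)
}
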