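#' Elliptical attractor regions around landscape minima
#'
#' Each attractor is represented by a small axis-aligned ellipse centred on
#' its potential minimum; a transition is complete once the trajectory
#' enters the destination ellipse.
#'
#' @param attractors An `attractor_set` from [find_minima()], or a data
#'   frame with columns `label`, `r1`, `r2`.
#' @param semi_axes Semi-axes in spikes/s: a single number (circle, applied
#'   to all regions, default 5), a length-2 vector, or a named list per
#'   label.
#' @return List of `attractor_region` objects (fields `label`, `center`,
#'   `semi`). Overlapping ellipses are rejected.
#' @export
define_regions <- function(attractors, semi_axes = 5) {
  stopifnot(nrow(attractors) >= 1)
  get_semi <- function(lb) {
    s <- if (is.list(semi_axes)) semi_axes[[lb]] else semi_axes
    if (length(s) == 1) s <- c(s, s)
    stopifnot(all(s > 0))
    s
  }
  regs <- lapply(seq_len(nrow(attractors)), function(k) {
    structure(list(label = attractors$label[k],
                   center = c(attractors$r1[k], attractors$r2[k]),
                   semi = get_semi(attractors$label[k])),
              class = "attractor_region")
  })
  if (length(regs) > 1) {
    for (a in seq_len(length(regs) - 1)) for (b in (a + 1):length(regs)) {
      d <- regs[[b]]$center - regs[[a]]$center
      dist <- sqrt(sum(d^2))
      if (dist < 1e-12) stop("coincident attractor centres")
      u <- d / dist
      ra <- sqrt(sum((regs[[a]]$semi * u)^2))
      rb <- sqrt(sum((regs[[b]]$semi * u)^2))
      if (dist <= ra + rb)
        stop("attractor regions '", regs[[a]]$label, "' and '",
             regs[[b]]$label, "' overlap; use smaller semi-axes")
    }
  }
  names(regs) <- attractors$label
  regs
}

#' Is a point inside an attractor region?
#' @param region An `attractor_region`.
#' @param x,y Coordinates (vectorized).
#' @return Logical vector.
#' @export
inside_region <- function(region, x, y) {
  ((x - region$center[1]) / region$semi[1])^2 +
    ((y - region$center[2]) / region$semi[2])^2 <= 1
}

#' First-passage times between two attractor regions
#'
#' The clock arms when the trajectory is inside the source region; a
#' first-passage sample is recorded at the first subsequent entry into the
#' destination region, and the clock re-arms at the next visit to the
#' source. The mean first-passage time (MFPT) is the arithmetic mean of the
#' samples. Observation windows that end mid-transition are dropped
#' (censored); a note is attached when more than 10% of windows are
#' censored.
#'
#' @param traj A [rate_trajectory()] or a list of them (trials); clocks
#'   never run across trajectory boundaries.
#' @param from,to `attractor_region`s.
#' @return An `fpt_result`: `samples` (seconds), `K`, `MFPT` (s; `NA` when
#'   `K = 0`), `se`, `n_censored`.
#' @export
first_passage_times <- function(traj, from, to) {
  trajs <- if (is.data.frame(traj)) list(traj) else traj
  samples <- numeric(0)
  n_censored <- 0L
  for (d in trajs) {
    in_from <- inside_region(from, d$r1, d$r2)
    in_to <- inside_region(to, d$r1, d$r2)
    armed <- FALSE
    t0 <- NA_real_
    for (k in seq_len(nrow(d))) {
      if (!armed && in_from[k]) { armed <- TRUE; t0 <- d$t[k] }
      else if (armed && in_to[k]) {
        samples <- c(samples, (d$t[k] - t0) / 1000)
        armed <- FALSE
      }
    }
    if (armed) n_censored <- n_censored + 1L
  }
  K <- length(samples)
  res <- list(samples = samples, K = K,
              MFPT = if (K > 0) mean(samples) else NA_real_,
              se = if (K > 1) sd(samples) / sqrt(K) else NA_real_,
              n_censored = n_censored,
              from = from$label, to = to$label)
  if (n_censored > 0.1 * (K + n_censored))
    res$note <- "more than 10% of observation windows censored; MFPT is biased low"
  structure(res, class = "fpt_result")
}

#' @export
print.fpt_result <- function(x, ...) {
  cat("<fpt_result> ", x$from, " -> ", x$to, ": K = ", x$K,
      ", MFPT = ", signif(x$MFPT, 4), " s (se ", signif(x$se, 3), "), ",
      x$n_censored, " censored\n", sep = "")
  invisible(x)
}

#' Extract raw transition paths between two attractor regions
#'
#' A transition path runs from the last trajectory point inside the source
#' region before leaving it for good, to the first point inside the
#' destination region; excursions that return to the source region restart
#' the path from the new exit.
#'
#' @inheritParams first_passage_times
#' @return A `transition_path_set`: `paths` (list of data frames with
#'   columns `t`, `r1`, `r2`), `from`, `to` labels; possibly empty.
#' @export
extract_transition_paths <- function(traj, from, to) {
  trajs <- if (is.data.frame(traj)) list(traj) else traj
  paths <- list()
  for (d in trajs) {
    in_from <- inside_region(from, d$r1, d$r2)
    in_to <- inside_region(to, d$r1, d$r2)
    last_from <- NA_integer_
    for (k in seq_len(nrow(d))) {
      if (in_from[k]) last_from <- k
      else if (in_to[k] && !is.na(last_from)) {
        paths[[length(paths) + 1]] <-
          data.frame(t = d$t[last_from:k] - d$t[last_from],
                     r1 = d$r1[last_from:k], r2 = d$r2[last_from:k])
        last_from <- NA_integer_
      }
    }
  }
  structure(list(paths = paths, K = length(paths),
                 from = from$label, to = to$label, psi = NULL),
            class = "transition_path_set")
}

#' @export
print.transition_path_set <- function(x, ...) {
  cat("<transition_path_set> ", x$from, " -> ", x$to, ": K = ", x$K,
      if (!is.null(x$psi)) paste0(", averaged over ", nrow(x$psi), " points"),
      "\n", sep = "")
  invisible(x)
}

#' Average transition path
#'
#' Raw transition paths have diverse durations, so each path is first
#' resampled to `n_points` by even interpolation along its sample index,
#' and the average path is the pointwise mean of the resampled paths.
#'
#' @param pathset A `transition_path_set` with `K >= 1`.
#' @param n_points Number of points of the average path (default 100).
#' @return The path set with `psi` (data frame `r1`, `r2`), pointwise
#'   standard errors `se_r1`, `se_r2`, and the resampled paths array
#'   `resampled` (`n_points x 2 x K`).
#' @export
average_path <- function(pathset, n_points = 100) {
  stopifnot(inherits(pathset, "transition_path_set"))
  if (pathset$K < 1) stop("no transition paths to average")
  res <- array(NA_real_, c(n_points, 2, pathset$K))
  for (k in seq_len(pathset$K)) {
    p <- pathset$paths[[k]]
    m <- nrow(p)
    if (m == 1) {
      res[, 1, k] <- p$r1; res[, 2, k] <- p$r2
    } else {
      at <- seq(1, m, length.out = n_points)
      res[, 1, k] <- approx(seq_len(m), p$r1, xout = at)$y
      res[, 2, k] <- approx(seq_len(m), p$r2, xout = at)$y
    }
  }
  pathset$resampled <- res
  pathset$psi <- data.frame(r1 = apply(res[, 1, , drop = FALSE], 1, mean),
                            r2 = apply(res[, 2, , drop = FALSE], 1, mean))
  pathset$se_r1 <- apply(res[, 1, , drop = FALSE], 1, sd) / sqrt(pathset$K)
  pathset$se_r2 <- apply(res[, 2, , drop = FALSE], 1, sd) / sqrt(pathset$K)
  pathset$n_points <- n_points
  pathset
}

#' Time-reverse a trajectory
#'
#' Utility for irreversibility checks: reverses the sample order (and
#' re-labels times to keep them increasing).
#'
#' @param traj A [rate_trajectory()].
#' @return The reversed trajectory.
#' @export
reverse_trajectory <- function(traj) {
  n <- nrow(traj)
  out <- traj[n:1, , drop = FALSE]
  out$t <- traj$t[1] + (traj$t[n] - rev(traj$t))
  rownames(out) <- NULL
  rate_trajectory(as.data.frame(out), window = attr(traj, "window"),
                  stride = attr(traj, "stride"))
}
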