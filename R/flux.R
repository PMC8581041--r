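#' Coarse-grain a trajectory onto a rectangular box grid
#'
#' Divides the (r1, r2) subspace into `N1 x N2` equally sized rectangular
#' boxes (discrete states) and assigns every trajectory sample to a box.
#' Samples outside the domain are clipped into the edge boxes with a
#' warning.
#'
#' @param traj A [rate_trajectory()].
#' @param N1,N2 Number of boxes per axis (default 20), both >= 2.
#' @param domain Optional list with `r1`, `r2` limits `c(lo, hi)`; default
#'   `[0, max + tiny]` per axis.
#' @return List of class `coarse_trajectory`: per-sample box indices
#'   (`i1`, `i2`), the sample coordinates, times, and the box grid spec.
#' @export
coarse_grain <- function(traj, N1 = 20, N2 = 20, domain = NULL) {
  stopifnot(N1 >= 2, N2 >= 2)
  if (nrow(traj) == 0) stop("empty trajectory")
  x <- traj$r1; y <- traj$r2
  if (is.null(domain)) {
    eps <- 1e-9
    domain <- list(r1 = c(min(0, min(x)), max(x) * (1 + eps) + eps),
                   r2 = c(min(0, min(y)), max(y) * (1 + eps) + eps))
  }
  e1 <- seq(domain$r1[1], domain$r1[2], length.out = N1 + 1)
  e2 <- seq(domain$r2[1], domain$r2[2], length.out = N2 + 1)
  i1 <- findInterval(x, e1, rightmost.closed = TRUE)
  i2 <- findInterval(y, e2, rightmost.closed = TRUE)
  n_out <- sum(i1 < 1 | i1 > N1 | i2 < 1 | i2 > N2)
  if (n_out > 0)
    warning(n_out, " samples outside the domain were clipped to edge boxes")
  structure(list(i1 = pmin(pmax(i1, 1L), N1), i2 = pmin(pmax(i2, 1L), N2),
                 x = x, y = y, t = traj$t, edges1 = e1, edges2 = e2,
                 mid1 = (e1[-1] + e1[-length(e1)]) / 2,
                 mid2 = (e2[-1] + e2[-length(e2)]) / 2,
                 N1 = N1, N2 = N2),
            class = "coarse_trajectory")
}

#' Count directed face crossings between adjacent boxes
#'
#' For every consecutive sample pair lying in different boxes, the straight
#' segment between the two points is traced and each crossed box face
#' increments the corresponding directed tally, ordered by the parametric
#' crossing position along the segment, so multi-box jumps are linearly
#' interpolated into chains of adjacent-box transitions.
#'
#' @param cg A `coarse_trajectory` from [coarse_grain()].
#' @return List of four tally matrices: `xp`, `xm` (crossings of vertical
#'   faces in +r1 / -r1 direction, dim `(N1-1) x N2`) and `yp`, `ym`
#'   (horizontal faces, dim `N1 x (N2-1)`).
#' @export
count_transitions <- function(cg) {
  stopifnot(inherits(cg, "coarse_trajectory"))
  N1 <- cg$N1; N2 <- cg$N2
  xp <- matrix(0L, N1 - 1, N2); xm <- matrix(0L, N1 - 1, N2)
  yp <- matrix(0L, N1, N2 - 1); ym <- matrix(0L, N1, N2 - 1)
  n <- length(cg$i1)
  if (n < 2) return(list(xp = xp, xm = xm, yp = yp, ym = ym))
  moved <- which(cg$i1[-1] != cg$i1[-n] | cg$i2[-1] != cg$i2[-n])
  for (k in moved) {
    x0 <- cg$x[k]; y0 <- cg$y[k]; x1 <- cg$x[k + 1]; y1 <- cg$y[k + 1]
    ci <- cg$i1[k]; cj <- cg$i2[k]
    # parametric positions of grid-line crossings along the segment
    tx <- numeric(0); sx <- integer(0)
    if (cg$i1[k + 1] != ci) {
      s <- sign(cg$i1[k + 1] - ci)
      lines_ <- if (s > 0) cg$edges1[(ci + 1):cg$i1[k + 1]]
                else cg$edges1[ci:(cg$i1[k + 1] + 1)]
      tx <- (lines_ - x0) / (x1 - x0)
      sx <- rep(s, length(tx))
    }
    ty <- numeric(0); sy <- integer(0)
    if (cg$i2[k + 1] != cj) {
      s <- sign(cg$i2[k + 1] - cj)
      lines_ <- if (s > 0) cg$edges2[(cj + 1):cg$i2[k + 1]]
                else cg$edges2[cj:(cg$i2[k + 1] + 1)]
      ty <- (lines_ - y0) / (y1 - y0)
      sy <- rep(s, length(ty))
    }
    ord <- order(c(tx, ty))
    ax <- c(rep(1L, length(tx)), rep(2L, length(ty)))[ord]
    ss <- c(sx, sy)[ord]
    for (m in seq_along(ord)) {
      if (ax[m] == 1L) {
        face <- if (ss[m] > 0) ci else ci - 1L
        if (face >= 1 && face <= N1 - 1) {
          if (ss[m] > 0) xp[face, cj] <- xp[face, cj] + 1L
          else xm[face, cj] <- xm[face, cj] + 1L
        }
        ci <- ci + ss[m]
      } else {
        face <- if (ss[m] > 0) cj else cj - 1L
        if (face >= 1 && face <= N2 - 1) {
          if (ss[m] > 0) yp[ci, face] <- yp[ci, face] + 1L
          else ym[ci, face] <- ym[ci, face] + 1L
        }
        cj <- cj + ss[m]
      }
    }
  }
  list(xp = xp, xm = xm, yp = yp, ym = ym)
}

#' Probability flux field from directed transition tallies
#'
#' Net signed transition rates across each box face,
#' `w = (N_forward - N_backward) / t_total`, and the per-box flux vector
#' `J`, the average of the net rates across the two faces of the box in
#' each direction. Rates across the domain boundary are zero.
#'
#' @param tallies Face tallies from [count_transitions()].
#' @param t_total Total trajectory time in seconds.
#' @param cg The `coarse_trajectory` (for the grid geometry).
#' @return A `flux_field`: `wx` (`(N1-1) x N2`), `wy` (`N1 x (N2-1)`)
#'   net rates (1/s), and box-centre flux components `Jx`, `Jy`
#'   (`N1 x N2`), plus grid midpoints.
#' @export
flux_field <- function(tallies, t_total, cg) {
  stopifnot(t_total > 0)
  N1 <- cg$N1; N2 <- cg$N2
  wx <- (tallies$xp - tallies$xm) / t_total
  wy <- (tallies$yp - tallies$ym) / t_total
  padx <- rbind(rep(0, N2), wx, rep(0, N2))        # (N1+1) x N2 faces
  pady <- cbind(rep(0, N1), wy, rep(0, N1))        # N1 x (N2+1)
  Jx <- (padx[1:N1, , drop = FALSE] + padx[2:(N1 + 1), , drop = FALSE]) / 2
  Jy <- (pady[, 1:N2, drop = FALSE] + pady[, 2:(N2 + 1), drop = FALSE]) / 2
  structure(list(wx = wx, wy = wy, Jx = Jx, Jy = Jy,
                 mid1 = cg$mid1, mid2 = cg$mid2, N1 = N1, N2 = N2,
                 t_total = t_total, tallies = tallies),
            class = "flux_field")
}

#' Estimate the flux field of a trajectory, with block standard errors
#'
#' Convenience wrapper: coarse-grains, counts interpolated face crossings,
#' forms the flux field, and estimates per-box standard errors of `J` by
#' splitting the trajectory into contiguous blocks and taking the
#' across-block dispersion of the block-wise flux estimates.
#'
#' @param traj A [rate_trajectory()] or a list of them (flux tallies are
#'   accumulated per trajectory and pooled; segments never span
#'   trajectory boundaries).
#' @param N1,N2 Boxes per axis (default 20).
#' @param domain Optional domain, as in [coarse_grain()].
#' @param n_blocks Number of contiguous blocks for the standard errors
#'   (default 10; 0 disables).
#' @return A `flux_field` with additional matrices `SEx`, `SEy`.
#' @export
estimate_flux <- function(traj, N1 = 20, N2 = 20, domain = NULL,
                          n_blocks = 10) {
  trajs <- if (is.data.frame(traj)) list(traj) else traj
  if (is.null(domain)) {
    x <- unlist(lapply(trajs, `[[`, "r1")); y <- unlist(lapply(trajs, `[[`, "r2"))
    eps <- 1e-9
    domain <- list(r1 = c(min(0, min(x)), max(x) * (1 + eps) + eps),
                   r2 = c(min(0, min(y)), max(y) * (1 + eps) + eps))
  }
  cgs <- lapply(trajs, coarse_grain, N1 = N1, N2 = N2, domain = domain)
  tals <- lapply(cgs, count_transitions)
  add <- function(a, b) Map(`+`, a, b)
  tot <- Reduce(add, tals)
  span_s <- sum(vapply(trajs, function(d) diff(range(d$t)), numeric(1))) / 1000
  ff <- flux_field(tot, span_s, cgs[[1]])
  if (n_blocks > 1) {
    # split each trajectory into contiguous chunks; pool chunks into blocks
    blocks <- vector("list", n_blocks)
    for (ti in seq_along(trajs)) {
      n <- nrow(trajs[[ti]])
      brk <- floor(seq(0, n, length.out = n_blocks + 1))
      for (bi in seq_len(n_blocks)) {
        idx <- (brk[bi] + 1):brk[bi + 1]
        if (length(idx) < 2) next
        sub <- trajs[[ti]][idx, ]
        cgb <- coarse_grain(sub, N1, N2, domain)
        tb <- count_transitions(cgb)
        fb <- flux_field(tb, diff(range(sub$t)) / 1000, cgb)
        blocks[[bi]] <- if (is.null(blocks[[bi]])) list(fb)
                        else c(blocks[[bi]], list(fb))
      }
    }
    blocks <- Filter(Negate(is.null), blocks)
    nb <- length(blocks)
    mean_J <- function(b, comp)
      Reduce(`+`, lapply(b, `[[`, comp)) / length(b)
    Jxs <- simplify2array(lapply(blocks, mean_J, "Jx"))
    Jys <- simplify2array(lapply(blocks, mean_J, "Jy"))
    ff$SEx <- apply(Jxs, c(1, 2), sd) / sqrt(nb)
    ff$SEy <- apply(Jys, c(1, 2), sd) / sqrt(nb)
    ff$n_blocks <- nb
  }
  ff
}

#' Sign of circulation of the flux field around a centre
#'
#' For each box above the noise floor, evaluates the angular component of
#' `J` about `center` (the z-component of `(x - center) x J`). Used to test
#' whether the flux circulates in a consistent sense, e.g. around an
#' attractor or in a rotational surrogate with known sense.
#'
#' @param flux A `flux_field` from [estimate_flux()] (needs `SEx`/`SEy`
#'   when `noise_mult > 0`).
#' @param center Length-2 centre of rotation (default: domain centre).
#' @param noise_mult Boxes with `|J|` below `noise_mult` times the block
#'   standard error of `|J|` are excluded (default 2).
#' @return List: `n_boxes` considered, `frac_positive` (fraction with
#'   counter-clockwise angular component), `mean_cross` (mean angular
#'   component), `frac_sign` of the majority sense.
#' @export
curl_direction <- function(flux, center = NULL, noise_mult = 2) {
  stopifnot(inherits(flux, "flux_field"))
  if (is.null(center)) center <- c(mean(flux$mid1), mean(flux$mid2))
  rx <- outer(flux$mid1 - center[1], rep(1, flux$N2))
  ry <- outer(rep(1, flux$N1), flux$mid2 - center[2])
  cross <- rx * flux$Jy - ry * flux$Jx
  Jmag <- sqrt(flux$Jx^2 + flux$Jy^2)
  keep <- Jmag > 0
  if (noise_mult > 0 && !is.null(flux$SEx)) {
    noise <- noise_mult * sqrt(flux$SEx^2 + flux$SEy^2)
    keep <- Jmag > noise & noise > 0
  }
  n <- sum(keep)
  fp <- if (n > 0) mean(cross[keep] > 0) else NA_real_
  list(n_boxes = n, frac_positive = fp,
       mean_cross = if (n > 0) mean(cross[keep]) else NA_real_,
       frac_sign = if (n > 0) max(fp, 1 - fp) else NA_real_)
}
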