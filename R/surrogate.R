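#' Specification of a 2D Langevin surrogate
#'
#' Three stochastic test systems with known stationary laws, used to
#' validate the landscape, flux and first-passage estimators:
#' \describe{
#'   \item{double_well}{gradient drift of `V = a (x^2 - 1)^2 + h x + b y^2`
#'     (`h` tilts the two wells apart): bistable, zero stationary flux
#'     (detailed balance).}
#'   \item{triple_well}{gradient drift of three Gaussian wells plus a weak
#'     harmonic confinement: tristable, zero stationary flux.}
#'   \item{linear_rotational}{linear drift `-k x - w y, w x - k y`
#'     (stable spiral): Gaussian stationary law with covariance `(D/k) I`
#'     and a purely rotational flux `J = w (-y, x) p_ss`, counter-clockwise
#'     for `w > 0`.}
#' }
#' Trajectories are integrated by Euler-Maruyama with noise `sqrt(2 D)` and
#' emitted in the same positive-range units and container as network rate
#' trajectories (`x_out = origin + scale * x`), so all downstream analysis
#' consumes them unchanged.
#'
#' @param family One of `"double_well"`, `"triple_well"`,
#'   `"linear_rotational"`.
#' @param D Noise intensity (> 0).
#' @param dt Integration step (ms).
#' @param duration Total simulated time (ms).
#' @param seed Integer seed (deterministic trajectories).
#' @param params Named list of drift parameters; defaults per family:
#'   double_well `a = 1, b = 1, h = 0`; triple_well `A = 1.5, s = 0.45,
#'   conf = 0.8, wells` (3x2 matrix), `conf_center`; linear_rotational
#'   `k = 1, omega = 1`.
#' @param origin,scale Affine map into rate-like units (defaults
#'   `c(20, 20)` and 8; use `c(0, 0)` and 1 for analytic work in natural
#'   coordinates).
#' @param sample_stride Keep every `sample_stride`-th step (default 10).
#' @param x0 Initial point in natural coordinates (default: first well /
#'   the fixed point).
#' @return A `langevin_spec`.
#' @export
langevin_spec <- function(family = c("double_well", "triple_well",
                                     "linear_rotational"),
                          D = 0.25, dt = 0.01, duration = 1000, seed = 1,
                          params = list(), origin = c(20, 20), scale = 8,
                          sample_stride = 10, x0 = NULL) {
  family <- match.arg(family)
  stopifnot(D > 0, dt > 0, duration > dt)
  def <- switch(family,
    double_well = list(a = 1, b = 1, h = 0),
    triple_well = list(A = 1.5, s = 0.45, conf = 0.8,
                       wells = matrix(c(0, 0, 1.4, 0, 0, 1.4), 3, 2,
                                      byrow = TRUE),
                       conf_center = c(0.45, 0.45)),
    linear_rotational = list(k = 1, omega = 1))
  def[names(params)] <- params
  if (family == "linear_rotational") stopifnot(def$k > 0)
  if (is.null(x0))
    x0 <- switch(family, double_well = c(-1, 0), triple_well = c(0, 0),
                 linear_rotational = c(0, 0))
  structure(list(family = family, D = D, dt = dt, duration = duration,
                 seed = as.integer(seed), params = def, origin = origin,
                 scale = scale, sample_stride = as.integer(sample_stride),
                 x0 = x0),
            class = "langevin_spec")
}

spec_par_vector <- function(spec) {
  p <- spec$params
  switch(spec$family,
         double_well = c(p$a, p$b, p$h),
         triple_well = c(p$A, p$s, p$conf,
                         p$wells[1, 1], p$wells[1, 2], p$wells[2, 1],
                         p$wells[2, 2], p$wells[3, 1], p$wells[3, 2],
                         p$conf_center[1], p$conf_center[2]),
         linear_rotational = c(p$k, p$omega))
}

family_id <- function(family)
  match(family, c("double_well", "triple_well", "linear_rotational"))

#' Simulate a Langevin surrogate trajectory
#'
#' @param spec A [langevin_spec()].
#' @return A [rate_trajectory()] with columns `t` (ms), `r1`, `r2`
#'   (affine-mapped coordinates); deterministic given `spec$seed`.
#' @export
simulate_langevin <- function(spec) {
  stopifnot(inherits(spec, "langevin_spec"))
  res <- sim_langevin_cpp(family_id(spec$family), spec_par_vector(spec),
                          spec$D, spec$dt, spec$duration, spec$sample_stride,
                          spec$x0, spec$seed)
  rate_trajectory(
    data.frame(t = res$t,
               r1 = spec$origin[1] + spec$scale * res$x,
               r2 = spec$origin[2] + spec$scale * res$y),
    window = NA_real_, stride = spec$dt * spec$sample_stride)
}

#' Potential of a gradient surrogate in natural coordinates
#'
#' @param spec A [langevin_spec()] of a gradient family.
#' @param x,y Coordinates (vectorized, natural units).
#' @return Potential values `V(x, y)`.
#' @export
surrogate_potential <- function(spec, x, y) {
  p <- spec$params
  switch(spec$family,
    double_well = p$a * (x^2 - 1)^2 + p$h * x + p$b * y^2,
    triple_well = {
      v <- p$conf / 2 * ((x - p$conf_center[1])^2 + (y - p$conf_center[2])^2)
      for (w in seq_len(nrow(p$wells)))
        v <- v - p$A * exp(-((x - p$wells[w, 1])^2 + (y - p$wells[w, 2])^2) /
                             (2 * p$s^2))
      v
    },
    linear_rotational = p$k * (x^2 + y^2) / 2)
}

#' Analytic references for a surrogate
#'
#' Known stationary density, stationary flux and (for the double well)
#' quadrature first-passage references, against which the trajectory-based
#' estimators are validated.
#'
#' For gradient families the stationary density is the Boltzmann form
#' `p ~ exp(-V/D)` (normalized over the requested grid) and the stationary
#' flux is identically zero. For the rotational family the stationary law
#' is Gaussian with covariance `(D/k) I` and the flux is
#' `J = omega (-y, x) p_ss`: divergence-free, circulating
#' counter-clockwise for `omega > 0`.
#'
#' @param spec A [langevin_spec()].
#' @param grid_mid1,grid_mid2 Optional box-centre coordinates (trajectory
#'   units) on which to evaluate the references.
#' @return List with `family`, `flux_zero` (logical), `cov` (2x2 stationary
#'   covariance, rotational/linear only, natural units), and when a grid is
#'   supplied: `P` (normalized density per box), `U = -ln P`, `Jx`, `Jy`
#'   (flux direction field in trajectory units).
#' @export
analytic_references <- function(spec, grid_mid1 = NULL, grid_mid2 = NULL) {
  stopifnot(inherits(spec, "langevin_spec"))
  out <- list(family = spec$family,
              flux_zero = spec$family != "linear_rotational")
  if (spec$family == "linear_rotational")
    out$cov <- diag(spec$D / spec$params$k, 2)
  if (!is.null(grid_mid1)) {
    # natural coordinates of the box centres
    nx <- (grid_mid1 - spec$origin[1]) / spec$scale
    ny <- (grid_mid2 - spec$origin[2]) / spec$scale
    X <- outer(nx, rep(1, length(ny)))
    Y <- outer(rep(1, length(nx)), ny)
    if (spec$family == "linear_rotational") {
      s2 <- spec$D / spec$params$k
      dens <- exp(-(X^2 + Y^2) / (2 * s2))
    } else {
      dens <- exp(-surrogate_potential(spec, X, Y) / spec$D)
    }
    out$P <- dens / sum(dens)
    out$U <- -log(out$P)
    if (spec$family == "linear_rotational") {
      om <- spec$params$omega
      out$Jx <- -om * Y * out$P
      out$Jy <- om * X * out$P
    } else {
      out$Jx <- 0 * X
      out$Jy <- 0 * X
    }
  }
  out
}

#' Quadrature mean first-passage time for the 1D double well
#'
#' For the overdamped 1D dynamics `dx = -V'(x) dt + sqrt(2 D) dW` with
#' `V = a (x^2 - 1)^2 + h x`, the mean time to first reach `x_to` starting from
#' `x_from < x_to` is the classical double integral
#' `T = (1/D) int_{x_from}^{x_to} exp(V(y)/D) int_{-inf}^{y} exp(-V(z)/D) dz dy`,
#' evaluated here by trapezoidal quadrature on a fine grid (the lower limit
#' is truncated where the integrand is negligible).
#'
#' The `y` dimension of the 2D double-well surrogate is an independent OU
#' coordinate, so with slab-like destination regions (large `r2`
#' semi-axis) the 2D first-passage problem reduces to this 1D form.
#'
#' @param spec A double-well [langevin_spec()].
#' @param x_from,x_to Start point and absorbing point, natural units.
#' @param n_quad Quadrature points per dimension (default 2000).
#' @return MFPT in the time units of `spec` (ms).
#' @export
mfpt_quadrature <- function(spec, x_from = -1, x_to = 0.7, n_quad = 2000) {
  stopifnot(spec$family == "double_well", x_from < x_to)
  a <- spec$params$a; h <- spec$params$h; D <- spec$D
  V <- function(x) a * (x^2 - 1)^2 + h * x
  lo <- -3.5  # exp(-V/D) negligible below
  zs <- seq(lo, x_to, length.out = n_quad)
  dz <- zs[2] - zs[1]
  inner_cum <- cumsum(exp(-V(zs) / D)) * dz  # int_{lo}^{y} exp(-V/D) dz
  ys <- seq(x_from, x_to, length.out = n_quad)
  dy <- ys[2] - ys[1]
  inner_at_y <- approx(zs, inner_cum, xout = ys, rule = 2)$y
  integrand <- exp(V(ys) / D) * inner_at_y
  sum((integrand[-1] + integrand[-n_quad]) / 2) * dy / D
}
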