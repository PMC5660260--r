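#' Binned velocity profile across the channel
#'
#' Mean axial velocity per wall-normal bin, averaged over all snapshots of
#' the fluid particles. The mean velocity is the area-weighted (equal-bin)
#' mean of the profile, and the pseudo-shear rate is `gamma_bar = vbar / W`.
#'
#' @param traj a [trajectory()] with recorded velocities (>= 10 snapshots).
#' @param n_bins number of bins across the width.
#' @param species particle species entering the profile (default fluid).
#' @return object of class `flow_field`: data frame `profile` (`y`, `vx`,
#'   `n`), plus `vbar`, `gamma_bar`, `W`, `n_frames`.
#' @export
velocity_profile <- function(traj, n_bins = 100L, species = "fluid") {
  if (is.null(traj$vel) || length(traj$vel) == 0)
    stop("trajectory has no recorded velocities")
  if (n_frames(traj) < 10L)
    warning("fewer than 10 snapshots; profile may be noisy")
  W <- traj$box$width_W
  keep <- traj$species %in% species_code(species)
  breaks <- seq(0, W, length.out = n_bins + 1L)
  y <- as.vector(traj$pos[keep, 2, ])
  vx <- as.vector(traj$vel[keep, 1, ])
  bin <- findInterval(y, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  sums <- tapply(vx, factor(bin, levels = seq_len(n_bins)), sum)
  cnts <- tabulate(bin, nbins = n_bins)
  v <- ifelse(cnts > 0, as.numeric(sums) / cnts, NA_real_)
  if (anyNA(v)) {
    warning("empty velocity bins; merged-bin fallback (NA bins dropped from vbar)")
  }
  centers <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  vbar <- mean(v, na.rm = TRUE)
  structure(list(profile = data.frame(y = centers, vx = v, n = cnts),
                 vbar = vbar, gamma_bar = vbar / W, W = W,
                 n_frames = n_frames(traj)),
            class = "flow_field")
}

#' Construct a flow field from an explicit profile
#'
#' Mostly for tests and synthetic data: wraps a `(y, vx)` profile into the
#' same `flow_field` object that [velocity_profile()] returns.
#'
#' @param y bin centres; `vx` mean axial velocities; `W` channel width.
#' @export
flow_field <- function(y, vx, W) {
  vbar <- mean(vx)
  structure(list(profile = data.frame(y = y, vx = vx, n = NA_integer_),
                 vbar = vbar, gamma_bar = vbar / W, W = W, n_frames = NA),
            class = "flow_field")
}

#' Wall shear rate from a velocity profile
#'
#' Fits the near-wall velocity profile over a window (default the first
#' 1 um from each wall, excluding the bin adjacent to the wall) and returns
#' the velocity gradient at the wall, averaged over both walls.
#'
#' The default `"quadratic"` method fits a local parabola over a window
#' offset away from the wall and evaluates its derivative at the wall
#' plane; this is exact for parabolic (Newtonian Poiseuille) flow and
#' insensitive to the thin near-wall layer where particle walls distort
#' the binned profile. `"linear"` fits a straight line through the first
#' 1 um (excluding the wall-adjacent bin); for a curved profile its slope
#' estimates the gradient at the window centre rather than at the wall,
#' biasing the Newtonian `gamma_w / gamma_bar` ratio low by about
#' `2 ybar / W`.
#'
#' @param field a `flow_field`.
#' @param window fit window depth (micrometres); default 2 for
#'   `"quadratic"`, 1 for `"linear"`.
#' @param offset distance from the wall excluded from the fit; default
#'   0.5 um for `"quadratic"`, the wall-adjacent bin for `"linear"`.
#' @param method `"quadratic"` or `"linear"`.
#' @return list with `gamma_w` (mean of both walls), `per_wall`, `method`.
#' @export
wall_shear_rate <- function(field, window = NULL, offset = NULL,
                            method = c("quadratic", "linear")) {
  method <- match.arg(method)
  pr <- field$profile
  dy <- diff(pr$y[1:2])
  if (is.null(window)) window <- if (method == "quadratic") 2 else 1
  if (is.null(offset)) offset <- if (method == "quadratic") 0.5 else dy
  fit_one <- function(yw) {        # yw: distance from this wall
    keep <- is.finite(pr$vx) & yw <= offset + window & yw >= offset
    if (sum(keep) < 4L) stop("wall-shear fit window contains fewer than 4 bins")
    yy <- yw[keep]; vv <- pr$vx[keep]
    if (method == "linear") {
      unname(coef(lm(vv ~ yy))[2])
    } else {
      unname(coef(lm(vv ~ yy + I(yy^2)))[2])  # dv/dy at the wall
    }
  }
  lo <- fit_one(pr$y)                 # lower wall: distance = y
  hi <- fit_one(field$W - pr$y)       # upper wall: distance = W - y
  res <- c(lower = lo, upper = hi)
  # per-wall slopes are signed (velocity vs distance from that wall);
  # the scalar wall shear rate is the mean gradient magnitude
  list(gamma_w = mean(abs(res)), per_wall = res, method = method)
}

#' Newtonian Poiseuille reference
#'
#' Analytic parabolic profile and the exact ratio of wall shear rate to
#' pseudo-shear rate (`gamma_bar = vbar / W`, W the slit width or the tube
#' diameter): 6 for a 2D slit, 8 for a 3D tube; the equality holds only for
#' a parabolic Newtonian flow, suspensions push the ratio higher.
#'
#' @param geometry `"slit"` or `"tube"`.
#' @param v_mean,v_max supply one of the two to scale the profile
#'   (`v_mean / v_max` is 2/3 for a slit, 1/2 for a tube).
#' @return list with `ratio`, `v_mean`, `v_max` and `profile(y, W)`
#'   (position measured across the slit, or radially for a tube).
#' @export
poiseuille_reference <- function(geometry = c("slit", "tube"),
                                 v_mean = NULL, v_max = NULL) {
  geometry <- match.arg(geometry)
  frac <- if (geometry == "slit") 2 / 3 else 1 / 2
  if (is.null(v_max) && is.null(v_mean)) v_max <- 1
  if (is.null(v_max)) v_max <- v_mean / frac
  v_mean <- v_max * frac
  profile <- if (geometry == "slit") {
    function(y, W) 4 * v_max * (y / W) * (1 - y / W)
  } else {
    function(r, W) v_max * (1 - (2 * r / W)^2)
  }
  list(geometry = geometry, ratio = if (geometry == "slit") 6 else 8,
       v_mean = v_mean, v_max = v_max, profile = profile)
}

#' Non-dimensional shear rate
#'
#' `gamma_star = gamma_bar * tau_RBC = gamma_bar * eta * D_r^3 / kappa_r`,
#' the pseudo-shear rate scaled by the RBC relaxation time.
#'
#' @param gamma_bar pseudo-shear rate (1/time).
#' @param eta fluid viscosity; `D_r` effective RBC diameter; `kappa_r`
#'   membrane bending rigidity — all in one consistent unit system.
#' @param D_r effective RBC diameter.
#' @param kappa_r membrane bending rigidity (energy units).
#' @export
nondim_shear <- function(gamma_bar, eta, D_r, kappa_r) {
  if (eta <= 0 || D_r <= 0 || kappa_r <= 0) stop("scales must be positive")
  gamma_bar * eta * D_r^3 / kappa_r
}

#' Physiological RBC relaxation time
#'
#' `tau_RBC = eta * D_r^3 / kappa_r` with `D_r = sqrt(A_0 / pi)` from the
#' RBC surface area. With plasma viscosity 1.2 mPa s, `A_0 = 133 um^2` and
#' `kappa_r = 70 kBT` at 310 K this evaluates to about 1.1 s, so the
#' pseudo-shear rate in 1/s is roughly equal in magnitude to the
#' non-dimensional shear rate.
#'
#' @param eta fluid viscosity (Pa s).
#' @param A_0 RBC surface area (um^2).
#' @param kappa_kBT bending rigidity in units of kBT.
#' @param temperature absolute temperature (K).
#' @return relaxation time in seconds.
#' @export
rbc_relaxation_time <- function(eta = 1.2e-3, A_0 = 133, kappa_kBT = 70,
                                temperature = 310) {
  kB <- 1.380649e-23
  D_r <- sqrt(A_0 / pi) * 1e-6          # metres
  eta * D_r^3 / (kappa_kBT * kB * temperature)
}

#' Fit a parabolic profile
#'
#' Least-squares fit of `vx = 4 v_max (y/W)(1 - y/W) + slip` to a flow
#' field; returns the fitted centreline velocity, R^2 and residuals.
#'
#' @param field a `flow_field`.
#' @export
poiseuille_fit <- function(field) {
  pr <- field$profile[is.finite(field$profile$vx), ]
  W <- field$W
  z <- 4 * (pr$y / W) * (1 - pr$y / W)
  fit <- lm(pr$vx ~ z)
  list(v_max = unname(coef(fit)[2]), slip = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Measure the fluid viscosity from a driven pure-fluid run
#'
#' For a body-force-driven Newtonian slit flow the steady profile is
#' parabolic with `v_max = rho g W^2 / (8 eta)`, so
#' `eta = rho * g * W^2 / (8 * v_max_fit)`.
#'
#' @param field a `flow_field` from a pure-fluid driven run (or the
#'   trajectory itself).
#' @param g body acceleration; `density` fluid number density.
#' @param density fluid number density (mass density for unit mass).
#' @return list with `eta`, `v_max`, `r_squared`; warns if the parabola fit
#'   has R^2 < 0.98, errors on a zero-flow profile.
#' @export
measure_viscosity <- function(field, g, density) {
  if (inherits(field, "trajectory")) field <- velocity_profile(field)
  fit <- poiseuille_fit(field)
  if (!is.finite(fit$v_max) || fit$v_max <= 0)
    stop("degenerate (zero-flow) profile: cannot measure viscosity")
  if (fit$r_squared < 0.98)
    warning("profile fit R^2 = ", signif(fit$r_squared, 4),
            " < 0.98: viscosity estimate unreliable")
  list(eta = density * g * field$W^2 / (8 * fit$v_max),
       v_max = fit$v_max, r_squared = fit$r_squared)
}
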