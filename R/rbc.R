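#' 2D red blood cell model parameters
#'
#' A 2D RBC is a closed bead-spring ring of `N_v` vertices joined by
#' `N_s = N_v` springs, with bending resistance at every vertex angle and a
#' global area constraint. The effective diameter is `D_r = L_0 / pi`.
#'
#' The spring is a worm-like-chain attraction balanced by an inverse-power
#' repulsion (`kp / r`), with per-spring equilibrium length `l_0 = L_0/N_v`
#' and maximum extension `l_m = ext_max * l_0`; a plain harmonic spring is
#' available for tests. The bending energy is `k_b (1 - cos(theta - theta_0))`
#' per vertex angle, and the area energy is `k_a (A - A_0)^2 / (2 A_0)`.
#' The 2D enclosed-area target is set through the reduced area
#' `A_0 / (pi (L_0 / 2 pi)^2)` (default 0.48, a biconcave-like 2D
#' cross-section).
#'
#' @param N_v number of ring vertices.
#' @param L_0 cell circumference (micrometres).
#' @param k_b bending constant (units of kBT).
#' @param theta_0 spontaneous angle (radians).
#' @param k_a area-constraint coefficient in units of `kBT / D_r^2`.
#' @param reduced_area target enclosed area over the area of a circle with
#'   the same circumference.
#' @param spring_form `"wlc"` (worm-like chain + power repulsion) or
#'   `"harmonic"`.
#' @param persistence WLC persistence length as a fraction of `l_0`.
#' @param ext_max maximum spring extension `l_m / l_0`.
#' @param k_harm harmonic spring stiffness (units of kBT / l_0^2), used when
#'   `spring_form = "harmonic"`.
#' @return object of class `rbc_params` with derived fields `l_0`, `D_r`,
#'   `A_0_2d`.
#' @export
rbc_params <- function(N_v = 50L, L_0 = 19.22, k_b = 50, theta_0 = 0,
                       k_a = 17640, reduced_area = 0.48,
                       spring_form = c("wlc", "harmonic"),
                       persistence = 0.25, ext_max = 2.2, k_harm = 100) {
  spring_form <- match.arg(spring_form)
  l_0 <- L_0 / N_v
  D_r <- L_0 / pi
  structure(list(N_v = as.integer(N_v), L_0 = L_0, l_0 = l_0, D_r = D_r,
                 k_b = k_b, theta_0 = theta_0, k_a = k_a,
                 A_0_2d = reduced_area * L_0^2 / (4 * pi),
                 reduced_area = reduced_area, spring_form = spring_form,
                 persistence = persistence * l_0, ext_max = ext_max,
                 k_harm = k_harm / l_0^2),
            class = "rbc_params")
}

# registry entry consumed by the C++ engine; kp balances the WLC attraction
# at the equilibrium spring length
ring_entry <- function(params, start, kBT = 1) {
  l0 <- params$l_0
  lm <- params$ext_max * l0
  x0 <- l0 / lm
  kp <- l0^2 * (kBT / params$persistence) * (0.25 / (1 - x0)^2 - 0.25 + x0)
  list(start = as.integer(start - 1L), n = params$N_v,
       form = if (params$spring_form == "wlc") 0L else 1L,
       p = params$persistence, l0 = l0, lm = lm, kp = kp,
       k_harm = params$k_harm * kBT,
       kb = params$k_b * kBT, theta0 = params$theta_0,
       ka = params$k_a * kBT / params$D_r^2, A0 = params$A_0_2d)
}

# closed outline points (dense polyline, counter-clockwise) for a shape with
# unit scale; rescaled later so the N_v-gon perimeter equals L_0
rbc_outline <- function(shape, n_dense = 4000L) {
  t <- seq(0, 2 * pi, length.out = n_dense + 1L)[-(n_dense + 1L)]
  switch(shape,
    circle = cbind(cos(t), sin(t)),
    ellipse = {
      # aspect ratio chosen so that (perimeter, area) match (L_0, A_0) for
      # the default reduced area; solved at build time in build_rbc
      cbind(cos(t), sin(t))
    },
    biconcave = {
      # classic biconcave cross-section outline
      c0 <- 0.207; c1 <- 2.003; c2 <- -1.123
      xs <- cos(t)
      half <- 0.5 * sqrt(pmax(0, 1 - xs^2)) * (c0 + c1 * xs^2 + c2 * xs^4)
      cbind(xs, ifelse(t <= pi, half, -half))
    },
    stop("unknown RBC shape '", shape, "'"))
}

# equal-arclength resampling of a closed polyline to n points
resample_closed <- function(xy, n) {
  seg <- sqrt(rowSums((rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]) - xy)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  st <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  idx <- findInterval(st, cum, rightmost.closed = TRUE)
  frac <- (st - cum[idx]) / pmax(seg[idx], 1e-300)
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  xy[idx, , drop = FALSE] + frac * (xy[nxt[idx], , drop = FALSE] - xy[idx, , drop = FALSE])
}

polygon_perimeter <- function(xy) {
  sum(sqrt(rowSums((rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]) - xy)^2)))
}

#' Build a 2D RBC ring
#'
#' Places `N_v` vertices on a closed curve, rescaled so the polygon
#' perimeter equals `L_0` (for a circle all spring lengths then equal
#' `L_0 / N_v`), oriented counter-clockwise so the enclosed area is
#' positive.
#'
#' @param center numeric length-2 centre position (micrometres).
#' @param params an [rbc_params()].
#' @param shape `"circle"`, `"biconcave"`, or `"ellipse"` (the ellipse
#'   matches both the circumference `L_0` and the target area `A_0_2d`,
#'   which makes it a convenient relaxed initial shape).
#' @param orientation rotation angle (radians).
#' @param box optional [box_spec()]: if given, the ring must fit inside the
#'   channel with at least one vertex-radius (`l_0 / 2`) wall clearance.
#' @param start 1-based index the first vertex will have in the assembled
#'   particle set.
#' @param kBT thermal energy used to scale the membrane moduli.
#' @return list with `particles` (a [particle_set()] of the new vertices,
#'   species `"rbc"`) and `ring` (registry entry for the engine).
#' @export
build_rbc <- function(center, params = rbc_params(),
                      shape = c("biconcave", "circle", "ellipse"),
                      orientation = 0, box = NULL, start = 1L, kBT = 1) {
  shape <- match.arg(shape)
  if (shape == "ellipse") {
    ab <- ellipse_axes(params$L_0, params$A_0_2d)
    t <- seq(0, 2 * pi, length.out = 4001L)[-4001L]
    out <- cbind(ab[1] * cos(t), ab[2] * sin(t))
  } else {
    out <- rbc_outline(shape)
  }
  xy <- resample_closed(out, params$N_v)
  xy <- xy * params$L_0 / polygon_perimeter(xy)     # exact polygon perimeter
  xy <- sweep(xy, 2, colMeans(xy))
  rot <- matrix(c(cos(orientation), sin(orientation),
                  -sin(orientation), cos(orientation)), 2, 2)
  xy <- xy %*% t(rot)
  xy <- sweep(xy, 2, center, "+")
  if (shoelace_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  if (!is.null(box)) {
    clear <- params$l_0 / 2
    if (any(xy[, 2] < clear) || any(xy[, 2] > box$width_W - clear))
      stop("RBC placement error: ring intersects a wall (needs ",
           signif(clear, 3), " um clearance)")
  }
  ps <- particle_set(xy, species = "rbc", struct_id = rep(0L, params$N_v),
                     bead_index = seq_len(params$N_v) - 1L)
  list(particles = ps, ring = ring_entry(params, start, kBT))
}

# semi-axes of an ellipse with given perimeter and area
ellipse_axes <- function(perimeter, area) {
  per_of <- function(a) {
    b <- area / (pi * a)
    t <- seq(0, 2 * pi, length.out = 2001L)
    polygon_perimeter(cbind(a * cos(t[-2001L]), b * sin(t[-2001L])))
  }
  amin <- sqrt(area / pi)          # circle limit
  f <- function(a) per_of(a) - perimeter
  upper <- amin * 1.5
  while (f(upper) < 0) upper <- upper * 1.5
  a <- stats::uniroot(f, c(amin * 1.0001, upper), tol = 1e-10)$root
  c(a = a, b = area / (pi * a))
}

shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# unwrap ring/chain coordinates along periodic axes by walking the bonds
unwrap_coords <- function(xy, box) {
  d <- diff(xy)
  if (!is.null(box)) {
    L <- box$length_x
    d[, 1] <- d[, 1] - L * round(d[, 1] / L)
    if (box$periodic_y) {
      Wp <- box$width_W
      d[, 2] <- d[, 2] - Wp * round(d[, 2] / Wp)
    }
  }
  cs <- apply(d, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = 2)
  rbind(xy[1, , drop = FALSE], sweep(cs, 2, xy[1, ], "+"))
}

#' Enclosed area of an RBC ring
#'
#' Shoelace polygon area of the (periodically unwrapped) ring; positive for
#' counter-clockwise orientation.
#'
#' @param rbc ring descriptor from [build_rbc()] (the `ring` element), or a
#'   1-based vertex index vector.
#' @param particles the assembled [particle_set()].
#' @param box optional [box_spec()] for periodic unwrapping.
#' @export
rbc_area <- function(rbc, particles, box = NULL) {
  idx <- ring_indices(rbc, particles)
  xy <- unwrap_coords(particles$pos[idx, , drop = FALSE], box)
  shoelace_area(xy)
}

ring_indices <- function(rbc, particles) {
  if (is.numeric(rbc)) return(as.integer(rbc))
  rbc$start + seq_len(rbc$n)       # start is 0-based
}

ring_force_wrapper <- function(rbc, particles, box, component, kBT) {
  if (is.null(box))
    box <- box_spec(2 * (max(abs(particles$pos)) + 1),
                    2 * (max(abs(particles$pos)) + 1), periodic_y = FALSE)
  params <- dpd_params(kBT = kBT)
  sys <- build_system(particles, box, params, rings = list(rbc))
  cpp_forces(particles$pos, particles$vel, sys, params$dt, 0, 0, component)
}

#' Ring spring forces
#'
#' Axial, equal-and-opposite forces on the two vertices of every spring;
#' zero at the per-spring equilibrium length. Exceeding the maximum WLC
#' extension raises an error.
#'
#' @inheritParams rbc_area
#' @param kBT thermal energy (the WLC force scales with it).
#' @export
spring_forces <- function(rbc, particles, box = NULL, kBT = 1) {
  if (rbc$form == 0L) {
    idx <- ring_indices(rbc, particles)
    xy <- unwrap_coords(particles$pos[idx, , drop = FALSE], box)
    xy <- rbind(xy, xy[1, ])
    len <- sqrt(rowSums(diff(xy)^2))
    if (any(len >= rbc$lm))
      stop("spring extension overflow: length ", signif(max(len), 4),
           " exceeds the maximum extension ", signif(rbc$lm, 4))
  }
  ring_force_wrapper(rbc, particles, box, "spring", kBT)
}

#' Ring bending forces
#'
#' Forces from the angle potential `k_b (1 - cos(theta - theta_0))` at each
#' vertex. Bending alone exerts zero total force and zero total torque on
#' the ring.
#'
#' @inheritParams spring_forces
#' @export
bending_forces <- function(rbc, particles, box = NULL, kBT = 1)
  ring_force_wrapper(rbc, particles, box, "bend", kBT)

#' Ring area-constraint forces
#'
#' Gradient of the quadratic penalty `k_a (A - A_0)^2 / (2 A_0)` through the
#' shoelace area; zero when the enclosed area equals the target.
#'
#' @inheritParams spring_forces
#' @export
area_constraint_forces <- function(rbc, particles, box = NULL, kBT = 1)
  ring_force_wrapper(rbc, particles, box, "area", kBT)
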