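#' Assemble a hematocrit / shear-rate diagram
#'
#' Collects per-run observable values on scattered `(H_t, gamma_star)`
#' nodes and interpolates between them. Interpolation is piecewise linear
#' (barycentric on the best containing triangle), which reproduces node
#' values exactly and introduces no overshoot beyond the node range.
#'
#' @param runs data frame with columns `H_t`, `gamma_star`, `value` and
#'   optionally `stderr`; at least 4 non-collinear nodes.
#' @param observable tag naming the observable (`"P"`, `"stretch"`,
#'   `"Psi"`, ...).
#' @return object of class `phase_diagram`.
#' @export
assemble_diagram <- function(runs, observable = "P") {
  runs <- as.data.frame(runs)
  stopifnot(all(c("H_t", "gamma_star", "value") %in% names(runs)))
  key <- paste(signif(runs$H_t, 12), signif(runs$gamma_star, 12))
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      if (length(unique(runs$value[key == k])) > 1L)
        stop("duplicate nodes with conflicting values at (H_t, gamma*) = ", k)
    }
    runs <- runs[!duplicated(key), ]
  }
  if (nrow(runs) < 4L) stop("need >= 4 nodes for 2D interpolation")
  xy <- cbind(runs$H_t, runs$gamma_star)
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2L)
    stop("nodes are collinear; 2D interpolation impossible")
  runs <- runs[order(runs$H_t, runs$gamma_star), ]
  structure(list(nodes = runs, observable = observable,
                 interpolation = "piecewise-linear"),
            class = "phase_diagram")
}

#' Interpolate a phase diagram at query points
#'
#' Exact at nodes. For interior queries, evaluates the barycentric linear
#' interpolant on the containing triangle of nodes with the smallest
#' circumradius (a Delaunay-like choice); any non-degenerate containing
#' triangle reproduces a linear field exactly. Queries outside the convex
#' hull return `NA`.
#'
#' @param object a `phase_diagram`.
#' @param H_t,gamma_star query coordinates (equal-length vectors).
#' @param ... unused.
#' @export
predict.phase_diagram <- function(object, H_t, gamma_star, ...) {
  nd <- object$nodes
  # scale axes so the triangle search is not distorted by units
  sx <- diff(range(nd$H_t)); sy <- diff(range(nd$gamma_star))
  px <- nd$H_t / sx; py <- nd$gamma_star / sy
  qx <- H_t / sx; qy <- gamma_star / sy
  n <- nrow(nd)
  tri <- t(utils::combn(n, 3L))
  out <- rep(NA_real_, length(qx))
  for (q in seq_along(qx)) {
    hit <- which(abs(px - qx[q]) < 1e-12 & abs(py - qy[q]) < 1e-12)
    if (length(hit) > 0) { out[q] <- nd$value[hit[1]]; next }
    best <- Inf; val <- NA_real_
    for (t_i in seq_len(nrow(tri))) {
      i <- tri[t_i, 1]; j <- tri[t_i, 2]; k <- tri[t_i, 3]
      d <- (py[j] - py[k]) * (px[i] - px[k]) + (px[k] - px[j]) * (py[i] - py[k])
      if (abs(d) < 1e-14) next
      w1 <- ((py[j] - py[k]) * (qx[q] - px[k]) + (px[k] - px[j]) * (qy[q] - py[k])) / d
      w2 <- ((py[k] - py[i]) * (qx[q] - px[k]) + (px[i] - px[k]) * (qy[q] - py[k])) / d
      w3 <- 1 - w1 - w2
      if (w1 < -1e-9 || w2 < -1e-9 || w3 < -1e-9) next
      r <- tri_circumradius(px[c(i, j, k)], py[c(i, j, k)])
      if (r < best) {
        best <- r
        val <- w1 * nd$value[i] + w2 * nd$value[j] + w3 * nd$value[k]
      }
    }
    out[q] <- val
  }
  out
}

tri_circumradius <- function(x, y) {
  a <- sqrt((x[1] - x[2])^2 + (y[1] - y[2])^2)
  b <- sqrt((x[2] - x[3])^2 + (y[2] - y[3])^2)
  cc <- sqrt((x[3] - x[1])^2 + (y[3] - y[1])^2)
  ar <- abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
  if (ar < 1e-15) return(Inf)
  a * b * cc / (4 * ar)
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram> observable '", x$observable, "', ",
      nrow(x$nodes), " nodes, ", x$interpolation, " interpolation\n", sep = "")
  invisible(x)
}
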