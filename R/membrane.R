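# The enclosing membrane: a counterclockwise simple polygon in 2D evolving
# under a discretized Helfrich (squared mean curvature) energy.
#
# Discretization: with d_i = x_i - x_{i-1}, v_i = |d_i|, unit tangents
# t_i = d_i / v_i, tangent differences w_i = t_{i+1} - t_i, g_i = |w_i|^2 and
# dual edge lengths z_i = (v_i + v_{i+1})/2, the mean curvature at vertex i is
# |H_i| = sqrt(g_i) / z_i and the total energy is
#   U_mem = 2 kappa sum_i g_i / z_i
# (the arc-length quadrature of 2 kappa H^2). All indices are cyclic.

# cyclic row shift: row i of result is row i+k of M (wrapping)
.shift <- function(M, k) {
  n <- nrow(M)
  M[((seq_len(n) - 1 + k) %% n) + 1, , drop = FALSE]
}
.shiftv <- function(v, k) {
  n <- length(v)
  v[((seq_len(n) - 1 + k) %% n) + 1]
}

# tangent geometry shared by curvature/energy/gradient
.mem_geom <- function(V) {
  d <- V - .shift(V, -1)
  v <- sqrt(rowSums(d^2))
  if (any(v == 0)) stop("degenerate membrane: coincident vertices")
  t <- d / v
  w <- .shift(t, 1) - t
  g <- rowSums(w^2)
  z <- (v + .shiftv(v, 1)) / 2
  list(d = d, v = v, t = t, w = w, g = g, z = z)
}

#' Discrete mean curvature of a membrane polygon
#'
#' Finite-difference mean curvature at each vertex: the norm of the
#' arc-length derivative of the unit tangent, `|H_i| = |t_{i+1} - t_i| / z_i`
#' with `z_i` the mean of the two incident edge lengths. For a regular n-gon
#' inscribed in a circle of radius R this converges to 1/R as n grows.
#'
#' @param V n x 2 matrix of vertex positions, ordered counterclockwise,
#'   n >= 5.
#' @param i Optional vertex index; if omitted, curvature at every vertex.
#' @return Curvature magnitude(s) (1/length).
#' @export
mean_curvature <- function(V, i = NULL) {
  if (nrow(V) < 5) stop("mean curvature needs at least 5 vertices")
  geo <- .mem_geom(V)
  H <- sqrt(geo$g) / geo$z
  if (is.null(i)) H else H[i]
}

#' Discrete Helfrich energy of a membrane polygon
#'
#' `U_mem = 2 kappa sum_i g_i / z_i`, the polygonal quadrature of
#' `2 kappa integral H^2 dw` over the closed curve.
#'
#' @inheritParams mean_curvature
#' @param kappa Curvature modulus (energy times length).
#' @return Scalar energy.
#' @export
membrane_energy <- function(V, kappa = 1) {
  geo <- .mem_geom(V)
  2 * kappa * sum(geo$g / geo$z)
}

#' Analytic gradient of the discrete Helfrich energy
#'
#' Exact gradient of [membrane_energy()] with respect to every vertex,
#' assembled from the chain rule through the unit tangents (projector
#' `P_j = I - t_j t_j^T`) and the dual lengths. Used by the membrane kinetic
#' update rule; verified against finite differences in the test suite.
#'
#' @inheritParams membrane_energy
#' @return n x 2 matrix of gradient vectors.
#' @export
membrane_gradient <- function(V, kappa = 1) {
  geo <- .mem_geom(V)
  t <- geo$t; v <- geo$v; w <- geo$w; g <- geo$g; z <- geo$z
  tp <- .shift(t, 1)       # t_{j+1}
  vp <- .shiftv(v, 1)      # v_{j+1}
  wm <- .shift(w, -1)      # w_{j-1}
  wp <- .shift(w, 1)       # w_{j+1}
  zm <- .shiftv(z, -1); zp <- .shiftv(z, 1)
  gm <- .shiftv(g, -1); gp <- .shiftv(g, 1)
  # projector applications P_j y = y - t_j (t_j . y)
  proj <- function(t, y) y - t * rowSums(t * y)
  A <- 2 * proj(t, wm) / v / zm
  B <- -2 * (proj(t, w) / v + proj(tp, w) / vp) / z
  C <- 2 * proj(tp, wp) / vp / zp
  D <- -(gm / zm^2) * t / 2 - (g / z^2) * (t - tp) / 2 + (gp / zp^2) * tp / 2
  2 * kappa * (A + B + C + D)
}

#' Gradient-descent update of one membrane vertex
#'
#' One firing of the membrane curvature kinetic rule: vertex `j` moves by
#' `-grad_j U_mem / (zeta_mem * k_kinetic)`. A move that would make the
#' polygon self-intersect is rejected (no state change).
#'
#' @inheritParams membrane_energy
#' @param j Vertex index.
#' @param zeta_mem Vertex drag coefficient.
#' @param k_kinetic Kinetic rule rate (1/s).
#' @param extra_grad Optional additional gradient (e.g. from attachment
#'   forces) added to the curvature gradient before the step.
#' @return Updated vertex matrix (unchanged if the move was rejected).
#' @export
helfrich_update <- function(V, j, kappa = 1, zeta_mem = 1, k_kinetic = 1,
                            extra_grad = c(0, 0)) {
  gr <- membrane_gradient(V, kappa)[j, ] + extra_grad
  prop <- V
  prop[j, ] <- V[j, ] - gr / (zeta_mem * k_kinetic)
  if (.edges_ok_after_move(prop, j)) prop else V
}

# ---- polygon predicates -----------------------------------------------------

# proper/improper intersection test between segments p1-p2 and p3-p4,
# vectorized over rows of p3/p4
.seg_intersect <- function(p1, p2, P3, P4, eps = 1e-12) {
  d1 <- p2 - p1
  d3x <- P4[, 1] - P3[, 1]; d3y <- P4[, 2] - P3[, 2]
  denom <- d1[1] * d3y - d1[2] * d3x
  ex <- P3[, 1] - p1[1]; ey <- P3[, 2] - p1[2]
  s <- (ex * d3y - ey * d3x) / denom
  u <- (ex * d1[2] - ey * d1[1]) / denom
  ok <- abs(denom) > eps & s > eps & s < 1 - eps & u > eps & u < 1 - eps
  ok[is.na(ok)] <- FALSE
  ok
}

# check the two edges incident to moved vertex j against all other edges
.edges_ok_after_move <- function(V, j) {
  n <- nrow(V)
  prev <- ((j - 2) %% n) + 1
  nxt <- (j %% n) + 1
  A <- V; B <- .shift(V, 1)  # edge i: V[i] -> V[i+1]
  for (e in c(prev, j)) {
    p1 <- A[e, ]; p2 <- B[e, ]
    others <- setdiff(seq_len(n), c(e, ((e - 2) %% n) + 1, (e %% n) + 1))
    if (any(.seg_intersect(p1, p2, A[others, , drop = FALSE],
                           B[others, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

#' Test whether a polygon is simple
#'
#' Full O(n^2) check that no two non-adjacent edges intersect.
#'
#' @param V n x 2 vertex matrix.
#' @return TRUE if the polygon is simple.
#' @export
polygon_is_simple <- function(V) {
  n <- nrow(V)
  A <- V; B <- .shift(V, 1)
  for (e in seq_len(n - 1)) {
    others <- setdiff((e + 1):n, c(((e - 2) %% n) + 1, (e %% n) + 1))
    if (!length(others)) next
    if (any(.seg_intersect(A[e, ], B[e, ], A[others, , drop = FALSE],
                           B[others, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

#' Signed (shoelace) area of a polygon
#'
#' Positive for counterclockwise orientation.
#'
#' @param V n x 2 vertex matrix.
#' @return Signed area.
#' @export
polygon_area <- function(V) {
  Vp <- .shift(V, 1)
  sum(V[, 1] * Vp[, 2] - Vp[, 1] * V[, 2]) / 2
}

#' Point-in-polygon test
#'
#' Even-odd ray casting, vectorized over query points.
#'
#' @param P m x 2 matrix of query points.
#' @param V n x 2 polygon vertex matrix.
#' @return Logical vector of length m.
#' @export
points_in_polygon <- function(P, V) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 2)
  n <- nrow(V)
  Vp <- .shift(V, 1)
  vapply(seq_len(nrow(P)), function(k) {
    x <- P[k, 1]; y <- P[k, 2]
    cross <- (V[, 2] > y) != (Vp[, 2] > y)
    xi <- V[, 1] + (y - V[, 2]) / (Vp[, 2] - V[, 2]) * (Vp[, 1] - V[, 1])
    sum(cross & xi > x, na.rm = TRUE) %% 2 == 1
  }, logical(1))
}

#' Morphometric measurement of a membrane polygon
#'
#' Computes the three membrane phenotypes tracked per snapshot: enclosed
#' area (shoelace formula), perimeter (edge-length sum), and aspect ratio,
#' defined as `sqrt(lambda_max / lambda_min)` of the polygon's second
#' central area-moment (gyration) tensor, so a circle gives 1 and a 2:1
#' rectangle gives 2.
#'
#' @param V n x 2 vertex matrix (internal units).
#' @param scale Length of one internal unit in the reporting unit (e.g.
#'   micrometres per internal unit); areas scale with its square.
#' @return A data.frame row with `area`, `perimeter`, `aspect_ratio`.
#' @export
measure_membrane <- function(V, scale = 1) {
  A <- polygon_area(V)
  per <- sum(sqrt(rowSums((.shift(V, 1) - V)^2)))
  x <- V[, 1]; y <- V[, 2]
  xp <- .shiftv(x, 1); yp <- .shiftv(y, 1)
  cr <- x * yp - xp * y
  cx <- sum((x + xp) * cr) / (6 * A)
  cy <- sum((y + yp) * cr) / (6 * A)
  Ixx <- sum((y^2 + y * yp + yp^2) * cr) / 12 - A * cy^2
  Iyy <- sum((x^2 + x * xp + xp^2) * cr) / 12 - A * cx^2
  Ixy <- sum((x * yp + 2 * x * y + 2 * xp * yp + xp * y) * cr) / 24 -
    A * cx * cy
  M <- matrix(c(Iyy, -Ixy, -Ixy, Ixx), 2) / A
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  data.frame(area = abs(A) * scale^2,
             perimeter = per * scale,
             aspect_ratio = sqrt(max(ev) / max(min(ev), .Machine$double.eps)))
}

#' Brownian-ratchet polymerization factor
#'
#' Multiplier in (0, 1] applied to the elongation propensity of a
#' membrane-attached filament end: `exp(-f * delta / kT)` where `f` is the
#' compressive load transmitted through the attachment along the filament
#' axis and `delta` the insertion length a new subunit requires. Zero load
#' gives 1; the factor decreases monotonically with load.
#'
#' @param load Compressive force along the filament axis (kT/length;
#'   negative values, i.e. tension, give factor 1).
#' @param delta Required insertion length.
#' @param kT Thermal energy.
#' @return Scalar multiplier in (0, 1].
#' @export
ratchet_factor <- function(load, delta, kT = 1) {
  exp(-max(0, load) * delta / kT)
}
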