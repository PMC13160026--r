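# Filament mechanics: separation (Lennard-Jones) potential with repulsive-core
# clipping, radial gradients and Hessians over the connection graph, angular
# bending energy with analytic gradients and positive-semidefinite Hessian
# blocks, and the heat-bath acceptance rule for thermal moves.
#
# All functions work in internal units (length in coarse-grained rest lengths,
# energy in kT). The potential minimum sits at r_min = 2^(1/6) * sigma; with
# the default sigma = 2^(-1/6), r_min = 1.

#' Lennard-Jones separation potential
#'
#' The pairwise energy between two graph-connected filament segments,
#' `U(r) = eps * ((sigma/r)^12 - (sigma/r)^6)`. In this (un-prefactored) form
#' the minimum lies at `r = 2^(1/6) sigma` with depth `-eps/4`, and
#' `U(sigma) = 0`.
#'
#' @param r Separation distance(s), > 0.
#' @param eps Well-depth scale (kT).
#' @param sigma Length scale; the default puts the minimum at r = 1.
#' @return Energy value(s), same length as `r`.
#' @export
u_sep <- function(r, eps = 1, sigma = 2^(-1 / 6)) {
  s6 <- (sigma / r)^6
  eps * (s6^2 - s6)
}

# first derivative of the unclipped potential
du_sep <- function(r, eps = 1, sigma = 2^(-1 / 6)) {
  s6 <- (sigma / r)^6
  eps * (-12 * s6^2 + 6 * s6) / r
}

# second derivative of the unclipped potential
d2u_sep <- function(r, eps = 1, sigma = 2^(-1 / 6)) {
  s6 <- (sigma / r)^6
  eps * (156 * s6^2 - 42 * s6) / r^2
}

#' Clipped separation potential
#'
#' Below the clip point `eps_clip * r_min` the repulsive core is replaced by
#' its tangent line (value- and slope-matched first-order Taylor expansion at
#' the clip point), so the energy and force stay finite down to r = 0. Above
#' the clip point the potential is the unmodified [u_sep()].
#'
#' @inheritParams u_sep
#' @param eps_clip Clip point as a fraction of the minimum-energy distance
#'   (0 < eps_clip < 1).
#' @return Energy value(s).
#' @export
u_sep_clipped <- function(r, eps = 1, sigma = 2^(-1 / 6), eps_clip = 0.75) {
  k <- length(r)
  sigma <- rep_len(sigma, k)
  rc <- eps_clip * 2^(1 / 6) * sigma
  below <- r < rc
  out <- numeric(k)
  out[!below] <- u_sep(r[!below], eps, sigma[!below])
  if (any(below))
    out[below] <- u_sep(rc[below], eps, sigma[below]) +
      du_sep(rc[below], eps, sigma[below]) * (r[below] - rc[below])
  out
}

#' Derivative of the clipped separation potential
#'
#' Scalar radial derivative `U'(r)`; constant below the clip point by
#' construction, so the force is continuous and bounded.
#'
#' @inheritParams u_sep_clipped
#' @return Derivative value(s).
#' @export
grad_sep_clipped <- function(r, eps = 1, sigma = 2^(-1 / 6), eps_clip = 0.75) {
  k <- length(r)
  sigma <- rep_len(sigma, k)
  rc <- eps_clip * 2^(1 / 6) * sigma
  below <- r < rc
  out <- numeric(k)
  out[!below] <- du_sep(r[!below], eps, sigma[!below])
  if (any(below)) out[below] <- du_sep(rc[below], eps, sigma[below])
  out
}

# second derivative of the clipped potential (zero in the linearized core)
d2u_sep_clipped <- function(r, eps = 1, sigma = 2^(-1 / 6), eps_clip = 0.75) {
  k <- length(r)
  sigma <- rep_len(sigma, k)
  rc <- eps_clip * 2^(1 / 6) * sigma
  below <- r < rc
  out <- numeric(k)
  out[!below] <- d2u_sep(r[!below], eps, sigma[!below])
  out
}

#' Radial force kernel
#'
#' `psi(r) = U'_clipped(r) / r`, the scalar weight with which each connected
#' neighbor enters the radial gradient. Positive under tension (r > r_min,
#' restoring), negative under compression (r < r_min, transverse buckling).
#'
#' @inheritParams u_sep_clipped
#' @return psi value(s).
#' @export
psi_sep <- function(r, eps = 1, sigma = 2^(-1 / 6), eps_clip = 0.75) {
  grad_sep_clipped(r, eps, sigma, eps_clip) / r
}

#' Radial gradient at one node of a connection graph
#'
#' Gradient of the summed pairwise separation energy with respect to the
#' position of node `l`:
#' `sum_j G_lj psi(||x_l - x_j||) (x_l - x_j)`.
#' Edges may carry their own rest length (bundling links, membrane
#' attachments): the potential's length scale is shifted so its minimum sits
#' at that rest length.
#'
#' @param X n x 2 matrix of node positions.
#' @param G n x n symmetric 0/1 adjacency matrix.
#' @param l Node index.
#' @param eps,eps_clip Potential parameters (see [u_sep_clipped()]).
#' @param rest Either a scalar rest length applied to all edges or an n x n
#'   matrix of per-edge rest lengths (entries used where `G == 1`).
#' @return Length-2 gradient vector.
#' @export
radial_gradient <- function(X, G, l, eps = 1, eps_clip = 0.75, rest = 1) {
  nb <- which(G[l, ] != 0)
  if (!length(nb)) return(c(0, 0))
  d <- X[l, ] - t(X[nb, , drop = FALSE])   # 2 x k, columns x_l - x_j
  r <- sqrt(colSums(d^2))
  rl <- if (is.matrix(rest)) rest[l, nb] else rep(rest, length(nb))
  w <- psi_sep(r, eps = eps, sigma = rl * 2^(-1 / 6), eps_clip = eps_clip)
  as.numeric(d %*% w)
}

#' Diagonal radial Hessian block at one node
#'
#' The 2 x 2 diagonal block of the radial-energy Hessian used as the
#' precision scale of thermal proposals:
#' `(sum_j G_lj U''_clipped(||x_l - x_j||) + eps_sep^2) * I`.
#' A weighted graph Laplacian; when all `U'' > 0` its eigenvalues are
#' nonnegative by Gershgorin's theorem.
#'
#' @inheritParams radial_gradient
#' @param eps_sep Regularizer added to the diagonal curvature.
#' @return A 2 x 2 matrix (scalar times identity).
#' @export
radial_hessian_diag <- function(X, G, l, eps = 1, eps_clip = 0.75, rest = 1,
                                eps_sep = 1e-6) {
  nb <- which(G[l, ] != 0)
  h <- eps_sep^2
  if (length(nb)) {
    d <- X[l, ] - t(X[nb, , drop = FALSE])
    r <- sqrt(colSums(d^2))
    rl <- if (is.matrix(rest)) rest[l, nb] else rep(rest, length(nb))
    h <- h + sum(d2u_sep_clipped(r, eps = eps, sigma = rl * 2^(-1 / 6),
                                 eps_clip = eps_clip))
  }
  diag(h, 2)
}

# total radial energy of a configuration (sum over edges, each counted once)
radial_energy <- function(X, G, eps = 1, eps_clip = 0.75, rest = 1) {
  e <- 0
  n <- nrow(X)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (G[i, j] != 0) {
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    rl <- if (is.matrix(rest)) rest[i, j] else rest
    e <- e + u_sep_clipped(r, eps = eps, sigma = rl * 2^(-1 / 6),
                           eps_clip = eps_clip)
  }
  e
}

#' Geometric terms of the angular bending energy
#'
#' For three consecutive positions `x1, x2, x3`, returns the scalar and
#' vector quantities entering the bending gradient and Hessian:
#' `a = cos(theta)` (the cosine of the enclosed bend angle; 1 for a straight
#' run), `b = |x3 - x2| / |x2 - x1|`, `c = |x2 - x1| |x3 - x2|`,
#' `L = x1 - 2 x2 + x3`, `Lt = b x1 - (b + 1/b) x2 + x3 / b`, and the
#' derivative vectors `K = (x2 - x3) - a b (x1 - x2)` (so that
#' `grad_x1 a = K / c`) and `Kt = K` of the reversed triple, satisfying
#' `Kt(x1,x2,x3) = K(x3,x2,x1)`.
#'
#' @param x1,x2,x3 Length-2 position vectors; `x1 != x2`, `x2 != x3`.
#' @return A list with elements `a`, `b`, `cc`, `L`, `Lt`, `K`, `Kt`.
#' @export
angle_terms <- function(x1, x2, x3) {
  d1 <- x2 - x1
  d2 <- x3 - x2
  v1 <- sqrt(sum(d1^2))
  v2 <- sqrt(sum(d2^2))
  if (v1 == 0 || v2 == 0)
    stop("degenerate geometry: coincident points in angle_terms")
  a <- sum(d1 * d2) / (v1 * v2)
  a <- max(-1, min(1, a))
  b <- v2 / v1
  cc <- v1 * v2
  L <- x1 - 2 * x2 + x3
  Lt <- b * x1 - (b + 1 / b) * x2 + x3 / b
  K <- (x2 - x3) - a * b * (x1 - x2)
  Kt <- (x2 - x1) - (a / b) * (x3 - x2)   # equals K of the reversed triple
  list(a = a, b = b, cc = cc, L = L, Lt = Lt, K = K, Kt = Kt)
}

# bending energy of one triple
angle_energy <- function(x1, x2, x3, theta_target = 0, k_bend = 1) {
  at <- angle_terms(x1, x2, x3)
  0.5 * k_bend * (acos(at$a) - theta_target)^2
}

# shared scalar factor (acos(a) - theta_target) / (c * sqrt(1 - a^2)) with the
# l'Hopital limit at a -> 1 for theta_target = 0; at an exact colinear point
# with a nonzero target angle the direction of steepest descent is undefined
# by symmetry, so the zero vector is returned (thermal noise breaks the tie).
.angle_factor <- function(at, theta_target) {
  s <- sqrt(max(0, 1 - at$a^2))
  if (s < 1e-8) {
    if (abs(theta_target) < 1e-12 && at$a > 0) return(1 / at$cc)
    return(NA_real_)
  }
  (acos(at$a) - theta_target) / (at$cc * s)
}

#' Bending-energy gradient at the interior node of a triple
#'
#' Analytic gradient of `(k_bend/2) (acos(a) - theta_target)^2` with respect
#' to the middle position `x2`. Equal and opposite to the sum of the two end
#' gradients, so each triple's internal bending forces sum to zero.
#'
#' @inheritParams angle_terms
#' @param theta_target Preferred angle (radians): 0 along a filament,
#'   ~70 degrees across an Arp2/3 branch.
#' @param k_bend Bending constant (kT per rad^2).
#' @return Length-2 gradient vector.
#' @export
angle_gradient_interior <- function(x1, x2, x3, theta_target = 0, k_bend = 1) {
  at <- angle_terms(x1, x2, x3)
  f <- .angle_factor(at, theta_target)
  if (is.na(f)) return(c(0, 0))
  k_bend * f * (at$K + at$Kt)
}

#' Bending-energy gradient at an end node of a triple
#'
#' Gradient with respect to `x1` (`which = 1`) or `x3` (`which = 3`).
#'
#' @inheritParams angle_gradient_interior
#' @param which End node: 1 or 3.
#' @return Length-2 gradient vector.
#' @export
angle_gradient_end <- function(x1, x2, x3, theta_target = 0, k_bend = 1,
                               which = 1) {
  at <- angle_terms(x1, x2, x3)
  f <- .angle_factor(at, theta_target)
  if (is.na(f)) return(c(0, 0))
  if (which == 1) -k_bend * f * at$K else -k_bend * f * at$Kt
}

#' Diagonal bending Hessian block of one triple
#'
#' The positive-semidefinite part of the bending Hessian at one node of a
#' triple: the outer product of the relevant derivative vector, weighted by
#' `k_bend / (c^2 (1 - a^2))`, plus the `eps_ang^2` identity regularizer.
#' Terms carrying the variable-sign factor `(acos(a) - theta_target)` are
#' dropped by construction, so the result has strictly positive eigenvalues
#' and stays finite at colinearity.
#'
#' @inheritParams angle_gradient_interior
#' @param node Which node of the triple (1, 2 or 3).
#' @param eps_ang Diagonal regularizer.
#' @return A 2 x 2 positive-definite matrix.
#' @export
angle_hessian_diag <- function(x1, x2, x3, theta_target = 0, k_bend = 1,
                               node = 2, eps_ang = 1e-6) {
  at <- angle_terms(x1, x2, x3)
  s2 <- max(1e-12, 1 - at$a^2)
  v <- switch(as.character(node),
              "1" = at$K, "3" = at$Kt, "2" = -(at$K + at$Kt))
  H <- (k_bend / (at$cc^2 * s2)) * tcrossprod(v) + diag(eps_ang^2, 2)
  H
}

#' Heat-bath acceptance probability for a thermal move
#'
#' `A = z / (1 + z)` with
#' `z = exp(-(dU - dUq)/kT) * |H(x)| / |H(x')|`, where `dU` is the change in
#' the local separation energy, `dUq` the quadratic (Hessian) part of its
#' Taylor expansion at the current point, and `|H|` the determinant of the
#' proposal precision matrix at the current and proposed positions. Always in
#' (0, 1); equals 1/2 when `dU = dUq` and the determinants match.
#'
#' @param dU Energy change of the proposed move (kT).
#' @param dUq Quadratic Taylor part of the change (kT).
#' @param detH_cur,detH_prop Hessian determinants at current and proposed
#'   positions.
#' @param kT Thermal energy (internal default 1).
#' @return Acceptance probability in (0, 1).
#' @export
heat_bath_accept <- function(dU, dUq, detH_cur = 1, detH_prop = 1, kT = 1) {
  lz <- -(dU - dUq) / kT + log(detH_cur) - log(detH_prop)
  # 1/(1 + exp(-lz)) in overflow-safe form
  if (lz > 0) 1 / (1 + exp(-lz)) else exp(lz) / (1 + exp(lz))
}
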