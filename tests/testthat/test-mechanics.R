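# Separation potential, radial gradients/Hessians, angle-bending terms, and
# the heat-bath acceptance rule.

test_that("separation potential has the textbook landmarks", {
  expect_equal(u_sep(2^(-1 / 6)), 0)          # r = sigma
  expect_equal(u_sep(1), -1 / 4)              # global minimum, depth -eps/4
  expect_lt(u_sep(50), 0)                     # asymptote approached from below
  expect_gt(u_sep(50), -1e-8)
  # minimum is where the derivative vanishes
  expect_equal(grad_sep_clipped(1), 0, tolerance = 1e-12)
})

test_that("clipped potential is value- and slope-continuous at the clip point", {
  eps <- 3.7
  rc <- 0.75                                   # eps_clip * r_min
  h <- 1e-8
  expect_equal(u_sep_clipped(rc - h, eps = eps), u_sep_clipped(rc + h, eps = eps),
               tolerance = 1e-6)
  expect_equal(grad_sep_clipped(rc - h, eps = eps),
               grad_sep_clipped(rc + h, eps = eps), tolerance = 1e-4)
  # finite energy and force down to contact
  expect_true(is.finite(u_sep_clipped(0, eps = eps)))
  expect_true(is.finite(grad_sep_clipped(1e-12, eps = eps)))
  # identical to the unclipped form at and beyond the minimum
  expect_equal(u_sep_clipped(1, eps = eps), u_sep(1, eps = eps))
  expect_equal(u_sep_clipped(1.6, eps = eps), u_sep(1.6, eps = eps))
})

test_that("psi is zero at the rest length, positive under tension, negative under compression", {
  expect_equal(psi_sep(1), 0, tolerance = 1e-12)
  expect_gt(psi_sep(1.3), 0)
  expect_lt(psi_sep(0.85), 0)
  expect_lt(psi_sep(0.3), 0)   # clipped core still repulsive
})

test_that("radial gradient cancels on a straight equally spaced run and conserves momentum", {
  X <- cbind(0:2, c(0, 0, 0))
  G <- matrix(0, 3, 3); G[1, 2] <- G[2, 1] <- G[2, 3] <- G[3, 2] <- 1
  expect_equal(radial_gradient(X, G, 2), c(0, 0), tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:10) {
    cfg <- random_chain_config(6)
    total <- Reduce(`+`, lapply(1:6, function(l)
      radial_gradient(cfg$X, cfg$G, l, eps = 2)))
    expect_equal(total, c(0, 0), tolerance = 1e-9)
  }
})

test_that("radial gradient matches a finite-difference oracle", {
  set.seed(7)
  for (rep in 1:25) {
    cfg <- random_chain_config(5)
    l <- sample(5, 1)
    g <- radial_gradient(cfg$X, cfg$G, l, eps = 2)
    fg <- fd_grad2(function(x) {
      Xp <- cfg$X; Xp[l, ] <- x
      spinedgg:::radial_energy(Xp, cfg$G, eps = 2)
    }, cfg$X[l, ])
    expect_equal(g, fg, tolerance = 1e-5)
  }
})

test_that("radial Hessian block is the weighted Laplacian diagonal", {
  # isolated pair: diagonal entries U'' at both nodes, matching the 2x2
  # graph Laplacian [[U'', -U''], [-U'', U'']]
  r <- 1.13
  X <- rbind(c(0, 0), c(r, 0))
  G <- matrix(c(0, 1, 1, 0), 2)
  upp <- spinedgg:::d2u_sep(r, eps = 2)
  H1 <- radial_hessian_diag(X, G, 1, eps = 2, eps_sep = 0)
  expect_equal(H1, diag(upp, 2), tolerance = 1e-12)
  expect_equal(radial_hessian_diag(X, G, 2, eps = 2, eps_sep = 0), H1)
  # directional second derivative along the pair axis
  fd <- fd_dir2(function(x) {
    Xp <- X; Xp[2, ] <- x
    spinedgg:::radial_energy(Xp, G, eps = 2)
  }, X[2, ], d = c(1, 0))
  expect_equal(upp, fd, tolerance = 1e-5)
})

test_that("radial Hessian is nonnegative in the convex regime (Gershgorin)", {
  set.seed(11)
  for (rep in 1:10) {
    # separations drawn beyond the inflection so all U'' > 0
    n <- 4
    X <- cbind(cumsum(stats::runif(n, 0.95, 1.1)), stats::rnorm(n, 0, 0.01))
    G <- matrix(0, n, n)
    for (i in seq_len(n - 1)) G[i, i + 1] <- G[i + 1, i] <- 1
    # assemble the full 2n x 2n weighted Laplacian of the scalar scheme
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      r <- sqrt(sum((X[i, ] - X[i + 1, ])^2))
      W[i, i + 1] <- W[i + 1, i] <- spinedgg:::d2u_sep_clipped(r, eps = 2)
    }
    L <- diag(rowSums(W)) - W
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9)
  }
})

test_that("angle terms behave as stated", {
  x1 <- c(0, 0); x2 <- c(1, 0); x3 <- c(2, 0)
  at <- angle_terms(x1, x2, x3)
  expect_equal(at$a, 1)                         # straight: theta = 0, a = 1
  at2 <- angle_terms(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(at2$a, 0)                        # right angle
  set.seed(3)
  for (rep in 1:10) {
    p <- matrix(stats::rnorm(6), 3)
    f <- angle_terms(p[1, ], p[2, ], p[3, ])
    b <- angle_terms(p[3, ], p[2, ], p[1, ])
    expect_equal(f$a, b$a)                       # a is symmetric
    expect_equal(f$Kt, b$K)                      # Kt(ijk) = K(kji)
  }
  expect_error(angle_terms(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
})

test_that("bending gradients match finite differences and sum to zero", {
  set.seed(5)
  for (tt in c(0, 70 * pi / 180)) {
    for (rep in 1:15) {
      p <- matrix(stats::rnorm(6, sd = 1), 3) + cbind(0:2, 0)
      kb <- 2.3
      en <- function(x1, x2, x3)
        spinedgg:::angle_energy(x1, x2, x3, tt, kb)
      g1 <- angle_gradient_end(p[1, ], p[2, ], p[3, ], tt, kb, which = 1)
      g2 <- angle_gradient_interior(p[1, ], p[2, ], p[3, ], tt, kb)
      g3 <- angle_gradient_end(p[1, ], p[2, ], p[3, ], tt, kb, which = 3)
      expect_equal(g1, fd_grad2(function(x) en(x, p[2, ], p[3, ]), p[1, ]),
                   tolerance = 1e-4)
      expect_equal(g2, fd_grad2(function(x) en(p[1, ], x, p[3, ]), p[2, ]),
                   tolerance = 1e-4)
      expect_equal(g3, fd_grad2(function(x) en(p[1, ], p[2, ], x), p[3, ]),
                   tolerance = 1e-4)
      expect_equal(g1 + g2 + g3, c(0, 0), tolerance = 1e-10)
    }
  }
})

test_that("bending gradient of a straight triple with zero target vanishes", {
  g <- angle_gradient_interior(c(0, 0), c(1, 0), c(2, 0), 0, 5)
  expect_equal(g, c(0, 0))
  # the a -> 1 limit is evaluated without overflow for slightly bent runs
  g2 <- angle_gradient_interior(c(0, 0), c(1, 1e-9), c(2, 0), 0, 5)
  expect_true(all(is.finite(g2)))
})

test_that("bending Hessian blocks are positive definite and finite at colinearity", {
  set.seed(9)
  for (rep in 1:10) {
    p <- matrix(stats::rnorm(6), 3) + cbind(0:2, 0)
    for (node in 1:3) {
      H <- angle_hessian_diag(p[1, ], p[2, ], p[3, ], 0, 2, node = node)
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
  Hc <- angle_hessian_diag(c(0, 0), c(1, 0), c(2, 0), 0, 2)
  expect_true(all(is.finite(Hc)))
})

test_that("bending Hessian diagonal matches finite differences at the target angle", {
  # at theta = theta_target the dropped variable-sign term vanishes, so the
  # retained outer-product part is the exact Hessian there
  tt <- 0.6
  x1 <- c(0, 0); x2 <- c(1, 0)
  x3 <- x2 + c(cos(tt), sin(tt))     # enclosed angle exactly tt
  kb <- 1.7
  H <- angle_hessian_diag(x1, x2, x3, tt, kb, node = 1, eps_ang = 0)
  en <- function(x) spinedgg:::angle_energy(x, x2, x3, tt, kb)
  for (d in list(c(1, 0), c(0, 1), c(1, 1))) {
    dn <- d / sqrt(sum(d^2))
    expect_equal(as.numeric(t(dn) %*% H %*% dn), fd_dir2(en, x1, d),
                 tolerance = 1e-4)
  }
})

test_that("heat-bath acceptance has the logistic limits", {
  expect_equal(heat_bath_accept(1.3, 1.3, 2, 2), 0.5)
  expect_gt(heat_bath_accept(-5, 0), 0.99)
  expect_lt(heat_bath_accept(50, 0), 1e-6)
  for (dU in c(-30, -1, 0, 1, 30)) {
    A <- heat_bath_accept(dU, 0.3, 1.2, 0.7)
    expect_gt(A, 0); expect_lt(A, 1)
  }
  # heat-bath form A(z) = z/(1+z) satisfies A(z)/A(1/z) = z, the detailed
  # balance ratio for a move whose reverse has the reciprocal odds
  dU <- 0.8; R <- 1.3
  z <- exp(-dU) * R
  A_f <- heat_bath_accept(dU, 0, R, 1)
  A_r <- heat_bath_accept(-dU, 0, 1, R)
  expect_equal(A_f / A_r, z, tolerance = 1e-12)
})

test_that("kinetic updates relax a stretched pair and dissipate energy", {
  p <- toy_params(zeta_k = 2000)
  S <- make_fixture("straight_filament", 1, p, n = 2)
  S$params <- p
  S$x[2] <- 1.25                      # stretched beyond rest length
  r0 <- S$x[2] - S$x[1]
  kinetic_update(S, 2)
  expect_lt(S$x[2] - S$x[1], r0)      # moved together, downhill on U
  # with thermal noise off, repeated kinetic firings never increase energy
  S2 <- make_fixture("straight_filament", 1, p, n = 6)
  S2$params <- p
  set.seed(2)
  S2$y[2:5] <- stats::rnorm(4, 0, 0.2)
  spinedgg:::update_angles(S2, 1:6)
  e0 <- total_energy(S2)
  ok <- TRUE
  for (i in 1:200) {
    id <- sample(2:5, 1)
    kinetic_update(S2, id)
  }
  expect_lt(total_energy(S2), e0)
})

test_that("mean kinetic relaxation follows the overdamped ODE", {
  # a pair at r0 = 1.2 relaxes as dr/dt = -2 U'(r) / zeta; the stochastic
  # kinetic rule (rate k_kinetic per node, jump -U'/(zeta k_kinetic)) has
  # the same drift, so the seed-averaged trajectory tracks the ODE
  p <- toy_params(zeta_k = 2000)
  zi <- p$internal$zeta_actin
  Tend <- 2
  # fine-step Euler reference for the relative coordinate
  r <- 1.2; hstep <- 1e-4
  for (i in seq_len(Tend / hstep))
    r <- r - hstep * 2 * spinedgg:::grad_sep_clipped(r, eps = p$internal$eps_LJ) / zi
  finals <- replicate(200, {
    set.seed(sample.int(1e6, 1))
    S <- make_fixture("straight_filament", 1, p, n = 2)
    S$params <- p
    S$x[2] <- 1.2
    t <- 0
    repeat {
      dt <- stats::rexp(1, 2 * p$k_kinetic)
      if (t + dt > Tend) break
      t <- t + dt
      kinetic_update(S, sample(1:2, 1))
    }
    S$x[2] - S$x[1]
  })
  expect_equal(mean(finals), r, tolerance = 0.03)
})
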