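# shared test utilities: finite-difference oracles and toy parameter sets

# central finite-difference gradient of f: R^2 -> R
fd_grad2 <- function(f, x, h = 1e-6) {
  g <- numeric(2)
  for (k in 1:2) {
    e <- c(0, 0); e[k] <- h
    g[k] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

# central second difference of f along direction d at x
fd_dir2 <- function(f, x, d, h = 1e-4) {
  d <- d / sqrt(sum(d^2))
  (f(x + h * d) - 2 * f(x) + f(x - h * d)) / h^2
}

# parameters with a soft, thermally active toy potential: well depth a few
# kT and a drag low enough that thermal proposals are a sizable fraction of
# the equilibrium spread (proposal variance = 0.5 * kT/U''(r_min))
toy_params <- function(eps_kT = 20, zeta_k = 4) {
  p <- resolve_params()
  p$internal$eps_LJ <- eps_kT
  # zeta_k = zeta * k_kinetic in internal units; 4 gives thermal proposals
  # with variance 0.5 kT/U''(r_min); use >> 2 U''(r_min) (= 36 eps) for
  # stable gradient-descent jumps
  p$internal$zeta_actin <- zeta_k / p$k_kinetic
  p
}

# random small filament-graph configuration for gradient oracles: a chain
# with positions jittered around unit spacing
random_chain_config <- function(n = 5, jitter = 0.15) {
  X <- cbind(seq_len(n) - 1, rep(0, n)) + matrix(stats::rnorm(2 * n, 0, jitter), ncol = 2)
  G <- matrix(0, n, n)
  for (i in seq_len(n - 1)) G[i, i + 1] <- G[i + 1, i] <- 1
  list(X = X, G = G)
}

# exhaustive permutation distribution of the Jonckheere-Terpstra statistic
# for small fixtures: all distinct assignments of the pooled observations to
# the given group sizes
jt_stat <- function(groups) {
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    J <- J + sum(outer(groups[[i]], groups[[j]], "<")) +
      0.5 * sum(outer(groups[[i]], groups[[j]], "=="))
  }
  J
}

jt_perm_tail <- function(groups, observed_J) {
  vals <- unlist(groups)
  sizes <- lengths(groups)
  N <- length(vals)
  idx_all <- seq_len(N)
  count <- 0; total <- 0
  # enumerate all assignments of observation indices to ordered groups
  enum <- function(avail, gi, acc) {
    if (gi > length(sizes)) {
      gr <- lapply(acc, function(ii) vals[ii])
      total <<- total + 1
      if (jt_stat(gr) >= observed_J - 1e-9) count <<- count + 1
      return(invisible(NULL))
    }
    cmb <- utils::combn(avail, sizes[gi], simplify = FALSE)
    for (cc in cmb) enum(setdiff(avail, cc), gi + 1, c(acc, list(cc)))
  }
  enum(idx_all, 1, list())
  c(p = count / total, total = total)
}
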