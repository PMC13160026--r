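# Sweep driver and trend statistics: Pearson correlation, the
# Jonckheere-Terpstra ordered-alternative trend test (tie-corrected normal
# approximation), the epistasis change of variables for double parameter
# sweeps, and dissociation constants.

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two numeric vectors with the usual
#' t-distributed two-sided p-value (delegates to [stats::cor.test()]).
#'
#' @param xs,ys Numeric vectors of equal length (n >= 3).
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(xs, ys) {
  ct <- stats::cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend across `k` ordered groups. The statistic is
#' `J = sum_{i<j} (number of pairs (a in group i, b in group j) with a < b)`
#' counting ties as 1/2. The p-value uses the tie-corrected normal
#' approximation of the null mean and variance.
#'
#' @param groups List of numeric vectors, ordered by increasing dose.
#' @param alternative `"increasing"`, `"decreasing"` or `"two.sided"`.
#' @return List with `J`, `z`, and `p`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing", "decreasing",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  k <- length(groups)
  stopifnot(k >= 2)
  J <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    gi <- groups[[i]]; gj <- groups[[j]]
    J <- J + sum(outer(gi, gj, "<")) + 0.5 * sum(outer(gi, gj, "=="))
  }
  n <- lengths(groups)
  N <- sum(n)
  allv <- unlist(groups)
  t <- table(allv)                      # tie group sizes
  muJ <- (N^2 - sum(n^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(n * (n - 1) * (2 * n + 5)) -
           sum(t * (t - 1) * (2 * t + 5))) / 72
  v2 <- sum(n * (n - 1) * (n - 2)) * sum(t * (t - 1) * (t - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(n * (n - 1)) * sum(t * (t - 1)) / (8 * N * (N - 1))
  varJ <- v1 + v2 + v3
  if (varJ <= 0) return(list(J = J, z = 0, p = 1))
  z <- (J - muJ) / sqrt(varJ)
  p <- switch(alternative,
              increasing = stats::pnorm(z, lower.tail = FALSE),
              decreasing = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(J = J, z = z, p = min(1, p))
}

#' Epistasis exponent from a pair of single-sweep correlations
#'
#' The double-sweep nullification exponent
#' `q = -(d phenotype / d alpha) / (d phenotype / d gamma)`, estimated by
#' the ratio of the two species' single-sweep dose-response slopes (their
#' Pearson r values stand in for the slopes). Equal and same-signed
#' responses give `q = -1`, the pure nullification ratio.
#'
#' @param r_a,r_b Dose-response correlations of species A and B.
#' @return The exponent `q`.
#' @export
epistasis_q <- function(r_a, r_b) -r_a / r_b

#' Epistasis change of variables and its inverse
#'
#' For log-synthesis coordinates `alpha` (species A) and `gamma` (species
#' B) and exponent `q`, the sweep coordinate is `mu = alpha + gamma/q` with
#' the complementary coordinate `nu = alpha - gamma/q`; the inverse is
#' `alpha = (mu + nu)/2`, `gamma = (q/2)(mu - nu)`. Along `mu`, a phenotype
#' depending on `alpha + gamma` exactly is constant when `q = -1`
#' (nullification).
#'
#' @param alpha,gamma Log10 synthesis-rate coordinates.
#' @param q Exponent.
#' @return List with `mu` and `nu`.
#' @export
change_of_variables <- function(alpha, gamma, q) {
  list(mu = alpha + gamma / q, nu = alpha - gamma / q)
}

#' @rdname change_of_variables
#' @param mu,nu Transformed coordinates.
#' @return For the inverse: list with `alpha` and `gamma`.
#' @export
change_of_variables_inv <- function(mu, nu, q) {
  list(alpha = (mu + nu) / 2, gamma = (q / 2) * (mu - nu))
}

#' Dissociation constant from rate constants
#'
#' `K_d = k_off / k_on` in molar.
#'
#' @param k_off Off rate (1/s).
#' @param k_on On rate (1/(M s)).
#' @return K_d (M).
#' @export
dissociation_constant <- function(k_off, k_on) k_off / k_on

# ---- sweep driver -----------------------------------------------------------

#' Default single-sweep dose grid
#'
#' Seven log-spaced multipliers spanning 0.1x to 10x the basal synthesis
#' rate, centred on 1 (the basal configuration). For species whose upper
#' range is truncated (Arp2/3, Aip1) the span is 0.1x to 1x.
#'
#' @param truncated Truncate the upper end at the basal rate.
#' @param n_steps Number of grid points.
#' @return Numeric vector of multipliers.
#' @export
sweep_grid <- function(truncated = FALSE, n_steps = 7) {
  if (truncated) 10^seq(-1, 0, length.out = n_steps)
  else 10^seq(-1, 1, length.out = n_steps)
}

#' Run a synthesis-rate parameter sweep
#'
#' For each dose multiplier, scales the synthesis rate of `species` (and,
#' for a double sweep, applies the complementary `1/eta^q` factor to
#' `species_b`), runs `replicates` stochastic simulations to
#' `measure_time`, and records the membrane morphometrics of the final
#' snapshot. The grid midpoint of the default grids is the unmodified basal
#' configuration. Seeds are derived deterministically from `seed_base`, so
#' the whole sweep is reproducible.
#'
#' @param params Resolved parameters.
#' @param species Pool species swept (dose `eta^k`).
#' @param multipliers Dose multipliers for `species` (default
#'   [sweep_grid()]).
#' @param species_b Optional second species for a double sweep; it receives
#'   the reciprocal dose `multiplier^(-q)`.
#' @param q Double-sweep exponent (1, 2 or 4 in the study design).
#' @param replicates Stochastic replicates per dose.
#' @param measure_time Simulation horizon and measurement time (s).
#' @param seed_base Integer seed base.
#' @param max_events Per-run event cap passed to [simulate_spine()].
#' @return A tidy data.frame with columns species, multiplier, q, replicate,
#'   time, area, perimeter, aspect_ratio.
#' @export
run_sweep <- function(params = resolve_params(), species,
                      multipliers = NULL, species_b = NULL, q = 1,
                      replicates = 5, measure_time = 20,
                      seed_base = 1L, max_events = 5e5) {
  if (is.null(multipliers))
    multipliers <- sweep_grid(truncated = species %in% c("arp23", "aip1"))
  rows <- vector("list", length(multipliers) * replicates)
  k <- 1
  for (di in seq_along(multipliers)) {
    m <- multipliers[di]
    pp <- apply_sweep_multiplier(params, species, m)
    if (!is.null(species_b))
      pp <- apply_sweep_multiplier(pp, species_b, m^(-q))
    for (rep in seq_len(replicates)) {
      seed <- seed_base + 7919L * (di - 1L) + rep
      res <- simulate_spine(pp, seed = seed, t_end = measure_time,
                            snapshot_every = measure_time,
                            max_events = max_events)
      last <- res$morpho[nrow(res$morpho), ]
      rows[[k]] <- data.frame(species = species, multiplier = m, q = q,
                              replicate = rep, time = last$time,
                              area = last$area, perimeter = last$perimeter,
                              aspect_ratio = last$aspect_ratio)
      k <- k + 1
    }
  }
  do.call(rbind, rows)
}

#' Trend statistics of a sweep table
#'
#' For each membrane phenotype, computes the Pearson correlation of the
#' phenotype against log10 dose and the one-sided Jonckheere-Terpstra trend
#' p-value across the dose groups, with the test's sidedness chosen by the
#' sign of the Pearson r (the convention of the study's summary tables).
#'
#' @param sweep A data.frame from [run_sweep()].
#' @return A data.frame with one row per phenotype: `phenotype`, `r`,
#'   `p_pearson`, `J`, `p_jt`, `side`.
#' @export
sweep_stats <- function(sweep) {
  phen <- c("area", "perimeter", "aspect_ratio")
  out <- lapply(phen, function(ph) {
    x <- log10(sweep$multiplier)
    y <- sweep[[ph]]
    if (stats::sd(y) == 0) {
      pr <- list(r = 0, p = 1)      # constant phenotype carries no trend
    } else {
      pr <- pearson_r(x, y)
    }
    doses <- sort(unique(sweep$multiplier))
    groups <- lapply(doses, function(d) y[sweep$multiplier == d])
    side <- if (pr$r >= 0) "increasing" else "decreasing"
    jt <- jonckheere_terpstra(groups, alternative = side)
    data.frame(phenotype = ph, r = pr$r, p_pearson = pr$p,
               J = jt$J, p_jt = jt$p, side = side)
  })
  do.call(rbind, out)
}
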