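# Stochastic simulation engine: exact continuous-time event selection
# (Gillespie direct method) over all rule instances, with the pool ODEs
# advanced deterministically between events (hybrid ODE/SSA). All rules -
# biochemical rewrites, kinetic mechanics updates, thermal noise, and
# membrane updates - compete on one shared clock.

#' Build the full rule set of the model
#'
#' Assembles every stochastic rewrite rule: polymerization/depolymerization
#' at both ends, ATP hydrolysis and Pi release, Arp2/3 branching and
#' debranching, capping/uncapping, the three cofilin binding modes and
#' unbinding, CaMKII-beta bundling/unbundling, angle-gated breaking, Aip1
#' binding and severing (omitted when `params$aip1_model` is FALSE), the
#' three mutually exclusive buckling rules, the angle-bending rules, Hessian
#' thermal noise, and the membrane curvature update.
#'
#' @param params Resolved parameters.
#' @return A list of rule objects (each with `name`, `enumerate`, `fire`).
#' @export
build_ruleset <- function(params = resolve_params()) {
  rules <- list(
    rule_elongate_barbed(), rule_retract_barbed(),
    rule_elongate_pointed(), rule_retract_pointed(),
    rule_hydrolysis(), rule_pi_release(),
    rule_branch(), rule_debranch(),
    rule_cap(), rule_uncap(),
    rule_cofilin_bare(), rule_cofilin_edge(), rule_cofilin_seed(),
    rule_cofilin_unbind(),
    rule_camkii_bind(), rule_camkii_unbind(),
    rule_break(),
    rule_aip1_bind(), rule_aip1_sever(),
    rule_buckle_interior(), rule_buckle_branch(), rule_buckle_end(),
    rule_bend_center(), rule_bend_end1(), rule_bend_end2(),
    rule_thermal(),
    rule_membrane()
  )
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  rules
}

# refresh the per-step caches used by rule enumerations
.refresh_caches <- function(S) {
  S$ids_cache <- live_nodes(S)
  S$area_cache <- abs(polygon_area(S$mem))
  invisible(S)
}

#' Enumerate the concrete instances of one rule
#'
#' Returns every embedding of the rule's left-hand-side motif in the current
#' state together with its evaluated propensity (embeddings with zero
#' propensity may be omitted). Embeddings are listed in ascending node-id
#' order.
#'
#' @param S A `spine_state`.
#' @param rule A rule object from [build_ruleset()] (or its name).
#' @param rules Rule set to look the name up in (when `rule` is a string).
#' @return A data.frame of instances with a `prop` column.
#' @export
enumerate_instances <- function(S, rule, rules = NULL) {
  if (is.character(rule)) {
    if (is.null(rules)) rules <- build_ruleset(S$params)
    rule <- rules[[rule]]
    if (is.null(rule)) stop("configuration error: unknown rule name")
  }
  if (!is.list(rule) || !is.function(rule$enumerate))
    stop("configuration error: malformed rule object")
  .refresh_caches(S)
  as.data.frame(rule$enumerate(S))
}

#' Fire one rule instance
#'
#' Applies the rewrite of a concrete embedding. Instances referring to nodes
#' that no longer exist (stale embeddings) are rejected without any state
#' change. After the rewrite, barbed ends touched by the rule are checked
#' for membrane attachment creation and removal.
#'
#' @param S A `spine_state`.
#' @param rule Rule object.
#' @param inst One-row data.frame (a row of [enumerate_instances()] output).
#' @return TRUE if the instance fired, FALSE if it was rejected as stale.
#' @export
fire_instance <- function(S, rule, inst) {
  idcols <- intersect(c("id", "a", "b", "u", "j", "w"), names(inst))
  for (cl in idcols) {
    v <- inst[[cl]]
    if (v < 1 || v > S$nn || !S$alive[v]) return(FALSE)
  }
  if ("link" %in% names(inst) && !S$bl_alive[inst$link]) return(FALSE)
  if ("v" %in% names(inst) && inst$v > nrow(S$mem)) return(FALSE)
  touched <- rule$fire(S, inst)
  S$n_events <- S$n_events + 1L
  if (length(touched)) {
    touched <- touched[touched > 0 & touched <= S$nn]
    touched <- touched[S$alive[touched]]
    for (id in touched) {
      if (S$kind[id] == KIND_BARBED) {
        .detach_check(S, id)
        .attach_check(S, id)
      } else if (S$vref[id] > 0) {
        .detach_check(S, id)
      }
    }
  }
  TRUE
}

#' Advance the simulation by one stochastic event
#'
#' One step of the Gillespie direct method: all rule instances are
#' enumerated, a waiting time `dt ~ Exponential(a0)` is drawn from the total
#' propensity `a0`, the pool ODEs are advanced by `dt`, one instance is
#' selected with probability proportional to its propensity, and its rewrite
#' is applied atomically. If `a0 = 0` the state is flagged quiescent and
#' returned unchanged.
#'
#' @param S A `spine_state`.
#' @param rules Rule set from [build_ruleset()].
#' @return Invisibly, a list with `fired` (rule name or NA), `dt`, and `a0`.
#' @export
ssa_step <- function(S, rules) {
  .refresh_caches(S)
  tabs <- lapply(rules, function(rl) rl$enumerate(S))
  tot <- vapply(tabs, function(tb) sum(tb$prop), numeric(1))
  a0 <- sum(tot)
  if (!is.finite(a0) || a0 <= 0) {
    S$quiescent <- TRUE
    return(invisible(list(fired = NA_character_, dt = 0, a0 = a0)))
  }
  dt <- stats::rexp(1, a0)
  S$pools <- ode_advance(S$pools, S$params, dt, S$area_cache)
  ri <- sample.int(length(rules), 1, prob = tot)
  tb <- tabs[[ri]]
  ni <- length(tb$prop)
  ii <- if (ni == 1) 1L else sample.int(ni, 1, prob = tb$prop)
  inst <- lapply(tb, `[`, ii)
  fire_instance(S, rules[[ri]], inst)
  S$time <- S$time + dt
  invisible(list(fired = rules[[ri]]$name, dt = dt, a0 = a0))
}

#' Total mechanical energy of the state
#'
#' The global energy whose local terms drive every kinetic rule: the summed
#' clipped separation potential over filament, bundling and attachment
#' edges, the angular bending energy over connected triples (with
#' cofilin-softened stiffness), and the membrane's discrete Helfrich energy.
#'
#' @param S A `spine_state`.
#' @return Scalar energy (kT).
#' @export
total_energy <- function(S) {
  par <- S$params
  .refresh_caches(S)
  ids <- S$ids_cache
  e <- 0
  # separation edges (each once): next edges, branch edges
  for (id in ids) {
    for (b in c(S$nxt[id], S$brn[id])) if (b > 0) {
      r <- sqrt((S$x[id] - S$x[b])^2 + (S$y[id] - S$y[b])^2)
      e <- e + u_sep_clipped(r, eps = par$internal$eps_LJ,
                             sigma = .edge_rest(S, id, b) * 2^(-1 / 6),
                             eps_clip = par$eps_clip)
    }
  }
  lk <- which(S$bl_alive)
  for (l in lk) {
    r <- sqrt((S$x[S$bl_a[l]] - S$x[S$bl_b[l]])^2 +
                (S$y[S$bl_a[l]] - S$y[S$bl_b[l]])^2)
    e <- e + u_sep_clipped(r, eps = par$internal$eps_LJ,
                           sigma = S$bl_rest[l] * 2^(-1 / 6),
                           eps_clip = par$eps_clip)
  }
  att <- which(S$vnode > 0)
  for (v in att) {
    a <- S$vnode[v]
    r <- sqrt((S$x[a] - S$mem[v, 1])^2 + (S$y[a] - S$mem[v, 2])^2)
    e <- e + u_sep_clipped(r, eps = par$internal$eps_LJ,
                           eps_clip = par$eps_clip)
  }
  tr <- .bend_triples(S)
  if (length(tr$u)) for (k in seq_along(tr$u)) {
    e <- e + angle_energy(c(S$x[tr$u[k]], S$y[tr$u[k]]),
                          c(S$x[tr$j[k]], S$y[tr$j[k]]),
                          c(S$x[tr$w[k]], S$y[tr$w[k]]),
                          tr$tgt[k], .k_bend_eff(S, tr$j[k]))
  }
  e + membrane_energy(S$mem, par$internal$kappa_mem)
}

#' Run a spine-head simulation
#'
#' Initializes the standard initial condition (a circular membrane of the
#' configured radius enclosing a two-node seed filament, pools at the basal
#' steady state), then repeatedly applies [ssa_step()] until the time
#' horizon, the event budget, or quiescence is reached. Membrane
#' morphometrics are recorded on a fixed time grid.
#'
#' @param params Resolved parameters.
#' @param seed Integer RNG seed (all stochastic draws flow from it).
#' @param t_end Simulation horizon (s).
#' @param snapshot_every Morphometrics recording interval (s).
#' @param max_events Safety cap on the number of events.
#' @param state Optional pre-built initial state (default: `seed_spine`).
#' @return A list with `state` (final `spine_state`), `morpho` (data.frame
#'   of time, area, perimeter, aspect ratio; lengths in micrometres), and
#'   `n_events`.
#' @export
simulate_spine <- function(params = resolve_params(), seed = 1L, t_end = 5,
                           snapshot_every = 1, max_events = 5e5,
                           state = NULL) {
  set.seed(seed)
  S <- if (is.null(state)) make_fixture("seed_spine", seed, params) else state
  rules <- build_ruleset(params)
  scale <- params$internal$l0 * 1e6   # micrometres per internal unit
  snaps <- seq(0, t_end, by = snapshot_every)
  rec <- vector("list", length(snaps))
  k <- 1
  record <- function() {
    m <- measure_membrane(S$mem, scale)
    m$time <- snaps[k]
    rec[[k]] <<- m
    k <<- k + 1
  }
  record()
  while (S$time < t_end && !S$quiescent && S$n_events < max_events) {
    ssa_step(S, rules)
    while (k <= length(snaps) && S$time >= snaps[k]) record()
  }
  while (k <= length(snaps)) record()
  morpho <- do.call(rbind, rec)
  morpho <- morpho[, c("time", "area", "perimeter", "aspect_ratio")]
  list(state = S, morpho = morpho, n_events = S$n_events)
}
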