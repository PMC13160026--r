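# Well-mixed free-protein pools.
#
# Each species M follows dM/dt = I_M (+ I_S,M when stimulated) - k_M * M in
# concentration units; the simulator carries pools as molecule counts in the
# membrane-enclosed effective volume V_eff = area * slab thickness, so the
# same linear ODE holds for counts with the influx scaled by N_A * V_eff.

.AVOGADRO <- 6.02214076e23

.pool_species <- c("actin", "actin_ADP", "arp23", "cof", "camkii", "cap", "aip1")

# effective volume in litres from membrane area in internal units^2
.v_eff_litre <- function(area_internal, params) {
  area_m2 <- area_internal * params$internal$l0^2
  area_m2 * params$slab_thickness * 1000
}

# per-species (synthesis, influx, degradation) triple from the config
.pool_rates <- function(params, species) {
  list(synth = params[[paste0("k_synth_", species)]],
       influx = params[[paste0("k_influx_", species)]],
       deg = params[[paste0("k_deg_", species)]])
}

#' Initialize pools at the basal steady state
#'
#' Every species starts at the fixed point of its synthesis/degradation
#' balance, `M_ss = I_M / k_M`, converted to molecule counts in the
#' membrane-enclosed effective volume (area times slab thickness).
#'
#' @param params Resolved parameters ([resolve_params()]).
#' @param area_internal Membrane-enclosed area in internal units squared.
#' @return Named numeric vector of molecule counts (actin counted in
#'   monomers).
#' @export
init_steady_state <- function(params, area_internal) {
  v <- .v_eff_litre(area_internal, params)
  out <- vapply(.pool_species, function(sp) {
    r <- .pool_rates(params, sp)
    max(0, r$synth / r$deg) * .AVOGADRO * v
  }, numeric(1))
  names(out) <- .pool_species
  out
}

#' Advance the pool ODEs by a time step
#'
#' Exact (closed-form) solution of the linear synthesis/degradation ODE for
#' each species over `dt`:
#' `N(t+dt) = N_ss + (N(t) - N_ss) exp(-k dt)` with
#' `N_ss = (I + I_S) N_A V_eff / k`. The stimulated influx `I_S` enters only
#' when `stimulated = TRUE` (the LTP mode); it is negative for CaMKII-beta,
#' whose concentration falls during potentiation. Counts are clamped at zero
#' (the closed form can otherwise undershoot when the stimulated fixed point
#' is negative).
#'
#' @param pools Named count vector (see [init_steady_state()]).
#' @param params Resolved parameters.
#' @param dt Time step (s).
#' @param area_internal Current membrane-enclosed area (internal units^2).
#' @param stimulated Include the stimulated influx terms.
#' @return Updated named count vector.
#' @export
ode_advance <- function(pools, params, dt, area_internal,
                        stimulated = params$ltp) {
  if (dt == 0) return(pools)
  v <- .v_eff_litre(area_internal, params)
  rt <- .pool_rate_table(params)
  inflow <- rt$synth + if (stimulated) rt$influx else 0
  ninf <- inflow * .AVOGADRO * v
  out <- pools
  pos <- rt$deg > 0
  nss <- ifelse(pos, ninf / rt$deg, 0)
  out[pos] <- nss[pos] + (pools[pos] - nss[pos]) * exp(-rt$deg[pos] * dt)
  out[!pos] <- pools[!pos] + ninf[!pos] * dt
  out[out < 0] <- 0
  out
}

# rate triples for all species as vectors (cached on the parameter list)
.pool_rate_table <- function(params) {
  tb <- params$.pool_rate_cache
  if (!is.null(tb)) return(tb)
  list(synth = vapply(.pool_species, function(sp)
         params[[paste0("k_synth_", sp)]], numeric(1)),
       influx = vapply(.pool_species, function(sp)
         params[[paste0("k_influx_", sp)]], numeric(1)),
       deg = vapply(.pool_species, function(sp)
         params[[paste0("k_deg_", sp)]], numeric(1)))
}

#' Convert a molar rate constant to a per-second propensity factor
#'
#' Binding rate constants are tabulated per molar per second; inside the
#' simulated compartment the corresponding propensity factor is
#' `k_on * N_free / (N_A * V_eff)`, i.e. the rate constant times the current
#' free concentration implied by the molecule count and the membrane-enclosed
#' effective volume.
#'
#' @param k_on Rate constant (1/(M s)).
#' @param n_free Free molecule count of the binding species.
#' @param area_internal Membrane-enclosed area (internal units^2).
#' @param params Resolved parameters.
#' @return Propensity factor (1/s).
#' @export
convert_rate <- function(k_on, n_free, area_internal, params) {
  if (n_free <= 0) return(0)
  k_on * n_free / (.AVOGADRO * .v_eff_litre(area_internal, params))
}

#' Scale a species' synthesis rate for a parameter sweep
#'
#' Multiplies the basal synthesis rate (and, optionally, the stimulated
#' influx) of one pool species by `factor`; the sweep drivers build their
#' dose grids by repeated application. A factor of 1 is the identity and
#' factors `f` and `1/f` compose to the identity.
#'
#' @param params Raw or resolved parameter list.
#' @param species One of `"actin"`, `"arp23"`, `"cof"`, `"camkii"`, `"cap"`,
#'   `"aip1"`.
#' @param factor Positive multiplier.
#' @param scale_influx Also scale the stimulated influx term.
#' @return The modified parameter list (re-resolved if it was resolved).
#' @export
apply_sweep_multiplier <- function(params, species, factor,
                                   scale_influx = FALSE) {
  species <- match.arg(species, .pool_species)
  key <- paste0("k_synth_", species)
  params[[key]] <- params[[key]] * factor
  if (scale_influx) {
    ik <- paste0("k_influx_", species)
    params[[ik]] <- params[[ik]] * factor
  }
  if (inherits(params, "spine_params")) params <- resolve_params(params)
  params
}
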