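# Model parameters and unit conversion.
#
# All user-facing parameters are stored in laboratory units (molar, seconds,
# metres, joules). The simulator works in internal units:
#   length: one coarse-grained segment rest length l0 = N_CG * 2.7 nm
#   energy: kT at the simulation temperature
#   time:   seconds
# resolve_params() performs the conversion once, up front, and records every
# converted value so the mapping is auditable.

#' Default model parameters
#'
#' Returns the full parameter set of the spine-head model in laboratory
#' units: rate constants for actin polymerization/depolymerization at both
#' filament ends, nucleotide dynamics, Arp2/3 branching and debranching,
#' capping, cofilin binding/unbinding, CaMKII-beta bundling, Aip1 binding and
#' severing, angle-gated filament breaking thresholds, mechanical constants
#' (Lennard-Jones dissociation energy, actin spring constant, bending
#' stiffness, drag coefficients, membrane curvature modulus), and the
#' synthesis / stimulated-influx / degradation triples for each well-mixed
#' protein pool.
#'
#' Keys follow the conventional subscript notation of the actin literature
#' (`k_barbed_on_ATP`, `k_sever`, `k_synth_actin`, ...). Rate constants with
#' molar units are converted to per-second propensity factors at run time via
#' [convert_rate()] using the current membrane-enclosed volume.
#'
#' @return A named list of parameters (class `spine_params_raw`).
#' @export
#' @examples
#' p <- default_params()
#' p$k_sever # 1.43 per second
default_params <- function() {
  p <- list(
    ## global / numerical
    k_kinetic          = 0.35,      # 1/s, propensity of each kinetic (mechanics) rule
    r_spinehead_init   = 0.125e-6,  # m, starting spine head radius
    N_CG               = 12,        # monomers per coarse-grained object
    monomer_rise       = 2.7e-9,    # m, rise per monomer along the filament
    temperature        = 310,       # K
    k_Boltzmann        = 1.380649e-23, # J/K
    eps_clip           = 0.75,      # clipping factor for the LJ potential
    eps_sep            = 1e-6,      # separation-Hessian regularizer (internal units)
    eps_ang            = 1e-6,      # bending-Hessian regularizer (internal units)

    ## mechanics
    theta_Arp          = 70,        # degrees, Arp2/3 branch angle
    k_s                = 15.9,      # N/m, monomer-monomer spring constant
    k_B_bend           = 4.0e-26,   # N m^2, flexural rigidity of actin
    eps_LJ             = 7.36e-16,  # J, dissociation energy of one coarse-grained bond
    DU_bundle          = 0.0175e-6, # m, CaMKII-beta binding distance constraint
    theta_Bundle       = 15,        # degrees, CaMKII-beta bundling angle constraint
    k_s_arp23          = 20,        # N/m, branch bond spring constant
    k_s_camkii         = 20,        # N/m, bundling bond spring constant
    zeta_actin         = 500,       # N s/m, drag coefficient of an actin object
    zeta_mem           = 500,       # N s/m, drag coefficient of a membrane vertex
    L_p                = 17.7e-6,   # m, persistence length of actin
    kappa_mem          = 5e-22,     # J, membrane curvature modulus (per unit internal length)
    cofilin_soften     = 5,         # x-fold bending-stiffness reduction at full cofilin occupancy

    ## breaking thresholds (degrees)
    theta_break_actin      = 57,
    theta_break_cofilactin = 73,
    theta_break_boundary   = 31,
    k_break            = 0.35,      # 1/s, firing rate of an angle-eligible breaking site

    ## polymerization (per-monomer rates)
    k_barbed_on_ATP    = 11.6e6,    # 1/(M s)
    k_barbed_off_ATP   = 1.4,       # 1/s
    k_pointed_on_ATP   = 1.3e6,     # 1/(M s)
    k_pointed_off_ATP  = 0.8,       # 1/s
    k_barbed_on_ADP    = 3.8e6,     # 1/(M s)
    k_barbed_off_ADP   = 7.2,       # 1/s
    k_pointed_on_ADP   = 0.16e6,    # 1/(M s)
    k_pointed_off_ADP  = 0.27,      # 1/s

    ## branching / capping
    k_branch           = 3000,      # 1/(M s)
    k_unbranch         = 0.47,      # 1/s
    k_cap_on           = 6.3e6,     # 1/(M s)
    k_cap_off          = 0.95,      # 1/s (end-capping off rate; printed exponent ambiguous)
    k_debranch         = 2e-3,      # 1/s
    sigma_comp         = 4.0,       # cofilin-vs-Arp2/3 on-site competition constant
    k_comp             = 45,        # neighbor-strain acceleration; with sigma_comp gives x50 at full occupancy

    ## nucleotide dynamics
    k_ATP_hydrolysis   = 0.35,      # 1/s per monomer
    k_Pi               = 0.006,     # 1/s per monomer
    k_cof_Pi           = 0.035,     # 1/s per monomer with adjacent cofilin

    ## cofilin
    k_cof_on_edge_ADP  = 17e6,      # 1/(M s), cooperative edge binding
    k_cof_off          = 0.7,       # 1/s
    k_single_on_cof    = 1e4,       # 1/(M s), isolated binding

    ## CaMKII-beta
    k_camkii_on        = 0.5e6,     # 1/(M s)
    k_camkii_off       = 0.23,      # 1/s

    ## Aip1
    k_on_aip1          = 112e6,     # 1/(M s), binding to cofilactin
    k_sever            = 1.43,      # 1/s per bound Aip1

    ## pools: synthesis (M/s), stimulated influx (M/s), degradation (1/s)
    k_synth_actin      = 19.5e-6,  k_influx_actin  = 18.8e-6,  k_deg_actin  = 0.096,
    # the free ADP-actin sub-pool is fed only by depolymerization
    k_synth_actin_ADP  = 0,        k_influx_actin_ADP = 0,     k_deg_actin_ADP = 0.096,
    k_synth_arp23      = 2.6e-6,   k_influx_arp23  = 0.41e-6,  k_deg_arp23  = 0.053,
    k_synth_cof        = 0.47e-6,  k_influx_cof    = 0.78e-6,  k_deg_cof    = 0.057,
    k_synth_camkii     = 4.29e-6,  k_influx_camkii = -1.96e-6, k_deg_camkii = 0.052,
    k_synth_cap        = 0.0046e-6, k_influx_cap   = 0.0014e-6, k_deg_cap   = 0.052,
    # Aip1 turnover is not tabulated in the source literature; defaults give a
    # 0.5 uM basal steady state, a few discrete molecules in the compartment
    # (see the methods vignette).
    k_synth_aip1       = 2.6e-8,   k_influx_aip1   = 0,        k_deg_aip1   = 0.052,

    ## membrane / coupling
    slab_thickness     = 0.25e-6,   # m, effective thickness converting area to volume
    membrane_vertices  = 64,        # initial polygon resolution
    overgrowth         = 0.5,       # l0, pseudo-extension length for attachment tests
    detach_factor      = 2,         # attachment removed beyond detach_factor * r_min
    aip1_model         = TRUE,      # include the Aip1 binding/severing mechanism
    ltp                = FALSE,     # stimulated influx terms active
    seed_nucleotide    = "ADP"      # nucleotide state of the pre-existing seed filament
  )
  class(p) <- c("spine_params_raw", "list")
  p
}

#' Resolve parameters to internal simulation units
#'
#' Converts the laboratory-unit parameter list of [default_params()] into the
#' internal unit system (length in coarse-grained rest lengths `l0`, energy in
#' `kT`, time in seconds). Derived quantities are added: `l0` (m), `kT_J` (J),
#' `sigma_LJ = 2^(-1/6)` so the separation-potential minimum sits at one
#' internal length unit, the bending constant per unit length, the elongation
#' angle spread `sigma_theta = sqrt(2 l0 / L_p)` of semiflexible-polymer
#' statistics, drag coefficients, and the branch/bundling geometric gates in
#' internal length units.
#'
#' @param raw A parameter list from [default_params()] (possibly modified).
#' @return A named list of class `spine_params` with both the raw values and
#'   the `internal` sub-list of converted values.
#' @export
resolve_params <- function(raw = default_params()) {
  stopifnot(is.list(raw))
  req <- c("k_kinetic", "N_CG", "monomer_rise", "temperature", "k_Boltzmann",
           "eps_LJ", "k_B_bend", "zeta_actin", "zeta_mem", "L_p", "eps_clip",
           "kappa_mem", "r_spinehead_init")
  missing <- setdiff(req, names(raw))
  if (length(missing))
    stop("configuration error: missing required parameter(s): ",
         paste(missing, collapse = ", "))
  pos <- c("k_kinetic", "N_CG", "temperature", "eps_LJ", "k_B_bend",
           "zeta_actin", "zeta_mem", "L_p", "kappa_mem", "r_spinehead_init")
  for (key in pos)
    if (!is.numeric(raw[[key]]) || raw[[key]] <= 0)
      stop("configuration error: parameter '", key, "' must be positive")
  if (raw$eps_clip <= 0 || raw$eps_clip >= 1)
    stop("configuration error: eps_clip must lie in (0, 1)")

  l0 <- raw$N_CG * raw$monomer_rise           # m per internal length unit
  kT <- raw$k_Boltzmann * raw$temperature     # J per internal energy unit

  internal <- list(
    l0          = l0,
    kT_J        = kT,
    # separation potential: minimum at r_min = 1 internal unit
    r_min       = 1,
    sigma_LJ    = 2^(-1 / 6),
    eps_LJ      = raw$eps_LJ / kT,                    # kT
    eps_clip_r  = raw$eps_clip * 1,                   # clip point (internal length)
    # bending: flexural rigidity / rest length -> energy per rad^2
    k_bend      = raw$k_B_bend / l0 / kT,             # kT / rad^2
    # drag: N s/m -> kT s / l0^2
    zeta_actin  = raw$zeta_actin * l0^2 / kT,
    zeta_mem    = raw$zeta_mem * l0^2 / kT,
    # membrane curvature modulus: J per unit internal length -> kT * l0
    kappa_mem   = raw$kappa_mem / kT,
    sigma_theta = sqrt(2 * l0 / raw$L_p),             # rad
    theta_Arp   = raw$theta_Arp * pi / 180,           # rad
    theta_Bundle = raw$theta_Bundle * pi / 180,       # rad
    DU_bundle   = raw$DU_bundle / l0,                 # internal length
    r_init      = raw$r_spinehead_init / l0,          # internal length
    theta_break_actin      = raw$theta_break_actin * pi / 180,
    theta_break_cofilactin = raw$theta_break_cofilactin * pi / 180,
    theta_break_boundary   = raw$theta_break_boundary * pi / 180,
    eps_sep     = raw$eps_sep,
    eps_ang     = raw$eps_ang
  )
  out <- raw
  out$internal <- internal
  out$.pool_rate_cache <- NULL
  class(out) <- c("spine_params", "list")
  out$.pool_rate_cache <- .pool_rate_table(out)
  out
}

#' Read a configuration file
#'
#' Loads a YAML configuration of model parameters, overlays it on
#' [default_params()], validates it, and resolves it to internal units.
#' Unknown keys are rejected so typos cannot silently revert a parameter to
#' its default.
#'
#' @param path Path to a YAML file of parameter overrides.
#' @return A resolved parameter list (see [resolve_params()]).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_params()
  if (length(cfg)) {
    unknown <- setdiff(names(cfg), names(base))
    if (length(unknown))
      stop("configuration error: unknown parameter key(s): ",
           paste(unknown, collapse = ", "))
    base[names(cfg)] <- cfg
  }
  resolve_params(base)
}

#' Write a configuration file
#'
#' Serializes the laboratory-unit portion of a parameter list to YAML so that
#' `load_config(write_config(p, f))` round-trips exactly.
#'
#' @param params A raw or resolved parameter list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  p <- unclass(params)
  p$internal <- NULL
  p$.pool_rate_cache <- NULL
  yaml::write_yaml(p, path)
  invisible(path)
}
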