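# Biochemical rewrite rules of the actin graph grammar: polymerization and
# depolymerization at both filament ends, nucleotide state dynamics, Arp2/3
# branch nucleation and debranching, barbed-end capping, cofilin binding
# modes, CaMKII-beta bundling, angle-gated filament breaking, and Aip1
# binding/severing.
#
# Each rule is a list(name, enumerate, fire). enumerate(S) returns a
# data.frame of concrete embeddings with their propensities (column `prop`);
# fire(S, inst) applies the rewrite of one embedding and returns the ids of
# touched nodes (used by the engine's membrane attachment hook). Rules use
# the per-step caches S$ids_cache (live ids) and S$area_cache (membrane
# area) set by the engine.

.no_inst <- list(id = integer(0), prop = numeric(0))

# value of `vec` at (possibly zero) indices, with a default for index 0
.at <- function(vec, idx, default) {
  out <- rep(default, length(idx))
  ok <- idx > 0
  out[ok] <- vec[idx[ok]]
  out
}

# combined free-actin monomer count
.actin_avail <- function(S) S$pools[["actin"]] + S$pools[["actin_ADP"]]

# draw the nucleotide state of a newly polymerized object from the pool
# composition weighted by the end-specific on-rates, decrement the chosen
# sub-pool, and return "ATP" or "ADP"
.draw_new_state <- function(S, nmono, k_on_ATP, k_on_ADP) {
  wA <- k_on_ATP * S$pools[["actin"]]
  wD <- k_on_ADP * S$pools[["actin_ADP"]]
  st <- if (stats::runif(1) * (wA + wD) < wD) "ADP" else "ATP"
  pool <- if (st == "ADP") "actin_ADP" else "actin"
  other <- if (pool == "actin") "actin_ADP" else "actin"
  # when the sampled sub-pool cannot supply a whole object, draw the
  # remainder from the other one; the object is labelled by its majority
  # source so monomer totals stay exactly conserved
  take <- min(nmono, S$pools[[pool]])
  rest <- nmono - take
  S$pools[[pool]] <- S$pools[[pool]] - take
  if (rest > 0) S$pools[[other]] <- S$pools[[other]] - rest
  if (rest > take) st <- if (st == "ATP") "ADP" else "ATP"
  st
}

# monomer count per node over a set of ids
.n_mono <- function(S, ids) S$nATP[ids] + S$nPi[ids] + S$nADP[ids]

# rest length of the separation edge between adjacent nodes a and b:
# partial end segments shorten their terminal edge
.edge_rest <- function(S, a, b) {
  ra <- if (S$kind[a] %in% c(KIND_BARBED, KIND_POINTED, KIND_CAPPED))
    S$restlen[a] else 1
  rb <- if (S$kind[b] %in% c(KIND_BARBED, KIND_POINTED, KIND_CAPPED))
    S$restlen[b] else 1
  min(ra, rb)
}

# distance along direction `dir` from point p to the first membrane-edge
# crossing (Inf if none within `maxlen`)
.ray_gap <- function(S, p, dir, maxlen = 10) {
  V <- S$mem
  Vp <- .shift(V, 1)
  ex <- Vp[, 1] - V[, 1]; ey <- Vp[, 2] - V[, 2]
  denom <- dir[1] * ey - dir[2] * ex
  qx <- V[, 1] - p[1]; qy <- V[, 2] - p[2]
  t <- (qx * ey - qy * ex) / denom
  u <- (qx * dir[2] - qy * dir[1]) / denom
  ok <- is.finite(t) & t > 1e-9 & t <= maxlen & u >= -1e-9 & u <= 1 + 1e-9
  if (!any(ok)) Inf else min(t[ok])
}

# ratchet multiplier for an attached end: compressive load along the
# filament axis carried by the attachment edge
.end_ratchet <- function(S, id, delta) {
  v <- S$vref[id]
  if (v == 0) return(1)
  p <- S$prv[id]; if (p == 0) p <- S$brnp[id]
  if (p == 0) return(1)
  dirv <- c(S$x[id] - S$x[p], S$y[id] - S$y[p])
  dirv <- dirv / sqrt(sum(dirv^2))
  dv <- c(S$x[id] - S$mem[v, 1], S$y[id] - S$mem[v, 2])
  r <- sqrt(sum(dv^2))
  if (r < 1e-12) return(1)
  par <- S$params
  f <- -grad_sep_clipped(r, eps = par$internal$eps_LJ,
                         eps_clip = par$eps_clip)  # force on end, along dv/r
  load <- -sum(f * dv / r * dirv)   # compressive if force opposes the axis
  ratchet_factor(load, delta)
}

# release a node's bound proteins back to the pools (used before deletion)
.release_occupancy <- function(S, id) {
  S$pools[["cof"]] <- S$pools[["cof"]] + S$ncof[id] + as.integer(S$cofS[id])
  if (S$aip1[id]) S$pools[["aip1"]] <- S$pools[["aip1"]] + 1
  if (S$capA[id]) S$pools[["aip1"]] <- S$pools[["aip1"]] + 1
  if (S$kind[id] == KIND_CAPPED && !S$capA[id])
    S$pools[["cap"]] <- S$pools[["cap"]] + 1
  if (S$camk[id] > 0) S$pools[["camkii"]] <- S$pools[["camkii"]] + 1
  if (S$arp[id]) S$pools[["arp23"]] <- S$pools[["arp23"]] + 1
  invisible(S)
}

# ---- polymerization ---------------------------------------------------------

rule_elongate_barbed <- function() list(
  name = "elongate_barbed",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    ids <- ids[S$kind[ids] == KIND_BARBED &
                 (S$prv[ids] > 0 | S$brnp[ids] > 0)]
    if (!length(ids) || .actin_avail(S) < par$N_CG) return(.no_inst)
    base <- (convert_rate(par$k_barbed_on_ATP, S$pools[["actin"]],
                          S$area_cache, par) +
             convert_rate(par$k_barbed_on_ADP, S$pools[["actin_ADP"]],
                          S$area_cache, par)) / par$N_CG
    prop <- rep(base, length(ids))
    for (k in seq_along(ids)) {
      id <- ids[k]
      p <- .parent_of(S, id)
      dirv <- c(S$x[id] - S$x[p], S$y[id] - S$y[p])
      nd <- sqrt(sum(dirv^2)); dirv <- dirv / nd
      gap <- .ray_gap(S, c(S$x[id], S$y[id]), dirv)
      if (S$vref[id] > 0) {
        # adaptive sub-unit stepping against the membrane
        step <- min(1, max(0, gap - 0.05))
        if (step < 0.25) { prop[k] <- 0; next }
        prop[k] <- prop[k] * .end_ratchet(S, id, step)
      } else if (gap < 1 - par$overgrowth) {
        prop[k] <- 0   # a full step would overshoot the membrane
      }
    }
    list(id = ids, prop = prop)
  },
  fire = function(S, inst) {
    par <- S$params
    id <- inst$id
    p <- .parent_of(S, id)
    dirv <- c(S$x[id] - S$x[p], S$y[id] - S$y[p])
    dirv <- dirv / sqrt(sum(dirv^2))
    th <- stats::rnorm(1, 0, par$internal$sigma_theta)
    step <- 1
    if (S$vref[id] > 0) {
      gap <- .ray_gap(S, c(S$x[id], S$y[id]), dirv)
      step <- min(1, max(0.25, gap - 0.05))
    }
    newd <- as.numeric(rot2(th) %*% dirv) * step
    nx <- S$x[id] + newd[1]; ny <- S$y[id] + newd[2]
    if (!points_in_polygon(c(nx, ny), S$mem) &&
        .dist_to_polygon(c(nx, ny), S$mem) > par$overgrowth)
      return(integer(0))   # step would overshoot the membrane
    nmono <- max(1L, as.integer(round(par$N_CG * step)))
    st <- .draw_new_state(S, nmono, par$k_barbed_on_ATP, par$k_barbed_on_ADP)
    nid <- node_add(S, KIND_BARBED, nx, ny,
                    nATP = if (st == "ATP") nmono else 0L,
                    nADP = if (st == "ADP") nmono else 0L)
    S$restlen[nid] <- step
    link_next(S, id, nid)
    S$kind[id] <- KIND_INTERIOR
    S$restlen[id] <- 1
    if (S$vref[id] > 0) {           # attachment follows the growing end
      v <- S$vref[id]
      S$vref[id] <- 0L; S$vnode[v] <- nid; S$vref[nid] <- v
    }
    update_angles(S, c(p, id, nid))
    c(id, nid)
  })

rule_retract_barbed <- function() list(
  name = "retract_barbed",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    ids <- ids[S$kind[ids] == KIND_BARBED & S$vref[ids] == 0 & S$prv[ids] > 0]
    if (!length(ids)) return(.no_inst)
    p <- S$prv[ids]
    keep <- S$kind[p] != KIND_JUNCTION & (S$prv[p] > 0 | S$brnp[p] > 0)
    ids <- ids[keep]
    if (!length(ids)) return(.no_inst)
    nm <- .n_mono(S, ids)
    prop <- (S$nATP[ids] * par$k_barbed_off_ATP +
               (S$nPi[ids] + S$nADP[ids]) * par$k_barbed_off_ADP) / pmax(nm, 1)
    list(id = ids, prop = prop)
  },
  fire = function(S, inst) {
    id <- inst$id
    p <- S$prv[id]
    S$pools[["actin"]] <- S$pools[["actin"]] + S$nATP[id]
    S$pools[["actin_ADP"]] <- S$pools[["actin_ADP"]] + S$nPi[id] + S$nADP[id]
    .release_occupancy(S, id)
    node_del(S, id)   # also detaches any bundling link
    S$kind[p] <- KIND_BARBED
    S$theta[p] <- 0
    S$restlen[p] <- 1
    update_angles(S, S$prv[p])
    p
  })

rule_elongate_pointed <- function() list(
  name = "elongate_pointed",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    ids <- ids[S$kind[ids] == KIND_POINTED & S$nxt[ids] > 0]
    if (!length(ids) || .actin_avail(S) < par$N_CG) return(.no_inst)
    base <- (convert_rate(par$k_pointed_on_ATP, S$pools[["actin"]],
                          S$area_cache, par) +
             convert_rate(par$k_pointed_on_ADP, S$pools[["actin_ADP"]],
                          S$area_cache, par)) / par$N_CG
    prop <- rep(base, length(ids))
    for (k in seq_along(ids)) {
      id <- ids[k]
      nx <- S$nxt[id]
      dirv <- c(S$x[id] - S$x[nx], S$y[id] - S$y[nx])
      dirv <- dirv / sqrt(sum(dirv^2))
      if (.ray_gap(S, c(S$x[id], S$y[id]), dirv) < 1 - par$overgrowth)
        prop[k] <- 0
    }
    list(id = ids, prop = prop)
  },
  fire = function(S, inst) {
    par <- S$params
    id <- inst$id
    nx <- S$nxt[id]
    dirv <- c(S$x[id] - S$x[nx], S$y[id] - S$y[nx])
    dirv <- dirv / sqrt(sum(dirv^2))
    th <- stats::rnorm(1, 0, par$internal$sigma_theta)
    newd <- as.numeric(rot2(-th) %*% dirv)   # reverse-traversal sign
    px <- S$x[id] + newd[1]; py <- S$y[id] + newd[2]
    if (!points_in_polygon(c(px, py), S$mem) &&
        .dist_to_polygon(c(px, py), S$mem) > par$overgrowth)
      return(integer(0))
    st <- .draw_new_state(S, par$N_CG, par$k_pointed_on_ATP,
                          par$k_pointed_on_ADP)
    nid <- node_add(S, KIND_POINTED, px, py,
                    nATP = if (st == "ATP") par$N_CG else 0L,
                    nADP = if (st == "ADP") par$N_CG else 0L)
    link_next(S, nid, id)
    S$kind[id] <- KIND_INTERIOR
    update_angles(S, c(nid, id, nx))
    c(id, nid)
  })

rule_retract_pointed <- function() list(
  name = "retract_pointed",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    ids <- ids[S$kind[ids] == KIND_POINTED & S$nxt[ids] > 0]
    if (!length(ids)) return(.no_inst)
    nx <- S$nxt[ids]
    ids <- ids[S$kind[nx] != KIND_JUNCTION & S$nxt[nx] > 0]
    if (!length(ids)) return(.no_inst)
    nm <- .n_mono(S, ids)
    prop <- (S$nATP[ids] * par$k_pointed_off_ATP +
               (S$nPi[ids] + S$nADP[ids]) * par$k_pointed_off_ADP) / pmax(nm, 1)
    list(id = ids, prop = prop)
  },
  fire = function(S, inst) {
    id <- inst$id
    nx <- S$nxt[id]
    S$pools[["actin"]] <- S$pools[["actin"]] + S$nATP[id]
    S$pools[["actin_ADP"]] <- S$pools[["actin_ADP"]] + S$nPi[id] + S$nADP[id]
    .release_occupancy(S, id)
    node_del(S, id)
    S$kind[nx] <- KIND_POINTED
    S$theta[nx] <- 0
    update_angles(S, S$nxt[nx])
    nx
  })

# ---- nucleotide dynamics ----------------------------------------------------

rule_hydrolysis <- function() list(
  name = "atp_hydrolysis",
  enumerate = function(S) {
    ids <- S$ids_cache[S$nATP[S$ids_cache] > 0]
    if (!length(ids)) return(.no_inst)
    list(id = ids, prop = S$nATP[ids] * S$params$k_ATP_hydrolysis)
  },
  fire = function(S, inst) {
    S$nATP[inst$id] <- S$nATP[inst$id] - 1L
    S$nPi[inst$id] <- S$nPi[inst$id] + 1L
    inst$id
  })

rule_pi_release <- function() list(
  name = "pi_release",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache[S$nPi[S$ids_cache] > 0]
    if (!length(ids)) return(.no_inst)
    cf <- S$ncof > 0 | S$cofS
    near_cof <- cf[ids] | .at(cf, S$nxt[ids], FALSE) |
      .at(cf, S$prv[ids], FALSE) | .at(cf, S$brn[ids], FALSE) |
      .at(cf, S$brnp[ids], FALSE)
    rate <- ifelse(near_cof, par$k_cof_Pi, par$k_Pi)
    list(id = ids, prop = S$nPi[ids] * rate)
  },
  fire = function(S, inst) {
    S$nPi[inst$id] <- S$nPi[inst$id] - 1L
    S$nADP[inst$id] <- S$nADP[inst$id] + 1L
    inst$id
  })

# ---- branching --------------------------------------------------------------

rule_branch <- function() list(
  name = "branch_nucleate",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    ids <- ids[S$kind[ids] == KIND_INTERIOR & S$ncof[ids] == 0 &
                 !S$cofS[ids] & (S$prv[ids] > 0 | S$brnp[ids] > 0)]
    if (!length(ids) || S$pools[["arp23"]] < 1 ||
        .actin_avail(S) < par$N_CG)
      return(.no_inst)
    prop <- convert_rate(par$k_branch, S$pools[["arp23"]], S$area_cache, par)
    list(id = ids, prop = rep(prop, length(ids)))
  },
  fire = function(S, inst) {
    par <- S$params
    id <- inst$id
    p <- .parent_of(S, id)
    dirv <- c(S$x[id] - S$x[p], S$y[id] - S$y[p])
    dirv <- dirv / sqrt(sum(dirv^2))
    s <- sample(c(-1, 1), 1)
    th <- stats::rnorm(1, s * par$internal$theta_Arp, par$internal$sigma_theta)
    newd <- as.numeric(rot2(th) %*% dirv)
    nx <- S$x[id] + newd[1]; ny <- S$y[id] + newd[2]
    if (!points_in_polygon(c(nx, ny), S$mem) &&
        .dist_to_polygon(c(nx, ny), S$mem) > par$overgrowth)
      return(integer(0))   # daughter would seed outside the membrane
    st <- .draw_new_state(S, par$N_CG, par$k_barbed_on_ATP,
                          par$k_barbed_on_ADP)
    nid <- node_add(S, KIND_BARBED, nx, ny,
                    nATP = if (st == "ATP") par$N_CG else 0L,
                    nADP = if (st == "ADP") par$N_CG else 0L)
    S$arp[nid] <- TRUE
    S$kind[id] <- KIND_JUNCTION
    link_branch(S, id, nid)
    S$pools[["arp23"]] <- S$pools[["arp23"]] - 1
    update_angles(S, c(id, nid))
    c(id, nid)
  })

rule_debranch <- function() list(
  name = "debranch",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    ids <- ids[S$kind[ids] == KIND_JUNCTION & S$brn[ids] > 0]
    # a daughter must have grown into a legal free filament (>= 2 nodes)
    ids <- ids[S$nxt[S$brn[ids]] > 0]
    if (!length(ids)) return(.no_inst)
    nm <- pmax(.n_mono(S, ids), 1)
    cfrac <- S$ncof[ids] / nm
    allfrac <- S$ncof[seq_len(S$nn)] /
      pmax(S$nATP[seq_len(S$nn)] + S$nPi[seq_len(S$nn)] +
             S$nADP[seq_len(S$nn)], 1)
    nbsum <- .at(allfrac, S$nxt[ids], 0) + .at(allfrac, S$prv[ids], 0) +
      .at(allfrac, S$brn[ids], 0) + .at(allfrac, S$brnp[ids], 0)
    nbcnt <- pmax((S$nxt[ids] > 0) + (S$prv[ids] > 0) +
                    (S$brn[ids] > 0) + (S$brnp[ids] > 0), 1)
    cadj <- nbsum / nbcnt
    prop <- par$k_debranch * (1 + par$sigma_comp * cfrac + par$k_comp * cadj)
    list(id = ids, prop = prop)
  },
  fire = function(S, inst) {
    id <- inst$id
    d <- S$brn[id]
    S$brn[id] <- 0L
    S$brnp[d] <- 0L
    S$kind[id] <- KIND_INTERIOR
    S$theta_branch[id] <- 0
    S$arp[d] <- FALSE
    S$pools[["arp23"]] <- S$pools[["arp23"]] + 1
    if (S$kind[d] == KIND_INTERIOR) S$kind[d] <- KIND_POINTED
    S$theta[d] <- 0
    update_angles(S, c(id, d))
    c(id, d)
  })

# ---- capping ----------------------------------------------------------------

rule_cap <- function() list(
  name = "cap_barbed",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache[S$kind[S$ids_cache] == KIND_BARBED]
    if (!length(ids) || S$pools[["cap"]] < 1) return(.no_inst)
    prop <- convert_rate(par$k_cap_on, S$pools[["cap"]], S$area_cache, par)
    list(id = ids, prop = rep(prop, length(ids)))
  },
  fire = function(S, inst) {
    S$kind[inst$id] <- KIND_CAPPED
    S$capA[inst$id] <- FALSE
    S$pools[["cap"]] <- S$pools[["cap"]] - 1
    inst$id
  })

rule_uncap <- function() list(
  name = "uncap_barbed",
  enumerate = function(S) {
    ids <- S$ids_cache[S$kind[S$ids_cache] == KIND_CAPPED]
    if (!length(ids)) return(.no_inst)
    list(id = ids, prop = rep(S$params$k_cap_off, length(ids)))
  },
  fire = function(S, inst) {
    id <- inst$id
    pool <- if (S$capA[id]) "aip1" else "cap"
    S$pools[[pool]] <- S$pools[[pool]] + 1
    S$capA[id] <- FALSE
    S$kind[id] <- KIND_BARBED
    id
  })

# ---- cofilin ----------------------------------------------------------------

rule_cofilin_bare <- function() list(
  name = "cofilin_bind_bare",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    nm <- .n_mono(S, ids)
    ids2 <- ids[nm > 0 & S$ncof[ids] == 0 & !S$cofS[ids] & S$camk[ids] == 0 &
                  S$nADP[ids] > 0]
    if (!length(ids2) || S$pools[["cof"]] < 1) return(.no_inst)
    base <- convert_rate(par$k_single_on_cof, S$pools[["cof"]],
                         S$area_cache, par)
    prop <- base * S$nADP[ids2] / .n_mono(S, ids2)
    list(id = ids2, prop = prop)
  },
  fire = function(S, inst) {
    S$cofS[inst$id] <- TRUE
    S$pools[["cof"]] <- S$pools[["cof"]] - 1
    inst$id
  })

# cooperative whole-node conversion seeded by an adjacent cofilin-saturated
# node; doubled propensity when both neighbors qualify
rule_cofilin_edge <- function() list(
  name = "cofilin_bind_accel_edge",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    nm <- .n_mono(S, ids)
    cand <- ids[nm > 0 & S$ncof[ids] == 0 & S$camk[ids] == 0 &
                  S$nADP[ids] == nm]
    if (!length(cand) || S$pools[["cof"]] < par$N_CG) return(.no_inst)
    full <- S$ncof[seq_len(S$nn)] >=
      pmax(S$nATP[seq_len(S$nn)] + S$nPi[seq_len(S$nn)] +
             S$nADP[seq_len(S$nn)], 1L) & S$ncof[seq_len(S$nn)] > 0
    nsrc <- .at(full, S$nxt[cand], FALSE) + .at(full, S$prv[cand], FALSE) +
      .at(full, S$brn[cand], FALSE) + .at(full, S$brnp[cand], FALSE)
    cand <- cand[nsrc > 0]; nsrc <- nsrc[nsrc > 0]
    if (!length(cand)) return(.no_inst)
    base <- convert_rate(par$k_cof_on_edge_ADP, S$pools[["cof"]],
                         S$area_cache, par)
    list(id = cand, prop = base * nsrc)
  },
  fire = function(S, inst) {
    id <- inst$id
    n <- .n_mono(S, id)
    take <- n - as.integer(S$cofS[id])
    S$ncof[id] <- n
    S$cofS[id] <- FALSE
    S$pools[["cof"]] <- S$pools[["cof"]] - take
    id
  })

# conversion of a singly-bound seed to a saturated node on the same object
rule_cofilin_seed <- function() list(
  name = "cofilin_bind_accel_seed",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    nm <- .n_mono(S, ids)
    cand <- ids[S$cofS[ids] & nm > 0 & S$nADP[ids] == nm]
    if (!length(cand) || S$pools[["cof"]] < par$N_CG) return(.no_inst)
    base <- convert_rate(par$k_cof_on_edge_ADP, S$pools[["cof"]],
                         S$area_cache, par)
    list(id = cand, prop = rep(base, length(cand)))
  },
  fire = function(S, inst) {
    id <- inst$id
    n <- .n_mono(S, id)
    S$pools[["cof"]] <- S$pools[["cof"]] - (n - 1L)
    S$ncof[id] <- n
    S$cofS[id] <- FALSE
    id
  })

rule_cofilin_unbind <- function() list(
  name = "cofilin_unbind",
  enumerate = function(S) {
    ids <- S$ids_cache[S$ncof[S$ids_cache] > 0 | S$cofS[S$ids_cache]]
    if (!length(ids)) return(.no_inst)
    list(id = ids, prop = rep(S$params$k_cof_off, length(ids)))
  },
  fire = function(S, inst) {
    id <- inst$id
    S$pools[["cof"]] <- S$pools[["cof"]] + S$ncof[id] + as.integer(S$cofS[id])
    S$ncof[id] <- 0L
    S$cofS[id] <- FALSE
    if (S$aip1[id]) {           # Aip1 binds cofilactin only
      S$aip1[id] <- FALSE
      S$pools[["aip1"]] <- S$pools[["aip1"]] + 1
    }
    id
  })

# ---- CaMKII-beta bundling ---------------------------------------------------

# local filament direction at a node (unit vector; NA for isolated nodes)
.node_dirs <- function(S, ids) {
  p <- S$prv[ids]; pz <- p == 0; p[pz] <- S$brnp[ids][pz]
  n <- S$nxt[ids]; nz <- n == 0; n[nz] <- S$brn[ids][nz]
  ax <- ifelse(p > 0, .at(S$x, p, 0), S$x[ids])
  ay <- ifelse(p > 0, .at(S$y, p, 0), S$y[ids])
  bx <- ifelse(n > 0, .at(S$x, n, 0), S$x[ids])
  by <- ifelse(n > 0, .at(S$y, n, 0), S$y[ids])
  dx <- bx - ax; dy <- by - ay
  nd <- sqrt(dx^2 + dy^2)
  nd[nd == 0] <- NA_real_
  cbind(dx / nd, dy / nd)
}

rule_camkii_bind <- function() list(
  name = "camkii_bind",
  enumerate = function(S) {
    par <- S$params
    if (S$pools[["camkii"]] < 1)
      return(list(a = integer(0), b = integer(0), prop = numeric(0)))
    ids <- S$ids_cache
    nm <- .n_mono(S, ids)
    el <- ids[nm > 0 & S$ncof[ids] == 0 & !S$cofS[ids] & S$camk[ids] == 0]
    if (length(el) < 2)
      return(list(a = integer(0), b = integer(0), prop = numeric(0)))
    X <- cbind(S$x[el], S$y[el])
    D <- .node_dirs(S, el)
    ok <- !is.na(D[, 1])
    el <- el[ok]; X <- X[ok, , drop = FALSE]; D <- D[ok, , drop = FALSE]
    if (length(el) < 2)
      return(list(a = integer(0), b = integer(0), prop = numeric(0)))
    dx <- outer(X[, 1], X[, 1], "-"); dy <- outer(X[, 2], X[, 2], "-")
    dist <- sqrt(dx^2 + dy^2)
    cosang <- abs(D %*% t(D))        # acute angle between filament axes
    pair_ok <- dist < par$internal$DU_bundle &
      cosang > cos(par$internal$theta_Bundle)
    pair_ok[lower.tri(pair_ok, diag = TRUE)] <- FALSE
    idx <- which(pair_ok, arr.ind = TRUE)
    if (!nrow(idx))
      return(list(a = integer(0), b = integer(0), prop = numeric(0)))
    a <- el[idx[, 1]]; b <- el[idx[, 2]]
    adj <- vapply(seq_along(a), function(k)
      b[k] %in% node_neighbors(S, a[k]), logical(1))
    a <- a[!adj]; b <- b[!adj]
    if (!length(a))
      return(list(a = integer(0), b = integer(0), prop = numeric(0)))
    prop <- convert_rate(par$k_camkii_on, S$pools[["camkii"]],
                         S$area_cache, par)
    list(a = a, b = b, prop = rep(prop, length(a)))
  },
  fire = function(S, inst) {
    a <- inst$a; b <- inst$b
    r <- sqrt((S$x[a] - S$x[b])^2 + (S$y[a] - S$y[b])^2)
    lk <- length(S$bl_a) + 1L
    S$bl_a <- c(S$bl_a, a); S$bl_b <- c(S$bl_b, b)
    S$bl_rest <- c(S$bl_rest, r); S$bl_alive <- c(S$bl_alive, TRUE)
    S$camk[a] <- lk; S$camk[b] <- lk
    S$pools[["camkii"]] <- S$pools[["camkii"]] - 1
    c(a, b)
  })

rule_camkii_unbind <- function() list(
  name = "camkii_unbind",
  enumerate = function(S) {
    lk <- which(S$bl_alive)
    if (!length(lk)) return(list(link = integer(0), prop = numeric(0)))
    list(link = lk, prop = rep(S$params$k_camkii_off, length(lk)))
  },
  fire = function(S, inst) {
    lk <- inst$link
    a <- S$bl_a[lk]; b <- S$bl_b[lk]
    S$bl_alive[lk] <- FALSE
    S$camk[a] <- 0L; S$camk[b] <- 0L
    S$pools[["camkii"]] <- S$pools[["camkii"]] + 1
    c(a, b)
  })

# ---- breaking and severing --------------------------------------------------

# cut the filament edge from `id` toward its barbed-side neighbor; the
# upstream node becomes the new barbed-side terminus of kind `up_kind`
.cut_edge <- function(S, id, up_kind = KIND_BARBED) {
  nx <- S$nxt[id]
  S$nxt[id] <- 0L
  S$prv[nx] <- 0L
  S$kind[id] <- up_kind
  S$theta[id] <- 0
  if (S$kind[nx] == KIND_INTERIOR) S$kind[nx] <- KIND_POINTED
  S$theta[nx] <- 0
  c(id, nx)
}

rule_break <- function() list(
  name = "break_filament",
  enumerate = function(S) {
    par <- S$params
    ids <- S$ids_cache
    ids <- ids[S$kind[ids] == KIND_INTERIOR & S$prv[ids] > 0 & S$nxt[ids] > 0]
    if (!length(ids)) return(.no_inst)
    nx <- S$nxt[ids]
    c2 <- S$ncof[ids] > 0
    c3 <- S$ncof[nx] > 0
    thr <- ifelse(c2 != c3, par$internal$theta_break_boundary,
                  ifelse(c2, par$internal$theta_break_cofilactin,
                         par$internal$theta_break_actin))
    el <- abs(S$theta[ids]) > thr
    ids <- ids[el]
    if (!length(ids)) return(.no_inst)
    list(id = ids, prop = rep(par$k_break, length(ids)))
  },
  fire = function(S, inst) .cut_edge(S, inst$id, KIND_BARBED))

rule_aip1_bind <- function() list(
  name = "aip1_bind",
  enumerate = function(S) {
    par <- S$params
    if (!par$aip1_model || S$pools[["aip1"]] < 1) return(.no_inst)
    ids <- S$ids_cache[S$ncof[S$ids_cache] > 0 & !S$aip1[S$ids_cache]]
    if (!length(ids)) return(.no_inst)
    prop <- convert_rate(par$k_on_aip1, S$pools[["aip1"]], S$area_cache, par)
    list(id = ids, prop = rep(prop, length(ids)))
  },
  fire = function(S, inst) {
    S$aip1[inst$id] <- TRUE
    S$pools[["aip1"]] <- S$pools[["aip1"]] - 1
    inst$id
  })

rule_aip1_sever <- function() list(
  name = "aip1_sever",
  enumerate = function(S) {
    par <- S$params
    if (!par$aip1_model) return(.no_inst)
    ids <- S$ids_cache
    ids <- ids[S$aip1[ids] & S$kind[ids] == KIND_INTERIOR &
                 S$prv[ids] > 0 & S$nxt[ids] > 0]
    if (!length(ids)) return(.no_inst)
    list(id = ids, prop = rep(par$k_sever, length(ids)))
  },
  fire = function(S, inst) {
    id <- inst$id
    touched <- .cut_edge(S, id, KIND_CAPPED)
    S$capA[id] <- TRUE     # the severing Aip1 caps the new barbed end
    S$aip1[id] <- FALSE
    touched
  })
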