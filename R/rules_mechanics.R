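# Energy-based kinetic rules: anisotropic buckling (gradient descent on the
# clipped separation potential, in mutually exclusive interior / branch / end
# variants selected by the node's filament degree), angle-bending updates,
# Hessian heat-bath thermal noise, and the membrane curvature update with
# attachment reaction forces.

# separation edges incident to a node: filament neighbors, the bundling
# partner, and the membrane attachment vertex. Returns neighbor coordinates,
# per-edge rest lengths, and which edge (if any) is the membrane vertex.
.sep_edges <- function(S, id) {
  nb <- node_neighbors(S, id)
  rest <- vapply(nb, function(b) .edge_rest(S, id, b), numeric(1))
  px <- S$x[nb]; py <- S$y[nb]
  if (S$camk[id] > 0) {
    lk <- S$camk[id]
    other <- if (S$bl_a[lk] == id) S$bl_b[lk] else S$bl_a[lk]
    px <- c(px, S$x[other]); py <- c(py, S$y[other])
    rest <- c(rest, S$bl_rest[lk])
    nb <- c(nb, other)
  }
  vtx <- 0L
  if (S$vref[id] > 0) {
    v <- S$vref[id]
    px <- c(px, S$mem[v, 1]); py <- c(py, S$mem[v, 2])
    rest <- c(rest, 1)
    nb <- c(nb, NA_integer_)
    vtx <- v
  }
  list(nb = nb, px = px, py = py, rest = rest, vtx = vtx)
}

# radial gradient at a node over all its separation edges
.state_radial_gradient <- function(S, id, edges = .sep_edges(S, id)) {
  if (!length(edges$px)) return(c(0, 0))
  par <- S$params
  dx <- S$x[id] - edges$px; dy <- S$y[id] - edges$py
  r <- sqrt(dx^2 + dy^2)
  w <- psi_sep(r, eps = par$internal$eps_LJ,
               sigma = edges$rest * 2^(-1 / 6), eps_clip = par$eps_clip)
  c(sum(w * dx), sum(w * dy))
}

# scalar diagonal radial Hessian at a node (buckling Hessian of the
# thermal-proposal precision)
.state_radial_h <- function(S, id, edges = .sep_edges(S, id)) {
  par <- S$params
  h <- par$internal$eps_sep^2
  if (length(edges$px)) {
    dx <- S$x[id] - edges$px; dy <- S$y[id] - edges$py
    r <- sqrt(dx^2 + dy^2)
    h <- h + sum(d2u_sep_clipped(r, eps = par$internal$eps_LJ,
                                 sigma = edges$rest * 2^(-1 / 6),
                                 eps_clip = par$eps_clip))
  }
  h
}

# local separation energy of a node at a hypothetical position
.local_sep_energy <- function(S, id, pos, edges = .sep_edges(S, id)) {
  if (!length(edges$px)) return(0)
  par <- S$params
  r <- sqrt((pos[1] - edges$px)^2 + (pos[2] - edges$py)^2)
  sum(u_sep_clipped(r, eps = par$internal$eps_LJ,
                    sigma = edges$rest * 2^(-1 / 6),
                    eps_clip = par$eps_clip))
}

# move a node if the proposed position stays inside the membrane (with the
# overgrowth tolerance); returns TRUE if the move was applied
.try_move_node <- function(S, id, pos) {
  inside <- points_in_polygon(pos, S$mem)
  if (!inside && .dist_to_polygon(pos, S$mem) > S$params$overgrowth)
    return(FALSE)
  S$x[id] <- pos[1]; S$y[id] <- pos[2]
  update_angles(S, c(id, node_neighbors(S, id)))
  TRUE
}

# effective bending constant at a node, softened by cofilin occupancy
.k_bend_eff <- function(S, id) {
  par <- S$params
  nm <- max(1L, S$nATP[id] + S$nPi[id] + S$nADP[id])
  cfrac <- S$ncof[id] / nm
  par$internal$k_bend / (1 + (par$cofilin_soften - 1) * cfrac)
}

# ---- buckling (radial gradient descent) -------------------------------------

# one rule per motif; the three motifs partition nodes by filament degree
# (end = 1, interior = 2, branch/junction = 3) and are mutually exclusive.
.rule_buckle <- function(motif, want_deg) list(
  name = paste0("buckle_", motif),
  enumerate = function(S) {
    ids <- S$ids_cache
    deg <- node_degrees(S, ids)
    ids <- ids[deg == want_deg]
    if (!length(ids)) return(.no_inst)
    list(id = ids, prop = rep(S$params$k_kinetic, length(ids)))
  },
  fire = function(S, inst) {
    kinetic_update(S, inst$id)
    inst$id
  })

rule_buckle_interior <- function() .rule_buckle("interior", 2L)
rule_buckle_branch <- function() .rule_buckle("branch", 3L)
rule_buckle_end <- function() .rule_buckle("end", 1L)

# ---- angle bending ----------------------------------------------------------

# connected triples (u, j, w) with their target angles: along-filament
# triples relax to 0; parent-to-daughter triples across a junction relax to
# the Arp2/3 branch angle.
.bend_triples <- function(S) {
  ids <- S$ids_cache
  par_ids <- S$prv[ids]
  pz <- par_ids == 0L
  par_ids[pz] <- S$brnp[ids][pz]
  u <- integer(0); j <- integer(0); w <- integer(0); tgt <- numeric(0)
  # along-filament triples: the branch daughter's first node takes its
  # junction as the upstream neighbor, with a straight target along the
  # daughter's own axis
  has_pn <- par_ids > 0 & S$nxt[ids] > 0
  cj <- ids[has_pn]
  if (length(cj)) {
    u <- c(u, par_ids[has_pn]); j <- c(j, cj); w <- c(w, S$nxt[cj])
    tgt <- c(tgt, rep(0, length(cj)))
  }
  jn_sel <- S$kind[ids] == KIND_JUNCTION & par_ids > 0 & S$brn[ids] > 0
  jn <- ids[jn_sel]
  if (length(jn)) {
    u <- c(u, par_ids[jn_sel]); j <- c(j, jn); w <- c(w, S$brn[jn])
    tgt <- c(tgt, rep(S$params$internal$theta_Arp, length(jn)))
  }
  list(u = u, j = j, w = w, tgt = tgt)
}

# mover: 1 = first node, 2 = centre, 3 = last node of the triple
.rule_bend <- function(mover) list(
  name = paste0("bend_", c("end1", "center", "end2")[mover]),
  enumerate = function(S) {
    tr <- .bend_triples(S)
    tr$prop <- rep(S$params$k_kinetic, length(tr$u))
    tr
  },
  fire = function(S, inst) {
    par <- S$params
    x1 <- c(S$x[inst$u], S$y[inst$u])
    x2 <- c(S$x[inst$j], S$y[inst$j])
    x3 <- c(S$x[inst$w], S$y[inst$w])
    kb <- .k_bend_eff(S, inst$j)
    gr <- switch(mover,
                 angle_gradient_end(x1, x2, x3, inst$tgt, kb, which = 1),
                 angle_gradient_interior(x1, x2, x3, inst$tgt, kb),
                 angle_gradient_end(x1, x2, x3, inst$tgt, kb, which = 3))
    id <- c(inst$u, inst$j, inst$w)[mover]
    delta <- -gr / (par$internal$zeta_actin * par$k_kinetic)
    pos <- c(S$x[id] + delta[1], S$y[id] + delta[2])
    .try_move_node(S, id, pos)
    id
  })

rule_bend_center <- function() .rule_bend(2L)
rule_bend_end1 <- function() .rule_bend(1L)
rule_bend_end2 <- function() .rule_bend(3L)

# ---- thermal noise ----------------------------------------------------------

rule_thermal <- function() list(
  name = "thermal_noise",
  enumerate = function(S) {
    ids <- S$ids_cache
    ids <- ids[node_degrees(S, ids) > 0 | S$camk[ids] > 0 | S$vref[ids] > 0]
    if (!length(ids)) return(.no_inst)
    list(id = ids, prop = rep(S$params$k_kinetic, length(ids)))
  },
  fire = function(S, inst) {
    thermal_move(S, inst$id)
    inst$id
  })

# ---- membrane ---------------------------------------------------------------

rule_membrane <- function() list(
  name = "membrane_update",
  enumerate = function(S) {
    nv <- nrow(S$mem)
    list(v = seq_len(nv), prop = rep(S$params$k_kinetic, nv))
  },
  fire = function(S, inst) {
    par <- S$params
    v <- inst$v
    extra <- c(0, 0)
    a <- S$vnode[v]
    if (a > 0) {   # Newtonian reaction force from the attachment edge
      dx <- S$mem[v, 1] - S$x[a]; dy <- S$mem[v, 2] - S$y[a]
      r <- sqrt(dx^2 + dy^2)
      if (r > 1e-12) {
        w <- psi_sep(r, eps = par$internal$eps_LJ, eps_clip = par$eps_clip)
        extra <- w * c(dx, dy)
      }
    }
    old_mem <- S$mem
    S$mem <- helfrich_update(S$mem, v, kappa = par$internal$kappa_mem,
                             zeta_mem = par$internal$zeta_mem,
                             k_kinetic = par$k_kinetic, extra_grad = extra)
    if (a > 0) {
      # an inward move must not strand the attached end outside the
      # membrane beyond the overgrowth tolerance
      pos <- c(S$x[a], S$y[a])
      if (!points_in_polygon(pos, S$mem) &&
          .dist_to_polygon(pos, S$mem) > par$overgrowth) {
        S$mem <- old_mem
      } else {
        .detach_check(S, a)
      }
    }
    integer(0)
  })

# ---- membrane attachment hooks ----------------------------------------------

# create an attachment if the end's pseudo-extended segment crosses the
# membrane: a new vertex is inserted at the crossing point
.attach_check <- function(S, id) {
  if (S$kind[id] != KIND_BARBED || S$vref[id] > 0) return(invisible(S))
  p <- S$prv[id]; if (p == 0) p <- S$brnp[id]
  if (p == 0) return(invisible(S))
  dirv <- c(S$x[id] - S$x[p], S$y[id] - S$y[p])
  nd <- sqrt(sum(dirv^2))
  if (nd == 0) return(invisible(S))
  dirv <- dirv / nd
  gap <- .ray_gap(S, c(S$x[id], S$y[id]), dirv,
                  maxlen = S$params$overgrowth)
  if (!is.finite(gap)) return(invisible(S))
  hit <- c(S$x[id], S$y[id]) + gap * dirv
  # locate the crossed edge to splice the new vertex into the cycle
  V <- S$mem
  Vp <- .shift(V, 1)
  ex <- Vp[, 1] - V[, 1]; ey <- Vp[, 2] - V[, 2]
  denom <- dirv[1] * ey - dirv[2] * ex
  qx <- V[, 1] - S$x[id]; qy <- V[, 2] - S$y[id]
  t <- (qx * ey - qy * ex) / denom
  u <- (qx * dirv[2] - qy * dirv[1]) / denom
  ok <- is.finite(t) & abs(t - gap) < 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
  e <- which(ok)[1]
  if (is.na(e)) return(invisible(S))
  n <- nrow(V)
  newV <- unname(rbind(V[seq_len(e), , drop = FALSE], hit,
                       if (e < n) V[(e + 1):n, , drop = FALSE]))
  newvn <- append(S$vnode, 0L, after = e)
  # vertex indices above the insertion point shift by one
  shift_ids <- which(S$vref[seq_len(S$nn)] > e)
  S$vref[shift_ids] <- S$vref[shift_ids] + 1L
  S$mem <- newV
  S$vnode <- newvn
  S$vnode[e + 1] <- id
  S$vref[id] <- e + 1L
  invisible(S)
}

# drop an attachment whose end has moved out of interaction range; the
# inserted vertex is retained as part of the membrane
.detach_check <- function(S, id) {
  v <- S$vref[id]
  if (v == 0) return(invisible(S))
  r <- sqrt((S$x[id] - S$mem[v, 1])^2 + (S$y[id] - S$mem[v, 2])^2)
  if (r > S$params$detach_factor * 1) {
    S$vnode[v] <- 0L
    S$vref[id] <- 0L
  }
  invisible(S)
}

# ---- exported operation wrappers --------------------------------------------

#' Attach eligible filament ends to the membrane
#'
#' Scans every barbed end; any end whose segment, pseudo-extended by the
#' overgrowth length, crosses a membrane edge is attached by inserting a new
#' membrane vertex at the crossing point (enclosed area is unchanged by the
#' collinear insertion) and recording the attachment. Ends that have moved
#' out of interaction range are detached (the inserted vertex is retained).
#'
#' @param S A `spine_state`.
#' @return The state, invisibly.
#' @export
attach_if_intersecting <- function(S) {
  for (id in live_nodes(S)) {
    if (S$vref[id] > 0) .detach_check(S, id)
    if (S$kind[id] == KIND_BARBED) .attach_check(S, id)
  }
  invisible(S)
}

#' Apply one gradient-descent kinetic update to a node
#'
#' The overdamped buckling displacement
#' `delta = -grad U_radial / (zeta_actin * k_kinetic)` over all separation
#' edges of the node (filament neighbors, bundling partner, membrane
#' attachment), applied if it keeps the node inside the membrane; stored
#' angles of the affected neighborhood are refreshed.
#'
#' @param S A `spine_state`.
#' @param id Node id.
#' @return The displacement actually applied (length-2; zero if rejected).
#' @export
kinetic_update <- function(S, id) {
  par <- S$params
  gr <- .state_radial_gradient(S, id)
  delta <- -gr / (par$internal$zeta_actin * par$k_kinetic)
  old <- c(S$x[id], S$y[id])
  ok <- .try_move_node(S, id, old + delta)
  if (ok) delta else c(0, 0)
}

#' Propose and accept/reject one heat-bath thermal move
#'
#' Draws a Gaussian displacement with covariance
#' `2 kT / (zeta_actin k_kinetic) * H^-1` from the node's diagonal buckling
#' Hessian `H`, and accepts it with the heat-bath probability built from the
#' local separation-energy change, its quadratic Taylor part, and the
#' Hessian determinants at the current and proposed positions.
#'
#' @param S A `spine_state`.
#' @param id Node id.
#' @return TRUE if the proposal was accepted and applied.
#' @export
thermal_move <- function(S, id) {
  par <- S$params
  edges <- .sep_edges(S, id)
  h <- .state_radial_h(S, id, edges)
  if (h <= 0) return(FALSE)
  svar <- 2 / (par$internal$zeta_actin * par$k_kinetic * h)
  u <- stats::rnorm(2, 0, sqrt(svar))
  cur <- c(S$x[id], S$y[id])
  prop_pos <- cur + u
  dU <- .local_sep_energy(S, id, prop_pos, edges) -
    .local_sep_energy(S, id, cur, edges)
  S$x[id] <- prop_pos[1]; S$y[id] <- prop_pos[2]
  hp <- .state_radial_h(S, id, edges)
  S$x[id] <- cur[1]; S$y[id] <- cur[2]
  # dUq is the difference of the quadratic Taylor parts of the forward and
  # reverse proposals; it vanishes in the locally harmonic regime
  dUq <- 0.5 * (h - hp) * sum(u^2)
  A <- heat_bath_accept(dU, dUq, detH_cur = h^2,
                        detH_prop = max(hp, par$internal$eps_sep^2)^2)
  if (stats::runif(1) < A) return(.try_move_node(S, id, prop_pos))
  FALSE
}
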