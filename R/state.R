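# Simulation state: a mutable environment holding the actin graph (struct of
# arrays), the membrane polygon, attachments, bundling links, pools, clock
# and parameters. Environments give reference semantics, so rule firings
# mutate the state in place the way an event-driven simulator requires.
#
# Graph encoding: every actin object has a "next" pointer toward the barbed
# end (0 for the barbed end itself); junction objects additionally carry a
# branch pointer to the first node of the daughter filament. The inverse
# pointers (prv = who points at me via next, brnp = my parent junction) are
# maintained incrementally so adjacency queries are O(1).

KIND_INTERIOR <- 1L
KIND_BARBED   <- 2L
KIND_POINTED  <- 3L
KIND_JUNCTION <- 4L
KIND_CAPPED   <- 5L

#' Kind labels of actin graph nodes
#'
#' @return Character vector naming the five node kinds in code order.
#' @export
node_kinds <- function() {
  c("interior", "barbed_end", "pointed_end", "junction", "capped_end")
}

.state_fields_int <- c("kind", "nxt", "brn", "prv", "brnp",
                       "nATP", "nPi", "nADP", "ncof", "camk", "vref")
.state_fields_dbl <- c("x", "y", "theta", "theta_branch", "restlen")
.state_fields_lgl <- c("alive", "cofS", "aip1", "capA", "arp")

#' Create an empty simulation state
#'
#' Allocates a state environment with an empty actin graph, a membrane
#' polygon, pools initialized at the basal steady state, zero clock, and the
#' supplied resolved parameters. Most users build states through
#' [make_fixture()] or [simulate_spine()].
#'
#' @param params Resolved parameters ([resolve_params()]).
#' @param membrane n x 2 matrix of counterclockwise membrane vertices
#'   (internal units); default a regular polygon of the configured initial
#'   radius and resolution.
#' @return A `spine_state` environment.
#' @export
new_sim_state <- function(params = resolve_params(), membrane = NULL) {
  S <- new.env(parent = emptyenv())
  class(S) <- "spine_state"
  S$params <- params
  n0 <- 256L
  for (f in .state_fields_int) S[[f]] <- integer(n0)
  for (f in .state_fields_dbl) S[[f]] <- numeric(n0)
  for (f in .state_fields_lgl) S[[f]] <- logical(n0)
  S$restlen <- rep(1, n0)
  S$nn <- 0L              # highest node id in use
  if (is.null(membrane)) {
    nv <- params$membrane_vertices
    ang <- 2 * pi * (seq_len(nv) - 1) / nv
    membrane <- params$internal$r_init * cbind(cos(ang), sin(ang))
  }
  S$mem <- membrane
  S$vnode <- integer(nrow(membrane))   # attached node id per vertex (0 = none)
  S$bl_a <- integer(0); S$bl_b <- integer(0)
  S$bl_rest <- numeric(0); S$bl_alive <- logical(0)
  S$pools <- init_steady_state(params, abs(polygon_area(membrane)))
  S$time <- 0
  S$n_events <- 0L
  S$quiescent <- FALSE
  S
}

# grow node arrays when capacity is exhausted
.grow_state <- function(S) {
  for (f in c(.state_fields_int, .state_fields_dbl, .state_fields_lgl)) {
    v <- S[[f]]
    length(v) <- 2L * length(v)
    if (is.numeric(v)) v[is.na(v)] <- 0 else if (is.logical(v)) v[is.na(v)] <- FALSE
    if (f == "restlen") v[v == 0] <- 1
    S[[f]] <- v
  }
  invisible(S)
}

# add one node; returns the new id
node_add <- function(S, kind, x, y, nATP = 0L, nPi = 0L, nADP = 0L) {
  id <- S$nn + 1L
  if (id > length(S$alive)) .grow_state(S)
  S$nn <- id
  S$alive[id] <- TRUE
  S$kind[id] <- kind
  S$x[id] <- x; S$y[id] <- y
  S$nxt[id] <- 0L; S$brn[id] <- 0L; S$prv[id] <- 0L; S$brnp[id] <- 0L
  S$theta[id] <- 0; S$theta_branch[id] <- 0
  S$nATP[id] <- as.integer(nATP); S$nPi[id] <- as.integer(nPi)
  S$nADP[id] <- as.integer(nADP)
  S$ncof[id] <- 0L; S$camk[id] <- 0L; S$vref[id] <- 0L
  S$cofS[id] <- FALSE; S$aip1[id] <- FALSE; S$capA[id] <- FALSE
  S$arp[id] <- FALSE
  S$restlen[id] <- 1
  id
}

# connect a -> b along the filament (next pointer)
link_next <- function(S, a, b) {
  S$nxt[a] <- b
  if (b > 0) S$prv[b] <- a
  invisible(S)
}

# connect junction j -> daughter d (branch pointer)
link_branch <- function(S, j, d) {
  S$brn[j] <- d
  if (d > 0) S$brnp[d] <- j
  invisible(S)
}

# delete a node, detaching all pointers into it
node_del <- function(S, id) {
  if (S$prv[id] > 0) S$nxt[S$prv[id]] <- 0L
  if (S$brnp[id] > 0) S$brn[S$brnp[id]] <- 0L
  if (S$nxt[id] > 0) S$prv[S$nxt[id]] <- 0L
  if (S$brn[id] > 0) S$brnp[S$brn[id]] <- 0L
  if (S$vref[id] > 0) S$vnode[S$vref[id]] <- 0L
  if (S$camk[id] > 0) {
    lk <- S$camk[id]
    S$bl_alive[lk] <- FALSE
    other <- if (S$bl_a[lk] == id) S$bl_b[lk] else S$bl_a[lk]
    S$camk[other] <- 0L
  }
  S$alive[id] <- FALSE
  S$nxt[id] <- 0L; S$brn[id] <- 0L; S$prv[id] <- 0L; S$brnp[id] <- 0L
  S$vref[id] <- 0L; S$camk[id] <- 0L
  invisible(S)
}

# ids of live nodes
live_nodes <- function(S) which(S$alive[seq_len(S$nn)])

# filament-graph neighbors (next/branch edges, both directions)
node_neighbors <- function(S, id) {
  nb <- c(S$nxt[id], S$brn[id], S$prv[id], S$brnp[id])
  nb[nb > 0L]
}

# filament-graph degree of every live node (vectorized)
node_degrees <- function(S, ids = live_nodes(S)) {
  (S$nxt[ids] > 0) + (S$brn[ids] > 0) + (S$prv[ids] > 0) + (S$brnp[ids] > 0)
}

# pointed-side parent of a node: the upstream filament neighbor, which for
# the first node of a branch daughter is its junction
.parent_of <- function(S, id) {
  p <- S$prv[id]
  if (p == 0L) p <- S$brnp[id]
  p
}

# signed bend angle at a node given its parent and nxt neighbors; 0 for ends
.bend_angle <- function(S, id) {
  p <- .parent_of(S, id); n <- S$nxt[id]
  if (p == 0L || n == 0L) return(0)
  d1 <- c(S$x[id] - S$x[p], S$y[id] - S$y[p])
  d2 <- c(S$x[n] - S$x[id], S$y[n] - S$y[id])
  atan2(d1[1] * d2[2] - d1[2] * d2[1], sum(d1 * d2))
}

# refresh stored angles of a node set (after a move or rewrite); junction
# branch angles are refreshed alongside
update_angles <- function(S, ids) {
  ids <- ids[ids > 0 & ids <= S$nn]
  ids <- ids[S$alive[ids]]
  for (id in ids) {
    S$theta[id] <- .bend_angle(S, id)
    if (S$kind[id] == KIND_JUNCTION && S$prv[id] > 0 && S$brn[id] > 0) {
      p <- S$prv[id]; d <- S$brn[id]
      d1 <- c(S$x[id] - S$x[p], S$y[id] - S$y[p])
      d2 <- c(S$x[d] - S$x[id], S$y[d] - S$y[id])
      S$theta_branch[id] <- atan2(d1[1] * d2[2] - d1[2] * d2[1], sum(d1 * d2))
    }
  }
  invisible(S)
}

# total actin monomers bound in the graph
graph_monomers <- function(S) {
  ids <- live_nodes(S)
  sum(S$nATP[ids] + S$nPi[ids] + S$nADP[ids])
}

# 2D rotation matrix
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
}

#' Verify the structural invariants of a simulation state
#'
#' Checks pointer integrity (no dangling ids, inverse pointers consistent),
#' kind/pointer consistency (barbed and capped ends have no outgoing next
#' edge, junctions have exactly two outgoing edges), occupancy sanity
#' (nucleotide counts nonnegative, cofilin not exceeding monomers, Aip1 only
#' on cofilactin, zero stored angle on end nodes), membrane simplicity and
#' counterclockwise orientation, attachment bijectivity, and containment of
#' all node positions inside the membrane up to the overgrowth tolerance.
#'
#' @param S A `spine_state`.
#' @param containment Also check node containment (disable for bare-graph
#'   fixtures without a meaningful membrane).
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
check_state <- function(S, containment = TRUE) {
  ids <- live_nodes(S)
  ptr_ok <- function(p) all(p == 0 | (p >= 1 & p <= S$nn & S$alive[pmax(p, 1)]))
  stopifnot(ptr_ok(S$nxt[ids]), ptr_ok(S$brn[ids]),
            ptr_ok(S$prv[ids]), ptr_ok(S$brnp[ids]))
  for (id in ids) {
    if (S$nxt[id] > 0) stopifnot(S$prv[S$nxt[id]] == id)
    if (S$brn[id] > 0) stopifnot(S$brnp[S$brn[id]] == id)
    if (S$prv[id] > 0) stopifnot(S$nxt[S$prv[id]] == id)
    if (S$brnp[id] > 0) stopifnot(S$brn[S$brnp[id]] == id)
  }
  k <- S$kind[ids]
  stopifnot(all(S$nxt[ids][k %in% c(KIND_BARBED, KIND_CAPPED)] == 0))
  stopifnot(all(S$nxt[ids][k %in% c(KIND_INTERIOR, KIND_POINTED, KIND_JUNCTION)] > 0))
  stopifnot(all(S$brn[ids][k == KIND_JUNCTION] > 0))
  stopifnot(all(S$brn[ids][k != KIND_JUNCTION] == 0))
  nm <- S$nATP[ids] + S$nPi[ids] + S$nADP[ids]
  stopifnot(all(S$nATP[ids] >= 0), all(S$nPi[ids] >= 0), all(S$nADP[ids] >= 0),
            all(S$ncof[ids] <= pmax(nm, S$params$N_CG)))
  stopifnot(all(!S$aip1[ids] | S$ncof[ids] > 0))
  endk <- k %in% c(KIND_BARBED, KIND_POINTED, KIND_CAPPED)
  stopifnot(all(abs(S$theta[ids][endk]) < 1e-12))
  # attachments
  att <- which(S$vnode > 0)
  stopifnot(all(S$vref[S$vnode[att]] == att))
  own <- ids[S$vref[ids] > 0]
  stopifnot(all(S$vnode[S$vref[own]] == own))
  # links
  lk <- which(S$bl_alive)
  stopifnot(all(S$camk[S$bl_a[lk]] == lk), all(S$camk[S$bl_b[lk]] == lk))
  stopifnot(all(S$pools >= 0))
  stopifnot(polygon_area(S$mem) > 0)
  stopifnot(polygon_is_simple(S$mem))
  if (containment && length(ids)) {
    P <- cbind(S$x[ids], S$y[ids])
    inside <- points_in_polygon(P, S$mem)
    if (!all(inside)) {
      # allow the overgrowth tolerance for membrane-coupled ends
      tol <- S$params$overgrowth
      bad <- which(!inside)
      d <- vapply(bad, function(b) .dist_to_polygon(P[b, ], S$mem), numeric(1))
      stopifnot(all(d <= tol + 1e-9))
    }
  }
  invisible(TRUE)
}

# distance from a point to the polygon boundary
.dist_to_polygon <- function(p, V) {
  Vp <- .shift(V, 1)
  ex <- Vp[, 1] - V[, 1]; ey <- Vp[, 2] - V[, 2]
  px <- p[1] - V[, 1]; py <- p[2] - V[, 2]
  t <- pmin(1, pmax(0, (px * ex + py * ey) / (ex^2 + ey^2)))
  dx <- px - t * ex; dy <- py - t * ey
  sqrt(min(dx^2 + dy^2))
}

# ---- fixtures ---------------------------------------------------------------

#' Construct a named test fixture state
#'
#' Deterministic small states used throughout the test surface:
#' \describe{
#'   \item{`seed_spine`}{the simulation initial condition: a regular polygon
#'     of the configured resolution inscribed in the initial spine-head
#'     radius, enclosing a two-node seed filament at the centre.}
#'   \item{`straight_filament(n)`}{an unbranched n-node filament along the
#'     x axis (pointed end at the origin), no membrane interaction.}
#'   \item{`branched_Y`}{a four-node mother filament with a junction at node
#'     3 and a one-node daughter at the configured branch angle.}
#'   \item{`bundled_pair`}{two parallel filaments joined by one bundling
#'     link.}
#'   \item{`ellipse_membrane(a,b)`}{a node-free elliptical membrane.}
#'   \item{`cofilactin_boundary_filament`}{a straight filament whose barbed
#'     half is fully cofilin-decorated, creating a boundary edge.}
#' }
#'
#' @param name Fixture name.
#' @param seed Integer RNG seed (fixtures are deterministic given the seed).
#' @param params Resolved parameters.
#' @param n Node count for `straight_filament`.
#' @param a,b Semi-axes for `ellipse_membrane` (internal units).
#' @return A `spine_state`.
#' @export
make_fixture <- function(name, seed = 1L,
                         params = resolve_params(), n = 5,
                         a = 6, b = 3) {
  set.seed(seed)
  big <- function(r = 50) {
    ang <- 2 * pi * (seq_len(64) - 1) / 64
    r * cbind(cos(ang), sin(ang))
  }
  add_chain <- function(S, xs, ys, state = "ATP") {
    ncg <- params$N_CG
    ids <- integer(length(xs))
    for (i in seq_along(xs)) {
      kind <- if (i == 1) KIND_POINTED else if (i == length(xs)) KIND_BARBED
              else KIND_INTERIOR
      ids[i] <- node_add(S, kind, xs[i], ys[i],
                         nATP = if (state == "ATP") ncg else 0L,
                         nADP = if (state == "ADP") ncg else 0L)
      if (i > 1) link_next(S, ids[i - 1], ids[i])
    }
    update_angles(S, ids)
    ids
  }
  switch(name,
    seed_spine = {
      S <- new_sim_state(params)
      add_chain(S, c(-0.5, 0.5), c(0, 0),
                state = params$seed_nucleotide)
      S
    },
    straight_filament = {
      S <- new_sim_state(params, membrane = big())
      add_chain(S, seq_len(n) - 1, rep(0, n))
      S
    },
    branched_Y = {
      S <- new_sim_state(params, membrane = big())
      ids <- add_chain(S, 0:3, rep(0, 4))
      j <- ids[3]
      S$kind[j] <- KIND_JUNCTION
      th <- params$internal$theta_Arp
      d <- node_add(S, KIND_BARBED,
                    S$x[j] + cos(th), S$y[j] + sin(th), nATP = params$N_CG)
      S$arp[d] <- TRUE
      link_branch(S, j, d)
      update_angles(S, c(ids, d))
      S
    },
    bundled_pair = {
      S <- new_sim_state(params, membrane = big())
      f1 <- add_chain(S, 0:3, rep(0, 4))
      f2 <- add_chain(S, 0:3, rep(0.5, 4))
      lk <- 1L
      S$bl_a <- f1[2]; S$bl_b <- f2[2]; S$bl_rest <- 0.5; S$bl_alive <- TRUE
      S$camk[f1[2]] <- lk; S$camk[f2[2]] <- lk
      S
    },
    ellipse_membrane = {
      nv <- params$membrane_vertices
      ang <- 2 * pi * (seq_len(nv) - 1) / nv
      new_sim_state(params, membrane = cbind(a * cos(ang), b * sin(ang)))
    },
    cofilactin_boundary_filament = {
      S <- new_sim_state(params, membrane = big())
      ids <- add_chain(S, seq_len(6) - 1, rep(0, 6))
      half <- ids[4:5]
      ncg <- params$N_CG
      S$nATP[ids] <- 0L; S$nADP[ids] <- ncg
      S$ncof[half] <- ncg
      S
    },
    stop("unknown fixture: ", name)
  )
}
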