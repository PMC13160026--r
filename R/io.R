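# Snapshot serialization (JSON), GraphML export of the cytoskeleton graph,
# membrane polyline CSV export, and a basic state plotter.

#' Write a simulation snapshot
#'
#' Serializes the full state losslessly to structured JSON: every live node
#' (id, kind, position at full precision, pointers, nucleotide and binding
#' occupancy, stored angles, rest length, attachment), the membrane
#' vertices in counterclockwise order with their attachments, bundling
#' links, pools, and the clock.
#'
#' @param S A `spine_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(S, path) {
  ids <- live_nodes(S)
  snap <- list(
    time = S$time,
    n_events = S$n_events,
    nodes = lapply(ids, function(id) list(
      id = id, kind = node_kinds()[S$kind[id]],
      x = S$x[id], y = S$y[id],
      nxt = S$nxt[id], brn = S$brn[id],
      theta = S$theta[id], theta_branch = S$theta_branch[id],
      nATP = S$nATP[id], nPi = S$nPi[id], nADP = S$nADP[id],
      ncof = S$ncof[id], cofS = S$cofS[id], aip1 = S$aip1[id],
      capA = S$capA[id], arp = S$arp[id], camk = S$camk[id],
      vref = S$vref[id], restlen = S$restlen[id])),
    membrane = list(x = S$mem[, 1], y = S$mem[, 2], vnode = S$vnode),
    links = list(a = S$bl_a, b = S$bl_b, rest = S$bl_rest,
                 alive = S$bl_alive),
    pools = as.list(S$pools)
  )
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a simulation snapshot
#'
#' Reconstructs a `spine_state` from [write_snapshot()] output. Together
#' with the writer this round-trips all state exactly (positions to full
#' float precision, all occupancy integers, pools, time).
#'
#' @param path Snapshot file.
#' @param params Resolved parameters to attach to the rebuilt state.
#' @return A `spine_state`.
#' @export
read_snapshot <- function(path, params = resolve_params()) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  mem <- cbind(snap$membrane$x, snap$membrane$y)
  S <- new_sim_state(params, membrane = mem)
  S$vnode <- as.integer(snap$membrane$vnode)
  nd <- snap$nodes
  maxid <- max(nd$id)
  while (length(S$alive) < maxid) .grow_state(S)
  S$nn <- as.integer(maxid)
  kindcode <- match(nd$kind, node_kinds())
  S$alive[nd$id] <- TRUE
  S$kind[nd$id] <- as.integer(kindcode)
  S$x[nd$id] <- nd$x; S$y[nd$id] <- nd$y
  S$nxt[nd$id] <- as.integer(nd$nxt); S$brn[nd$id] <- as.integer(nd$brn)
  S$theta[nd$id] <- nd$theta; S$theta_branch[nd$id] <- nd$theta_branch
  S$nATP[nd$id] <- as.integer(nd$nATP); S$nPi[nd$id] <- as.integer(nd$nPi)
  S$nADP[nd$id] <- as.integer(nd$nADP); S$ncof[nd$id] <- as.integer(nd$ncof)
  S$cofS[nd$id] <- nd$cofS; S$aip1[nd$id] <- nd$aip1
  S$capA[nd$id] <- nd$capA; S$arp[nd$id] <- nd$arp
  S$camk[nd$id] <- as.integer(nd$camk)
  S$vref[nd$id] <- as.integer(nd$vref)
  S$restlen[nd$id] <- nd$restlen
  # rebuild inverse pointers
  for (id in nd$id) {
    if (S$nxt[id] > 0) S$prv[S$nxt[id]] <- id
    if (S$brn[id] > 0) S$brnp[S$brn[id]] <- id
  }
  S$bl_a <- as.integer(snap$links$a); S$bl_b <- as.integer(snap$links$b)
  S$bl_rest <- as.numeric(snap$links$rest)
  S$bl_alive <- as.logical(snap$links$alive)
  S$pools <- unlist(snap$pools)[.pool_species]
  S$time <- snap$time
  S$n_events <- as.integer(snap$n_events)
  S
}

#' Export the cytoskeleton graph as GraphML
#'
#' Writes the actin connectivity (next and branch edges) with node kind,
#' position and occupancy attributes, for external graph viewers.
#'
#' @param S A `spine_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(S, path) {
  ids <- live_nodes(S)
  idx <- match(seq_len(S$nn), ids)
  from <- c(ids[S$nxt[ids] > 0], ids[S$brn[ids] > 0])
  to <- c(S$nxt[ids][S$nxt[ids] > 0], S$brn[ids][S$brn[ids] > 0])
  g <- igraph::make_empty_graph(n = length(ids), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(ids))
  g <- igraph::set_vertex_attr(g, "kind", value = node_kinds()[S$kind[ids]])
  g <- igraph::set_vertex_attr(g, "x", value = S$x[ids])
  g <- igraph::set_vertex_attr(g, "y", value = S$y[ids])
  g <- igraph::set_vertex_attr(g, "ncof", value = S$ncof[ids])
  if (length(from))
    g <- igraph::add_edges(g, rbind(idx[from], idx[to]))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export the membrane polygon as CSV
#'
#' Plain x,y rows of the closed polyline, in counterclockwise order.
#'
#' @param S A `spine_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_membrane_csv <- function(S, path) {
  utils::write.csv(data.frame(x = S$mem[, 1], y = S$mem[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Render the state to a PNG image
#'
#' A basic plot: the membrane polygon, actin nodes colored by their local
#' bending energy, barbed ends highlighted in green, capped ends and
#' junctions marked by triangles, and bundling links drawn as dashed
#' segments.
#'
#' @param S A `spine_state`.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
render_state <- function(S, path, width = 800, height = 800) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  par_old <- graphics::par(mar = c(2, 2, 1, 1))
  on.exit(graphics::par(par_old), add = TRUE)
  lim <- range(S$mem)
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1, xlab = "", ylab = "")
  graphics::polygon(S$mem[, 1], S$mem[, 2], border = "grey30", lwd = 2)
  ids <- live_nodes(S)
  if (length(ids)) {
    kb <- S$params$internal$k_bend
    bende <- 0.5 * kb * S$theta[ids]^2
    col <- grDevices::hcl.colors(32, "YlOrRd", rev = TRUE)[
      pmin(32, 1 + floor(31 * bende / max(bende, 1e-9)))]
    for (id in ids) {
      for (b in c(S$nxt[id], S$brn[id])) if (b > 0)
        graphics::segments(S$x[id], S$y[id], S$x[b], S$y[b], col = "grey60")
    }
    graphics::points(S$x[ids], S$y[ids], pch = 19, cex = 0.8, col = col)
    be <- ids[S$kind[ids] == KIND_BARBED]
    graphics::points(S$x[be], S$y[be], pch = 19, cex = 0.9, col = "green3")
    jc <- ids[S$kind[ids] == KIND_JUNCTION]
    graphics::points(S$x[jc], S$y[jc], pch = 17, cex = 1, col = "purple")
    cp <- ids[S$kind[ids] == KIND_CAPPED]
    graphics::points(S$x[cp], S$y[cp], pch = 17, cex = 1, col = "red")
    lk <- which(S$bl_alive)
    for (l in lk)
      graphics::segments(S$x[S$bl_a[l]], S$y[S$bl_a[l]],
                         S$x[S$bl_b[l]], S$y[S$bl_b[l]],
                         lty = 2, col = "blue")
  }
  invisible(path)
}
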