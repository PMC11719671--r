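# Skeleton-image-to-network extraction: replaces manual tracing of binary
# vessel masks. The vessel mask is topologically thinned, skeleton pixels are
# classified by 8-neighbour count (endpoint = 1, path = 2, node >= 3),
# node-to-node paths are traced into segments, short spurs pruned, and the
# segment graph rooted at the ring by breadth-first search: ring-touching
# segments become initial vessels, everything else a branch; graph edges that
# close a cycle are recorded as anastomoses.

#' Mask pair
#'
#' A binary vessel mask and the matching explant (ring) mask on the same
#' raster, with the physical pixel size.
#'
#' @param vessel_mask,ring_mask Logical matrices of identical dimensions
#'   (rows = y, columns = x; pixel indices are 0-based in the coordinate
#'   mapping, a pixel centre sits at (index + 0.5) * pixel size).
#' @param pixel_size_um Pixel edge length in um (> 0).
#' @param check_ring Verify that the ring mask is a single connected
#'   component (default TRUE).
#' @return An object of class `mask_pair`.
#' @export
mask_pair <- function(vessel_mask, ring_mask, pixel_size_um, check_ring = TRUE) {
  stopifnot(is.matrix(vessel_mask), is.matrix(ring_mask),
            all(dim(vessel_mask) == dim(ring_mask)),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  vessel_mask <- vessel_mask != 0
  ring_mask <- ring_mask != 0
  if (check_ring) {
    ncomp <- count_components_mask(ring_mask)
    if (ncomp != 1L) {
      stop_angioring("invalid_mask",
                     paste0("ring mask must be one connected component, found ", ncomp))
    }
  }
  structure(list(vessel_mask = vessel_mask, ring_mask = ring_mask,
                 pixel_size = pixel_size_um),
            class = "mask_pair")
}

# Shift a logical matrix by (di, dj), padding with FALSE; out[i, j] =
# m[i + di, j + dj].
shift_mask <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ri <- max(1, 1 - di):min(nr, nr - di)
  rj <- max(1, 1 - dj):min(nc, nc - dj)
  out[ri, rj] <- m[ri + di, rj + dj]
  out
}

# 8-connected component count via run-based union-find (fast for large disks).
count_components_mask <- function(m) {
  nr <- nrow(m)
  runs <- list()
  run_row <- integer(0); run_lo <- integer(0); run_hi <- integer(0)
  for (i in seq_len(nr)) {
    v <- m[i, ]
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    run_row <- c(run_row, rep(i, sum(keep)))
    run_lo <- c(run_lo, starts[keep])
    run_hi <- c(run_hi, ends[keep])
  }
  n <- length(run_row)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prev_rows <- split(seq_len(n), run_row)
  for (i in seq_len(n)) {
    above <- prev_rows[[as.character(run_row[i] - 1L)]]
    if (is.null(above)) next
    for (j in above) {
      # 8-connectivity: runs overlap when extended by one pixel each side
      if (run_lo[i] <= run_hi[j] + 1L && run_hi[i] >= run_lo[j] - 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Zhang-Suen topological thinning of a binary image, fully vectorized over the
# raster. Returns a 1-pixel-wide 8-connected skeleton. Pixels in `protect`
# are never deleted (used to anchor vessel stubs where they abut the ring, so
# end erosion cannot detach them from the explant).
thin_mask <- function(m, protect = NULL) {
  m <- m != 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mask(m, -1L, 0L)   # N
      p3 <- shift_mask(m, -1L, 1L)   # NE
      p4 <- shift_mask(m, 0L, 1L)    # E
      p5 <- shift_mask(m, 1L, 1L)    # SE
      p6 <- shift_mask(m, 1L, 0L)    # S
      p7 <- shift_mask(m, 1L, -1L)   # SW
      p8 <- shift_mask(m, 0L, -1L)   # W
      p9 <- shift_mask(m, -1L, -1L)  # NW
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (sub == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (!is.null(protect)) cond <- cond & !protect
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Thinning erodes blunt stroke ends by up to roughly the stroke width. Regrow
# each skeleton endpoint through the original mask along its outgoing
# direction until the stroke boundary is reached, restoring the lost tip
# length to within about a pixel.
regrow_tips <- function(skel, mask, max_steps = 20L) {
  idx <- which(skel, arr.ind = TRUE)
  if (!nrow(idx)) return(skel)
  deg <- matrix(0L, nrow(skel), ncol(skel))
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  nr <- nrow(skel); nc <- ncol(skel)
  for (k in seq_len(8)) {
    ni <- idx[, 1] + offs[k, 1]; nj <- idx[, 2] + offs[k, 2]
    ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
    ok[ok] <- skel[cbind(ni[ok], nj[ok])]
    deg[idx[ok, , drop = FALSE]] <- deg[idx[ok, , drop = FALSE]] + 1L
  }
  ends <- idx[deg[idx] == 1L, , drop = FALSE]
  for (e in seq_len(nrow(ends))) {
    cur <- ends[e, ]
    nb <- NULL
    for (k in seq_len(8)) {
      p <- cur + offs[k, ]
      if (p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc && skel[p[1], p[2]]) {
        nb <- p; break
      }
    }
    if (is.null(nb)) next
    dir <- cur - nb
    dir <- dir / sqrt(sum(dir^2))
    for (step in seq_len(max_steps)) {
      best <- NULL; best_dot <- 0.3
      for (k in seq_len(8)) {
        p <- cur + offs[k, ]
        if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
        if (!mask[p[1], p[2]] || skel[p[1], p[2]]) next
        d <- offs[k, ] / sqrt(sum(offs[k, ]^2))
        dt <- sum(d * dir)
        if (dt > best_dot) { best <- p; best_dot <- dt }
      }
      if (is.null(best)) break
      skel[best[1], best[2]] <- TRUE
      dir <- 0.6 * dir + 0.4 * (best - cur) / sqrt(sum((best - cur)^2))
      dir <- dir / sqrt(sum(dir^2))
      cur <- best
    }
  }
  skel
}

# Corrected path length of a pixel chain: chord resampling every `by` pixels
# removes most of the 8-connected digitization overestimate.
chain_resample <- function(coords, by = 4L) {
  n <- nrow(coords)
  idx <- unique(c(seq(1L, n, by = by), n))
  coords[idx, , drop = FALSE]
}

#' Extract a vessel network from a binary mask pair
#'
#' Thins the vessel mask (ring interior excluded), classifies skeleton pixels
#' by 8-neighbour count, traces node-to-node segments (diagonal steps weighted
#' sqrt(2) x pixel size; lengths measured on chord-resampled paths), prunes
#' terminal spurs shorter than `spur_min_length`, and roots the segment graph
#' at the ring by breadth-first search. Where several segments meet the ring
#' at one contact node, the longest becomes the initial vessel and the rest
#' branches. Cycle-closing segments are recorded as anastomoses, so loop
#' counting on the result matches the skeleton's cycles. Vessel components not
#' connected to the ring are discarded with a warning.
#'
#' @param masks A [mask_pair()].
#' @param spur_min_length Minimum terminal segment length in um; shorter spurs
#'   are removed as thinning artifacts (default 20).
#' @return A [vessel_network()]; empty (no segments) when the vessel mask is
#'   blank or nothing touches the ring.
#' @export
extract_network <- function(masks, spur_min_length = 20) {
  stopifnot(inherits(masks, "mask_pair"))
  px <- masks$pixel_size
  ring <- estimate_ring(masks)
  vm <- masks$vessel_mask & !masks$ring_mask
  if (!any(vm)) {
    return(vessel_network(ring, list()))
  }
  # ring-adjacent vessel pixels are anchored during thinning so vessel stubs
  # stay attached to the explant
  ring_adj <- masks$ring_mask
  for (k in seq_len(8)) {
    ring_adj <- ring_adj | shift_mask(masks$ring_mask,
                                      c(-1, 1, 0, 0, -1, -1, 1, 1)[k],
                                      c(0, 0, -1, 1, -1, 1, -1, 1)[k])
  }
  skel <- thin_mask(vm, protect = vm & ring_adj & !masks$ring_mask)
  if (!any(skel)) {
    return(vessel_network(ring, list()))
  }
  skel <- regrow_tips(skel, vm)
  idx <- which(skel, arr.ind = TRUE)  # (row, col)
  npx <- nrow(idx)
  id_of <- matrix(0L, nrow(skel), ncol(skel))
  id_of[skel] <- order(order(which(skel)))  # identity mapping in column-major order
  id_of[which(skel)] <- seq_len(npx)
  # 8-neighbour adjacency, dropping diagonal links that have an orthogonal
  # 2-step alternative (avoids spurious 3-cycles along staircases)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  nbrs <- vector("list", npx)
  nr <- nrow(skel); nc <- ncol(skel)
  at <- function(i, j) i >= 1 & i <= nr & j >= 1 & j <= nc & skel[cbind(pmax(pmin(i, nr), 1), pmax(pmin(j, nc), 1))]
  for (k in seq_len(8)) {
    di <- offs[k, 1]; dj <- offs[k, 2]
    ni <- idx[, 1] + di; nj <- idx[, 2] + dj
    ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
    ok[ok] <- skel[cbind(ni[ok], nj[ok])]
    if (k > 4) {
      # diagonal: skip when either orthogonal stepping stone exists
      s1 <- ok; s2 <- ok
      s1[ok] <- skel[cbind(idx[ok, 1] + di, idx[ok, 2])]
      s2[ok] <- skel[cbind(idx[ok, 1], idx[ok, 2] + dj)]
      ok <- ok & !(s1 | s2)
    }
    w <- which(ok)
    for (p in w) {
      nbrs[[p]] <- c(nbrs[[p]], id_of[idx[p, 1] + di, idx[p, 2] + dj])
    }
  }
  deg <- lengths(nbrs)
  # ring contact: skeleton pixel 8-adjacent to the ring mask (anchored stubs
  # guarantee such pixels exist wherever a vessel meets the explant)
  ring_contact <- ring_adj[cbind(idx[, 1], idx[, 2])]
  is_node <- deg != 2L | ring_contact
  # guard: a component that is a pure cycle has no node pixel; make one
  comp_seed <- which(!is_node)
  if (length(comp_seed)) {
    visited <- is_node
    for (s in comp_seed) {
      if (visited[s]) next
      # walk this degree-2 component; if we return to s it is a pure cycle
      queue <- s; visited[s] <- TRUE; hit_node <- FALSE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (w in nbrs[[v]]) {
          if (is_node[w]) hit_node <- TRUE
          else if (!visited[w]) { visited[w] <- TRUE; queue <- c(queue, w) }
        }
      }
      if (!hit_node) is_node[s] <- TRUE
    }
  }
  # trace node-to-node paths
  paths <- list()
  used <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  node_ids <- which(is_node)
  for (u in node_ids) {
    for (v in nbrs[[u]]) {
      if (!is.null(used[[ekey(u, v)]])) next
      path <- c(u, v)
      used[[ekey(u, v)]] <- TRUE
      prev <- u; cur <- v
      while (!is_node[cur]) {
        nxt <- nbrs[[cur]]
        nxt <- nxt[nxt != prev]
        if (!length(nxt)) break  # dead end (shouldn't happen: deg-2 interior)
        nxt <- nxt[[1]]
        used[[ekey(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  if (!length(paths)) {
    return(vessel_network(ring, list()))
  }
  # supernodes: adjacent node pixels merged (junction clusters, ring contacts)
  super <- integer(npx)
  nn <- length(node_ids)
  parent <- seq_len(nn)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  pos_in_nodes <- integer(npx)
  pos_in_nodes[node_ids] <- seq_len(nn)
  for (u in node_ids) {
    for (v in nbrs[[u]]) {
      if (is_node[v]) {
        a <- find(pos_in_nodes[u]); b <- find(pos_in_nodes[v])
        if (a != b) parent[b] <- a
      }
    }
  }
  roots <- vapply(seq_len(nn), find, integer(1))
  super[node_ids] <- match(roots, unique(roots))
  n_super <- max(super)
  super_ring <- vapply(seq_len(n_super), function(s) {
    any(ring_contact[node_ids[super[node_ids] == s]])
  }, logical(1))
  # pixel (row, col) -> um; 0-based indices, pixel centres at (index + .5) * px
  to_um <- function(pix_ids) {
    cbind((idx[pix_ids, 2] - 0.5) * px, (idx[pix_ids, 1] - 0.5) * px)
  }
  edges <- data.frame(a = integer(0), b = integer(0), length = numeric(0))
  epaths <- list()
  for (p in paths) {
    a <- super[p[[1]]]; b <- super[p[[length(p)]]]
    coords <- to_um(p)
    rs <- chain_resample(coords)
    len <- polyline_length(rs)
    if (a == b && len < 2 * masks$pixel_size) next  # degenerate micro-loop
    edges <- rbind(edges, data.frame(a = a, b = b, length = len))
    epaths[[nrow(edges)]] <- rs
  }
  out <- prune_and_build(edges, epaths, super_ring, ring, spur_min_length, px)
  out
}

# Spur pruning, degree-2 splicing, connectivity filtering and BFS rooting of
# the traced segment graph into a vessel_network.
prune_and_build <- function(edges, epaths, super_ring, ring, spur_min_length, px) {
  drop_unreachable <- function(edges, epaths) {
    if (!nrow(edges)) return(list(edges = edges, epaths = epaths, dropped = 0L))
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$a, to = edges$b), directed = FALSE,
      vertices = data.frame(name = seq_along(super_ring)))
    comp <- igraph::components(g)$membership
    ring_comps <- unique(comp[which(super_ring)])
    keep <- comp[edges$a] %in% ring_comps
    list(edges = edges[keep, , drop = FALSE], epaths = epaths[keep],
         dropped = sum(!keep))
  }
  dr <- drop_unreachable(edges, epaths)
  if (dr$dropped > 0) {
    warning(dr$dropped, " vessel segment(s) in components not touching the ring were discarded")
  }
  edges <- dr$edges; epaths <- dr$epaths
  repeat {
    changed <- FALSE
    if (!nrow(edges)) break
    degree_of <- tabulate(c(edges$a, edges$b), nbins = length(super_ring))
    # prune terminal spurs
    leaf_a <- degree_of[edges$a] == 1L & !super_ring[edges$a]
    leaf_b <- degree_of[edges$b] == 1L & !super_ring[edges$b]
    spur <- (leaf_a | leaf_b) & edges$length < spur_min_length &
      !(leaf_a & leaf_b)  # keep isolated two-leaf stubs out of the spur rule
    if (any(spur)) {
      edges <- edges[!spur, , drop = FALSE]
      epaths <- epaths[!spur]
      changed <- TRUE
      next
    }
    # collapse junction-zone thinning artifacts: a very short edge joining two
    # junctions is one junction blob that thinned into a micro-cycle
    degree_of <- tabulate(c(edges$a, edges$b), nbins = length(super_ring))
    short_jj <- which(edges$a != edges$b & edges$length < 6 * px &
                        degree_of[edges$a] >= 3L & degree_of[edges$b] >= 3L)
    if (length(short_jj)) {
      e <- short_jj[[1]]
      keep_nd <- edges$a[e]; drop_nd <- edges$b[e]
      edges <- edges[-e, , drop = FALSE]
      epaths <- epaths[-e]
      edges$a[edges$a == drop_nd] <- keep_nd
      edges$b[edges$b == drop_nd] <- keep_nd
      super_ring[keep_nd] <- super_ring[keep_nd] || super_ring[drop_nd]
      micro_self <- which(edges$a == edges$b & edges$length < 15 * px)
      if (length(micro_self)) {
        edges <- edges[-micro_self, , drop = FALSE]
        epaths <- epaths[-micro_self]
      }
      changed <- TRUE
      next
    }
    # splice pass-through nodes (degree 2, not ring contact)
    degree_of <- tabulate(c(edges$a, edges$b), nbins = length(super_ring))
    cand <- which(degree_of == 2L & !super_ring)
    spliced <- FALSE
    for (nd in cand) {
      eids <- which(edges$a == nd | edges$b == nd)
      if (length(eids) != 2L) next  # self-loop at nd
      e1 <- eids[1]; e2 <- eids[2]
      p1 <- epaths[[e1]]; p2 <- epaths[[e2]]
      if (edges$a[e1] == nd) { p1 <- p1[nrow(p1):1, , drop = FALSE]; o1 <- edges$b[e1] } else o1 <- edges$a[e1]
      if (edges$b[e2] == nd) { p2 <- p2[nrow(p2):1, , drop = FALSE]; o2 <- edges$a[e2] } else o2 <- edges$b[e2]
      newp <- rbind(p1, p2[-1, , drop = FALSE])
      edges$a[e1] <- o1; edges$b[e1] <- o2
      edges$length[e1] <- edges$length[e1] + edges$length[e2]
      epaths[[e1]] <- newp
      edges <- edges[-e2, , drop = FALSE]
      epaths <- epaths[-e2]
      spliced <- TRUE
      break
    }
    if (spliced) { changed <- TRUE; next }
    if (!changed) break
  }
  if (!nrow(edges)) {
    return(vessel_network(ring, list()))
  }
  build_segments_bfs(edges, epaths, super_ring, ring)
}

# Breadth-first rooting at the ring with collinear continuation merging: at a
# junction the traced edge whose direction continues the incoming vessel most
# straightly is spliced onto the same logical segment (the way a human tracer
# follows a vessel through its side branches); the remaining edges become
# branches. Edges that reach an already-visited node close a cycle and are
# recorded as anastomoses.
build_segments_bfs <- function(edges, epaths, super_ring, ring) {
  n_e <- nrow(edges)
  oriented_path <- function(e, from) {
    p <- epaths[[e]]
    if (edges$a[e] == from) p else p[nrow(p):1, , drop = FALSE]
  }
  other_end <- function(e, from) if (edges$a[e] == from) edges$b[e] else edges$a[e]

  ## phase 1: breadth-first discovery at edge granularity. Roots every
  ## ring-touching edge (longest per contact = initial), assigns every other
  ## edge a provisional parent, and records cycle-closing arrivals.
  e_kind <- rep(NA_character_, n_e)
  e_parent <- rep(NA_integer_, n_e)       # parent edge index
  e_attach_node <- rep(NA_integer_, n_e)  # node where the edge was claimed
  e_from <- rep(NA_integer_, n_e)         # proximal node at discovery
  e_order <- rep(NA_integer_, n_e)
  e_fused <- rep(FALSE, n_e)
  e_fusion_target <- rep(NA_integer_, n_e)
  e_fusion_node <- rep(NA_integer_, n_e)
  visited_node <- rep(FALSE, length(super_ring))
  via_edge <- rep(NA_integer_, length(super_ring))
  assigned <- rep(FALSE, n_e)
  queue <- list()
  ord <- 0L
  claim <- function(e, kind, parent, nd) {
    ord <<- ord + 1L
    e_kind[e] <<- kind; e_parent[e] <<- parent
    e_attach_node[e] <<- nd; e_from[e] <<- nd; e_order[e] <<- ord
    assigned[e] <<- TRUE
    queue[[length(queue) + 1L]] <<- e
  }
  for (rn in which(super_ring)) visited_node[rn] <- TRUE
  for (rn in which(super_ring)) {
    eids <- which((edges$a == rn | edges$b == rn) & !assigned)
    if (!length(eids)) next
    eids <- eids[order(-edges$length[eids])]
    claim(eids[[1]], "initial", NA_integer_, rn)
    via_edge[rn] <- eids[[1]]
    for (e in eids[-1]) claim(e, "branch", eids[[1]], rn)
  }
  qi <- 1L
  while (qi <= length(queue)) {
    e <- queue[[qi]]; qi <- qi + 1L
    far <- other_end(e, e_from[e])
    if (far == e_from[e] || visited_node[far]) {
      if (far != e_from[e] || !is.na(via_edge[far])) {
        e_fused[e] <- TRUE
        e_fusion_target[e] <- via_edge[far]
        e_fusion_node[e] <- far
      }
      next
    }
    visited_node[far] <- TRUE
    via_edge[far] <- e
    for (e2 in which((edges$a == far | edges$b == far) & !assigned)) {
      claim(e2, "branch", e, far)
    }
  }

  ## phase 2: at every non-ring node, pair edge stubs whose directions
  ## continue each other most straightly (within 60 degrees). Pairing is
  ## globally greedy per node, so a vessel passing through a junction is
  ## reassembled even when its halves were discovered from opposite ends,
  ## and a fused tip cannot steal another vessel's continuation.
  stub_dir <- function(e, nd) {
    # direction over ~40 um of path: the junction blob distorts the first few
    # pixels, so a short lookahead misreads which arm continues the vessel
    p <- oriented_path(e, nd)   # starts at nd
    d <- p[1, ] - p[min(6L, nrow(p)), ]
    d / max(sqrt(sum(d^2)), 1e-9)  # pointing INTO the node
  }
  # pairing[[e]] is c(a_partner_edge, b_partner_edge); NA = free stub
  pair_a <- rep(NA_integer_, n_e)
  pair_b <- rep(NA_integer_, n_e)
  set_pair <- function(e, nd, partner) {
    if (edges$a[e] == nd && is.na(pair_a[e])) pair_a[e] <<- partner
    else pair_b[e] <<- partner
  }
  side_free <- function(e, nd) {
    if (edges$a[e] == nd && is.na(pair_a[e])) TRUE
    else edges$b[e] == nd && is.na(pair_b[e])
  }
  for (nd in seq_along(super_ring)) {
    if (super_ring[nd]) next
    inc <- which(edges$a == nd | edges$b == nd)
    if (length(inc) < 2) next
    # stub list: self-loop edges contribute both ends but never pair with
    # themselves
    stubs <- list()
    for (e in inc) {
      k <- (edges$a[e] == nd) + (edges$b[e] == nd)
      for (rep_i in seq_len(k)) {
        stubs[[length(stubs) + 1L]] <- list(e = e, dir = stub_dir(e, nd))
      }
    }
    if (length(stubs) < 2) next
    taken <- rep(FALSE, length(stubs))
    repeat {
      best_i <- 0L; best_j <- 0L; best_ang <- 60 * pi / 180
      for (i in seq_len(length(stubs) - 1L)) {
        if (taken[i]) next
        for (j in seq.int(i + 1L, length(stubs))) {
          if (taken[j] || stubs[[i]]$e == stubs[[j]]$e) next
          ang <- acos(max(-1, min(1, -sum(stubs[[i]]$dir * stubs[[j]]$dir))))
          if (ang < best_ang) { best_i <- i; best_j <- j; best_ang <- ang }
        }
      }
      if (best_i == 0L) break
      taken[best_i] <- TRUE; taken[best_j] <- TRUE
      set_pair(stubs[[best_i]]$e, nd, stubs[[best_j]]$e)
      set_pair(stubs[[best_j]]$e, nd, stubs[[best_i]]$e)
    }
  }

  ## phase 3: assemble chains of paired edges into vessel segments and
  ## re-derive hierarchy (attachments, fusions) from the free chain ends.
  chain_of <- rep(NA_integer_, n_e)
  chains <- list()  # each: list(edges = ordered edge ids, nodes = node seq)
  for (e0 in seq_len(n_e)) {
    if (!is.na(chain_of[e0])) next
    # find a free stub to start from; if the chain is closed, break the
    # weakest pairing by starting anywhere
    comp <- e0
    repeat {
      grow <- unique(stats::na.omit(c(pair_a[comp], pair_b[comp])))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    start_e <- NA_integer_; start_nd <- NA_integer_
    for (e in comp) {
      if (is.na(pair_a[e])) { start_e <- e; start_nd <- edges$a[e]; break }
      if (is.na(pair_b[e])) { start_e <- e; start_nd <- edges$b[e]; break }
    }
    if (is.na(start_e)) {  # closed chain: cut it open at e0's a-side
      start_e <- e0; start_nd <- edges$a[e0]
      partner <- pair_a[e0]
      pair_a[e0] <- NA_integer_
      if (!is.na(partner)) {
        if (!is.na(pair_a[partner]) && pair_a[partner] == e0) pair_a[partner] <- NA_integer_
        else pair_b[partner] <- NA_integer_
      }
    }
    seq_e <- integer(0); seq_nd <- start_nd
    cur_e <- start_e; cur_nd <- start_nd
    repeat {
      seq_e <- c(seq_e, cur_e)
      chain_of[cur_e] <- length(chains) + 1L
      nxt_nd <- other_end(cur_e, cur_nd)
      seq_nd <- c(seq_nd, nxt_nd)
      partner <- if (edges$a[cur_e] == nxt_nd && !is.na(pair_a[cur_e]) &&
                       is.na(chain_of[pair_a[cur_e]])) pair_a[cur_e]
                 else if (edges$b[cur_e] == nxt_nd && !is.na(pair_b[cur_e]) &&
                       is.na(chain_of[pair_b[cur_e]])) pair_b[cur_e]
                 else NA_integer_
      if (is.na(partner)) break
      cur_e <- partner; cur_nd <- nxt_nd
    }
    chains[[length(chains) + 1L]] <- list(edges = seq_e, nodes = seq_nd)
  }
  n_c <- length(chains)
  seg_id <- sprintf("s%03d", seq_len(n_c))
  # end roles: for a chain end (edge e entered/left at node nd), what was it?
  end_role <- function(e, nd) {
    if (e_kind[e] == "initial" && e_from[e] == nd && super_ring[nd]) return("ring")
    if (!is.na(e_attach_node[e]) && e_from[e] == nd && e_kind[e] == "branch") return("attach")
    if (e_fused[e] && !is.na(e_fusion_node[e]) && e_fusion_node[e] == nd) return("fused")
    "tip"
  }
  c_kind <- character(n_c); c_parent <- rep(NA_character_, n_c)
  c_path <- vector("list", n_c)
  fusion_rows <- list()
  # canonical node positions: mean of the incident edge path endpoints, so
  # every record at one supernode uses one point
  node_pos <- matrix(NA_real_, length(super_ring), 2)
  for (nd in seq_along(super_ring)) {
    inc <- which(edges$a == nd | edges$b == nd)
    if (!length(inc)) next
    pts <- t(vapply(inc, function(e) oriented_path(e, nd)[1, ], numeric(2)))
    node_pos[nd, ] <- colMeans(pts)
  }
  node_point <- function(e, nd) node_pos[nd, ]
  # chain owning some OTHER edge at node nd (prefer the BFS via edge)
  chain_at_node <- function(nd, exclude_ci) {
    if (!is.na(via_edge[nd]) && chain_of[via_edge[nd]] != exclude_ci) {
      return(chain_of[via_edge[nd]])
    }
    for (e in which(edges$a == nd | edges$b == nd)) {
      if (chain_of[e] != exclude_ci) return(chain_of[e])
    }
    NA_integer_
  }
  for (ci in seq_len(n_c)) {
    ch <- chains[[ci]]
    e_first <- ch$edges[1]; e_last <- ch$edges[length(ch$edges)]
    nd_first <- ch$nodes[1]; nd_last <- ch$nodes[length(ch$nodes)]
    role_first <- end_role(e_first, nd_first)
    role_last <- end_role(e_last, nd_last)
    # proximal-end preference: ring > attachment > fused > connected tip >
    # free tip; ties between two attach ends go to the earlier discovery
    end_score <- function(role, nd) {
      if (role == "ring") return(4)
      if (role == "attach") return(3)
      if (role == "fused") return(2)
      if (!is.na(chain_at_node(nd, ci))) return(1)
      0
    }
    s_first <- end_score(role_first, nd_first)
    s_last <- end_score(role_last, nd_last)
    flip <- s_last > s_first ||
      (s_last == s_first && role_first == "attach" && role_last == "attach" &&
         e_order[e_last] < e_order[e_first])
    if (flip) {
      ch$edges <- rev(ch$edges); ch$nodes <- rev(ch$nodes)
      e_first <- ch$edges[1]; e_last <- ch$edges[length(ch$edges)]
      nd_first <- ch$nodes[1]; nd_last <- ch$nodes[length(ch$nodes)]
      role_first <- end_role(e_first, nd_first)
      role_last <- end_role(e_last, nd_last)
      chains[[ci]] <- ch
    }
    # polyline: concatenate oriented edge paths from the proximal end
    pl <- oriented_path(e_first, nd_first)
    if (length(ch$edges) > 1) {
      for (k in 2:length(ch$edges)) {
        pk <- oriented_path(ch$edges[k], ch$nodes[k])
        pl <- rbind(pl, pk[-1, , drop = FALSE])
      }
    }
    c_path[[ci]] <- pl
    if (role_first == "ring") {
      c_kind[ci] <- "initial"
    } else {
      c_kind[ci] <- "branch"
      if (role_first == "attach") {
        c_parent[ci] <- as.character(e_parent[e_first])  # edge idx, remapped below
      } else if (role_first == "fused") {
        c_parent[ci] <- as.character(e_fusion_target[e_first])
      } else {
        # tip-role proximal end: attach to whichever vessel shares the node
        # (resolved below via chain_at_node through the NA path)
        c_parent[ci] <- NA_character_
      }
    }
    # distal end: any chain end sitting at a node shared with another vessel
    # is an anastomosis (a surviving attach role means the chain was
    # discovered from both sides; a "tip" at a shared node means the paired
    # continuation displaced this adjacency)
    if (role_last != "ring") {
      target <- if (role_last == "fused") e_fusion_target[e_last]
                else if (role_last == "attach") e_parent[e_last]
                else NA_integer_
      target_ci <- if (!is.na(target)) chain_of[target] else NA_integer_
      if (is.na(target_ci) || target_ci == ci) {
        target_ci <- chain_at_node(nd_last, ci)
      }
      if (!is.na(target_ci)) {
        tp <- node_point(e_last, nd_last)
        fusion_rows[[length(fusion_rows) + 1L]] <- data.frame(
          target_ci = target_ci, segment_idx = ci, x = tp[1], y = tp[2])
      }
    }
  }
  # remap parent edge indices to chain ids; guard against self-parenting
  for (ci in seq_len(n_c)) {
    if (c_kind[ci] != "branch") { c_parent[ci] <- NA_character_; next }
    pe <- suppressWarnings(as.integer(c_parent[ci]))
    pc <- if (is.na(pe)) NA_integer_ else chain_of[pe]
    if (is.na(pc) || pc == ci) {
      pc <- chain_at_node(chains[[ci]]$nodes[1], ci)
    }
    c_parent[ci] <- if (is.na(pc)) NA_character_ else seg_id[pc]
    if (is.na(c_parent[ci])) c_kind[ci] <- "initial"  # last-resort orphan
  }
  fus <- NULL
  if (length(fusion_rows)) {
    fr <- do.call(rbind, fusion_rows)
    fus <- data.frame(segment_id = seg_id[fr$segment_idx],
                      target_id = seg_id[fr$target_ci], x = fr$x, y = fr$y)
  }
  segs <- lapply(seq_len(n_c), function(ci) {
    nd1 <- chains[[ci]]$nodes[1]
    vessel_segment(seg_id[ci], c_path[[ci]], kind = c_kind[ci],
                   parent_id = c_parent[ci],
                   attach_point = node_pos[nd1, ])
  })
  vessel_network(ring, segs, fusions = fus)
}


# Equivalent-disk ring estimate from the ring mask (centroid + area radius).
estimate_ring <- function(masks) {
  px <- masks$pixel_size
  rp <- which(masks$ring_mask, arr.ind = TRUE)
  if (!nrow(rp)) {
    stop_angioring("invalid_mask", "ring mask is empty")
  }
  center <- c(mean((rp[, 2] - 0.5) * px), mean((rp[, 1] - 0.5) * px))
  r <- sqrt(nrow(rp) * px^2 / pi)
  ring_explant(center = center, radius = r)
}
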