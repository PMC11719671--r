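# Domain types for explant vessel networks: the ring explant, vessel segments
# (initial vessels and branches) and the assembled network with optional
# anastomosis (fusion) records that close loops.

#' Ring explant geometry
#'
#' The aortic explant as seen in the image plane: either a circle (centre +
#' radius) or an explicit simple closed polygon. The outer circumference is
#' the explant-level size readout and the denominator of vessel density.
#'
#' @param center Numeric length-2, ring centre (um). Default `c(0, 0)`.
#' @param radius Ring radius in um (circular explants).
#' @param boundary Two-column matrix of polygon vertices in um (alternative to
#'   `radius`); must be a simple polygon with at least 3 vertices.
#' @return An object of class `ring_explant` with a `circumference` field.
#' @export
#' @examples
#' ring_explant(radius = 500)$circumference  # 2 * pi * 500
ring_explant <- function(center = c(0, 0), radius = NULL, boundary = NULL) {
  stopifnot(is.numeric(center), length(center) == 2)
  if (is.null(radius) && is.null(boundary)) {
    stop_angioring("invalid_geometry", "give either a radius or a boundary polygon")
  }
  if (!is.null(boundary)) {
    boundary <- as.matrix(boundary)
    if (nrow(boundary) < 3) {
      stop_angioring("invalid_geometry", "boundary polygon needs at least 3 vertices")
    }
    if (!polygon_is_simple(boundary)) {
      stop_angioring("invalid_geometry", "boundary polygon is self-intersecting")
    }
    circ <- polygon_perimeter(boundary)
  } else {
    if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
      stop_angioring("invalid_geometry", "radius must be a single positive number")
    }
    circ <- 2 * pi * radius
  }
  structure(
    list(center = as.numeric(center), radius = radius, boundary = boundary,
         circumference = circ),
    class = "ring_explant"
  )
}

#' Outer circumference of a ring explant
#'
#' @param ring A [ring_explant()].
#' @return Circumference in um (polygon perimeter, or `2*pi*radius`).
#' @export
circumference <- function(ring) {
  stopifnot(inherits(ring, "ring_explant"))
  ring$circumference
}

# Shortest distance from a point to the ring's outer boundary.
dist_to_ring <- function(ring, p) {
  if (!is.null(ring$boundary)) {
    dist_point_polygon(p, ring$boundary)
  } else {
    abs(sqrt(sum((p - ring$center)^2)) - ring$radius)
  }
}

#' Vessel segment
#'
#' One traced vessel: an ordered polyline in um. Initial (primary) vessels
#' sprout from the ring's outer edge (`parent_id = NA`); branches originate
#' from an initial vessel or another branch.
#'
#' @param id Segment identifier (character).
#' @param polyline Two-column numeric matrix of points in um, first point at
#'   the attachment, last point at the free tip.
#' @param kind `"initial"` or `"branch"`.
#' @param parent_id Identifier of the parent segment, `NA` for initial vessels.
#' @param attach_point Attachment coordinates on the parent or ring; defaults
#'   to the first polyline point.
#' @param generation Branch generation depth (0 for initial vessels); stored
#'   but not used by the twelve parameters.
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(id, polyline, kind = c("initial", "branch"),
                           parent_id = NA_character_,
                           attach_point = NULL, generation = NULL) {
  kind <- match.arg(kind)
  polyline <- as.matrix(polyline)
  storage.mode(polyline) <- "double"
  if (nrow(polyline) < 2) {
    stop_angioring("invalid_geometry", "segment polyline needs at least 2 points")
  }
  len <- polyline_length(polyline)
  if (len <= 0) {
    stop_angioring("invalid_geometry", "segment length must be positive")
  }
  if (kind == "initial" && !is.na(parent_id)) {
    stop_angioring("invalid_network", "initial vessels attach to the ring, not a parent segment")
  }
  if (kind == "branch" && is.na(parent_id)) {
    stop_angioring("invalid_network", "branches need a parent segment")
  }
  if (is.null(attach_point)) attach_point <- polyline[1, ]
  if (is.null(generation)) generation <- if (kind == "initial") 0L else NA_integer_
  structure(
    list(id = as.character(id), polyline = polyline, kind = kind,
         parent_id = as.character(parent_id), attach_point = as.numeric(attach_point),
         generation = generation, length = len),
    class = "vessel_segment"
  )
}

#' Explant vessel network
#'
#' @param ring A [ring_explant()].
#' @param segments List of [vessel_segment()] objects.
#' @param fusions Optional data frame of anastomoses with columns
#'   `segment_id` (the fused tip's segment), `target_id` (the segment it fused
#'   onto), `x`, `y` (fusion point, um). Fusions close loops.
#' @return An object of class `vessel_network`.
#' @export
vessel_network <- function(ring, segments = list(), fusions = NULL) {
  stopifnot(inherits(ring, "ring_explant"))
  if (length(segments)) {
    stopifnot(all(vapply(segments, inherits, logical(1), "vessel_segment")))
    ids <- vapply(segments, `[[`, character(1), "id")
    if (anyDuplicated(ids)) {
      stop_angioring("invalid_network", "duplicate segment ids")
    }
    names(segments) <- ids
    # parent references must form a forest rooted at the ring
    for (seg in segments) {
      if (seg$kind == "branch" && !seg$parent_id %in% ids) {
        stop_angioring("invalid_network",
                       paste0("branch ", seg$id, " references missing parent ", seg$parent_id))
      }
    }
    seen <- character(0)
    for (seg in segments) {
      chain <- character(0)
      cur <- seg
      while (cur$kind == "branch") {
        if (cur$id %in% chain) {
          stop_angioring("invalid_network", "parent references contain a cycle")
        }
        chain <- c(chain, cur$id)
        cur <- segments[[cur$parent_id]]
      }
      seen <- union(seen, chain)
    }
  }
  if (is.null(fusions)) {
    fusions <- data.frame(segment_id = character(0), target_id = character(0),
                          x = numeric(0), y = numeric(0))
  } else {
    fusions <- as.data.frame(fusions)
    stopifnot(all(c("segment_id", "target_id", "x", "y") %in% names(fusions)))
    ids <- names(segments)
    bad <- !(fusions$segment_id %in% ids & fusions$target_id %in% ids)
    if (any(bad)) stop_angioring("invalid_network", "fusion references unknown segments")
  }
  structure(list(ring = ring, segments = segments, fusions = fusions),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  kinds <- segment_kinds(x)
  cat("<vessel_network>",
      sprintf("ring circumference: %.1f um", x$ring$circumference),
      sprintf("segments: %d initial, %d branch",
              sum(kinds == "initial"), sum(kinds == "branch")),
      sprintf("anastomoses: %d", nrow(x$fusions)),
      sep = "\n")
  invisible(x)
}

n_segments <- function(net) length(net$segments)

segment_kinds <- function(net) {
  vapply(net$segments, `[[`, character(1), "kind")
}

segment_lengths <- function(net) {
  vapply(net$segments, `[[`, numeric(1), "length")
}

segment_tips <- function(net) {
  if (!n_segments(net)) return(matrix(numeric(0), ncol = 2))
  t(vapply(net$segments, function(s) s$polyline[nrow(s$polyline), ], numeric(2)))
}

#' Explant observation
#'
#' One aortic ring at one imaging time point, with either a traced network or
#' (for pre-measured tables) none.
#'
#' @param donor Donor label.
#' @param group Treatment group label (e.g. `"control"`, `"single_cells"`,
#'   `"spheroids_small"`, `"spheroids_large"`, or user-defined).
#' @param ring_id Ring label, unique within donor and group.
#' @param day Day of treatment (positive integer; the assay images days 1, 4
#'   and 7 by default).
#' @param imaging_time_h Hours since assay start at which the image was taken.
#' @param network A [vessel_network()] or `NULL`.
#' @param migrated Logical; sprouting visible. Defaults to the network having
#'   at least one segment.
#' @return An object of class `explant_observation`.
#' @export
explant_observation <- function(donor, group, ring_id, day,
                                imaging_time_h = day * 24,
                                network = NULL, migrated = NULL) {
  stopifnot(length(day) == 1, day > 0, day == round(day))
  if (!is.null(network)) {
    stopifnot(inherits(network, "vessel_network"))
    has_seg <- n_segments(network) > 0
    if (is.null(migrated)) migrated <- has_seg
    if (migrated != has_seg) {
      stop_angioring("invalid_network",
                     "migrated flag must equal 'network has >= 1 segment' when a network is present")
    }
  } else if (is.null(migrated)) {
    stop_angioring("invalid_network", "migrated must be given when no network is present")
  }
  structure(
    list(donor = as.character(donor), group = as.character(group),
         ring_id = as.character(ring_id), day = as.integer(day),
         imaging_time_h = as.numeric(imaging_time_h),
         network = network, migrated = isTRUE(migrated)),
    class = "explant_observation"
  )
}

# ---------------------------------------------------------------------------
# Node graph of a network: segments subdivided at every attachment event
# (branch origins, fusion targets) with coincident points (within `merge_tol`
# um) merged into single nodes. This is the graph on which junctions and loops
# are defined.
#
# Returns list(nodes = data.frame(node, x, y), edges = data.frame(from, to,
# seg_id, length), branch_attach_nodes, fusion_nodes, ring_nodes).
segment_node_graph <- function(net, merge_tol = 5) {
  segs <- net$segments
  if (!length(segs)) {
    return(list(nodes = data.frame(node = integer(0), x = numeric(0), y = numeric(0)),
                edges = data.frame(from = integer(0), to = integer(0),
                                   seg_id = character(0), length = numeric(0)),
                branch_attach_nodes = integer(0), fusion_nodes = integer(0),
                ring_nodes = integer(0)))
  }
  # event table: one row per (segment, arclength position, point, role)
  ev_seg <- character(0); ev_s <- numeric(0)
  ev_x <- numeric(0); ev_y <- numeric(0); ev_role <- character(0)
  add_event <- function(seg_id, s, p, role) {
    ev_seg <<- c(ev_seg, seg_id); ev_s <<- c(ev_s, s)
    ev_x <<- c(ev_x, p[1]); ev_y <<- c(ev_y, p[2]); ev_role <<- c(ev_role, role)
  }
  fused_ids <- net$fusions$segment_id
  for (seg in segs) {
    pl <- seg$polyline
    start_role <- if (seg$kind == "initial") "ring" else "branch_attach"
    add_event(seg$id, 0, pl[1, ], start_role)
    tip_role <- if (seg$id %in% fused_ids) "fused_tip" else "tip"
    add_event(seg$id, seg$length, pl[nrow(pl), ], tip_role)
  }
  # children subdivide their parent at the attachment point
  for (seg in segs) {
    if (seg$kind == "branch") {
      parent <- segs[[seg$parent_id]]
      s <- locate_on_polyline(parent$polyline, seg$attach_point)
      add_event(parent$id, s, seg$attach_point, "child_attach")
    }
  }
  # fusion points subdivide their target
  if (nrow(net$fusions)) {
    for (k in seq_len(nrow(net$fusions))) {
      f <- net$fusions[k, ]
      target <- segs[[f$target_id]]
      p <- c(f$x, f$y)
      s <- locate_on_polyline(target$polyline, p)
      add_event(target$id, s, p, "fusion_target")
    }
  }
  pts <- cbind(ev_x, ev_y)
  node_id <- cluster_points(pts, merge_tol)
  nodes <- data.frame(node = seq_len(max(node_id)))
  nodes$x <- vapply(nodes$node, function(k) mean(ev_x[node_id == k]), numeric(1))
  nodes$y <- vapply(nodes$node, function(k) mean(ev_y[node_id == k]), numeric(1))
  # edges: consecutive distinct nodes along each segment
  from <- integer(0); to <- integer(0); eseg <- character(0); elen <- numeric(0)
  for (seg in segs) {
    i <- which(ev_seg == seg$id)
    i <- i[order(ev_s[i])]
    nd <- node_id[i]
    ss <- ev_s[i]
    keep <- c(TRUE, nd[-1] != nd[-length(nd)])
    nd <- nd[keep]; ss <- ss[keep]
    if (length(nd) >= 2) {
      from <- c(from, nd[-length(nd)])
      to <- c(to, nd[-1])
      eseg <- c(eseg, rep(seg$id, length(nd) - 1L))
      elen <- c(elen, diff(ss))
    }
  }
  list(
    nodes = nodes,
    edges = data.frame(from = from, to = to, seg_id = eseg, length = elen,
                       stringsAsFactors = FALSE),
    branch_attach_nodes = unique(node_id[ev_role %in% c("branch_attach", "fusion_target")]),
    fusion_nodes = unique(node_id[ev_role == "fusion_target"]),
    ring_nodes = unique(node_id[ev_role == "ring"])
  )
}

#' Check the minimum-separation precondition for exact skeleton round trips
#'
#' Rasterized extraction can only recover counts exactly when distinct vessels
#' do not run closer to each other than the drawn stroke width, junctions are
#' mutually resolvable, and no segment is shorter than the spur-pruning
#' threshold. This predicate checks those purely geometric conditions on the
#' true network; it knows nothing about the extraction itself.
#'
#' @param net A [vessel_network()].
#' @param min_spacing Minimum clearance in um between points of two segments
#'   away from their connecting nodes (default 10: at 2 um/px the drawn
#'   strokes are 3 px wide, so centrelines closer than stroke width plus two
#'   pixels produce touching rasters).
#' @param node_exclusion Radius in um around a shared node within which close
#'   approaches are expected and allowed (default 25).
#' @param junction_spacing Distinct network nodes closer than this (but not
#'   coincident) are considered unresolvable (default 12 um).
#' @param min_segment_length Minimum segment length in um (default 30, above
#'   the default 20 um spur threshold).
#' @param endpoint_clearance Attachment/fusion nodes must clear every segment
#'   endpoint they do not coincide with by this many um (default 30): a free
#'   tip just past a junction leaves a terminal stub that spur pruning would
#'   remove, splicing the junction away.
#' @param ring_clearance Segments must stay at least this far from the ring
#'   boundary except near their own ring attachment (default 8 um).
#'
#' @details Branches must also depart at least 45 degrees from their parent's
#'   local tangent: a near-parallel branch cannot be told from the parent's
#'   own continuation in a rasterized trace.
#' @return TRUE/FALSE.
#' @export
is_well_separated <- function(net, min_spacing = 10, node_exclusion = 25,
                              junction_spacing = 12, min_segment_length = 30,
                              endpoint_clearance = 30, ring_clearance = 8) {
  segs <- net$segments
  if (!length(segs)) return(TRUE)
  if (any(segment_lengths(net) < min_segment_length)) return(FALSE)
  ids <- names(segs)
  # node points: ring attachments, branch attachments, fusion points
  node_pts <- do.call(rbind, lapply(segs, function(s) matrix(s$attach_point, ncol = 2)))
  node_ring <- vapply(segs, function(s) s$kind == "initial", logical(1))
  if (nrow(net$fusions)) {
    node_pts <- rbind(node_pts, as.matrix(net$fusions[, c("x", "y")]))
    node_ring <- c(node_ring, rep(FALSE, nrow(net$fusions)))
  }
  # junction resolvability: every attachment/fusion node must stand alone --
  # two events at or near one point make a four-way meet that a raster (or a
  # human tracer) resolves arbitrarily
  if (nrow(node_pts) > 1) {
    d <- as.matrix(stats::dist(node_pts))
    d <- d[upper.tri(d)]
    if (any(d < junction_spacing)) return(FALSE)
  }
  # nodes must not sit just short of a segment endpoint (an attachment almost
  # at a free tip is indistinguishable from a continuation in a raster)
  endpoints <- do.call(rbind, lapply(segs, function(s) {
    rbind(s$polyline[1, ], s$polyline[nrow(s$polyline), ])
  }))
  for (k in seq_len(nrow(node_pts))) {
    d <- sqrt((endpoints[, 1] - node_pts[k, 1])^2 +
              (endpoints[, 2] - node_pts[k, 2])^2)
    if (any(d > 2.5 & d < endpoint_clearance)) return(FALSE)
  }
  # an attachment at (or within a pixel of) the host vessel's own tip reads as
  # a plain continuation in a raster, not as a junction
  for (s in segs) {
    if (s$kind != "branch") next
    parent <- segs[[s$parent_id]]
    ptip <- parent$polyline[nrow(parent$polyline), ]
    if (sqrt(sum((s$attach_point - ptip)^2)) < endpoint_clearance) return(FALSE)
    # directional resolvability: a branch departing nearly parallel to its
    # parent cannot be told from the parent's own continuation when traced
    s_p <- locate_on_polyline(parent$polyline, s$attach_point)
    ppl <- parent$polyline
    cum <- c(0, cumsum(sqrt(rowSums(diff(ppl)^2))))
    i_p <- max(1, min(which(cum >= s_p), nrow(ppl)) - 1L)
    d_p <- ppl[min(i_p + 1L, nrow(ppl)), ] - ppl[i_p, ]
    d_b <- s$polyline[min(3L, nrow(s$polyline)), ] - s$polyline[1, ]
    cosang <- abs(sum(d_p * d_b)) /
      max(sqrt(sum(d_p^2)) * sqrt(sum(d_b^2)), 1e-9)
    if (cosang > cos(45 * pi / 180)) return(FALSE)
  }
  if (nrow(net$fusions)) {
    for (k in seq_len(nrow(net$fusions))) {
      target <- segs[[net$fusions$target_id[k]]]
      ttip <- target$polyline[nrow(target$polyline), ]
      fp <- c(net$fusions$x[k], net$fusions$y[k])
      if (sqrt(sum((fp - ttip)^2)) < endpoint_clearance) return(FALSE)
      # near-tangential anastomoses merge into one stroke when drawn
      fused <- segs[[net$fusions$segment_id[k]]]
      fpl <- fused$polyline
      d_in <- fpl[nrow(fpl), ] - fpl[max(1, nrow(fpl) - 2L), ]
      s_t <- locate_on_polyline(target$polyline, fp)
      tpl <- target$polyline
      cum <- c(0, cumsum(sqrt(rowSums(diff(tpl)^2))))
      i_t <- max(1, min(which(cum >= s_t), nrow(tpl)) - 1L)
      d_t <- tpl[min(i_t + 1L, nrow(tpl)), ] - tpl[i_t, ]
      cosang <- abs(sum(d_in * d_t)) /
        max(sqrt(sum(d_in^2)) * sqrt(sum(d_t^2)), 1e-9)
      if (cosang > cos(30 * pi / 180)) return(FALSE)
    }
  }
  dense <- lapply(segs, function(s) {
    pl <- s$polyline
    out <- list()
    for (i in seq_len(nrow(pl) - 1L)) {
      a <- pl[i, ]; b <- pl[i + 1L, ]
      n_s <- max(2L, ceiling(sqrt(sum((b - a)^2)) / 3))
      out[[i]] <- cbind(seq(a[1], b[1], length.out = n_s),
                        seq(a[2], b[2], length.out = n_s))
    }
    do.call(rbind, out)
  })
  # nodes touching each segment (within 1.5 um of its polyline)
  touches <- lapply(seq_along(segs), function(si) {
    pts <- dense[[si]]
    which(vapply(seq_len(nrow(node_pts)), function(k) {
      min((pts[, 1] - node_pts[k, 1])^2 + (pts[, 2] - node_pts[k, 2])^2) < 1.5^2
    }, logical(1)))
  })
  # self-approach: a vessel must not come back within min_spacing of itself
  for (si in seq_along(segs)) {
    pts <- dense[[si]]
    n_p <- nrow(pts)
    if (n_p < 20) next
    dx <- outer(pts[, 1], pts[, 1], "-")
    dy <- outer(pts[, 2], pts[, 2], "-")
    close <- dx * dx + dy * dy < min_spacing^2
    gap <- abs(outer(seq_len(n_p), seq_len(n_p), "-")) > 12  # ~> 36 um apart
    if (any(close & gap)) return(FALSE)
  }
  n_seg <- length(segs)
  for (si in seq_len(max(n_seg - 1L, 0L))) {
    for (ti in seq.int(si + 1L, n_seg)) {
      ps <- dense[[si]]; pt <- dense[[ti]]
      shared <- intersect(touches[[si]], touches[[ti]])
      dx <- outer(ps[, 1], pt[, 1], "-")
      dy <- outer(ps[, 2], pt[, 2], "-")
      close <- dx * dx + dy * dy < min_spacing^2
      if (!any(close)) next
      if (!length(shared)) return(FALSE)
      idx <- which(close, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        p <- ps[idx[r, 1], ]; q <- pt[idx[r, 2], ]
        ok <- FALSE
        for (k in shared) {
          c_pt <- node_pts[k, ]
          if (sum((p - c_pt)^2) < node_exclusion^2 &&
              sum((q - c_pt)^2) < node_exclusion^2) { ok <- TRUE; break }
        }
        if (!ok) return(FALSE)
      }
    }
  }
  # ring clearance away from own attachment
  ring_nodes <- node_pts[node_ring, , drop = FALSE]
  for (si in seq_len(n_seg)) {
    pts <- dense[[si]]
    dr <- vapply(seq_len(nrow(pts)), function(i) dist_to_ring(net$ring, pts[i, ]),
                 numeric(1))
    bad <- which(dr < ring_clearance)
    for (i in bad) {
      p <- pts[i, ]
      near_attach <- FALSE
      if (nrow(ring_nodes)) {
        near_attach <- any((ring_nodes[, 1] - p[1])^2 +
                           (ring_nodes[, 2] - p[2])^2 < node_exclusion^2)
      }
      if (!near_attach) return(FALSE)
    }
  }
  TRUE
}
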