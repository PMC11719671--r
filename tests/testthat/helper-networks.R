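# Fixture networks and independent brute-force oracles. The oracles share no
# code path with the package implementation: lengths are re-summed directly,
# boundary distances use dense sampling, junction clustering uses repeated
# scanning, and loop counting uses edge de-duplication plus flood-fill
# component counting (no igraph).

# The standard toy network: 3 initial vessels (200, 300, 500 um) and
# 2 branches (100, 150 um) on a ring of radius 500 um.
toy_network <- function() {
  ring <- ring_explant(radius = 500)
  segs <- list(
    vessel_segment("i1", rbind(c(500, 0), c(700, 0)), "initial"),
    vessel_segment("i2", rbind(c(0, 500), c(0, 800)), "initial"),
    vessel_segment("i3", rbind(c(-500, 0), c(-1000, 0)), "initial"),
    vessel_segment("b1", rbind(c(600, 0), c(600, 100)), "branch", parent_id = "i1"),
    vessel_segment("b2", rbind(c(0, 650), c(150, 650)), "branch", parent_id = "i2")
  )
  vessel_network(ring, segs)
}

# A single-loop network: one initial vessel carrying a triangle of three
# branches (b3's tip fuses onto b2).
triangle_loop_network <- function() {
  ring <- ring_explant(radius = 500)
  segs <- list(
    vessel_segment("i1", rbind(c(500, 0), c(800, 0)), "initial"),
    vessel_segment("b1", rbind(c(600, 0), c(650, 100)), "branch", parent_id = "i1"),
    vessel_segment("b2", rbind(c(700, 0), c(680, 100)), "branch", parent_id = "i1"),
    vessel_segment("b3", rbind(c(650, 100), c(680, 100)), "branch", parent_id = "b1")
  )
  vessel_network(ring, segs,
                 fusions = data.frame(segment_id = "b3", target_id = "b2",
                                      x = 680, y = 100))
}

# Random hierarchical network with <= max_segments segments. All "special"
# points (attachments, fusion targets, tips) are kept mutually > 15 um apart
# so node identity is unambiguous at the package's 5 um merge tolerance and
# every brute-force oracle clusters them identically.
random_toy_network <- function(seed, max_segments = 20, p_fusion = 0.3) {
  set.seed(seed)
  r <- runif(1, 300, 700)
  ring <- ring_explant(radius = r)
  n_init <- sample(1:4, 1)
  segs <- list()
  special <- NULL  # rows: all attach/fusion/tip points placed so far
  clear_of_special <- function(p, min_d = 15) {
    is.null(special) ||
      all((special[, 1] - p[1])^2 + (special[, 2] - p[2])^2 > min_d^2)
  }
  rand_polyline <- function(start, dir0, len_total) {
    n_pts <- sample(3:6, 1)
    step <- len_total / (n_pts - 1)
    pts <- matrix(NA_real_, n_pts, 2)
    pts[1, ] <- start
    dir <- dir0
    for (i in 2:n_pts) {
      dir <- dir + runif(1, -0.25, 0.25)
      pts[i, ] <- pts[i - 1, ] + step * c(cos(dir), sin(dir))
    }
    pts
  }
  for (k in seq_len(n_init)) {
    theta <- 2 * pi * (k - 0.5) / n_init
    start <- r * c(cos(theta), sin(theta))
    pl <- rand_polyline(start, theta, runif(1, 150, 600))
    id <- paste0("i", k)
    segs[[id]] <- vessel_segment(id, pl, "initial")
    special <- rbind(special, start, pl[nrow(pl), ])
  }
  n_branch <- sample(0:(max_segments - n_init), 1)
  bi <- 0; attempts <- 0
  while (bi < n_branch && attempts < 200) {
    attempts <- attempts + 1
    parent <- segs[[sample(length(segs), 1)]]
    pl <- parent$polyline
    ci <- sample(nrow(pl) - 1, 1)
    u <- runif(1, 0.2, 0.8)
    at <- pl[ci, ] + u * (pl[ci + 1, ] - pl[ci, ])
    if (!clear_of_special(at)) next
    dirs <- atan2(pl[ci + 1, 2] - pl[ci, 2], pl[ci + 1, 1] - pl[ci, 1])
    dir <- dirs + sample(c(-1, 1), 1) * runif(1, pi / 4, pi / 2)
    pl_b <- rand_polyline(at, dir, runif(1, 80, 300))
    if (!clear_of_special(pl_b[nrow(pl_b), ])) next
    bi <- bi + 1
    id <- paste0("b", bi)
    segs[[id]] <- vessel_segment(id, pl_b, "branch", parent_id = parent$id,
                                 attach_point = at)
    special <- rbind(special, at, pl_b[nrow(pl_b), ])
  }
  # occasional fusions: move a leaf branch tip onto a vertex of another segment
  fus <- NULL
  ids <- names(segs)
  parents <- vapply(segs, `[[`, character(1), "parent_id")
  for (id in ids) {
    if (runif(1) > p_fusion) next
    if (segs[[id]]$kind != "branch") next
    if (id %in% parents) next  # keep leaves only, attach geometry stays valid
    others <- setdiff(ids, c(id, segs[[id]]$parent_id))
    if (!length(others)) next
    target <- segs[[others[sample.int(length(others), 1)]]]
    tp <- target$polyline[sample(nrow(target$polyline), 1), ]
    old_tip <- segs[[id]]$polyline[nrow(segs[[id]]$polyline), ]
    # the retired tip leaves `special`; the fusion point must clear the rest
    keep <- !(special[, 1] == old_tip[1] & special[, 2] == old_tip[2])
    special_wo <- special[keep, , drop = FALSE]
    if (!all((special_wo[, 1] - tp[1])^2 + (special_wo[, 2] - tp[2])^2 > 15^2)) next
    pl <- segs[[id]]$polyline
    pl[nrow(pl), ] <- tp
    if (polyline_ok(pl)) {
      segs[[id]] <- vessel_segment(id, pl, "branch",
                                   parent_id = segs[[id]]$parent_id,
                                   attach_point = segs[[id]]$attach_point)
      special <- rbind(special_wo, tp)
      fus <- rbind(fus, data.frame(segment_id = id, target_id = target$id,
                                   x = tp[1], y = tp[2]))
    }
  }
  vessel_network(ring, unname(segs), fusions = fus)
}

polyline_ok <- function(pl) {
  sum(sqrt(rowSums(diff(pl)^2))) > 0
}

# --- independent oracles -----------------------------------------------------

oracle_polyline_length <- function(pl) {
  tot <- 0
  for (i in 2:nrow(pl)) {
    tot <- tot + sqrt((pl[i, 1] - pl[i - 1, 1])^2 + (pl[i, 2] - pl[i - 1, 2])^2)
  }
  tot
}

oracle_segment_lengths <- function(net) {
  vapply(net$segments, function(s) oracle_polyline_length(s$polyline), numeric(1))
}

oracle_kind_counts <- function(net) {
  kinds <- vapply(net$segments, `[[`, character(1), "kind")
  c(initial = sum(kinds == "initial"), branch = sum(kinds == "branch"))
}

# shortest tip-to-boundary distance by dense boundary sampling
oracle_max_radial <- function(net, n_samples = 4000) {
  ring <- net$ring
  if (!is.null(ring$boundary)) {
    poly <- rbind(ring$boundary, ring$boundary[1, , drop = FALSE])
    lens <- sqrt(rowSums(diff(poly)^2))
    pts <- NULL
    for (i in seq_len(nrow(poly) - 1)) {
      n_i <- max(2, ceiling(n_samples * lens[i] / sum(lens)))
      pts <- rbind(pts, cbind(seq(poly[i, 1], poly[i + 1, 1], length.out = n_i),
                              seq(poly[i, 2], poly[i + 1, 2], length.out = n_i)))
    }
  } else {
    th <- seq(0, 2 * pi, length.out = n_samples)
    pts <- cbind(ring$center[1] + ring$radius * cos(th),
                 ring$center[2] + ring$radius * sin(th))
  }
  best <- 0
  for (s in net$segments) {
    tip <- s$polyline[nrow(s$polyline), ]
    d <- min(sqrt((pts[, 1] - tip[1])^2 + (pts[, 2] - tip[2])^2))
    best <- max(best, d)
  }
  best
}

# junction nodes by repeated-scan clustering of branch attach + fusion points
oracle_junctions <- function(net, tol = 5) {
  pts <- NULL
  for (s in net$segments) {
    if (s$kind == "branch") pts <- rbind(pts, s$attach_point)
  }
  if (nrow(net$fusions)) {
    pts <- rbind(pts, as.matrix(net$fusions[, c("x", "y")]))
  }
  if (is.null(pts)) return(0L)
  cluster <- seq_len(nrow(pts))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(pts))) {
      for (j in seq_len(nrow(pts))) {
        if (cluster[i] != cluster[j] &&
            sqrt(sum((pts[i, ] - pts[j, ])^2)) <= tol) {
          cluster[cluster == cluster[j]] <- cluster[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(cluster))
}

# independent loop count: build the subdivided node graph with greedy point
# clustering and event ordering by dense-sampled arclength, de-duplicate
# parallel edges, drop self-loops, count m - n + c with flood fill
oracle_loops <- function(net, tol = 5) {
  segs <- net$segments
  if (!length(segs)) return(0L)
  events <- list()
  add_ev <- function(seg_id, p) {
    events[[length(events) + 1L]] <<- list(seg = seg_id, p = p)
  }
  for (s in segs) {
    add_ev(s$id, s$polyline[1, ])
    add_ev(s$id, s$polyline[nrow(s$polyline), ])
    for (t in segs) {
      if (t$kind == "branch" && t$parent_id == s$id) add_ev(s$id, t$attach_point)
    }
    if (nrow(net$fusions)) {
      for (k in seq_len(nrow(net$fusions))) {
        if (net$fusions$target_id[k] == s$id) {
          add_ev(s$id, c(net$fusions$x[k], net$fusions$y[k]))
        }
      }
    }
  }
  pts <- do.call(rbind, lapply(events, `[[`, "p"))
  node <- integer(nrow(pts))
  next_id <- 0L
  for (i in seq_len(nrow(pts))) {
    hit <- 0L
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= tol) { hit <- node[j]; break }
      }
    }
    if (hit == 0L) { next_id <- next_id + 1L; hit <- next_id }
    node[i] <- hit
  }
  # arclength of each event along its segment via dense sampling
  arc_of <- function(seg, p) {
    pl <- seg$polyline
    best <- Inf; best_s <- 0; s0 <- 0
    for (i in seq_len(nrow(pl) - 1)) {
      a <- pl[i, ]; b <- pl[i + 1, ]
      L <- sqrt(sum((b - a)^2))
      for (u in seq(0, 1, length.out = 50)) {
        q <- a + u * (b - a)
        d <- sum((q - p)^2)
        if (d < best) { best <- d; best_s <- s0 + u * L }
      }
      s0 <- s0 + L
    }
    best_s
  }
  edges <- NULL
  for (s in segs) {
    ii <- which(vapply(events, function(e) e$seg == s$id, logical(1)))
    arcs <- vapply(ii, function(i) arc_of(s, pts[i, ]), numeric(1))
    ord <- ii[order(arcs)]
    nds <- node[ord]
    nds <- nds[c(TRUE, nds[-1] != nds[-length(nds)])]
    if (length(nds) >= 2) {
      for (i in seq_len(length(nds) - 1)) {
        edges <- rbind(edges, c(nds[i], nds[i + 1]))
      }
    }
  }
  if (is.null(edges)) return(0L)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]  # drop self-loops
  if (!nrow(edges)) return(0L)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]
  verts <- unique(as.vector(edges))
  # flood-fill component count
  comp <- stats::setNames(rep(0L, length(verts)), verts)
  nc <- 0L
  for (v in verts) {
    if (comp[as.character(v)] > 0L) next
    nc <- nc + 1L
    frontier <- v
    comp[as.character(v)] <- nc
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- c(edges[edges[, 1] == f, 2], edges[edges[, 2] == f, 1])
        nb <- nb[comp[as.character(nb)] == 0L]
        comp[as.character(nb)] <- nc
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
  }
  nrow(edges) - length(verts) + nc
}

oracle_histogram <- function(lens, bin_width) {
  n_bins <- ceiling(max(lens) / bin_width + 1e-9)
  counts <- integer(n_bins)
  for (l in lens) {
    b <- ceiling(l / bin_width)
    b <- max(1L, min(b, n_bins))
    counts[b] <- counts[b] + 1L
  }
  counts / length(lens)
}

# rigid motion of a whole network
transform_network <- function(net, angle = 0, shift = c(0, 0)) {
  Rm <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  tr <- function(p) {
    if (is.matrix(p)) t(Rm %*% t(p)) + matrix(shift, nrow(p), 2, byrow = TRUE)
    else as.numeric(Rm %*% p + shift)
  }
  ring <- net$ring
  new_ring <- if (!is.null(ring$boundary)) {
    ring_explant(center = tr(ring$center), boundary = tr(ring$boundary))
  } else {
    ring_explant(center = tr(ring$center), radius = ring$radius)
  }
  segs <- lapply(net$segments, function(s) {
    vessel_segment(s$id, tr(s$polyline), s$kind, parent_id = s$parent_id,
                   attach_point = tr(s$attach_point), generation = s$generation)
  })
  fus <- net$fusions
  if (nrow(fus)) {
    xy <- tr(as.matrix(fus[, c("x", "y")]))
    fus$x <- xy[, 1]; fus$y <- xy[, 2]
  } else fus <- NULL
  vessel_network(new_ring, unname(segs), fusions = fus)
}

# small simulated measurement table with a built-in treatment effect, used by
# AAI tests (fast: few rings, low density)
small_sim_table <- function(seed = 7, mult = 1.5, rings = 4) {
  gp <- function(m = 1) growth_params(seed_density = 8, anastomosis_prob = 0.35,
                                      capture_radius = 25,
                                      treatment_multiplier = m)
  cfg <- simulation_config(
    days = c(1, 4, 7), rings_per_group = rings, donors = 2, seed = seed,
    donor_sd = 0.05,
    groups = list(control = gp(), treatment = gp(mult)))
  simulate_experiment(cfg)$table
}

# A loop whose junctions are all raster-visible (every cycle node has three
# incident vessel directions): b1 leaves i1 mid-segment, b2 leaves b1
# mid-segment and fuses back onto i1 mid-segment.
rendered_loop_network <- function() {
  ring <- ring_explant(radius = 500)
  i1 <- vessel_segment("i1", rbind(c(500, 0), c(900, 0)), "initial")
  b1 <- vessel_segment("b1", rbind(c(600, 0), c(640, 120), c(760, 180)),
                       "branch", parent_id = "i1")
  b2 <- vessel_segment("b2", rbind(c(640, 120), c(720, 60), c(780, 0)),
                       "branch", parent_id = "b1")
  vessel_network(ring, list(i1, b1, b2),
                 fusions = data.frame(segment_id = "b2", target_id = "i1",
                                      x = 780, y = 0))
}

# hand-built measurement table: one value per parameter/group/day, constructed
# so every parameter AAI is known in closed form
synthetic_table <- function(uplift) {
  reg <- parameter_registry()
  params <- scored_parameters()
  rows <- list()
  base <- stats::setNames(seq(10, 10 + 10 * (length(params) - 1), by = 10), params)
  for (g in c("control", "treated")) {
    for (day in c(4, 7)) {
      delta <- if (day == 4) 0 else base  # control gains `base` per parameter
      gain <- if (g == "treated" && day == 7) uplift * base else delta
      rows[[paste(g, day)]] <- data.frame(
        donor = "d1", group = g, ring_id = paste0(g, "_r1"), day = day,
        imaging_time_h = day * 24,
        parameter = params,
        category = parameter_category(params),
        value = unname(base + gain),
        units = rep("", length(params)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

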