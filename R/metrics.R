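# The twelve operational parameters of an explant outgrowth network, plus the
# ROI helpers used when only a circular sector of the well was evaluated.

#' Proportion of initial vessels among all vessels
#'
#' Pattern readout: 100 x (number of initial vessels) / (initial + branches).
#' 100% means only primary vessels (the day-1 situation); the value declines
#' as branching proceeds.
#'
#' @param net A [vessel_network()].
#' @return Percentage in \[0, 100\].
#' @export
vessel_structure_pct <- function(net) {
  kinds <- segment_kinds(net)
  if (!length(kinds)) {
    stop_angioring("undefined_parameter", "vessel structure is undefined for an empty network")
  }
  100 * sum(kinds == "initial") / length(kinds)
}

#' Number of loops (anastomotic circles)
#'
#' A loop is a closed circuit of three or more interconnected segments.
#' Formally: the cycle rank (independent cycles, m - n + c) of the network's
#' node graph after removing self-loop edges and collapsing parallel edges,
#' so that closures involving fewer than three segments are not counted.
#'
#' @param net A [vessel_network()].
#' @param merge_tol Node merge tolerance in um (attachment points closer than
#'   this are one node). Default 5.
#' @return Non-negative integer count.
#' @export
count_loops <- function(net, merge_tol = 5) {
  loops_from_graph(segment_node_graph(net, merge_tol))
}

# cycle rank of the simplified node graph (self-loops and parallel edges
# removed first so closures of < 3 segments never count)
loops_from_graph <- function(g) {
  if (!nrow(g$edges)) return(0L)
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = g$nodes$node)
  )
  ig <- igraph::simplify(ig, remove.multiple = TRUE, remove.loops = TRUE)
  m <- igraph::ecount(ig)
  n <- igraph::vcount(ig)
  comp <- igraph::components(ig)$no
  as.integer(m - n + comp)
}

#' Maximum radial outgrowth
#'
#' The greatest perpendicular (shortest) distance from any segment tip to the
#' ring's outer boundary. Tips of branches are included. This differs from the
#' maximum initial vessel length whenever vessels curve instead of growing
#' straight out.
#'
#' @param net A [vessel_network()].
#' @return Length in um.
#' @export
max_radial_outgrowth <- function(net) {
  tips <- segment_tips(net)
  if (!nrow(tips)) {
    stop_angioring("undefined_parameter", "radial outgrowth is undefined for an empty network")
  }
  max(apply(tips, 1, function(p) dist_to_ring(net$ring, p)))
}

#' Maximum initial vessel length
#'
#' The longest initial (primary) vessel, measured along its path from the
#' ring's outer edge; branches are not taken into account.
#'
#' @param net A [vessel_network()].
#' @return Length in um.
#' @export
max_initial_vessel_length <- function(net) {
  kinds <- segment_kinds(net)
  if (!any(kinds == "initial")) {
    stop_angioring("undefined_parameter", "no initial vessels present")
  }
  max(segment_lengths(net)[kinds == "initial"])
}

#' Total and mean vessel length
#'
#' Sum of the path lengths of all segments (initial vessels and branches) and
#' the mean over the number of segments.
#'
#' @param net A [vessel_network()].
#' @return Named list with `total` and `mean`, both in um.
#' @export
total_and_mean_vessel_length <- function(net) {
  lens <- segment_lengths(net)
  if (!length(lens)) {
    stop_angioring("undefined_parameter", "vessel length is undefined for an empty network")
  }
  list(total = sum(lens), mean = mean(lens))
}

#' Growth speed of initial vessel length between two observations
#'
#' Change in the mean and in the maximum initial vessel length of the same
#' ring between two imaging time points, divided by the exact elapsed time.
#' Negative values indicate regression.
#'
#' @param obs_early,obs_late [explant_observation()]s of the same ring,
#'   `obs_late` imaged strictly later.
#' @return Named list `mean_per_h`, `mean_per_day`, `max_per_h`, `max_per_day`
#'   (um/h and um/day); `NA` when either observation lacks initial vessels.
#' @export
growth_speeds <- function(obs_early, obs_late) {
  if (obs_early$ring_id != obs_late$ring_id ||
      obs_early$donor != obs_late$donor ||
      obs_early$group != obs_late$group) {
    stop_angioring("invalid_interval", "observations must be of the same ring")
  }
  dt_h <- obs_late$imaging_time_h - obs_early$imaging_time_h
  if (!is.finite(dt_h) || dt_h <= 0) {
    stop_angioring("invalid_interval", "late observation must be imaged after the early one")
  }
  initial_stats <- function(obs) {
    net <- obs$network
    if (is.null(net)) return(c(NA_real_, NA_real_))
    kinds <- segment_kinds(net)
    if (!any(kinds == "initial")) return(c(NA_real_, NA_real_))
    lens <- segment_lengths(net)[kinds == "initial"]
    c(mean(lens), max(lens))
  }
  e <- initial_stats(obs_early)
  l <- initial_stats(obs_late)
  mean_per_h <- (l[1] - e[1]) / dt_h
  max_per_h <- (l[2] - e[2]) / dt_h
  list(mean_per_h = mean_per_h, mean_per_day = mean_per_h * 24,
       max_per_h = max_per_h, max_per_day = max_per_h * 24)
}

#' Vessel count and vessel density
#'
#' Number of initial vessels (branches not counted) and the same count per
#' millimetre of ring circumference.
#'
#' @param net A [vessel_network()].
#' @return Named list with `count` and `density` (count per mm).
#' @export
vessel_count_and_density <- function(net) {
  circ_mm <- circumference(net$ring) / 1000
  if (circ_mm <= 0) {
    stop_angioring("invalid_geometry", "ring circumference must be positive")
  }
  count <- sum(segment_kinds(net) == "initial")
  list(count = as.integer(count), density = count / circ_mm)
}

#' Branch number, mean branch length and branch-length distribution
#'
#' @param net A [vessel_network()].
#' @param bin_width Histogram bin width in um (default 50).
#' @return Named list with `n_branches`, `mean_branch_length` (um, `NA` when
#'   there are no branches) and `histogram`, a data frame of `bin_lo`,
#'   `bin_hi`, `rel_freq` whose relative frequencies sum to 1 when branches
#'   exist.
#' @export
branch_statistics <- function(net, bin_width = 50) {
  stopifnot(bin_width > 0)
  kinds <- segment_kinds(net)
  lens <- segment_lengths(net)[kinds == "branch"]
  if (!length(lens)) {
    return(list(n_branches = 0L, mean_branch_length = NA_real_,
                histogram = data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                                       rel_freq = numeric(0))))
  }
  breaks <- seq(0, bin_width * ceiling(max(lens) / bin_width + 1e-9), by = bin_width)
  if (length(breaks) < 2) breaks <- c(0, bin_width)
  counts <- tabulate(findInterval(lens, breaks, left.open = TRUE, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  list(
    n_branches = length(lens),
    mean_branch_length = mean(lens),
    histogram = data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                           rel_freq = counts / length(lens))
  )
}

#' Junction count and junctions per initial vessel
#'
#' A junction is a distinct node at which at least one branch originates from
#' an initial vessel or from another branch (anastomosis points where a tip
#' fused onto a segment also attach a branch and are counted). Attachment
#' points closer than `merge_tol` um are one junction.
#'
#' @param net A [vessel_network()].
#' @param merge_tol Node merge tolerance in um. Default 5.
#' @return Named list with `n_junctions` and `junctions_per_vessel`
#'   (junctions / number of initial vessels; `NA` when the network is empty).
#' @export
junction_counts <- function(net, merge_tol = 5) {
  pts <- NULL
  for (s in net$segments) {
    if (s$kind == "branch") pts <- rbind(pts, s$attach_point)
  }
  if (nrow(net$fusions)) {
    pts <- rbind(pts, as.matrix(net$fusions[, c("x", "y")]))
  }
  n_j <- if (is.null(pts)) 0L else length(unique(cluster_points(pts, merge_tol)))
  n_initial <- sum(segment_kinds(net) == "initial")
  if (n_initial == 0 && n_j > 0) {
    stop_angioring("inconsistent_network", "junctions present without initial vessels")
  }
  list(n_junctions = as.integer(n_j),
       junctions_per_vessel = if (n_initial > 0) n_j / n_initial else NA_real_)
}

#' Extrapolate endpoint counts from a circular-sector ROI to the whole ring
#'
#' When only a circular sector centred on the ring was evaluated, counted
#' endpoints are scaled by 360 / sector angle.
#'
#' @param counted Endpoints counted inside the sector.
#' @param sector_angle Sector angle in degrees, in (0, 360\].
#' @return Extrapolated count per ring.
#' @export
#' @examples
#' roi_extrapolate_endpoints(50, 90)  # 200
roi_extrapolate_endpoints <- function(counted, sector_angle) {
  if (!is.numeric(sector_angle) || any(sector_angle <= 0) || any(sector_angle > 360)) {
    stop_angioring("invalid_angle", "sector angle must be in (0, 360] degrees")
  }
  counted * 360 / sector_angle
}

#' Vessel area from maximum outgrowth radius and sector angle
#'
#' Area covered by the outgrowth, from the maximum outgrowth radius and the
#' evaluated sector angle. `"sector"` mode treats the outgrowth as a circular
#' sector of radius `r_max` ((theta/2) r_max^2); `"annulus_sector"` measures
#' the sector of the annulus between the ring radius and ring radius + r_max.
#'
#' @param r_max Maximum outgrowth radius in um.
#' @param sector_angle Sector angle in degrees, in (0, 360\].
#' @param mode `"sector"` (default) or `"annulus_sector"`.
#' @param r_ring Ring radius in um; required in annulus mode.
#' @return Area in mm^2.
#' @export
#' @examples
#' vessel_area(1000, 360)  # pi mm^2
vessel_area <- function(r_max, sector_angle, mode = c("sector", "annulus_sector"),
                        r_ring = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(r_max) || r_max <= 0) {
    stop_angioring("invalid_geometry", "r_max must be positive")
  }
  if (!is.numeric(sector_angle) || sector_angle <= 0 || sector_angle > 360) {
    stop_angioring("invalid_angle", "sector angle must be in (0, 360] degrees")
  }
  theta <- sector_angle * pi / 180
  area_um2 <- switch(mode,
    sector = theta / 2 * r_max^2,
    annulus_sector = {
      if (is.null(r_ring)) {
        stop_angioring("invalid_geometry", "annulus_sector mode requires r_ring")
      }
      theta / 2 * ((r_ring + r_max)^2 - r_ring^2)
    }
  )
  area_um2 / 1e6
}

#' Quantify one explant observation
#'
#' Computes all per-observation registry parameters for a single ring at a
#' single time point. Non-migrated explants yield zero counts and missing
#' (`NA`, not zero) length metrics, so that absent outgrowth is not conflated
#' with short vessels. Growth speeds need two time points; see
#' [quantify_observations()].
#'
#' @param obs An [explant_observation()].
#' @param merge_tol Junction/loop node merge tolerance in um.
#' @return Tidy data frame with columns `donor`, `group`, `ring_id`, `day`,
#'   `imaging_time_h`, `parameter`, `category`, `value`, `units`.
#' @export
quantify <- function(obs, merge_tol = 5) {
  stopifnot(inherits(obs, "explant_observation"))
  net <- obs$network
  vals <- c(
    migration = if (obs$migrated) 100 else 0,
    ring_circumference = if (!is.null(net)) circumference(net$ring) else NA_real_
  )
  if (!is.null(net) && n_segments(net) > 0) {
    tl <- total_and_mean_vessel_length(net)
    vc <- vessel_count_and_density(net)
    bs <- branch_statistics(net)
    jc <- junction_counts(net, merge_tol)
    kinds <- segment_kinds(net)
    vals <- c(vals,
      vessel_structure_pct = vessel_structure_pct(net),
      n_loops = as.numeric(count_loops(net, merge_tol)),
      max_radial_outgrowth = max_radial_outgrowth(net),
      max_initial_vessel_length = if (any(kinds == "initial")) max_initial_vessel_length(net) else NA_real_,
      total_vessel_length = tl$total,
      mean_vessel_length = tl$mean,
      vessel_count = as.numeric(vc$count),
      vessel_density = vc$density,
      n_branches = as.numeric(bs$n_branches),
      mean_branch_length = bs$mean_branch_length,
      n_junctions = as.numeric(jc$n_junctions),
      junctions_per_vessel = jc$junctions_per_vessel
    )
  } else {
    vals <- c(vals,
      vessel_structure_pct = NA_real_,
      n_loops = 0,
      max_radial_outgrowth = NA_real_,
      max_initial_vessel_length = NA_real_,
      total_vessel_length = NA_real_,
      mean_vessel_length = NA_real_,
      vessel_count = 0,
      vessel_density = if (!is.null(net)) 0 else NA_real_,
      n_branches = 0,
      mean_branch_length = NA_real_,
      n_junctions = 0,
      junctions_per_vessel = NA_real_
    )
  }
  params <- names(vals)
  data.frame(
    donor = obs$donor, group = obs$group, ring_id = obs$ring_id,
    day = obs$day, imaging_time_h = obs$imaging_time_h,
    parameter = params,
    category = parameter_category(params),
    value = as.numeric(vals),
    units = parameter_units(params),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Quantify a set of observations, including growth speeds
#'
#' Applies [quantify()] to every observation and adds the growth-speed
#' parameters for each consecutive pair of imaging days of the same ring
#' (the speed is assigned to the later day).
#'
#' @param observations List of [explant_observation()]s.
#' @param merge_tol Node merge tolerance in um.
#' @return Tidy measurement data frame (one row per parameter, ring and day).
#' @export
quantify_observations <- function(observations, merge_tol = 5) {
  stopifnot(length(observations) > 0)
  rows <- lapply(observations, quantify, merge_tol = merge_tol)
  key <- vapply(observations, function(o) paste(o$donor, o$group, o$ring_id, sep = "\r"),
                character(1))
  speed_rows <- list()
  for (k in unique(key)) {
    obs_ring <- observations[key == k]
    ord <- order(vapply(obs_ring, `[[`, numeric(1), "imaging_time_h"))
    obs_ring <- obs_ring[ord]
    if (length(obs_ring) < 2) next
    for (i in seq_len(length(obs_ring) - 1L)) {
      early <- obs_ring[[i]]; late <- obs_ring[[i + 1L]]
      sp <- growth_speeds(early, late)
      params <- c("speed_mean_initial_length", "speed_max_initial_length",
                  "speed_mean_initial_length_per_h", "speed_max_initial_length_per_h")
      speed_rows[[length(speed_rows) + 1L]] <- data.frame(
        donor = late$donor, group = late$group, ring_id = late$ring_id,
        day = late$day, imaging_time_h = late$imaging_time_h,
        parameter = params,
        category = parameter_category(params),
        value = c(sp$mean_per_day, sp$max_per_day, sp$mean_per_h, sp$max_per_h),
        units = parameter_units(params),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, c(rows, speed_rows))
  rownames(out) <- NULL
  out
}
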