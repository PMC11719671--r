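# Stochastic simulator of explant outgrowth: initial vessels are recruited on
# the ring as a Poisson process, tips elongate with directional jitter,
# branches spawn along newly grown length after a short onset lag, and tips
# that come close to another vessel may fuse (anastomosis), closing loops.
# Treatments act as multipliers on elongation and branching. The generator is
# phenomenological: it reproduces the observable time course of the assay
# (100% primary vessels at day 1, declining primary fraction, rising density,
# loop formation by day 7), not endothelial mechanism.

#' Growth parameters
#'
#' @param seed_density Expected initial vessels per mm of ring circumference
#'   recruited over the first `recruitment_days` days (Poisson).
#' @param elongation Tip elongation speed in um/day.
#' @param direction_jitter Std dev of the per-day random change of a tip's
#'   growth direction, in degrees.
#' @param branching_rate Expected branch events per mm of newly grown vessel
#'   (applies after `branching_onset_day`).
#' @param branching_onset_day Day before which no branches form. The assay
#'   shows exclusively primary vessels on day 1; ramification follows the
#'   initial sprouting phase. Default 1.5.
#' @param anastomosis_prob Probability per growth step that an eligible tip
#'   within `capture_radius` of another vessel fuses to it (loop formation).
#' @param capture_radius Fusion capture radius in um.
#' @param treatment_multiplier Positive multiplier applied to `elongation` and
#'   `branching_rate`; 1 reproduces control kinetics.
#' @param branch_angle Range (degrees) of the absolute angle between a new
#'   branch and its parent's direction; drawn uniformly with random sign.
#' @param recruitment_days Days over which initial vessels are recruited
#'   (default 7, the assay horizon).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(seed_density = 12, elongation = 100,
                          direction_jitter = 20, branching_rate = 1.5,
                          branching_onset_day = 1.5,
                          anastomosis_prob = 0.15, capture_radius = 15,
                          treatment_multiplier = 1,
                          branch_angle = c(30, 90),
                          recruitment_days = 7) {
  stopifnot(seed_density >= 0, elongation >= 0, direction_jitter >= 0,
            branching_rate >= 0, branching_onset_day >= 0,
            anastomosis_prob >= 0, anastomosis_prob <= 1, capture_radius >= 0,
            treatment_multiplier > 0, length(branch_angle) == 2,
            all(branch_angle >= 0), branch_angle[2] >= branch_angle[1],
            recruitment_days > 0)
  structure(as.list(environment()), class = "growth_params")
}

#' Simulation configuration
#'
#' @param days Observation days (default `c(1, 4, 7)`).
#' @param rings_per_group Rings per donor and group.
#' @param donors Number of donors.
#' @param ring_radius Ring radius in um (default 540, a ~3.4 mm circumference
#'   explant).
#' @param seed Integer seed of the simulation's single global random stream;
#'   rings draw from counter-based substreams so that changing the ring count
#'   leaves other rings untouched.
#' @param groups Named list of [growth_params()], one per group; must contain
#'   `control_group`.
#' @param control_group Name of the control group (default `"control"`).
#' @param donor_sd Std dev (log scale) of a lognormal per-donor effect on
#'   elongation and branching, shared by all of a donor's rings (default 0.1).
#' @param step_days Integration step in days (default 0.25).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(days = c(1, 4, 7), rings_per_group = 5,
                              donors = 3, ring_radius = 540, seed = 1,
                              groups = list(control = growth_params(),
                                            treatment = growth_params(treatment_multiplier = 1.5)),
                              control_group = "control",
                              donor_sd = 0.1, step_days = 0.25) {
  stopifnot(all(days > 0), rings_per_group >= 1, donors >= 1, ring_radius > 0,
            step_days > 0, donor_sd >= 0,
            control_group %in% names(groups),
            all(vapply(groups, inherits, logical(1), "growth_params")))
  days <- sort(unique(as.integer(days)))
  structure(list(days = days, rings_per_group = rings_per_group,
                 donors = donors, ring_radius = ring_radius,
                 seed = as.integer(seed), groups = groups,
                 control_group = control_group, donor_sd = donor_sd,
                 step_days = step_days),
            class = "simulation_config")
}

# Deterministic 32-bit substream seed for (seed, donor, group, ring).
ring_substream_seed <- function(seed, donor_idx, group_idx, ring_idx) {
  h <- (as.double(seed) * 2654435.0 + donor_idx * 97911.0 +
        group_idx * 7919.0 + ring_idx * 131.0)
  as.integer(h %% 2147483647)
}

donor_substream_seed <- function(seed, donor_idx) {
  as.integer((as.double(seed) * 48271.0 + donor_idx * 69621.0) %% 2147483647)
}

#' Simulate one ring over a series of observation days
#'
#' Runs the continuous growth process once and snapshots the network at every
#' requested day, so later networks contain the earlier ones as sub-geometry
#' (monotone growth).
#'
#' @param params A [growth_params()].
#' @param days Observation days (increasing).
#' @param ring_radius Ring radius in um.
#' @param seed Integer seed for this ring's substream.
#' @param step_days Integration step in days.
#' @param donor_factor Multiplier on elongation and branching shared by all of
#'   a donor's rings (default 1).
#' @return Named list of [vessel_network()]s, one per day (names `"day<d>"`).
#' @export
simulate_ring_series <- function(params, days = c(1, 4, 7), ring_radius = 540,
                                 seed = 1, step_days = 0.25, donor_factor = 1) {
  stopifnot(inherits(params, "growth_params"))
  days <- sort(unique(days))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  ring <- ring_explant(center = c(0, 0), radius = ring_radius)
  circ_mm <- ring$circumference / 1000
  mult <- params$treatment_multiplier * donor_factor
  elong <- params$elongation * mult
  branch_rate <- params$branching_rate * mult
  recruit_rate <- params$seed_density * circ_mm / params$recruitment_days  # per day
  # segment state (parallel vectors/lists)
  seg_kind <- character(0); seg_parent <- character(0)
  seg_attach <- list(); seg_dir <- numeric(0); seg_active <- logical(0)
  seg_pts <- list(); seg_gen <- integer(0); seg_born <- numeric(0)
  fus <- data.frame(segment_id = character(0), target_id = character(0),
                    x = numeric(0), y = numeric(0))
  new_id <- function() sprintf("v%04d", length(seg_kind) + 1L)
  add_segment <- function(kind, parent, attach, dir, t, first_step_len) {
    id <- new_id()
    p2 <- attach + first_step_len * c(cos(dir), sin(dir))
    seg_kind[[length(seg_kind) + 1L]] <<- kind
    seg_parent[[length(seg_parent) + 1L]] <<- parent
    seg_attach[[length(seg_attach) + 1L]] <<- attach
    seg_dir[[length(seg_dir) + 1L]] <<- dir
    seg_active[[length(seg_active) + 1L]] <<- TRUE
    seg_pts[[length(seg_pts) + 1L]] <<- rbind(attach, p2)
    seg_gen[[length(seg_gen) + 1L]] <<-
      if (kind == "initial") 0L else NA_integer_
    seg_born[[length(seg_born) + 1L]] <<- t
    id
  }
  snapshots <- list()
  t <- 0
  t_end <- max(days)
  jitter_sd <- params$direction_jitter * pi / 180
  while (t < t_end - 1e-9) {
    dt <- min(step_days, t_end - t)
    step_len <- elong * dt
    # --- recruit new initial vessels
    if (t < params$recruitment_days) {
      n_new <- stats::rpois(1, recruit_rate * dt)
      if (n_new > 0) {
        for (k in seq_len(n_new)) {
          theta <- stats::runif(1, 0, 2 * pi)
          attach <- ring_radius * c(cos(theta), sin(theta))
          dir <- theta + stats::rnorm(1, 0, jitter_sd)
          if (step_len > 0) add_segment("initial", NA_character_, attach, dir, t, step_len)
        }
      }
    }
    # --- elongate active tips
    active <- which(seg_active)
    grown <- numeric(0)
    if (length(active) && step_len > 0) {
      jit <- stats::rnorm(length(active), 0, jitter_sd * sqrt(dt))
      for (i in seq_along(active)) {
        s <- active[i]
        seg_dir[s] <- seg_dir[s] + jit[i]
        pts <- seg_pts[[s]]
        tip <- pts[nrow(pts), ] + step_len * c(cos(seg_dir[s]), sin(seg_dir[s]))
        seg_pts[[s]] <- rbind(pts, tip)
      }
      grown <- rep(step_len, length(active))
    }
    t <- t + dt
    # --- branching along newly grown length
    if (t > params$branching_onset_day && branch_rate > 0 && length(active)) {
      ids <- sprintf("v%04d", active)
      n_b <- stats::rpois(length(active), branch_rate * grown / 1000)
      for (i in which(n_b > 0)) {
        s <- active[i]
        pts <- seg_pts[[s]]
        a <- pts[nrow(pts) - 1L, ]; b <- pts[nrow(pts), ]
        for (k in seq_len(n_b[i])) {
          u <- stats::runif(1)
          at <- a + u * (b - a)
          ang <- stats::runif(1, params$branch_angle[1], params$branch_angle[2]) *
            pi / 180 * sample(c(-1, 1), 1)
          dir <- seg_dir[s] + ang
          if (step_len > 0) {
            add_segment("branch", ids[i], at, dir, t, step_len)
            seg_gen[[length(seg_gen)]] <- seg_gen[[s]] + 1L
          }
        }
      }
    }
    # --- anastomosis: eligible tips within capture radius of another vessel
    if (params$anastomosis_prob > 0 && params$capture_radius > 0) {
      active <- which(seg_active)
      if (length(active) >= 1 && length(seg_pts) >= 2) {
        all_pts <- do.call(rbind, seg_pts)
        owner <- rep(seq_along(seg_pts), vapply(seg_pts, nrow, integer(1)))
        for (s in active) {
          pts <- seg_pts[[s]]
          own_len <- polyline_length(pts)
          if (own_len <= 2 * params$capture_radius) next
          tip <- pts[nrow(pts), ]
          # a tip may not fuse onto itself, its parent, or its own children
          # (a child's base is always next to the spawning tip)
          excl <- owner == s
          if (!is.na(seg_parent[s])) {
            excl <- excl | owner == as.integer(sub("^v", "", seg_parent[s]))
          }
          kids <- which(seg_parent == sprintf("v%04d", s))
          if (length(kids)) excl <- excl | owner %in% kids
          cand <- which(!excl)
          if (!length(cand)) next
          d2 <- (all_pts[cand, 1] - tip[1])^2 + (all_pts[cand, 2] - tip[2])^2
          j <- which.min(d2)
          if (sqrt(d2[j]) <= params$capture_radius &&
              stats::runif(1) < params$anastomosis_prob) {
            target <- owner[cand[j]]
            tp <- all_pts[cand[j], ]
            # the final growth step turns into the fusion point (no overshoot)
            n_p <- nrow(pts)
            if (n_p >= 2 && sqrt(sum((pts[n_p - 1L, ] - tp)^2)) > 0.5) {
              pts[n_p, ] <- tp
              seg_pts[[s]] <- pts
            } else {
              seg_pts[[s]] <- rbind(pts, tp)
            }
            seg_active[s] <- FALSE
            fus <- rbind(fus, data.frame(
              segment_id = sprintf("v%04d", s),
              target_id = sprintf("v%04d", target),
              x = tp[1], y = tp[2]))
          }
        }
      }
    }
    # --- snapshot
    hit <- days[abs(days - t) < 1e-9]
    if (length(hit)) {
      snapshots[[paste0("day", hit)]] <- materialize_network(
        ring, seg_kind, seg_parent, seg_attach, seg_pts, seg_gen, fus)
    }
  }
  snapshots
}

materialize_network <- function(ring, seg_kind, seg_parent, seg_attach,
                                seg_pts, seg_gen, fus) {
  if (!length(seg_kind)) return(vessel_network(ring, list()))
  segs <- lapply(seq_along(seg_kind), function(s) {
    vessel_segment(sprintf("v%04d", s), seg_pts[[s]], kind = seg_kind[s],
                   parent_id = seg_parent[s], attach_point = seg_attach[[s]],
                   generation = seg_gen[s])
  })
  vessel_network(ring, segs, fusions = if (nrow(fus)) fus else NULL)
}

#' Simulate one ring at a single day
#'
#' Convenience wrapper around [simulate_ring_series()].
#'
#' @inheritParams simulate_ring_series
#' @param day Observation day.
#' @return A [vessel_network()].
#' @export
simulate_ring <- function(params, day = 7, ring_radius = 540, seed = 1,
                          step_days = 0.25, donor_factor = 1) {
  simulate_ring_series(params, days = day, ring_radius = ring_radius,
                       seed = seed, step_days = step_days,
                       donor_factor = donor_factor)[[paste0("day", day)]]
}

#' Simulate a full multi-group explant experiment
#'
#' Control and treatment rings for every donor and observation day, with the
#' exact ground-truth measurement table attached (computed from the true
#' simulated geometry via [quantify_observations()]).
#'
#' @param config A [simulation_config()].
#' @return List with `observations` (list of [explant_observation()]s) and
#'   `table` (tidy ground-truth measurement data frame).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  observations <- list()
  group_names <- names(config$groups)
  for (d in seq_len(config$donors)) {
    donor_factor <- if (config$donor_sd > 0) {
      old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(donor_substream_seed(config$seed, d))
      f <- exp(stats::rnorm(1, 0, config$donor_sd))
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      f
    } else 1
    for (gi in seq_along(group_names)) {
      g <- group_names[gi]
      for (r in seq_len(config$rings_per_group)) {
        nets <- simulate_ring_series(
          config$groups[[g]], days = config$days,
          ring_radius = config$ring_radius,
          seed = ring_substream_seed(config$seed, d, gi, r),
          step_days = config$step_days, donor_factor = donor_factor)
        for (day in config$days) {
          observations[[length(observations) + 1L]] <- explant_observation(
            donor = paste0("donor", d), group = g,
            ring_id = sprintf("%s_d%d_r%02d", g, d, r),
            day = day, imaging_time_h = day * 24,
            network = nets[[paste0("day", day)]])
        }
      }
    }
  }
  list(observations = observations, table = quantify_observations(observations))
}

#' Render a network to a binary mask pair
#'
#' Rasterizes the ring (filled disk) and all vessel polylines at the given
#' pixel size, producing input for [extract_network()] round trips.
#'
#' @param net A [vessel_network()] with a circular ring.
#' @param pixel_size Pixel edge in um (default 2).
#' @param vessel_width_px Drawn vessel width in pixels (default 3).
#' @param margin_um Blank margin around the drawing (default 60).
#' @return A [mask_pair()].
#' @export
render_mask <- function(net, pixel_size = 2, vessel_width_px = 3, margin_um = 60) {
  stopifnot(inherits(net, "vessel_network"), pixel_size > 0,
            !is.null(net$ring$radius))
  ring <- net$ring
  pts <- if (n_segments(net)) do.call(rbind, lapply(net$segments, `[[`, "polyline"))
         else matrix(numeric(0), ncol = 2)
  ext <- ring$radius + margin_um
  if (nrow(pts)) {
    ext <- max(ext, max(abs(cbind(pts[, 1] - ring$center[1],
                                  pts[, 2] - ring$center[2])))) + margin_um
  }
  x0 <- ring$center[1] - ext
  y0 <- ring$center[2] - ext
  n_px <- ceiling(2 * ext / pixel_size)
  # pixel (row i, col j) centre: x = x0 + (j - .5) px, y = y0 + (i - .5) px
  xs <- x0 + (seq_len(n_px) - 0.5) * pixel_size
  ys <- y0 + (seq_len(n_px) - 0.5) * pixel_size
  ring_mask <- outer(ys, xs, function(y, x) {
    (x - ring$center[1])^2 + (y - ring$center[2])^2 <= ring$radius^2
  })
  vessel <- matrix(FALSE, n_px, n_px)
  if (n_segments(net)) {
    half_w <- vessel_width_px * pixel_size / 2
    rad_px <- ceiling(half_w / pixel_size - 1e-9)
    disk <- as.matrix(expand.grid(di = -rad_px:rad_px, dj = -rad_px:rad_px))
    disk <- disk[disk[, 1]^2 + disk[, 2]^2 <= (half_w / pixel_size)^2 + 0.26, , drop = FALSE]
    for (seg in net$segments) {
      pl <- seg$polyline
      # densify to sub-pixel spacing
      dense <- list()
      for (i in seq_len(nrow(pl) - 1L)) {
        a <- pl[i, ]; b <- pl[i + 1L, ]
        n_s <- max(2L, ceiling(sqrt(sum((b - a)^2)) / (0.4 * pixel_size)))
        dense[[i]] <- cbind(seq(a[1], b[1], length.out = n_s),
                            seq(a[2], b[2], length.out = n_s))
      }
      dp <- do.call(rbind, dense)
      cj <- pmin(pmax(ceiling((dp[, 1] - x0) / pixel_size), 1L), n_px)
      ci <- pmin(pmax(ceiling((dp[, 2] - y0) / pixel_size), 1L), n_px)
      for (k in seq_len(nrow(disk))) {
        ii <- pmin(pmax(ci + disk[k, 1], 1L), n_px)
        jj <- pmin(pmax(cj + disk[k, 2], 1L), n_px)
        vessel[cbind(ii, jj)] <- TRUE
      }
    }
  }
  mask_pair(vessel, ring_mask, pixel_size, check_ring = TRUE)
}
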