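# Angiogenic Activity Index (AAI): control-normalized relative change of each
# parameter between two treatment days, aggregated into four weighted
# subindices and a final index, plus the radar-style angiogenic profile.

#' AAI configuration
#'
#' @param parameters Character vector of scored registry parameters. Defaults
#'   to the twelve-parameter set of [scored_parameters()].
#' @param weights Named numeric vector of predictive-importance factors
#'   (positive; default 1 for every parameter). Parameters judged especially
#'   informative for vascular architecture may be given factor 2.
#' @param orientation Named vector of +1/-1 per parameter (default +1). A -1
#'   makes a decrease of the raw parameter score as pro-angiogenic.
#' @param day_early,day_late Treatment days entering the index (defaults 4, 7).
#' @param control_group Label of the untreated/vehicle group (default
#'   `"control"`).
#' @param subindex_mode `"literal"` (default): subindex = (1/n) sum w_i AAI_i,
#'   so weighted values may exceed the unit range; `"normalized"`:
#'   sum(w AAI)/sum(w), for sensitivity analysis.
#' @param aggregation `"per_donor"` (default): the index is computed per donor
#'   from that donor's group means and then averaged across donors;
#'   `"pooled"`: group means over all rings first.
#' @param degenerate_policy What to do when the control change is exactly zero
#'   while the treatment change is not: `"error"` (default) or `"epsilon"`
#'   (replace the zero control change by `epsilon`, keeping its sign
#'   convention). When both changes are exactly zero the parameter AAI is 0
#'   (continuous limit of the control-equals-treatment anchor).
#' @param epsilon Fallback control change under the `"epsilon"` policy.
#' @return An object of class `aai_config`.
#' @export
aai_config <- function(parameters = scored_parameters(),
                       weights = NULL, orientation = NULL,
                       day_early = 4L, day_late = 7L,
                       control_group = "control",
                       subindex_mode = c("literal", "normalized"),
                       aggregation = c("per_donor", "pooled"),
                       degenerate_policy = c("error", "epsilon"),
                       epsilon = 1e-8) {
  subindex_mode <- match.arg(subindex_mode)
  aggregation <- match.arg(aggregation)
  degenerate_policy <- match.arg(degenerate_policy)
  stopifnot(day_late > day_early, epsilon > 0)
  categories <- parameter_category(parameters)  # validates names
  w <- stats::setNames(rep(1, length(parameters)), parameters)
  if (!is.null(weights)) {
    stopifnot(!is.null(names(weights)), all(names(weights) %in% parameters),
              all(weights > 0))
    w[names(weights)] <- weights
  }
  o <- stats::setNames(rep(1, length(parameters)), parameters)
  if (!is.null(orientation)) {
    stopifnot(!is.null(names(orientation)), all(names(orientation) %in% parameters),
              all(orientation %in% c(-1, 1)))
    o[names(orientation)] <- orientation
  }
  structure(
    list(parameters = parameters,
         categories = stats::setNames(categories, parameters),
         weights = w, orientation = o,
         day_early = as.integer(day_early), day_late = as.integer(day_late),
         control_group = control_group,
         subindex_mode = subindex_mode, aggregation = aggregation,
         degenerate_policy = degenerate_policy, epsilon = epsilon),
    class = "aai_config"
  )
}

#' Per-parameter AAI
#'
#' The control-normalized relative change of one parameter between the early
#' and late treatment day:
#' \deqn{AAI = \frac{(T_{late} - T_{early}) - (C_{late} - C_{early})}
#'                  {C_{late} - C_{early}}}
#' multiplied by the parameter's orientation. 0 means the treatment changed
#' like the control, +1 a doubling of the control change, -1 no change at all.
#'
#' @param t_early,t_late Treatment-group parameter values at the two days.
#' @param c_early,c_late Control-group values at the two days.
#' @param orientation +1 or -1.
#' @param degenerate_policy,epsilon See [aai_config()].
#' @param parameter Parameter name used in error messages.
#' @return Dimensionless AAI value.
#' @export
#' @examples
#' parameter_aai(10, 20, 10, 15)  # treatment change doubles control change: 1
parameter_aai <- function(t_early, t_late, c_early, c_late, orientation = 1,
                          degenerate_policy = c("error", "epsilon"),
                          epsilon = 1e-8, parameter = NULL) {
  degenerate_policy <- match.arg(degenerate_policy)
  dt <- t_late - t_early
  dc <- c_late - c_early
  if (anyNA(c(dt, dc))) return(NA_real_)
  if (dc == 0) {
    if (dt == 0) return(0)
    if (degenerate_policy == "error") {
      stop_angioring("degenerate_control",
                     paste0("control change is zero for parameter ",
                            if (is.null(parameter)) "<unnamed>" else parameter))
    }
    dc <- epsilon
  }
  orientation * (dt - dc) / dc
}

#' Subindex from weighted per-parameter AAIs
#'
#' @param aai_values Numeric vector of per-parameter AAI values.
#' @param weights Matching vector of predictive-importance factors.
#' @param mode `"literal"` (default): (1/n) sum w_i AAI_i; `"normalized"`:
#'   sum(w AAI)/sum(w).
#' @return Subindex value. `NA` entries are dropped (with their weights).
#' @export
subindex_aai <- function(aai_values, weights = rep(1, length(aai_values)),
                         mode = c("literal", "normalized")) {
  mode <- match.arg(mode)
  stopifnot(length(aai_values) == length(weights))
  keep <- !is.na(aai_values)
  aai_values <- aai_values[keep]
  weights <- weights[keep]
  if (!length(aai_values)) {
    stop_angioring("undefined_subindex", "no parameters available for subindex")
  }
  switch(mode,
    literal = sum(weights * aai_values) / length(aai_values),
    normalized = sum(weights * aai_values) / sum(weights)
  )
}

#' Final AAI from subindex values
#'
#' Arithmetic mean of the available subindex values; missing categories are
#' excluded with a warning.
#'
#' @param subindices Named numeric vector, one value per subindex category.
#' @return Final AAI.
#' @export
final_aai <- function(subindices) {
  present <- !is.na(subindices)
  if (!any(present)) {
    stop_angioring("undefined_subindex", "no subindex values available")
  }
  if (!all(present)) {
    warning("excluding missing subindices: ",
            paste(names(subindices)[!present], collapse = ", "))
  }
  mean(subindices[present])
}

# Group-mean value of each scored parameter at one day. Means are over rings
# (and donors, if several are included); NA measurements (e.g. undefined
# lengths of non-migrated rings) are dropped, counts having been recorded as
# zero where genuinely zero.
group_day_means <- function(table, group, day, parameters) {
  sub <- table[table$group == group & table$day == day &
                 table$parameter %in% parameters, , drop = FALSE]
  out <- stats::setNames(rep(NA_real_, length(parameters)), parameters)
  if (nrow(sub)) {
    agg <- tapply(sub$value, sub$parameter, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
    out[names(agg)] <- as.numeric(agg)
  }
  out
}

# AAI vector for one treatment group from one slice of the table (one donor,
# or the pooled table).
aai_vector_from_slice <- function(table, group, config) {
  te <- group_day_means(table, group, config$day_early, config$parameters)
  tl <- group_day_means(table, group, config$day_late, config$parameters)
  ce <- group_day_means(table, config$control_group, config$day_early, config$parameters)
  cl <- group_day_means(table, config$control_group, config$day_late, config$parameters)
  vapply(config$parameters, function(p) {
    parameter_aai(te[p], tl[p], ce[p], cl[p],
                  orientation = config$orientation[p],
                  degenerate_policy = config$degenerate_policy,
                  epsilon = config$epsilon, parameter = p)
  }, numeric(1))
}

#' Compute the AAI report for one treatment group
#'
#' Computes per-parameter AAI values (control-normalized day-early to day-late
#' changes), the four weighted subindices and the final AAI. Under
#' `aggregation = "per_donor"` the index is computed separately from each
#' donor's group means and then averaged across donors; `"pooled"` uses group
#' means over all rings at once.
#'
#' @param table Tidy measurement table as produced by
#'   [quantify_observations()] (columns `donor`, `group`, `ring_id`, `day`,
#'   `parameter`, `value`, ...).
#' @param group Treatment-group label to score.
#' @param config An [aai_config()].
#' @return An object of class `aai_report`: per-parameter AAIs, subindex
#'   values, final AAI, and the aggregation mode used.
#' @export
compute_aai_report <- function(table, group, config = aai_config()) {
  stopifnot(inherits(config, "aai_config"))
  needed_days <- c(config$day_early, config$day_late)
  for (g in c(group, config$control_group)) {
    have <- unique(table$day[table$group == g])
    if (g == config$control_group && !any(table$group == g)) {
      stop_angioring("missing_control",
                     paste0("control group '", g, "' absent from table"))
    }
    if (!all(needed_days %in% have)) {
      stop_angioring("missing_days",
                     paste0("group '", g, "' lacks day(s) ",
                            paste(setdiff(needed_days, have), collapse = ", ")))
    }
  }
  if (config$aggregation == "per_donor") {
    donors <- intersect(unique(table$donor[table$group == group]),
                        unique(table$donor[table$group == config$control_group]))
    if (!length(donors)) {
      stop_angioring("missing_control", "no donor has both treatment and control rings")
    }
    per_donor <- vapply(donors, function(d) {
      aai_vector_from_slice(table[table$donor == d, , drop = FALSE], group, config)
    }, numeric(length(config$parameters)))
    per_donor <- matrix(per_donor, nrow = length(config$parameters),
                        dimnames = list(config$parameters, donors))
    aai <- apply(per_donor, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
  } else {
    aai <- aai_vector_from_slice(table, group, config)
  }
  cats <- config$categories
  subs <- stats::setNames(rep(NA_real_, length(subindex_categories())),
                          subindex_categories())
  for (cat in subindex_categories()) {
    in_cat <- names(aai)[cats[names(aai)] == cat]
    if (length(in_cat) && any(!is.na(aai[in_cat]))) {
      subs[cat] <- subindex_aai(aai[in_cat], config$weights[in_cat],
                                mode = config$subindex_mode)
    }
  }
  structure(
    list(group = group,
         per_parameter_aai = aai,
         categories = cats[names(aai)],
         weights = config$weights[names(aai)],
         subindex_values = subs,
         final_aai = final_aai(subs),
         aggregation = config$aggregation,
         subindex_mode = config$subindex_mode,
         day_early = config$day_early, day_late = config$day_late,
         control_group = config$control_group),
    class = "aai_report"
  )
}

#' Compute AAI reports for every treatment group in a table
#'
#' @inheritParams compute_aai_report
#' @return Named list of [compute_aai_report()] results, one per non-control
#'   group.
#' @export
compute_aai_reports <- function(table, config = aai_config()) {
  groups <- setdiff(unique(table$group), config$control_group)
  stats::setNames(lapply(groups, compute_aai_report, table = table, config = config),
                  groups)
}

#' @export
print.aai_report <- function(x, ...) {
  cat(sprintf("<aai_report> group '%s' vs control '%s' (days %d -> %d, %s)\n",
              x$group, x$control_group, x$day_early, x$day_late, x$aggregation))
  df <- data.frame(parameter = names(x$per_parameter_aai),
                   category = unname(x$categories),
                   aai = signif(unname(x$per_parameter_aai), 3))
  print(df, row.names = FALSE)
  cat("subindices:\n")
  print(signif(x$subindex_values, 3))
  cat(sprintf("final AAI: %.3g\n", x$final_aai))
  invisible(x)
}

#' Angiogenic profile layout
#'
#' Radar-chart layout of a report's per-parameter AAI values: parameters are
#' ordered by subindex category (explant, pattern, network properties,
#' sprouting) and placed at equal angles around the circle, with the category
#' of each spoke annotated.
#'
#' @param report An [aai_report].
#' @return An object of class `angiogenic_profile`: a data frame with columns
#'   `parameter`, `category`, `aai`, `angle_deg`, plus the group label and
#'   final AAI as attributes. Serializable with [write_profile_json()].
#' @export
build_profile <- function(report) {
  stopifnot(inherits(report, "aai_report"))
  ord <- order(match(report$categories, subindex_categories()))
  params <- names(report$per_parameter_aai)[ord]
  n <- length(params)
  df <- data.frame(
    parameter = params,
    category = unname(report$categories[params]),
    aai = unname(report$per_parameter_aai[params]),
    angle_deg = (seq_len(n) - 1) * 360 / n,
    stringsAsFactors = FALSE
  )
  structure(df, class = c("angiogenic_profile", "data.frame"),
            group = report$group, final_aai = report$final_aai,
            subindex_values = report$subindex_values)
}

#' Plot an angiogenic profile as a radar chart
#'
#' @param profile An [build_profile()] result.
#' @return A ggplot object (polar coordinates; spokes coloured by subindex
#'   category, the zero circle marking control-level activity).
#' @export
plot_profile <- function(profile) {
  stopifnot(inherits(profile, "angiogenic_profile"))
  df <- as.data.frame(profile)
  df$parameter <- factor(df$parameter, levels = df$parameter)
  lims <- range(c(0, df$aai), na.rm = TRUE)
  pad <- 0.1 * max(diff(lims), 1e-6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$aai,
                                   fill = .data$category)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_polar(start = -pi / length(df$parameter)) +
    ggplot2::ylim(lims[1] - pad, lims[2] + pad) +
    ggplot2::labs(
      title = sprintf("Angiogenic profile: %s", attr(profile, "group")),
      subtitle = sprintf("final AAI = %.3g", attr(profile, "final_aai")),
      x = NULL, y = "AAI", fill = "subindex"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}
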