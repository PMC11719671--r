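# File formats: network JSON (documented schema), tidy measurement CSV,
# AAI config and report files, PNG masks, run manifests.

#' Write a vessel network to JSON
#'
#' Schema: `ring` (center, radius or boundary, circumference; um),
#' `segments` (id, kind, parent_id, attach_point, generation, polyline as an
#' n x 2 array of um coordinates) and `fusions` (segment_id, target_id, x, y).
#'
#' @param net A [vessel_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "vessel_network"))
  obj <- list(
    ring = list(center = net$ring$center,
                radius = net$ring$radius,
                boundary = net$ring$boundary,
                circumference = net$ring$circumference),
    segments = unname(lapply(net$segments, function(s) {
      list(id = s$id, kind = s$kind,
           parent_id = if (is.na(s$parent_id)) NULL else s$parent_id,
           attach_point = s$attach_point,
           generation = if (is.na(s$generation)) NULL else s$generation,
           polyline = unname(s$polyline))
    })),
    fusions = if (nrow(net$fusions)) net$fusions else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a vessel network from JSON
#'
#' @param path Path to a file written by [write_network_json()].
#' @return A [vessel_network()].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$ring)) {
    stop_angioring("invalid_schema", "network JSON lacks a 'ring' field")
  }
  ring <- ring_explant(center = as.numeric(obj$ring$center),
                       radius = obj$ring$radius,
                       boundary = if (!is.null(obj$ring$boundary)) as.matrix(obj$ring$boundary))
  segs <- list()
  seg_list <- obj$segments
  if (is.data.frame(seg_list)) {
    seg_list <- lapply(seq_len(nrow(seg_list)), function(i) as.list(seg_list[i, ]))
  }
  for (s in seg_list) {
    pl <- s$polyline
    if (is.list(pl) && !is.matrix(pl)) pl <- do.call(rbind, pl)
    segs[[length(segs) + 1L]] <- vessel_segment(
      id = s$id, polyline = as.matrix(pl), kind = s$kind,
      parent_id = if (is.null(s$parent_id) || is.na(s$parent_id)) NA_character_ else s$parent_id,
      attach_point = as.numeric(unlist(s$attach_point)),
      generation = if (is.null(s$generation)) NULL else as.integer(s$generation))
  }
  fus <- obj$fusions
  if (!is.null(fus) && !is.data.frame(fus)) fus <- as.data.frame(fus)
  vessel_network(ring, segs, fusions = fus)
}

#' Write / read a tidy measurement table
#'
#' Columns: `donor`, `group`, `ring_id`, `day`, `imaging_time_h`, `parameter`,
#' `category`, `value`, `units`. Writing then reading is byte-stable.
#'
#' @param table Measurement data frame (see [quantify_observations()]).
#' @param path CSV file path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_measurements_csv <- function(table, path) {
  cols <- c("donor", "group", "ring_id", "day", "imaging_time_h",
            "parameter", "category", "value", "units")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("donor", "group", "ring_id", "day", "imaging_time_h",
            "parameter", "category", "value", "units")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_angioring("invalid_schema",
                   paste("measurement CSV lacks column(s):", paste(missing, collapse = ", ")))
  }
  df$donor <- as.character(df$donor)
  df$group <- as.character(df$group)
  df$ring_id <- as.character(df$ring_id)
  df
}

#' Read an AAI configuration file (YAML or JSON)
#'
#' Recognized fields mirror the [aai_config()] arguments: `parameters`,
#' `weights` (mapping parameter -> factor; the slot for predictive-importance
#' factor 2 parameters), `orientation`, `day_early`, `day_late`,
#' `control_group`, `subindex_mode`, `aggregation`, `degenerate_policy`,
#' `epsilon`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [aai_config()].
#' @export
read_aai_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_angioring("invalid_schema", "config must be a .yaml/.yml or .json file")
  }
  args <- list()
  if (!is.null(obj$parameters)) args$parameters <- unlist(obj$parameters)
  for (f in c("day_early", "day_late", "control_group", "subindex_mode",
              "aggregation", "degenerate_policy", "epsilon")) {
    if (!is.null(obj[[f]])) args[[f]] <- obj[[f]]
  }
  if (!is.null(obj$weights)) args$weights <- unlist(obj$weights)
  if (!is.null(obj$orientation)) args$orientation <- unlist(obj$orientation)
  do.call(aai_config, args)
}

#' Read a simulator configuration file (YAML or JSON)
#'
#' Top level mirrors [simulation_config()]; each entry of `groups` mirrors
#' [growth_params()]. Validation errors name the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [simulation_config()].
#' @export
read_simulation_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_angioring("invalid_schema", "config must be a .yaml/.yml or .json file")
  }
  args <- obj
  if (!is.null(obj$groups)) {
    args$groups <- lapply(obj$groups, function(gp) {
      gp <- as.list(gp)
      tryCatch(do.call(growth_params, gp), error = function(e) {
        stop_angioring("invalid_schema",
                       paste0("invalid growth params in config: ", conditionMessage(e)))
      })
    })
  }
  if (!is.null(args$days)) args$days <- unlist(args$days)
  tryCatch(do.call(simulation_config, args), error = function(e) {
    if (inherits(e, "angioring_invalid_schema")) stop(e)
    stop_angioring("invalid_schema",
                   paste0("invalid simulation config: ", conditionMessage(e)))
  })
}

#' Write AAI reports to JSON and flat CSV
#'
#' JSON keeps full precision; the CSV flattens per-parameter AAIs, subindices
#' and final values to one row per quantity, rounded to 3 significant figures
#' as in standard report output.
#'
#' @param reports A single `aai_report` or a named list of them.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return Invisible list of the paths written.
#' @export
write_aai_report <- function(reports, json_path = NULL, csv_path = NULL) {
  if (inherits(reports, "aai_report")) {
    reports <- stats::setNames(list(reports), reports$group)
  }
  stopifnot(all(vapply(reports, inherits, logical(1), "aai_report")))
  if (!is.null(json_path)) {
    obj <- lapply(reports, function(r) {
      list(group = r$group,
           per_parameter_aai = as.list(r$per_parameter_aai),
           subindex_values = as.list(r$subindex_values),
           final_aai = r$final_aai,
           aggregation = r$aggregation, subindex_mode = r$subindex_mode,
           day_early = r$day_early, day_late = r$day_late,
           control_group = r$control_group)
    })
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(reports, function(r) {
      rbind(
        data.frame(group = r$group, level = "parameter",
                   name = names(r$per_parameter_aai),
                   category = unname(r$categories),
                   aai = signif(unname(r$per_parameter_aai), 3)),
        data.frame(group = r$group, level = "subindex",
                   name = names(r$subindex_values),
                   category = names(r$subindex_values),
                   aai = signif(unname(r$subindex_values), 3)),
        data.frame(group = r$group, level = "final", name = "final_aai",
                   category = NA_character_, aai = signif(r$final_aai, 3))
      )
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(list(json = json_path, csv = csv_path))
}

#' Serialize an angiogenic profile to JSON
#'
#' @param profile A [build_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "angiogenic_profile"))
  obj <- list(group = attr(profile, "group"),
              final_aai = attr(profile, "final_aai"),
              subindex_values = as.list(attr(profile, "subindex_values")),
              spokes = as.data.frame(profile))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read binary masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNGs (foreground = white). The pixel
#' size is not stored in the PNG and must be supplied on read.
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `path` invisibly (write); logical matrix (read).
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Read a mask pair from two PNG files
#'
#' @param vessel_path,ring_path Grayscale PNG paths.
#' @param pixel_size_um Pixel size in um.
#' @return A [mask_pair()].
#' @export
read_mask_pair <- function(vessel_path, ring_path, pixel_size_um) {
  mask_pair(read_mask_png(vessel_path), read_mask_png(ring_path), pixel_size_um)
}

# FNV-1a hash of a serialized R object; used for config fingerprints in run
# manifests (no cryptographic intent).
fnv1a_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest
#'
#' Every CLI run records its command, configuration fingerprint, input paths,
#' RNG seed, tool version and timestamp, so that reruns with identical inputs
#' are auditable and (for deterministic commands) reproduce outputs.
#'
#' @param command Subcommand name.
#' @param inputs Character vector of input paths.
#' @param seed RNG seed used (or `NA`).
#' @param config Configuration object included by fingerprint.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, inputs, seed, config, path) {
  manifest <- list(
    command = command,
    config_hash = fnv1a_hash(config),
    inputs = as.character(inputs),
    rng_seed = if (is.null(seed)) NA else seed,
    tool_version = as.character(utils::packageVersion("angioring")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(manifest)
}
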