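# CSV/JSON I/O. Scenes travel as three kinds of CSV (supply, demand, one
# long-format OD table per mode; an absent OD row means unreachable);
# results are written with deterministic row/column order at full
# precision plus 3-decimal presentation columns, alongside a plain-text
# run manifest.

#' Read a scene from CSV files
#'
#' @param supply_csv Path to the supply table (`id,capacity[,x,y]`).
#' @param demand_csv Path to the demand table
#'   (`id,pop_<mode>...[,x,y]`).
#' @param od_csvs Named character vector/list of per-mode OD paths
#'   (`origin_id,dest_id,minutes`, long format), names matching the
#'   `pop_<mode>` columns.
#' @return A validated [scene()]. Schema violations raise errors naming
#'   the offending file (and row, for id mismatches).
#' @export
read_scene <- function(supply_csv, demand_csv, od_csvs) {
  read1 <- function(path, cols) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    df
  }
  supply <- read1(supply_csv, c("id", "capacity"))
  demand <- read1(demand_csv, "id")
  od <- lapply(od_csvs, read1, cols = c("origin_id", "dest_id", "minutes"))
  names(od) <- names(od_csvs)
  tryCatch(scene(supply, demand, od),
           error = function(e) stop("invalid scene [supply: ", supply_csv,
                                    "]: ", conditionMessage(e), call. = FALSE))
}

#' Write a scene to CSV files
#'
#' Emits `supply.csv`, `demand.csv` and one `od_<mode>.csv` per mode
#' into `dir`; [read_scene()] on these paths reconstructs an identical
#' scene.
#'
#' @param sc An [scene()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
write_scene <- function(sc, dir) {
  stopifnot(inherits(sc, "mm_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(supply = file.path(dir, "supply.csv"),
             demand = file.path(dir, "demand.csv"))
  utils::write.csv(sc$supply, paths["supply"], row.names = FALSE)
  utils::write.csv(sc$demand, paths["demand"], row.names = FALSE)
  for (m in sc$modes) {
    p <- file.path(dir, paste0("od_", m, ".csv"))
    utils::write.csv(sc$od[[m]], p, row.names = FALSE)
    paths[paste0("od_", m)] <- p
  }
  invisible(paths)
}

manifest_lines <- function(config = NULL, seed = NULL) {
  c(paste0("package: mmspar ", as.character(utils::packageVersion("mmspar"))),
    paste0("r_version: ", R.version.string),
    if (!is.null(seed)) paste0("seed: ", seed),
    if (!is.null(config)) paste0("config: ", jsonlite::toJSON(
      config, auto_unbox = TRUE, digits = NA)))
}

write_manifest <- function(outdir, config = NULL, seed = NULL) {
  writeLines(manifest_lines(config, seed), file.path(outdir, "manifest.txt"))
}

# full-precision columns plus *_3dp presentation twins for score columns
with_presentation <- function(df, cols) {
  for (cc in cols) df[[paste0(cc, "_3dp")]] <- round_half_away(df[[cc]], 3)
  df
}

#' Write result files
#'
#' `mm_access` results produce `scores.csv` (per-unit SPAI/SPAR, sorted
#' by id, full precision plus `_3dp` presentation columns) and
#' `site_ratios.csv`; `mm_sensitivity` results produce the long
#' `scores.csv` keyed by grid cell, `stats.csv`
#' (cell x family min/max/mean/sd/cv), and `anova.csv` (the hypothesis
#' battery). Both write a `manifest.txt` recording package version,
#' seed, and config.
#'
#' @param result An `mm_access` or `mm_sensitivity` object.
#' @param outdir Output directory, created if needed.
#' @param config,seed Optional run metadata recorded in the manifest.
#' @return Invisibly, the vector of written paths.
#' @export
write_results <- function(result, outdir, config = NULL, seed = NULL) {
  UseMethod("write_results")
}

#' @export
write_results.mm_access <- function(result, outdir, config = NULL, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- result$scores[order(result$scores$id), , drop = FALSE]
  num <- setdiff(names(sc), "id")
  utils::write.csv(with_presentation(sc, num),
                   file.path(outdir, "scores.csv"), row.names = FALSE)
  sr <- result$site_ratios[order(result$site_ratios$id), , drop = FALSE]
  utils::write.csv(with_presentation(sr, "ratio"),
                   file.path(outdir, "site_ratios.csv"), row.names = FALSE)
  write_manifest(outdir, config, seed)
  invisible(file.path(outdir, c("scores.csv", "site_ratios.csv", "manifest.txt")))
}

#' @export
write_results.mm_sensitivity <- function(result, outdir, config = NULL,
                                         seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- result$scores
  sc <- sc[order(sc$cell, sc$id), , drop = FALSE]
  num <- grep("^(spai|spar)_", names(sc), value = TRUE)
  utils::write.csv(with_presentation(sc, num),
                   file.path(outdir, "scores.csv"), row.names = FALSE)
  st <- result$stats[order(result$stats$cell, result$stats$family), ,
                     drop = FALSE]
  utils::write.csv(st, file.path(outdir, "stats.csv"), row.names = FALSE)
  utils::write.csv(hypothesis_battery(result),
                   file.path(outdir, "anova.csv"), row.names = FALSE)
  write_manifest(outdir, config, seed)
  invisible(file.path(outdir, c("scores.csv", "stats.csv", "anova.csv",
                                "manifest.txt")))
}

#' Export demand units with scores as GeoJSON
#'
#' Writes a GeoJSON FeatureCollection of demand-unit points carrying
#' their scores as properties. Coordinates are the scene's planar
#' kilometers in an unspecified local frame, not longitude/latitude;
#' the collection carries a `coordinate_note` property saying so unless
#' the caller supplies a CRS note of their own.
#'
#' @param sc An [scene()] whose demand table has `x`, `y` columns.
#' @param result An `mm_access` computed on that scene.
#' @param path Output file.
#' @param crs_note Free-text note stored on the collection.
#' @return Invisibly, `path`.
#' @export
write_geojson <- function(sc, result, path,
                          crs_note = "planar km, local non-geographic frame") {
  stopifnot(inherits(sc, "mm_scene"), inherits(result, "mm_access"))
  if (!all(c("x", "y") %in% names(sc$demand)))
    stop("demand table has no coordinates", call. = FALSE)
  sc_scores <- result$scores[match(sc$demand$id, result$scores$id), ,
                             drop = FALSE]
  feats <- lapply(seq_len(nrow(sc$demand)), function(i) {
    props <- as.list(sc_scores[i, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sc$demand$x[i], sc$demand$y[i])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", coordinate_note = crs_note,
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration (JSON)
#'
#' The config carries per-mode definitions (name, breakpoints, optional
#' representative times, `beta` or a `beta_grid` with `min`/`max`/`n`)
#' and an optional `weighting` field (`"stepped"`, the default, or
#' `"continuous"`).
#'
#' @param path Path to a JSON file.
#' @return List with `modes` (list of [mode_spec()]s), `grids` (named
#'   list of coefficient vectors, one per mode), and `weighting`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$modes)) stop(path, ": config needs a `modes` list",
                               call. = FALSE)
  modes <- list(); grids <- list()
  for (m in cfg$modes) {
    if (is.null(m$name) || is.null(m$breakpoints))
      stop(path, ": each mode needs `name` and `breakpoints`", call. = FALSE)
    sch <- subzone_scheme(unlist(m$breakpoints),
                          if (!is.null(m$representative_times))
                            unlist(m$representative_times) else NULL)
    if (!is.null(m$beta_grid)) {
      g <- as.list(m$beta_grid)
      grids[[m$name]] <- build_grid(g$min, g$max, g$n)
      beta <- grids[[m$name]][1]
    } else if (!is.null(m$beta)) {
      beta <- m$beta
      grids[[m$name]] <- as.numeric(m$beta)
    } else stop(path, ": mode '", m$name, "' needs `beta` or `beta_grid`",
                call. = FALSE)
    modes[[m$name]] <- mode_spec(m$name, sch, beta)
  }
  list(modes = modes, grids = grids,
       weighting = if (!is.null(cfg$weighting)) cfg$weighting else "stepped")
}
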