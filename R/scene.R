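# Scene container: supply sites, mode-split demand units, and per-mode
# origin-destination travel-time matrices in long (sparse) form. Absent
# OD rows mean the pair is unreachable in that mode.

#' Assemble and validate a scene
#'
#' @param supply data.frame with columns `id`, `capacity` and optionally
#'   `x`, `y` (planar km). Capacities are non-negative provider counts.
#' @param demand data.frame with columns `id`, one `pop_<mode>` column
#'   per transport mode (non-negative counts), and optionally `x`, `y`.
#' @param od Named list (one element per mode, names matching the
#'   `pop_<mode>` columns) of data.frames with columns `origin_id`
#'   (demand unit), `dest_id` (supply site), `minutes`. A pair absent
#'   from the table is unreachable in that mode. The same entry serves
#'   both steps of the access computation.
#'
#' @return An object of class `mm_scene`.
#' @export
scene <- function(supply, demand, od) {
  stopifnot(is.data.frame(supply), is.data.frame(demand), is.list(od))
  need <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      stop(what, " must have columns: ", paste(cols, collapse = ", "),
           call. = FALSE)
  need(supply, c("id", "capacity"), "`supply`")
  need(demand, "id", "`demand`")

  supply$id <- as.character(supply$id)
  demand$id <- as.character(demand$id)
  if (anyDuplicated(supply$id))
    stop("duplicate supply ids: ",
         paste(unique(supply$id[duplicated(supply$id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(demand$id))
    stop("duplicate demand ids: ",
         paste(unique(demand$id[duplicated(demand$id)]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(supply$capacity)) || any(supply$capacity < 0))
    stop("supply capacities must be non-negative", call. = FALSE)

  pop_cols <- grep("^pop_", names(demand), value = TRUE)
  if (length(pop_cols) == 0)
    stop("`demand` needs at least one pop_<mode> column", call. = FALSE)
  for (pc in pop_cols)
    if (any(is.na(demand[[pc]])) || any(demand[[pc]] < 0))
      stop("negative or missing population in column ", pc, call. = FALSE)

  modes <- sub("^pop_", "", pop_cols)
  if (is.null(names(od)) || !setequal(names(od), modes))
    stop("`od` must be a named list over modes: ",
         paste(modes, collapse = ", "), call. = FALSE)

  for (m in names(od)) {
    o <- od[[m]]
    need(o, c("origin_id", "dest_id", "minutes"), paste0("od[['", m, "']]"))
    o$origin_id <- as.character(o$origin_id)
    o$dest_id <- as.character(o$dest_id)
    bad <- which(!o$origin_id %in% demand$id)
    if (length(bad))
      stop("od[['", m, "']] row ", bad[1], ": unknown demand id '",
           o$origin_id[bad[1]], "'", call. = FALSE)
    bad <- which(!o$dest_id %in% supply$id)
    if (length(bad))
      stop("od[['", m, "']] row ", bad[1], ": unknown supply id '",
           o$dest_id[bad[1]], "'", call. = FALSE)
    if (any(is.na(o$minutes)) || any(o$minutes < 0))
      stop("od[['", m, "']]: travel times must be non-negative minutes",
           call. = FALSE)
    if (anyDuplicated(paste(o$origin_id, o$dest_id)))
      stop("od[['", m, "']]: duplicate origin/destination pair", call. = FALSE)
    od[[m]] <- o[, c("origin_id", "dest_id", "minutes")]
  }

  structure(list(supply = supply, demand = demand, od = od, modes = modes),
            class = "mm_scene")
}

#' @export
print.mm_scene <- function(x, ...) {
  cat("<mm_scene> ", nrow(x$supply), " supply sites, ",
      nrow(x$demand), " demand units\n", sep = "")
  for (m in x$modes)
    cat("  mode '", m, "': ", nrow(x$od[[m]]), " OD pairs, population ",
        sum(x$demand[[paste0("pop_", m)]]), "\n", sep = "")
  invisible(x)
}

# match mode_spec list against a scene; returns the specs named by mode
check_modes <- function(sc, modes) {
  stopifnot(inherits(sc, "mm_scene"))
  if (inherits(modes, "mode_spec")) modes <- list(modes)
  nm <- vapply(modes, function(m) {
    stopifnot(inherits(m, "mode_spec")); m$name
  }, character(1))
  names(modes) <- nm
  missing <- setdiff(sc$modes, nm)
  if (length(missing))
    stop("no mode_spec supplied for scene mode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(nm, sc$modes)
  if (length(unknown))
    stop("mode_spec(s) not present in scene: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  modes[sc$modes]
}
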