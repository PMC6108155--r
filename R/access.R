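# Multi-modal E2SFCA access computation.
#
# Step 1: each supply site's capacity is divided by its decay-weighted
# reachable population summed over all transport modes (supply-to-demand
# ratio R_i). Step 2: each demand unit sums the ratios of sites it can
# reach per mode (mode-specific SPAI A_{j,M}) and across modes
# (integrated SPAI A_j). Step 3: SPAI are normalized by their study-area
# mean to spatial access ratios (SPAR), which have mean 1 by construction.

# decay weight of each OD row under a mode; NA = beyond catchment.
# "stepped" evaluates the kernel at the sub-zone representative time
# (the reference implementation); "continuous" at the exact travel time.
mode_od_weights <- function(minutes, mode, weighting = c("stepped", "continuous")) {
  weighting <- match.arg(weighting)
  if (weighting == "stepped") {
    subzone_weight(minutes, mode$scheme, mode$beta)
  } else {
    w <- gaussian_weight(minutes, mode$beta)
    w[minutes > mode$threshold] <- NA_real_
    w
  }
}

#' Step 1: supply-to-demand ratio per site
#'
#' For each supply site, the denominator sums the decay-weighted
#' populations of every demand unit inside the site's catchment in every
#' mode; the ratio is the site's capacity over that weighted demand. A
#' site reached by no population in any mode has ratio 0 (it serves
#' nobody and contributes nothing downstream).
#'
#' @param sc An [scene()].
#' @param modes List of [mode_spec()]s covering the scene's modes.
#' @param weighting `"stepped"` (sub-zone representative-time weights,
#'   the default) or `"continuous"` (kernel at the exact travel time).
#' @return Named numeric vector of ratios `R_i`, one per supply id.
#' @export
supply_ratio_multimodal <- function(sc, modes, weighting = "stepped") {
  modes <- check_modes(sc, modes)
  denom <- stats::setNames(numeric(nrow(sc$supply)), sc$supply$id)
  for (m in names(modes)) {
    o <- sc$od[[m]]
    if (nrow(o) == 0) next
    w <- mode_od_weights(o$minutes, modes[[m]], weighting)
    keep <- !is.na(w)
    if (!any(keep)) next
    pop <- sc$demand[[paste0("pop_", m)]][match(o$origin_id[keep], sc$demand$id)]
    part <- rowsum(pop * w[keep], o$dest_id[keep])
    denom[rownames(part)] <- denom[rownames(part)] + part[, 1]
  }
  r <- ifelse(denom > 0, sc$supply$capacity / denom, 0)
  stats::setNames(r, sc$supply$id)
}

#' Step 2: mode-specific and integrated SPAI
#'
#' Each demand unit sums, per mode, the supply-to-demand ratios of all
#' sites inside its catchment, weighted by the same decay weights used
#' in step 1; the integrated score is the sum over modes. Units that can
#' reach no site in a mode score 0 in that mode.
#'
#' @param site_ratios Named ratio vector from
#'   [supply_ratio_multimodal()], computed on the same scene and modes.
#' @inheritParams supply_ratio_multimodal
#' @return data.frame with `id`, one `spai_<mode>` column per mode, and
#'   `spai_integrated` (the exact row sum of the mode columns).
#' @export
spai_multimodal <- function(site_ratios, sc, modes, weighting = "stepped") {
  modes <- check_modes(sc, modes)
  if (!setequal(names(site_ratios), sc$supply$id))
    stop("`site_ratios` does not match the scene's supply sites", call. = FALSE)
  out <- data.frame(id = sc$demand$id, stringsAsFactors = FALSE)
  for (m in names(modes)) {
    a <- stats::setNames(numeric(nrow(sc$demand)), sc$demand$id)
    o <- sc$od[[m]]
    if (nrow(o) > 0) {
      w <- mode_od_weights(o$minutes, modes[[m]], weighting)
      keep <- !is.na(w)
      if (any(keep)) {
        part <- rowsum(site_ratios[o$dest_id[keep]] * w[keep], o$origin_id[keep])
        a[rownames(part)] <- part[, 1]
      }
    }
    out[[paste0("spai_", m)]] <- unname(a)
  }
  out$spai_integrated <- rowSums(out[, paste0("spai_", names(modes)), drop = FALSE])
  out
}

#' Step 3: spatial access ratio
#'
#' Divides each score by the unweighted arithmetic mean over all demand
#' units, so the SPAR vector has mean exactly 1 whenever the mean score
#' is positive. An all-zero score vector (no access anywhere) yields all
#' SPAR 0 with a warning and attribute `no_access = TRUE` rather than a
#' division failure.
#'
#' @param scores Non-negative numeric SPAI vector, one value per demand
#'   unit.
#' @return Numeric SPAR vector with attribute `mean_spai` (and
#'   `no_access` in the degenerate case).
#' @export
spar <- function(scores) {
  if (length(scores) == 0)
    stop("`scores` must be non-empty", call. = FALSE)
  if (any(is.na(scores)) || any(scores < 0))
    stop("`scores` must be non-negative and complete", call. = FALSE)
  m <- mean(scores)
  if (m == 0) {
    warning("all SPAI are zero; SPAR undefined, reported as 0", call. = FALSE)
    return(structure(rep(0, length(scores)), mean_spai = 0, no_access = TRUE))
  }
  structure(scores / m, mean_spai = m)
}

#' Run the full three-step multi-modal access pipeline
#'
#' Composes [supply_ratio_multimodal()], [spai_multimodal()] and [spar()]:
#' per-site ratios, per-unit mode-specific and integrated SPAI, and the
#' corresponding SPARs (each mode normalized by its own mean, the
#' integrated score by the integrated mean).
#'
#' @inheritParams supply_ratio_multimodal
#' @return An object of class `mm_access`: list with `scores` (data.frame
#'   `id`, `spai_*`, `spar_*`), `site_ratios` (data.frame `id`, `ratio`),
#'   `mean_spai` (named vector, one entry per mode plus `integrated`),
#'   `modes`, and `weighting`.
#' @examples
#' sup <- data.frame(id = "s1", capacity = 10)
#' dem <- data.frame(id = "u1", pop_car = 100, pop_bus = 50)
#' od <- list(car = data.frame(origin_id = "u1", dest_id = "s1", minutes = 5),
#'            bus = data.frame(origin_id = "u1", dest_id = "s1", minutes = 45))
#' run_access(scene(sup, dem, od), default_modes())
#' @export
run_access <- function(sc, modes, weighting = "stepped") {
  modes <- check_modes(sc, modes)
  r <- supply_ratio_multimodal(sc, modes, weighting)
  scores <- spai_multimodal(r, sc, modes, weighting)
  fam <- c(names(modes), "integrated")
  mean_spai <- stats::setNames(numeric(length(fam)), fam)
  for (f in fam) {
    s <- spar(scores[[paste0("spai_", f)]])
    scores[[paste0("spar_", f)]] <- as.numeric(s)
    mean_spai[f] <- attr(s, "mean_spai")
  }
  structure(
    list(scores = scores,
         site_ratios = data.frame(id = names(r), ratio = unname(r),
                                  stringsAsFactors = FALSE),
         mean_spai = mean_spai,
         modes = modes,
         weighting = weighting),
    class = "mm_access")
}

#' @export
print.mm_access <- function(x, ...) {
  cat("<mm_access> ", nrow(x$scores), " demand units, ",
      nrow(x$site_ratios), " sites, weighting: ", x$weighting, "\n", sep = "")
  cat("mean SPAI:\n")
  print(signif(x$mean_spai, 5))
  invisible(x)
}

#' Classic single-mode E2SFCA baseline
#'
#' Collapses the scene to one transport mode carrying the TOTAL
#' population of every demand unit (sum of all mode populations) and
#' runs the same two-step computation, i.e. the original single-mode
#' model with stepped Gaussian sub-zone weights. With a genuinely
#' single-mode scene this is identical to the multi-modal pipeline.
#'
#' @inheritParams supply_ratio_multimodal
#' @param mode A single [mode_spec()]; its OD matrix must exist in the
#'   scene under `mode$name`.
#' @return An `mm_access` object with one mode.
#' @export
e2sfca_single_mode <- function(sc, mode, weighting = "stepped") {
  stopifnot(inherits(sc, "mm_scene"), inherits(mode, "mode_spec"))
  if (!mode$name %in% sc$modes)
    stop("scene has no OD matrix for mode '", mode$name, "'", call. = FALSE)
  pop_cols <- paste0("pop_", sc$modes)
  dem <- data.frame(id = sc$demand$id, stringsAsFactors = FALSE)
  dem[[paste0("pop_", mode$name)]] <-
    rowSums(sc$demand[, pop_cols, drop = FALSE])
  for (cc in intersect(c("x", "y"), names(sc$demand))) dem[[cc]] <- sc$demand[[cc]]
  sc1 <- scene(sc$supply, dem, sc$od[mode$name])
  run_access(sc1, list(mode), weighting)
}
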