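# Impedance-coefficient sensitivity battery: run the access pipeline over
# a Cartesian grid of per-mode coefficients, summarize each cell, and test
# score stability across coefficients with one-way ANOVA. The headline
# contrast: SPAI shifts significantly with beta while SPAR stays put
# (between-cell SPAR means are all exactly 1, so its ANOVA F collapses).

#' Equally spaced coefficient grid
#'
#' @param beta_min,beta_max Grid endpoints, `0 < beta_min < beta_max`.
#' @param n_points Number of grid values, at least 2; endpoints included.
#' @return Numeric vector of `n_points` equally spaced coefficients.
#' @examples
#' build_grid(140, 320, 13)   # step 15
#' build_grid(440, 1040, 13)  # step 50
#' @export
build_grid <- function(beta_min, beta_max, n_points) {
  if (!is.numeric(beta_min) || !is.numeric(beta_max) ||
      length(beta_min) != 1L || length(beta_max) != 1L ||
      is.na(beta_min) || is.na(beta_max) ||
      beta_min <= 0 || beta_min >= beta_max)
    stop("need 0 < beta_min < beta_max", call. = FALSE)
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2)
    stop("`n_points` must be at least 2", call. = FALSE)
  seq(beta_min, beta_max, length.out = as.integer(n_points))
}

#' Descriptive statistics of a score vector
#'
#' Minimum, maximum, mean, sample standard deviation (denominator n-1)
#' and coefficient of variation (SD/mean; `NA` when the mean is 0).
#'
#' @param scores Non-empty numeric vector.
#' @return Named list `min`, `max`, `mean`, `sd`, `cv`.
#' @export
describe_scores <- function(scores) {
  if (!is.numeric(scores) || length(scores) == 0 || any(is.na(scores)))
    stop("`scores` must be non-empty numeric without NA", call. = FALSE)
  m <- mean(scores)
  s <- if (length(scores) > 1) stats::sd(scores) else 0
  list(min = min(scores), max = max(scores), mean = m, sd = s,
       cv = if (m == 0) NA_real_ else s / m)
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance from the
#' sum-of-squares decomposition, with explicit handling of degenerate
#' groupings: when both the between-group and within-group sums of
#' squares are zero (all observations identical) the result is F = 0,
#' p = 1 rather than NaN.
#'
#' @param groups List of at least two numeric vectors, each with at
#'   least two observations.
#' @return List `F`, `df_between`, `df_within`, `p`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5, p ~ 0.0213
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  n_g <- lengths(groups)
  if (any(n_g < 2))
    stop("every group needs at least two observations", call. = FALSE)
  all_x <- unlist(groups, use.names = FALSE)
  if (any(is.na(all_x))) stop("groups must not contain NA", call. = FALSE)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_g * (means - grand)^2)
  ssw <- sum(vapply(seq_along(groups),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(all_x) - length(groups)
  if (ssb == 0 && ssw == 0)
    return(list(F = 0, df_between = df1, df_within = df2, p = 1))
  if (ssw == 0)
    return(list(F = Inf, df_between = df1, df_within = df2, p = 0))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df_between = df1, df_within = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Run the access pipeline over a coefficient grid
#'
#' Executes [run_access()] once per combination of per-mode impedance
#' coefficients (the Cartesian product of the grids; the default
#' 13 x 13 car/bus grids give 169 combinations) and collects per-unit
#' scores and per-cell descriptive statistics. Deterministic given the
#' scene.
#'
#' @inheritParams supply_ratio_multimodal
#' @param modes List of template [mode_spec()]s; each cell replaces
#'   their `beta` with the grid values.
#' @param grids Named list of coefficient vectors, names matching the
#'   modes. Defaults to [default_beta_grids()] for car/bus scenes.
#' @return Object of class `mm_sensitivity`: `cells` (one row per
#'   combination with `cell` and `beta_<mode>` columns), `scores` (long
#'   data.frame: cell key, unit `id`, all `spai_*`/`spar_*` families),
#'   `stats` (per cell x family: min/max/mean/sd/cv), `mode_names`,
#'   `grids`.
#' @export
run_grid <- function(sc, modes, grids = NULL, weighting = "stepped") {
  modes <- check_modes(sc, modes)
  if (is.null(grids)) {
    if (!setequal(names(modes), c("car", "bus")))
      stop("default grids only exist for car/bus scenes; supply `grids`",
           call. = FALSE)
    grids <- default_beta_grids()[names(modes)]
  }
  if (is.null(names(grids)) || !setequal(names(grids), names(modes)))
    stop("`grids` must be a named list over the scene's modes", call. = FALSE)
  grids <- grids[names(modes)]

  cells <- expand.grid(lapply(grids, as.numeric), KEEP.OUT.ATTRS = FALSE)
  names(cells) <- paste0("beta_", names(grids))
  cells <- cbind(cell = seq_len(nrow(cells)), cells)

  fam_cols <- c(paste0("spai_", c(names(modes), "integrated")),
                paste0("spar_", c(names(modes), "integrated")))
  scores_list <- vector("list", nrow(cells))
  stats_list <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    ms <- modes
    for (m in names(ms)) ms[[m]]$beta <- cells[[paste0("beta_", m)]][ci]
    res <- run_access(sc, ms, weighting)
    scores_list[[ci]] <- cbind(cells[ci, , drop = FALSE],
                               res$scores, row.names = NULL)
    stats_list[[ci]] <- do.call(rbind, lapply(fam_cols, function(fc) {
      d <- describe_scores(res$scores[[fc]])
      data.frame(cell = ci, family = fc, min = d$min, max = d$max,
                 mean = d$mean, sd = d$sd, cv = d$cv,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(cells = cells,
         scores = do.call(rbind, scores_list),
         stats = do.call(rbind, c(stats_list, list(make.row.names = FALSE))),
         mode_names = names(modes),
         grids = grids,
         weighting = weighting),
    class = "mm_sensitivity")
}

#' @export
print.mm_sensitivity <- function(x, ...) {
  cat("<mm_sensitivity> ", nrow(x$cells), " coefficient combinations (",
      paste(vapply(x$grids, length, integer(1)), collapse = " x "),
      "), ", length(unique(x$scores$id)), " demand units\n", sep = "")
  invisible(x)
}

# split per-unit scores of one family into groups by a beta column,
# optionally restricted to a fixed value of the other beta column
battery_groups <- function(scores, family, by_col, fix_col = NULL, fix_val = NULL) {
  d <- scores
  if (!is.null(fix_col)) d <- d[d[[fix_col]] == fix_val, , drop = FALSE]
  split(d[[family]], d[[by_col]])
}

#' ANOVA hypothesis battery over a sensitivity grid
#'
#' For every score family (per-mode and integrated SPAI and SPAR) and
#' every focal mode, tests (a) whether per-unit scores differ across the
#' focal mode's coefficients, pooling over the other mode's grid, and
#' (b) for each fixed focal coefficient, whether scores differ across
#' the other mode's coefficients. Rows that correspond to the
#' conventional twelve-hypothesis battery (7-18: SPAI then SPAR; car
#' across car, car within-car across bus, bus across bus, bus within-bus
#' across car, integrated across car, integrated within-car across bus)
#' carry that id in `hypothesis`; the remaining combinations are emitted
#' with `hypothesis = NA` for completeness.
#'
#' Because every cell's SPAR mean is exactly 1, the between-group
#' variance of any SPAR grouping is zero up to floating-point noise:
#' every SPAR row has F ~ 0 and p = 1 on any scene.
#'
#' @param sens An `mm_sensitivity` from [run_grid()] over exactly two
#'   modes.
#' @return data.frame with columns `hypothesis`, `family`, `focal_mode`,
#'   `grouping`, `fixed_beta`, `F`, `df_between`, `df_within`, `p`. A
#'   single-cell grid returns an empty table with a warning.
#' @export
hypothesis_battery <- function(sens) {
  stopifnot(inherits(sens, "mm_sensitivity"))
  if (length(sens$mode_names) != 2)
    stop("the hypothesis battery is defined for two-mode grids", call. = FALSE)
  if (nrow(sens$cells) < 2) {
    warning("single-cell grid: nothing to compare", call. = FALSE)
    return(data.frame(hypothesis = integer(0), family = character(0),
                      focal_mode = character(0), grouping = character(0),
                      fixed_beta = numeric(0), F = numeric(0),
                      df_between = integer(0), df_within = integer(0),
                      p = numeric(0)))
  }
  m1 <- sens$mode_names[1]; m2 <- sens$mode_names[2]
  families <- c(paste0("spai_", c(m1, m2, "integrated")),
                paste0("spar_", c(m1, m2, "integrated")))
  # focal mode of the conventional battery per family: the mode whose
  # grid indexes the "across" test (integrated families use mode 1)
  conv_focal <- stats::setNames(c(m1, m2, m1, m1, m2, m1), families)
  conv_id <- stats::setNames(c(7L, 9L, 11L, 13L, 15L, 17L), families)

  rows <- list()
  for (fam in families) {
    for (focal in c(m1, m2)) {
      other <- setdiff(c(m1, m2), focal)
      b_focal <- paste0("beta_", focal)
      b_other <- paste0("beta_", other)
      conventional <- identical(conv_focal[[fam]], focal)
      pooled_id <- if (conventional) conv_id[[fam]] else NA_integer_
      within_id <- if (conventional) conv_id[[fam]] + 1L else NA_integer_

      g <- battery_groups(sens$scores, fam, b_focal)
      a <- if (length(g) >= 2) anova_oneway(g) else NULL
      if (!is.null(a))
        rows[[length(rows) + 1L]] <- data.frame(
          hypothesis = pooled_id, family = fam, focal_mode = focal,
          grouping = paste0("across_", focal, "_pooled"),
          fixed_beta = NA_real_, F = a$F, df_between = a$df_between,
          df_within = a$df_within, p = a$p, stringsAsFactors = FALSE)

      if (length(sens$grids[[other]]) >= 2) {
        for (bv in sens$grids[[focal]]) {
          g <- battery_groups(sens$scores, fam, b_other, b_focal, bv)
          a <- anova_oneway(g)
          rows[[length(rows) + 1L]] <- data.frame(
            hypothesis = within_id, family = fam, focal_mode = focal,
            grouping = paste0("across_", other, "_at_", focal, "=", bv),
            fixed_beta = bv, F = a$F, df_between = a$df_between,
            df_within = a$df_within, p = a$p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
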