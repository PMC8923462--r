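#' Normalization configuration
#'
#' Parameters of the colony-size normalization cascade. Defaults reproduce
#' the standard treatment of pinned-array screens: scale every plate by its
#' 70th percentile, then remove row/column trends, smooth spatial fields, and
#' competition artifacts, and finally drop replicate-discordant jackpot
#' colonies keyed on a reference condition.
#'
#' @param percentile_q quantile used for intra-plate scaling, strictly in
#'   (0, 1). Default 0.70: high enough to sit above the bulk of true
#'   sensitives, low enough to be robust to a handful of resistant outliers.
#' @param do_row,do_col,do_neighborhood,do_competition toggles for the
#'   individual positional corrections.
#' @param neighborhood_radius half-width of the square window of the
#'   neighborhood (running-median) correction; the window is
#'   `(2 * radius + 1)^2` positions, clipped at plate edges.
#' @param competition_gamma strength of the competition (nutrient-windfall)
#'   shrinkage; 0 disables it exactly.
#' @param jackpot_factor `m` of the jackpot filter: a replicate is flagged
#'   when its reference-condition size exceeds `m` times the strain's
#'   cross-replicate median while at least one replicate does not.
#' @param jackpot_condition condition whose plates anchor the jackpot filter
#'   (e.g. `"HU"`); `NULL` disables the filter.
#' @param min_size sizes `<= min_size` are treated as dead: excluded from
#'   quantile/median computations (so they do not drag positional factors)
#'   but retained as values, since lethality is biological signal.
#' @param renormalize rescale after the positional corrections so the
#'   library-quantile of the finished plate is exactly 1 (the corrections are
#'   median-ratio factors and preserve the scale only approximately).
#' @return An object of class `normalization_config`.
#' @export
normalization_config <- function(percentile_q = 0.70,
                                 do_row = TRUE, do_col = TRUE,
                                 do_neighborhood = TRUE, do_competition = TRUE,
                                 neighborhood_radius = 2L,
                                 competition_gamma = 0.5,
                                 jackpot_factor = 1.5,
                                 jackpot_condition = NULL,
                                 min_size = 0,
                                 renormalize = TRUE) {
  stopifnot(
    percentile_q > 0, percentile_q < 1,
    neighborhood_radius >= 1L,
    competition_gamma >= 0,
    jackpot_factor > 1,
    min_size >= 0
  )
  structure(
    list(
      percentile_q = percentile_q,
      do_row = isTRUE(do_row), do_col = isTRUE(do_col),
      do_neighborhood = isTRUE(do_neighborhood),
      do_competition = isTRUE(do_competition),
      neighborhood_radius = as.integer(neighborhood_radius),
      competition_gamma = competition_gamma,
      jackpot_factor = jackpot_factor,
      jackpot_condition = jackpot_condition,
      min_size = min_size,
      renormalize = isTRUE(renormalize)
    ),
    class = "normalization_config"
  )
}

# Working copy of the size matrix with dead colonies (<= min_size) masked,
# and optionally non-library positions masked, for quantile/median purposes.
live_matrix <- function(plate, min_size, lib = NULL) {
  w <- plate$size
  w[!is.na(w) & w <= min_size] <- NA_real_
  if (!is.null(lib)) w[!lib] <- NA_real_
  w
}

plate_median <- function(plate, min_size, lib = NULL) {
  stats::median(live_matrix(plate, min_size, lib), na.rm = TRUE)
}

#' Scale a plate by an intra-plate quantile
#'
#' Divides every non-missing colony size by the `q`-quantile (linear
#' interpolation between order statistics) of the plate's live colonies. When
#' a design is supplied the quantile is computed over library positions only
#' (controls and border colonies differ systematically), but all positions
#' are rescaled. After the call the plate's `q`-quantile equals 1.
#'
#' @param plate a [plate_grid()].
#' @param q quantile in (0, 1); default 0.70.
#' @param min_size dead-colony threshold (see [normalization_config()]).
#' @param design optional [screen_design()] restricting the quantile to
#'   library positions.
#' @return The rescaled `plate_grid`.
#' @export
percentile_normalize <- function(plate, q = 0.70, min_size = 0, design = NULL) {
  stopifnot(q > 0, q < 1)
  lib <- if (!is.null(design)) {
    library_mask(design, plate$plate_id, nrow(plate$size), ncol(plate$size))
  }
  w <- live_matrix(plate, min_size, lib)
  if (all(is.na(w))) {
    stop(sprintf(
      "plate '%s' (%s, %s, rep %d): no live colonies to normalize against",
      plate$plate_id, plate$background, plate$condition, plate$replicate
    ))
  }
  denom <- stats::quantile(w, probs = q, na.rm = TRUE, names = FALSE, type = 7)
  if (denom <= 0) {
    stop(sprintf("plate '%s': %g-quantile is not positive", plate$plate_id, q))
  }
  plate$size <- plate$size / denom
  plate
}

#' Remove row and column trends
#'
#' Each colony is divided first by its row's median relative to the plate
#' median, then by its (row-corrected) column's median relative to the plate
#' median, all medians over live colonies. On gradient-only data this leaves
#' every row and column median equal to the plate median. A row or column
#' with no live colony gets a factor of 1 (with a warning).
#'
#' @inheritParams percentile_normalize
#' @return The corrected `plate_grid`.
#' @export
row_col_normalize <- function(plate, min_size = 0) {
  for (axis in 1:2) {
    w <- live_matrix(plate, min_size)
    pm <- stats::median(w, na.rm = TRUE)
    med <- apply(w, axis, stats::median, na.rm = TRUE)
    fac <- med / pm
    if (anyNA(fac)) {
      warning(sprintf(
        "plate '%s': %s(s) %s entirely dead/missing; correction factor set to 1",
        plate$plate_id, c("row", "column")[axis],
        paste(which(is.na(fac)), collapse = ", ")
      ))
      fac[is.na(fac)] <- 1
    }
    plate$size <- if (axis == 1L) plate$size / fac else
      sweep(plate$size, 2L, fac, `/`)
  }
  plate
}

#' Remove smooth spatial fields with a running-median correction
#'
#' Divides each colony by the median of its square neighborhood (half-width
#' `radius`, focal colony excluded, clipped at plate edges) relative to the
#' plate median. Smooth multiplicative gradients — corner-to-corner trends,
#' incubator hot spots — are flattened, while a lone outlier colony survives
#' largely intact because it does not move its own window's median.
#'
#' @inheritParams percentile_normalize
#' @param radius window half-width, >= 1; default 2 (a 5 x 5 window).
#' @return The corrected `plate_grid`.
#' @export
neighborhood_normalize <- function(plate, radius = 2L, min_size = 0) {
  stopifnot(radius >= 1L)
  w <- live_matrix(plate, min_size)
  pm <- stats::median(w, na.rm = TRUE)
  loc <- window_median_excl(w, as.integer(radius))
  fac <- loc / pm
  lone <- !is.na(plate$size) & is.na(fac)
  if (any(lone)) {
    warning(sprintf(
      "plate '%s': %d position(s) with no live neighbor in the window; factor 1",
      plate$plate_id, sum(lone)
    ))
  }
  fac[is.na(fac)] <- 1
  plate$size <- plate$size / fac
  plate
}

#' Shrink nutrient-windfall inflation next to dead or empty neighbors
#'
#' A colony whose 4-neighbors are small or dead faces less competition for
#' nutrients and grows artifactually large. Let `d = max(0, 1 - median size
#' of the 4-neighbors / plate median)`; the colony is divided by
#' `1 + gamma * d`. Colonies surrounded by normal neighbors (`d = 0`) are
#' untouched; `gamma = 0` makes the step the identity. Dead neighbors count
#' with their size (0); missing neighbors are ignored, and a colony with no
#' measurable neighbor gets `d = 0`.
#'
#' @inheritParams percentile_normalize
#' @param gamma shrinkage strength, >= 0; default 0.5.
#' @return The corrected `plate_grid`.
#' @export
competition_normalize <- function(plate, gamma = 0.5, min_size = 0) {
  stopifnot(gamma >= 0)
  if (gamma == 0) return(plate)
  pm <- plate_median(plate, min_size)
  nb <- neighbor4_median(plate$size)  # dead colonies count as 0 here
  d <- pmax(0, 1 - nb / pm)
  d[is.na(d)] <- 0
  plate$size <- plate$size / (1 + gamma * d)
  plate
}

#' Run the full normalization cascade on one plate
#'
#' Applies, in order: intra-plate quantile scaling, row/column trend removal,
#' neighborhood (running-median) correction, competition shrinkage, and a
#' final rescale restoring the library quantile to 1 (if
#' `config$renormalize`). Steps can be toggled individually via
#' [normalization_config()]. The jackpot filter is a cross-replicate
#' operation and lives in [jackpot_filter()].
#'
#' @param plate a [plate_grid()].
#' @param config a [normalization_config()].
#' @param design optional [screen_design()]; when given, quantiles are
#'   computed over library positions only.
#' @return The normalized `plate_grid`, with the applied steps recorded in
#'   `attr(, "normalization")`.
#' @export
normalize_plate <- function(plate, config = normalization_config(),
                            design = NULL) {
  stopifnot(inherits(config, "normalization_config"))
  ms <- config$min_size
  steps <- c(sprintf("percentile(q=%g)", config$percentile_q))
  plate <- percentile_normalize(plate, config$percentile_q, ms, design)
  if (config$do_row || config$do_col) {
    # row and column factors are both computed inside row_col_normalize;
    # partial toggles fall back to single-axis handling
    if (config$do_row && config$do_col) {
      plate <- row_col_normalize(plate, ms)
      steps <- c(steps, "row", "col")
    } else {
      axis <- if (config$do_row) 1L else 2L
      w <- live_matrix(plate, ms)
      pm <- stats::median(w, na.rm = TRUE)
      fac <- apply(w, axis, stats::median, na.rm = TRUE) / pm
      fac[is.na(fac)] <- 1
      plate$size <- if (axis == 1L) plate$size / fac else
        sweep(plate$size, 2L, fac, `/`)
      steps <- c(steps, c("row", "col")[axis])
    }
  }
  if (config$do_neighborhood) {
    plate <- neighborhood_normalize(plate, config$neighborhood_radius, ms)
    steps <- c(steps, sprintf("neighborhood(radius=%d)", config$neighborhood_radius))
  }
  if (config$do_competition) {
    plate <- competition_normalize(plate, config$competition_gamma, ms)
    steps <- c(steps, sprintf("competition(gamma=%g)", config$competition_gamma))
  }
  if (config$renormalize) {
    plate <- percentile_normalize(plate, config$percentile_q, ms, design)
    steps <- c(steps, sprintf("rescale(q=%g)", config$percentile_q))
  }
  attr(plate, "normalization") <- steps
  plate
}

#' Flag jackpot colonies from a reference condition
#'
#' Spontaneous suppressor mutations produce very large ("jackpot") colonies
#' in a subset of replicates; left in, they mimic resistance. A
#' (strain, replicate) pair is flagged when its normalized size on the
#' reference condition exceeds `m` times that strain's cross-replicate median
#' *and* at least one replicate stays within the bound — a strain that is
#' large in every replicate is genuine resistance and is never flagged.
#' Flagged pairs are meant to be excluded from *all* conditions of the
#' background downstream (pass the result as `exclusions=` to
#' [strain_values()] / [run_screen()]).
#'
#' @param plates list of normalized [plate_grid()]s of one background; plates
#'   of conditions other than `reference_condition` are ignored.
#' @param design a [screen_design()].
#' @param reference_condition condition anchoring the filter (e.g. `"HU"`).
#' @param m exclusion factor, > 1; default 1.5.
#' @return data.frame with columns `background`, `strain`, `replicate`, one
#'   row per flagged pair (zero rows when nothing is flagged or fewer than
#'   two reference replicates exist, the latter with a warning).
#' @export
jackpot_filter <- function(plates, design, reference_condition, m = 1.5) {
  stopifnot(m > 1)
  empty <- data.frame(background = character(), strain = character(),
                      replicate = integer(), stringsAsFactors = FALSE)
  ref <- Filter(function(p) p$condition == reference_condition, plates)
  if (length(ref) == 0L) {
    warning(sprintf("no plates of reference condition '%s'; jackpot filter disabled",
                    reference_condition))
    return(empty)
  }
  bg <- unique(vapply(ref, function(p) p$background, character(1)))
  if (length(bg) != 1L) {
    stop("jackpot_filter expects plates of a single background")
  }
  if (length(unique(vapply(ref, function(p) p$replicate, integer(1)))) < 2L) {
    warning("fewer than 2 reference replicates; jackpot filter disabled")
    return(empty)
  }
  long <- plates_to_long(ref)
  lay <- design$layout
  long$strain <- lay$strain[match(
    paste(long$plate_id, long$row, long$col, sep = "\r"),
    paste(lay$plate_id, lay$row, lay$col, sep = "\r")
  )]
  long <- long[!is.na(long$strain) & !long$strain %in% c("EMPTY", "BORDER") &
                 !is.na(long$size), , drop = FALSE]
  # one size per (strain, replicate); average if the strain is spotted twice
  agg <- stats::aggregate(size ~ strain + replicate, data = long, FUN = mean)
  med <- stats::aggregate(size ~ strain, data = agg, FUN = stats::median)
  names(med)[2L] <- "med"
  agg <- merge(agg, med, by = "strain")
  agg$exceeds <- agg$size > m * agg$med
  all_exceed <- stats::aggregate(exceeds ~ strain, data = agg, FUN = all)
  names(all_exceed)[2L] <- "all_exceed"
  agg <- merge(agg, all_exceed, by = "strain")
  flagged <- agg[agg$exceeds & !agg$all_exceed, , drop = FALSE]
  if (nrow(flagged) == 0L) return(empty)
  out <- data.frame(background = bg, strain = flagged$strain,
                    replicate = as.integer(flagged$replicate),
                    stringsAsFactors = FALSE)
  out[order(out$strain, out$replicate), , drop = FALSE]
}
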