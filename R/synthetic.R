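#' Ground truth and artifact parameters for a synthetic screen
#'
#' Defines everything [generate_screen()] needs to simulate a pinned
#' colony-array screen with known answers: per-strain baseline sizes,
#' planted log2 interaction effects, positional artifact strengths, jackpot
#' and missing-colony rates, and measurement noise. Colony noise is
#' log-normal (normal on the log2 scale): areas are positive and fitness
#' effects act multiplicatively.
#'
#' Defaults emulate a 1536-density deletion-library screen: ±10% row and
#' column trends, a smooth spatial field of amplitude 0.3, a 1.3-fold edge
#' ring, competition windfall of strength 0.5 next to missing colonies, 1%
#' missing positions, 1% jackpot rate at 4-fold size, and replicate noise of
#' 0.2 on the log2 scale.
#'
#' @param design a [screen_design()].
#' @param effects data.frame with columns `strain`, `background`,
#'   `condition`, `effect` (log2 multiplicative effect); strains absent from
#'   it have effect 0. See [plant_effects()].
#' @param baseline optional named numeric vector of baseline colony areas
#'   (pixel units) per strain; defaults to log-normal draws around 500 px,
#'   fixed by `seed`.
#' @param row_slope,col_slope linear trend half-span (fractional) across
#'   rows/columns.
#' @param smooth_amplitude amplitude of a smooth Gaussian spatial field.
#' @param edge_factor,edge_width multiplicative boost of the outer
#'   `edge_width` rings (extra nutrients at plate edges).
#' @param competition_coef inflation of colonies per fraction of missing
#'   4-neighbors (nutrient windfall).
#' @param jackpot_prob,jackpot_factor,jackpot_condition per-(strain,
#'   replicate) probability, size multiplier, and host condition of planted
#'   jackpot (spontaneous suppressor) colonies; jackpots never occur in all
#'   replicates of a strain. `NULL` condition disables them.
#' @param missing_prob probability a position fails to pin.
#' @param noise_sd replicate noise SD on the log2 scale.
#' @param seed integer seed; drives per-plate deterministic substreams.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(design,
                            effects = NULL,
                            baseline = NULL,
                            row_slope = 0.1, col_slope = 0.1,
                            smooth_amplitude = 0.3,
                            edge_factor = 1.3, edge_width = 2L,
                            competition_coef = 0.5,
                            jackpot_prob = 0.01, jackpot_factor = 4,
                            jackpot_condition = NULL,
                            missing_prob = 0.01,
                            noise_sd = 0.2,
                            seed = 1L) {
  stopifnot(inherits(design, "screen_design"),
            jackpot_prob >= 0, jackpot_prob <= 1,
            missing_prob >= 0, missing_prob <= 1,
            noise_sd >= 0, jackpot_factor > 1, edge_factor > 0)
  strains <- sort(unique(design$layout$strain))
  if (is.null(effects)) {
    effects <- data.frame(strain = character(), background = character(),
                          condition = character(), effect = numeric(),
                          stringsAsFactors = FALSE)
  }
  stray <- setdiff(effects$strain, strains)
  if (length(stray) > 0L) {
    stop(sprintf("effects reference strains absent from the design: %s",
                 paste(utils::head(stray, 3L), collapse = ", ")))
  }
  if (is.null(baseline)) {
    set.seed(as.integer(seed))
    baseline <- stats::setNames(
      exp(log(500) + stats::rnorm(length(strains), 0, 0.25)), strains
    )
    baseline[names(baseline) %in% c("EMPTY", "BORDER")] <- 500
  }
  structure(
    list(effects = effects, baseline = baseline,
         row_slope = row_slope, col_slope = col_slope,
         smooth_amplitude = smooth_amplitude,
         edge_factor = edge_factor, edge_width = as.integer(edge_width),
         competition_coef = competition_coef,
         jackpot_prob = jackpot_prob, jackpot_factor = jackpot_factor,
         jackpot_condition = jackpot_condition,
         missing_prob = missing_prob, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Plant interaction effects for a subset of strains
#'
#' Draws `n_hits` distinct library strains and assigns each a log2 effect
#' with magnitude uniform in `effect_range` and sign per `direction`, for
#' one background x condition. The draw is fixed by `seed`.
#'
#' @param design a [screen_design()].
#' @param n_hits number of strains to perturb.
#' @param background,condition where the effect acts.
#' @param effect_range magnitude range (log2).
#' @param direction `"both"` (random sign), `"negative"` (sensitivity) or
#'   `"positive"` (resistance/suppression).
#' @param seed integer seed.
#' @return data.frame suitable as `effects` for [synthetic_truth()].
#' @export
plant_effects <- function(design, n_hits, background, condition,
                          effect_range = c(1.5, 3),
                          direction = c("both", "negative", "positive"),
                          seed = 1L) {
  direction <- match.arg(direction)
  lib <- sort(setdiff(unique(design$layout$strain), c("EMPTY", "BORDER")))
  stopifnot(n_hits <= length(lib))
  set.seed(as.integer(seed))
  picked <- sample(lib, n_hits)
  mag <- stats::runif(n_hits, effect_range[1L], effect_range[2L])
  sgn <- switch(direction,
                both = sample(c(-1, 1), n_hits, replace = TRUE),
                negative = rep(-1, n_hits),
                positive = rep(1, n_hits))
  data.frame(strain = picked, background = background,
             condition = condition, effect = sgn * mag,
             stringsAsFactors = FALSE)
}

# Look up planted effects for a strain matrix on one background/condition.
effect_matrix <- function(strain_mat, effects, background, condition) {
  out <- matrix(0, nrow(strain_mat), ncol(strain_mat))
  sub <- effects[effects$background == background &
                   effects$condition == condition, , drop = FALSE]
  if (nrow(sub) > 0L) {
    i <- match(strain_mat, sub$strain)
    hit <- !is.na(i)
    out[hit] <- sub$effect[i[hit]]
  }
  out
}

#' Simulate a full set of screen plates with known truth
#'
#' For every background, condition, replicate and library plate of the
#' design, colony sizes are generated as
#' `baseline * 2^(effect + noise) * rowfac * colfac * smoothfield * edgefac *
#' competitionfac`, positions go missing with `missing_prob`, and — on the
#' jackpot condition — planted jackpot colonies multiply a strict subset of
#' a strain's replicates by `jackpot_factor`. One global seed drives a
#' deterministic per-plate substream, so any subset of plates is
#' reproducible independently; the same seed yields bit-identical plates.
#'
#' @param design a [screen_design()].
#' @param truth a [synthetic_truth()].
#' @return list with `plates` (list of [plate_grid()]) and `truth` (the
#'   input truth, with the realized jackpot assignments attached as
#'   `truth$jackpots`).
#' @export
generate_screen <- function(design, truth) {
  stopifnot(inherits(design, "screen_design"),
            inherits(truth, "synthetic_truth"))
  plate_ids <- unique(design$layout$plate_id)

  # cross-replicate jackpot plan, drawn from its own substream
  jackpots <- NULL
  if (!is.null(truth$jackpot_condition) && truth$jackpot_prob > 0) {
    set.seed((truth$seed + 7L) %% 2147483629L)
    lib <- sort(setdiff(unique(design$layout$strain), c("EMPTY", "BORDER")))
    rows <- list()
    for (bg in design$backgrounds) {
      n_rep <- truth$replicates_override %||% design$replicates[[bg]]
      flags <- matrix(stats::runif(length(lib) * n_rep) < truth$jackpot_prob,
                      nrow = length(lib))
      full <- rowSums(flags) == n_rep
      flags[full, 1L] <- FALSE  # jackpots never occur in all replicates
      idx <- which(flags, arr.ind = TRUE)
      if (nrow(idx) > 0L) {
        rows[[bg]] <- data.frame(background = bg, strain = lib[idx[, 1L]],
                                 replicate = as.integer(idx[, 2L]),
                                 stringsAsFactors = FALSE)
      }
    }
    jackpots <- if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(background = character(), strain = character(),
                 replicate = integer(), stringsAsFactors = FALSE)
    if (!is.null(jackpots)) rownames(jackpots) <- NULL
  }

  plates <- list()
  counter <- 0L
  for (bg in design$backgrounds) {
    for (cond in design$conditions) {
      for (rep_i in seq_len(design$replicates[[bg]])) {
        for (pid in plate_ids) {
          counter <- counter + 1L
          lay <- design$layout[design$layout$plate_id == pid, , drop = FALSE]
          nr <- max(lay$row)
          nc <- max(lay$col)
          strain_mat <- layout_matrix(design, pid, nr, nc)

          set.seed((truth$seed + 100003L * counter) %% 2147483629L)
          eff <- effect_matrix(strain_mat, truth$effects, bg, cond)
          eps <- matrix(stats::rnorm(nr * nc, 0, truth$noise_sd), nr, nc)

          rfac <- 1 + truth$row_slope *
            (2 * (seq_len(nr) - 1) / max(nr - 1, 1) - 1)
          cfac <- 1 + truth$col_slope *
            (2 * (seq_len(nc) - 1) / max(nc - 1, 1) - 1)
          rr <- matrix(seq_len(nr), nr, nc)
          cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
          sigma <- min(nr, nc) / 3
          d2 <- (rr - (nr + 1) / 2)^2 + (cc - (nc + 1) / 2)^2
          smooth <- 1 + truth$smooth_amplitude * exp(-d2 / (2 * sigma^2))
          edge <- matrix(1, nr, nc)
          if (truth$edge_width > 0L && truth$edge_factor != 1) {
            ring <- rr <= truth$edge_width | rr > nr - truth$edge_width |
              cc <= truth$edge_width | cc > nc - truth$edge_width
            edge[ring] <- truth$edge_factor
          }

          size <- truth$baseline[strain_mat] * 2^(eff + eps) *
            outer(rfac, cfac) * smooth * edge
          size <- matrix(size, nr, nc)
          size[strain_mat == "EMPTY" | is.na(strain_mat)] <- NA_real_

          miss <- matrix(stats::runif(nr * nc) < truth$missing_prob, nr, nc)
          size[miss] <- NA_real_

          if (truth$competition_coef > 0) {
            windfall <- 1 + truth$competition_coef * neighbor4_na_fraction(size)
            size <- size * windfall
          }

          if (!is.null(jackpots) && cond == truth$jackpot_condition) {
            jp <- jackpots[jackpots$background == bg &
                             jackpots$replicate == rep_i, , drop = FALSE]
            hit <- matrix(strain_mat %in% jp$strain, nr, nc)
            size[hit] <- size[hit] * truth$jackpot_factor
          }

          plates[[counter]] <- plate_grid(size, pid, bg, cond, rep_i)
        }
      }
    }
  }
  truth$jackpots <- jackpots
  list(plates = plates, truth = truth)
}

#' Confusion matrix of pipeline calls against planted truth
#'
#' A strain is truth-positive when the magnitude of its planted effect on
#' the screened (treated) condition is at least `effect_cutoff`; it is
#' called positive when its call is `"sensitive"` or `"resistant"`.
#'
#' @param scores data.frame from [run_screen()].
#' @param truth a [synthetic_truth()] (as echoed by [generate_screen()]).
#' @param effect_cutoff minimum |log2 effect| counted as a true effect.
#' @param condition treated condition; defaults to the one recorded on
#'   `scores`.
#' @return list with `tp`, `fp`, `fn`, `tn`, `recall`, `fdp` (false-discovery
#'   proportion, 0 when nothing is called).
#' @export
truth_confusion <- function(scores, truth, effect_cutoff = 1,
                            condition = NULL) {
  condition <- condition %||% attr(scores, "treated_condition")
  if (is.null(condition)) stop("treated condition unknown; pass `condition`")
  eff <- truth$effects[truth$effects$condition == condition, , drop = FALSE]
  i <- match(paste(scores$strain, scores$background),
             paste(eff$strain, eff$background))
  planted <- ifelse(is.na(i), 0, eff$effect[i])
  truth_pos <- abs(planted) >= effect_cutoff
  called <- !is.na(scores$call) & scores$call %in% c("sensitive", "resistant")
  tp <- sum(called & truth_pos)
  fp <- sum(called & !truth_pos)
  fn <- sum(!called & truth_pos)
  tn <- sum(!called & !truth_pos)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fdp = if (tp + fp > 0) fp / (tp + fp) else 0)
}
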