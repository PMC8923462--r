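#' Rank strains from sensitive to resistant
#'
#' Stable sort by score ascending within each background, ties broken by
#' strain ID, with a `rank` column — the x-axis of the classic screen rank
#' plot (sensitive left, resistant right). Uncallable strains (NA score)
#' sort last and get NA ranks.
#'
#' @param scores data.frame from [run_screen()].
#' @return The reordered data.frame with an added `rank` column.
#' @export
rank_table <- function(scores) {
  ord <- order(scores$background, is.na(scores$score), scores$score,
               scores$strain, method = "radix")
  out <- scores[ord, , drop = FALSE]
  out$rank <- NA_integer_
  for (bg in unique(out$background)) {
    idx <- which(out$background == bg & !is.na(out$score))
    out$rank[idx] <- seq_along(idx)
  }
  rownames(out) <- NULL
  out
}

#' Call hypersensitivity suppressors
#'
#' In a drug-hypersensitive background, a library deletion is a suppressor
#' when it increases drug-relative fitness with stringent support: BH
#' q-value below `fdr_alpha`, SD-corrected score at least `effect_floor` in
#' the resistance direction, and the two-SD separation rule — the latter two
#' are exactly what a `"resistant"` call encodes.
#'
#' @param scores data.frame from [run_screen()] carrying q-values.
#' @param config a [call_config()]; its `effect_floor` should be the
#'   stringent suppressor floor (0.5) rather than the primary-screen floor.
#' @return The subset of `scores` rows that qualify as suppressors.
#' @export
call_suppressors <- function(scores, config = call_config(effect_floor = 0.5)) {
  stopifnot(inherits(config, "call_config"))
  recall <- call_interaction(scores$delta_mean, scores$sum_sd, scores$score,
                             config)
  keep <- !is.na(recall) & recall == "resistant" &
    !is.na(scores$q_value) & scores$q_value < config$fdr_alpha &
    scores$score >= config$effect_floor
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate suppressors across drugs and backgrounds
#'
#' Builds one profile row per DON suppressor of the primary hypersensitive
#' background, annotated with whether it also suppresses the reference-drug
#' (HU) sensitivity there, whether its suppression is shared with a second
#' sensitized background, and the relative suppressor strength (ratio of
#' SD-corrected scores, secondary / primary). Strains absent from a
#' secondary screen are marked not-determined (`NA`).
#'
#' @param primary_scores [run_screen()] output for the primary drug in the
#'   hypersensitive background; suppressors are called from it.
#' @param counter_scores optional [run_screen()] output for the counter drug
#'   (e.g. HU) in the same background.
#' @param secondary_scores optional [run_screen()] output for the primary
#'   drug in a second background (e.g. ura8d).
#' @param config a [call_config()] with the suppressor thresholds.
#' @return data.frame with columns `strain`, `score_primary`,
#'   `score_counter`, `score_secondary`, `is_suppressor_counter`,
#'   `shared_with_secondary`, `relative_strength`; exactly one row per
#'   called suppressor.
#' @export
cross_tabulate <- function(primary_scores,
                           counter_scores = NULL,
                           secondary_scores = NULL,
                           config = call_config(effect_floor = 0.5)) {
  sup <- call_suppressors(primary_scores, config)
  out <- data.frame(
    strain = sup$strain,
    score_primary = sup$score,
    score_counter = NA_real_,
    score_secondary = NA_real_,
    is_suppressor_counter = NA,
    shared_with_secondary = NA,
    relative_strength = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(counter_scores)) {
    i <- match(out$strain, counter_scores$strain)
    out$score_counter <- counter_scores$score[i]
    counter_sup <- call_suppressors(counter_scores, config)
    out$is_suppressor_counter <- ifelse(is.na(i), NA,
                                        out$strain %in% counter_sup$strain)
  }
  if (!is.null(secondary_scores)) {
    i <- match(out$strain, secondary_scores$strain)
    out$score_secondary <- secondary_scores$score[i]
    secondary_sup <- call_suppressors(secondary_scores, config)
    out$shared_with_secondary <- ifelse(is.na(i), NA,
                                        out$strain %in% secondary_sup$strain)
    out$relative_strength <- ifelse(
      is.na(out$score_secondary) | is.na(out$score_primary) |
        out$score_primary == 0,
      NA_real_, out$score_secondary / out$score_primary
    )
  }
  rownames(out) <- NULL
  out
}
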