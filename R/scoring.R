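#' Significance-calling configuration
#'
#' @param sd_multiplier `k` of the two-SD rule and of the score denominator:
#'   an interaction is significant when `|dMEAN| > k * sSD`. Default 2.
#' @param effect_floor minimum `|S|` (SD-corrected score, log2 scale) for a
#'   call; 0.05 suits sensitivity/resistance screens, 0.5 the stringent
#'   suppressor criterion.
#' @param fdr_alpha Benjamini-Hochberg threshold on adjusted p-values for the
#'   validation / suppressor filter. Default 0.10.
#' @param log2_floor pseudo-size substituted for normalized sizes below it
#'   before the log2 transform, so dead colonies map to a finite, strongly
#'   negative fitness. Default 0.01 (log2 = -6.64).
#' @param welch use the Welch (unequal-variance) t-test instead of the
#'   classical Student form. Default `FALSE`.
#' @return An object of class `call_config`.
#' @export
call_config <- function(sd_multiplier = 2, effect_floor = 0.05,
                        fdr_alpha = 0.10, log2_floor = 0.01,
                        welch = FALSE) {
  stopifnot(sd_multiplier > 0, effect_floor >= 0,
            fdr_alpha > 0, fdr_alpha < 1, log2_floor > 0)
  structure(
    list(sd_multiplier = sd_multiplier, effect_floor = effect_floor,
         fdr_alpha = fdr_alpha, log2_floor = log2_floor,
         welch = isTRUE(welch)),
    class = "call_config"
  )
}

#' Replicate-level log2 fitness values per strain
#'
#' Joins normalized plates against the strain layout and returns one row per
#' surviving (strain, background, condition, replicate) with
#' `value = log2(max(normalized size, log2_floor))`. Missing colonies are
#' dropped; `EMPTY`/`BORDER` positions and jackpot-excluded
#' (strain, replicate) pairs are removed. A jackpot exclusion applies to all
#' conditions of its background.
#'
#' @param plates list of normalized [plate_grid()]s.
#' @param design a [screen_design()].
#' @param exclusions optional data.frame from [jackpot_filter()].
#' @param log2_floor pseudo-size for the log transform (see [call_config()]).
#' @return data.frame with columns `strain`, `background`, `condition`,
#'   `replicate`, `value`.
#' @export
strain_values <- function(plates, design, exclusions = NULL,
                          log2_floor = 0.01) {
  long <- plates_to_long(plates)
  lay <- design$layout
  long$strain <- lay$strain[match(
    paste(long$plate_id, long$row, long$col, sep = "\r"),
    paste(lay$plate_id, lay$row, lay$col, sep = "\r")
  )]
  orphan <- is.na(long$strain) & !is.na(long$size)
  if (any(orphan)) {
    warning(sprintf("%d measured position(s) absent from the layout; skipped",
                    sum(orphan)))
  }
  long <- long[!is.na(long$strain) & !long$strain %in% c("EMPTY", "BORDER") &
                 !is.na(long$size), , drop = FALSE]
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    drop <- paste(long$background, long$strain, long$replicate, sep = "\r") %in%
      paste(exclusions$background, exclusions$strain, exclusions$replicate,
            sep = "\r")
    long <- long[!drop, , drop = FALSE]
  }
  long$value <- log2(pmax(long$size, log2_floor))
  # average technical duplicates within a replicate, if any
  out <- stats::aggregate(value ~ strain + background + condition + replicate,
                          data = long, FUN = mean)
  out[order(out$strain, out$background, out$condition, out$replicate), ,
      drop = FALSE]
}

#' Per-strain mean and SD of log2 fitness
#'
#' @inheritParams strain_values
#' @return data.frame with columns `strain`, `background`, `condition`, `n`,
#'   `mean`, `sd` (sample SD, `NA` for `n < 2`).
#' @export
strain_stats <- function(plates, design, exclusions = NULL,
                         log2_floor = 0.01) {
  values <- strain_values(plates, design, exclusions, log2_floor)
  summarize_values(values)
}

summarize_values <- function(values) {
  key <- interaction(values$strain, values$background, values$condition,
                     drop = TRUE, sep = "\r")
  n <- tapply(values$value, key, length)
  mu <- tapply(values$value, key, mean)
  sdv <- tapply(values$value, key, stats::sd)
  parts <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  out <- data.frame(
    strain = parts[, 1L], background = parts[, 2L], condition = parts[, 3L],
    n = as.integer(n), mean = as.numeric(mu), sd = as.numeric(sdv),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$strain, out$background, out$condition), , drop = FALSE]
}

#' Treated-vs-reference effect and pooled spread
#'
#' `delta_mean = mean_treated - mean_untreated` (log2 scale) and
#' `sum_sd = sd_treated + sd_untreated`. `sum_sd` is `NA` (the strain is
#' uncallable) when either condition has fewer than two replicates.
#'
#' @param stat_treated,stat_untreated single rows of [strain_stats()] output
#'   for the same strain and background (vectorized over aligned rows).
#' @return data.frame with columns `delta_mean`, `sum_sd`.
#' @export
delta_mean <- function(stat_treated, stat_untreated) {
  stopifnot(all(stat_treated$strain == stat_untreated$strain),
            all(stat_treated$background == stat_untreated$background))
  dm <- stat_treated$mean - stat_untreated$mean
  ss <- ifelse(stat_treated$n >= 2L & stat_untreated$n >= 2L,
               stat_treated$sd + stat_untreated$sd, NA_real_)
  data.frame(delta_mean = dm, sum_sd = ss)
}

#' Standard-deviation-corrected interaction score
#'
#' Shrinks the raw log2 effect toward zero in proportion to replicate
#' spread:
#' \deqn{S = \frac{\Delta MEAN}{1 + k\,\Sigma SD / |\Delta MEAN|}}
#' so that `S = delta_mean` for noise-free data (`sum_sd = 0`), `S = 0` when
#' `delta_mean = 0` (continuous limit), the sign of the effect is preserved,
#' and `|S| <= |delta_mean|` always. `S` is strictly decreasing in `sum_sd`
#' for a fixed nonzero effect.
#'
#' @param delta_mean log2 effect(s).
#' @param sum_sd summed SDs, >= 0 (vectorized; `NA` propagates).
#' @param k shrinkage constant; default 2, matching the two-SD call rule.
#' @return Numeric vector of scores.
#' @examples
#' sd_corrected_score(1.0, 0.5)   # 0.5
#' sd_corrected_score(-1.0, 0.5)  # -0.5
#' @export
sd_corrected_score <- function(delta_mean, sum_sd, k = 2) {
  stopifnot(k > 0, all(sum_sd >= 0, na.rm = TRUE))
  out <- ifelse(delta_mean == 0, 0,
                delta_mean / (1 + k * sum_sd / abs(delta_mean)))
  out[is.na(delta_mean)] <- NA_real_
  out
}

#' Call an interaction from effect, spread and score
#'
#' Significant iff `|delta_mean| > k * sum_sd` (the two-SD separation rule)
#' *and* `|score| >= effect_floor` (minimum-effect filter). Significant
#' negative effects are `"sensitive"`, positive `"resistant"`, everything
#' else `"none"`. Strains with undefined `sum_sd` return `NA` (uncallable).
#'
#' @param delta_mean,sum_sd,score aligned numeric vectors.
#' @param config a [call_config()].
#' @return Character vector of calls.
#' @export
call_interaction <- function(delta_mean, sum_sd, score,
                             config = call_config()) {
  stopifnot(inherits(config, "call_config"))
  sig <- abs(delta_mean) > config$sd_multiplier * sum_sd &
    abs(score) >= config$effect_floor
  out <- ifelse(is.na(sig), NA_character_,
                ifelse(sig & delta_mean < 0, "sensitive",
                       ifelse(sig & delta_mean > 0, "resistant", "none")))
  out
}

#' Two-sided unpaired t-test p-value
#'
#' Classical Student form by default (`welch = TRUE` for the
#' unequal-variance correction). The degenerate zero-variance case, which
#' the standard test refuses, is resolved by its limit: p = 1 for equal
#' means, p = 0 otherwise.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch correction?
#' @return p-value in `[0, 1]`.
#' @export
two_sample_t_test <- function(values_a, values_b, welch = FALSE) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    return(if (mean(values_a) == mean(values_b)) 1 else 0)
  }
  stats::t.test(values_a, values_b, var.equal = !welch)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, `q_(i) = min_{j >= i} m p_(j) / j` clipped at
#' 1, preserving the order of the inputs. `NA` p-values yield `NA` q-values
#' without entering the family.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
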