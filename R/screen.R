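#' Run the full interaction-scoring pipeline on a set of plates
#'
#' End-to-end composition: normalize every plate (cascade of
#' [normalize_plate()]), flag jackpot colonies on the configured reference
#' condition per background, compute replicate-level log2 fitness, the
#' treated-vs-reference effect `delta_mean` and spread `sum_sd`, the
#' SD-corrected score, the two-SD + effect-floor call, a two-sided unpaired
#' t-test per strain, and Benjamini-Hochberg q-values over all callable
#' strains within each background. The result is sorted background by
#' background from most sensitive (lowest score) to most resistant, the rank
#' axis of a screen plot; uncallable strains (fewer than two surviving
#' replicates in either condition) are retained at the end with `call = NA`.
#'
#' @param plates list of raw [plate_grid()]s covering the treated and
#'   reference conditions (and the jackpot reference condition, if used) of
#'   one or more backgrounds.
#' @param design a [screen_design()].
#' @param treated_condition,reference_condition condition labels compared as
#'   treated vs untreated.
#' @param norm_config a [normalization_config()]; set its
#'   `jackpot_condition` to enable the jackpot filter.
#' @param call_cfg a [call_config()].
#' @return data.frame with one row per strain x background and columns
#'   `strain`, `background`, `condition_pair`, `n_treated`, `n_untreated`,
#'   `delta_mean`, `sum_sd`, `score`, `p_value`, `q_value`, `call`. The
#'   treated/reference condition labels and the jackpot exclusions are
#'   attached as attributes `"treated_condition"`, `"reference_condition"`,
#'   `"exclusions"`.
#' @export
run_screen <- function(plates, design,
                       treated_condition, reference_condition,
                       norm_config = normalization_config(),
                       call_cfg = call_config()) {
  stopifnot(inherits(design, "screen_design"),
            inherits(norm_config, "normalization_config"),
            inherits(call_cfg, "call_config"))
  conds <- vapply(plates, function(p) p$condition, character(1))
  if (!treated_condition %in% conds || !reference_condition %in% conds) {
    stop("plates must include both the treated and the reference condition")
  }

  normalized <- lapply(plates, normalize_plate, config = norm_config,
                       design = design)

  exclusions <- NULL
  if (!is.null(norm_config$jackpot_condition)) {
    bgs <- unique(vapply(normalized, function(p) p$background, character(1)))
    exclusions <- do.call(rbind, lapply(bgs, function(bg) {
      sub <- Filter(function(p) p$background == bg, normalized)
      jackpot_filter(sub, design, norm_config$jackpot_condition,
                     m = norm_config$jackpot_factor)
    }))
  }

  values <- strain_values(normalized, design, exclusions, call_cfg$log2_floor)
  values <- values[values$condition %in% c(treated_condition,
                                           reference_condition), , drop = FALSE]
  stats_tab <- summarize_values(values)

  tr <- stats_tab[stats_tab$condition == treated_condition, , drop = FALSE]
  un <- stats_tab[stats_tab$condition == reference_condition, , drop = FALSE]
  key_tr <- paste(tr$strain, tr$background, sep = "\r")
  key_un <- paste(un$strain, un$background, sep = "\r")
  keys <- sort(union(key_tr, key_un))
  tr <- tr[match(keys, key_tr), , drop = FALSE]
  un <- un[match(keys, key_un), , drop = FALSE]
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))

  n_tr <- ifelse(is.na(tr$n), 0L, tr$n)
  n_un <- ifelse(is.na(un$n), 0L, un$n)
  dm <- tr$mean - un$mean
  ss <- ifelse(n_tr >= 2L & n_un >= 2L, tr$sd + un$sd, NA_real_)
  s <- sd_corrected_score(dm, ss, k = call_cfg$sd_multiplier)
  call <- call_interaction(dm, ss, s, call_cfg)

  # per-strain t-test on the replicate-level log2 values
  vkey <- paste(values$strain, values$background, sep = "\r")
  pvals <- vapply(seq_along(keys), function(i) {
    v <- values[vkey == keys[i], , drop = FALSE]
    a <- v$value[v$condition == treated_condition]
    b <- v$value[v$condition == reference_condition]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    two_sample_t_test(a, b, welch = call_cfg$welch)
  }, numeric(1))

  out <- data.frame(
    strain = parts[, 1L], background = parts[, 2L],
    condition_pair = paste0(treated_condition, "_vs_", reference_condition),
    n_treated = as.integer(n_tr), n_untreated = as.integer(n_un),
    delta_mean = dm, sum_sd = ss, score = s, p_value = pvals,
    q_value = NA_real_, call = call,
    stringsAsFactors = FALSE
  )
  for (bg in unique(out$background)) {
    idx <- which(out$background == bg & !is.na(out$p_value))
    out$q_value[idx] <- bh_adjust(out$p_value[idx])
  }

  ord <- order(out$background, is.na(out$score), out$score, out$strain,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "treated_condition") <- treated_condition
  attr(out, "reference_condition") <- reference_condition
  attr(out, "exclusions") <- exclusions
  out
}
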