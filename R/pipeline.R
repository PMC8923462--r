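#' Read a screen configuration from YAML
#'
#' One flat YAML file holds the three parameter groups: `normalization:`
#' (fields of [normalization_config()]), `calling:` (fields of
#' [call_config()]) and `screen:` (design/simulation parameters:
#' `n_strains`, `n_rows`, `n_cols`, `backgrounds`, `conditions`,
#' `replicates`, `treated_condition`, `reference_condition`, and optional
#' `simulate:` overrides for [synthetic_truth()]). Missing fields take the
#' package defaults; unknown fields are a validation error, reported all at
#' once.
#'
#' @param path path to the YAML file.
#' @return list with elements `norm` ([normalization_config()]), `call`
#'   ([call_config()]), `screen` (named list).
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  problems <- character()
  known_norm <- names(formals(normalization_config))
  known_call <- names(formals(call_config))
  known_screen <- c("n_strains", "n_rows", "n_cols", "backgrounds",
                    "conditions", "replicates", "border",
                    "treated_condition", "reference_condition", "simulate")
  bad <- setdiff(names(raw$normalization), known_norm)
  if (length(bad)) problems <- c(problems,
    sprintf("normalization: unknown field(s) %s", paste(bad, collapse = ", ")))
  bad <- setdiff(names(raw$calling), known_call)
  if (length(bad)) problems <- c(problems,
    sprintf("calling: unknown field(s) %s", paste(bad, collapse = ", ")))
  bad <- setdiff(names(raw$screen), known_screen)
  if (length(bad)) problems <- c(problems,
    sprintf("screen: unknown field(s) %s", paste(bad, collapse = ", ")))
  if (length(problems) > 0L) {
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "))
  }
  list(
    norm = do.call(normalization_config, raw$normalization %||% list()),
    call = do.call(call_config, raw$calling %||% list()),
    screen = raw$screen %||% list()
  )
}

default_screen_params <- function(screen) {
  utils::modifyList(list(
    n_strains = 1536L, n_rows = 32L, n_cols = 48L,
    backgrounds = "query", conditions = c("untreated", "DON"),
    replicates = 4L, border = FALSE,
    treated_condition = "DON", reference_condition = "untreated",
    simulate = list()
  ), screen)
}

#' Run a complete simulated screen and write its outputs
#'
#' The `run_all` engine: builds the design, simulates plates with
#' [generate_screen()], scores them with [run_screen()], and writes to
#' `out_dir` the score table (`scores.tsv`), the ranked table
#' (`ranked.tsv`), the called-suppressor table (`suppressors.tsv`), the
#' ground truth (`truth.json`) and a run manifest (`manifest.json`)
#' recording package version, seed, full configuration and the MD5 checksum
#' of every output — rerunning with the same manifest inputs reproduces
#' every table byte for byte.
#'
#' @param config list as returned by [read_screen_config()] (or built
#'   in-code from [normalization_config()], [call_config()] and a `screen`
#'   list).
#' @param out_dir output directory, created if needed.
#' @param seed integer seed for the simulation.
#' @return Invisibly, a list with the scores data.frame and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  scr <- default_screen_params(config$screen %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- make_screen_design(
    n_strains = scr$n_strains, n_rows = scr$n_rows, n_cols = scr$n_cols,
    backgrounds = scr$backgrounds, conditions = scr$conditions,
    replicates = scr$replicates, border = isTRUE(scr$border)
  )
  sim_args <- utils::modifyList(
    list(design = design, seed = as.integer(seed),
         jackpot_condition = config$norm$jackpot_condition),
    scr$simulate %||% list()
  )
  if (!is.null(sim_args$effects) && is.list(sim_args$effects) &&
      !is.data.frame(sim_args$effects)) {
    sim_args$effects <- as.data.frame(sim_args$effects,
                                      stringsAsFactors = FALSE)
  }
  truth <- do.call(synthetic_truth, sim_args)
  sim <- generate_screen(design, truth)
  scores <- run_screen(sim$plates, design,
                       treated_condition = scr$treated_condition,
                       reference_condition = scr$reference_condition,
                       norm_config = config$norm, call_cfg = config$call)

  paths <- c(scores = file.path(out_dir, "scores.tsv"),
             ranked = file.path(out_dir, "ranked.tsv"),
             suppressors = file.path(out_dir, "suppressors.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_scores(scores, paths[["scores"]])
  ranked <- rank_table(scores)
  utils::write.table(ranked, paths[["ranked"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sup <- call_suppressors(scores, config$call)
  utils::write.table(sup, paths[["suppressors"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(effects = sim$truth$effects, jackpots = sim$truth$jackpots,
         seed = seed,
         noise_sd = sim$truth$noise_sd,
         jackpot_condition = sim$truth$jackpot_condition),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, null = "null"
  )

  manifest <- list(
    package = "pinscreen",
    version = as.character(utils::packageVersion("pinscreen")),
    seed = as.integer(seed),
    screen = scr[setdiff(names(scr), "simulate")],
    normalization = config$norm[!vapply(config$norm, is.null, logical(1))],
    calling = unclass(config$call),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(unname(paths))), basename(unname(paths))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scores = scores, suppressors = sup, manifest = manifest))
}
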