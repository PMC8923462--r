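#' Read a colony-quantification table into a plate grid
#'
#' Supports the three table shapes colony quantifiers and spreadsheets
#' commonly emit:
#'
#' * `"quantifier-dat"`: tab-delimited with `#`-prefixed comment header lines,
#'   then a header row and columns `row`, `col`, `size` (extra columns are
#'   ignored) — the format of grid-based colony quantifiers.
#' * `"long-csv"`: CSV with columns `row`, `col`, `size`.
#' * `"wide-csv"`: a bare `n_rows x n_cols` numeric CSV matrix, no header.
#'
#' Grid extent is inferred from the data (or forced with `n_rows`/`n_cols`);
#' positions absent from the file, or with a non-numeric size, become missing
#' (`NA`). A size of 0 is kept as a measured dead colony.
#'
#' @param path path to the table file.
#' @param dialect one of `"quantifier-dat"`, `"long-csv"`, `"wide-csv"`.
#' @param plate_id,background,condition,replicate metadata attached to the
#'   returned plate (see [plate_grid()]).
#' @param n_rows,n_cols optional declared plate extent; defaults to the
#'   maximum row/column index present in the file.
#' @return A [plate_grid()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
#'                      size = c(100, 200, 0, 150)), f, row.names = FALSE)
#' read_colony_table(f, "long-csv", plate_id = "P1", background = "sml1d",
#'                   condition = "untreated", replicate = 1)
#' @export
read_colony_table <- function(path,
                              dialect = c("long-csv", "wide-csv", "quantifier-dat"),
                              plate_id = "P01",
                              background = "query",
                              condition = "untreated",
                              replicate = 1L,
                              n_rows = NULL, n_cols = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))

  if (dialect == "wide-csv") {
    m <- as.matrix(utils::read.csv(path, header = FALSE,
                                   colClasses = "character"))
    size <- matrix(suppressWarnings(as.numeric(m)), nrow(m), ncol(m))
    return(plate_grid(size, plate_id, background, condition, replicate))
  }

  tab <- switch(dialect,
    "long-csv" = utils::read.csv(path, stringsAsFactors = FALSE),
    "quantifier-dat" = utils::read.delim(path, comment.char = "#",
                                         stringsAsFactors = FALSE)
  )
  names(tab) <- tolower(names(tab))
  req <- c("row", "col", "size")
  if (!all(req %in% names(tab))) {
    stop(sprintf("%s: required columns row, col, size not all present (found: %s)",
                 path, paste(names(tab), collapse = ", ")))
  }
  r <- as.integer(tab$row)
  c_ <- as.integer(tab$col)
  if (anyNA(r) || anyNA(c_) || any(r < 1L) || any(c_ < 1L)) {
    stop(sprintf("%s: row/col indices must be 1-based positive integers", path))
  }
  key <- paste(r, c_, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("%s: duplicate entry for position (%d, %d)", path, r[i], c_[i]))
  }
  sz <- suppressWarnings(as.numeric(tab$size))
  if (any(!is.na(sz) & sz < 0)) {
    i <- which(!is.na(sz) & sz < 0)[1L]
    stop(sprintf("%s: negative colony size at position (%d, %d)", path, r[i], c_[i]))
  }
  nr <- as.integer(n_rows %||% max(r))
  nc <- as.integer(n_cols %||% max(c_))
  if (max(r) > nr || max(c_) > nc) {
    stop(sprintf("%s: data exceed the declared %d x %d extent", path, nr, nc))
  }
  size <- matrix(NA_real_, nr, nc)
  size[cbind(r, c_)] <- sz
  plate_grid(size, plate_id, background, condition, replicate)
}

#' Read a strain layout file
#'
#' Reads a CSV or TSV mapping grid positions to strain IDs (columns
#' `plate_id`, `row`, `col`, `strain`; the separator is sniffed from the
#' header line). Strain IDs are preserved verbatim; `"EMPTY"` and `"BORDER"`
#' mark non-library positions. Position collisions are a hard error.
#'
#' @param path path to the layout file.
#' @param backgrounds,conditions,replicates screen structure attached to the
#'   returned design (see [screen_design()]).
#' @return A [screen_design()].
#' @export
read_layout <- function(path,
                        backgrounds = "query",
                        conditions = c("untreated", "DON"),
                        replicates = 4L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  lay <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(lay) <- tolower(names(lay))
  if (length(replicates) == 1L && length(backgrounds) > 1L) {
    replicates <- rep(replicates, length(backgrounds))
  }
  names(replicates) <- backgrounds
  screen_design(lay, backgrounds, conditions, replicates)
}

#' Write an interaction-score table
#'
#' Writes one tab-delimited row per strain with the score components and the
#' significance call. Values round-trip at full double precision through
#' [read_scores()].
#'
#' @param scores data.frame as returned by [run_screen()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  cols <- c("strain", "background", "condition_pair", "n_treated",
            "n_untreated", "delta_mean", "sum_sd", "score", "p_value",
            "q_value", "call")
  missing_cols <- setdiff(cols, names(scores))
  if (length(missing_cols) > 0L) {
    stop(sprintf("scores table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- scores[, cols, drop = FALSE]
  for (col in c("delta_mean", "sum_sd", "score", "p_value", "q_value")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
    out[[col]][out[[col]] == "NA"] <- "NA"
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write score table to '%s'", path))
  invisible(path)
}

#' Read back an interaction-score table written by [write_scores()]
#' @param path path to the TSV file.
#' @return A data.frame with the same columns and values.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(
                             strain = "character", background = "character",
                             condition_pair = "character",
                             n_treated = "integer", n_untreated = "integer",
                             delta_mean = "numeric", sum_sd = "numeric",
                             score = "numeric", p_value = "numeric",
                             q_value = "numeric", call = "character"
                           ))
  tab
}

#' Read a whole-screen long table into plates
#'
#' Import adapter for screen-level colony-size exports (one row per colony
#' across every plate, condition and replicate), the shape supplementary
#' colony-size tables take once exported to CSV/TSV. Required columns:
#' `plate_id`, `background`, `condition`, `replicate`, `row`, `col`, `size`;
#' extra columns are ignored, and the separator is sniffed from the header.
#' Each (plate_id, background, condition, replicate) combination becomes one
#' [plate_grid()] via the long-csv rules (non-numeric sizes become missing,
#' duplicates and negatives are hard errors).
#'
#' @param path path to the table.
#' @return list of [plate_grid()]s.
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  names(tab) <- tolower(names(tab))
  req <- c("plate_id", "background", "condition", "replicate", "row", "col",
           "size")
  if (!all(req %in% names(tab))) {
    stop(sprintf("%s: required columns missing: %s", path,
                 paste(setdiff(req, names(tab)), collapse = ", ")))
  }
  groups <- split(tab, interaction(tab$plate_id, tab$background,
                                   tab$condition, tab$replicate, drop = TRUE))
  nr <- max(as.integer(tab$row))
  nc <- max(as.integer(tab$col))
  plates <- lapply(groups, function(g) {
    f <- tempfile(fileext = ".csv")
    on.exit(unlink(f))
    utils::write.csv(g[, c("row", "col", "size")], f, row.names = FALSE)
    read_colony_table(f, "long-csv",
                      plate_id = g$plate_id[1L], background = g$background[1L],
                      condition = g$condition[1L],
                      replicate = as.integer(g$replicate[1L]),
                      n_rows = nr, n_cols = nc)
  })
  names(plates) <- NULL
  plates
}
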