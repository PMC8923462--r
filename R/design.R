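#' Screen design: strain layout plus replicate structure
#'
#' A `screen_design` binds the strain layout (which library strain sits at
#' each grid position of each library plate) to the set of query backgrounds,
#' growth conditions and per-background replicate counts that define a
#' chemogenomic screen. The reserved strain IDs `"EMPTY"` and `"BORDER"` mark
#' positions that carry no library mutant; they are excluded from quantile
#' and scoring computations but still normalized.
#'
#' @param layout data.frame with columns `plate_id`, `row`, `col`, `strain`;
#'   exactly one entry per grid position of every declared plate.
#' @param backgrounds character vector of query genotype labels.
#' @param conditions character vector of condition labels.
#' @param replicates named integer vector, replicate count per background
#'   (all >= 1; scoring requires >= 2).
#' @return An object of class `screen_design`.
#' @seealso [make_screen_design()] to build a design programmatically,
#'   [read_layout()] to read a layout file.
#' @export
screen_design <- function(layout, backgrounds, conditions, replicates) {
  req <- c("plate_id", "row", "col", "strain")
  if (!is.data.frame(layout) || !all(req %in% names(layout))) {
    stop("`layout` must be a data.frame with columns plate_id, row, col, strain")
  }
  layout$plate_id <- as.character(layout$plate_id)
  layout$row <- as.integer(layout$row)
  layout$col <- as.integer(layout$col)
  layout$strain <- as.character(layout$strain)
  key <- paste(layout$plate_id, layout$row, layout$col, sep = "\r")
  if (anyDuplicated(key)) {
    d <- layout[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "layout collision: two strains assigned to plate '%s' position (%d, %d)",
      d$plate_id, d$row, d$col
    ))
  }
  if (any(layout$row < 1L) || any(layout$col < 1L)) {
    stop("layout rows and columns must be 1-based positive integers")
  }
  if (is.null(names(replicates)) && length(replicates) == length(backgrounds)) {
    names(replicates) <- backgrounds
  }
  replicates <- vapply(replicates, as.integer, integer(1))
  if (any(replicates < 1L)) stop("replicate counts must be >= 1")
  structure(
    list(
      layout = layout,
      backgrounds = as.character(backgrounds),
      conditions = as.character(conditions),
      replicates = replicates
    ),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  n_lib <- sum(!x$layout$strain %in% c("EMPTY", "BORDER"))
  cat(sprintf(
    "<screen_design> %d plates, %d positions (%d library) | backgrounds: %s | conditions: %s\n",
    length(unique(x$layout$plate_id)), nrow(x$layout), n_lib,
    paste(x$backgrounds, collapse = ", "), paste(x$conditions, collapse = ", ")
  ))
  invisible(x)
}

# Strain at each position of one plate, as a character matrix aligned with the
# plate's size matrix. Errors if the layout references positions outside the
# plate extent.
layout_matrix <- function(design, plate_id, n_rows, n_cols) {
  lay <- design$layout[design$layout$plate_id == plate_id, , drop = FALSE]
  if (nrow(lay) == 0L) {
    stop(sprintf("plate '%s' has no layout entries", plate_id))
  }
  if (any(lay$row > n_rows) || any(lay$col > n_cols)) {
    stop(sprintf(
      "layout for plate '%s' references positions outside the %d x %d extent",
      plate_id, n_rows, n_cols
    ))
  }
  m <- matrix(NA_character_, n_rows, n_cols)
  m[cbind(lay$row, lay$col)] <- lay$strain
  m
}

# Logical matrix: TRUE for library (non-EMPTY, non-BORDER) positions.
library_mask <- function(design, plate_id, n_rows, n_cols) {
  m <- layout_matrix(design, plate_id, n_rows, n_cols)
  !is.na(m) & !(m %in% c("EMPTY", "BORDER"))
}

#' Build a rectangular screen design
#'
#' Lays out `n_strains` library strains row-major across as many
#' `n_rows x n_cols` plates as needed. With `border = TRUE` the outer ring of
#' each plate is reserved as `"BORDER"` (the usual control ring of pinned
#' arrays) and library strains fill the interior. Unused trailing positions
#' are `"EMPTY"`.
#'
#' @param n_strains number of library strains (named `strain0001`, ...).
#' @param n_rows,n_cols plate grid dimensions (default 32 x 48 = 1536 density).
#' @param backgrounds,conditions,replicates passed to [screen_design()].
#' @param border reserve the outer ring of each plate as `"BORDER"`?
#' @return A `screen_design`.
#' @examples
#' d <- make_screen_design(1536, backgrounds = "sml1d_mec1d",
#'                         conditions = c("untreated", "DON"), replicates = 4)
#' d
#' @export
make_screen_design <- function(n_strains,
                               n_rows = 32L, n_cols = 48L,
                               backgrounds = "query",
                               conditions = c("untreated", "DON"),
                               replicates = 4L,
                               border = FALSE) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  strains <- sprintf("strain%04d", seq_len(n_strains))
  if (length(replicates) == 1L && length(backgrounds) > 1L) {
    replicates <- rep(replicates, length(backgrounds))
  }
  names(replicates) <- backgrounds

  is_border <- function(r, c) {
    border & (r == 1L | r == n_rows | c == 1L | c == n_cols)
  }
  per_plate <- if (border) (n_rows - 2L) * (n_cols - 2L) else n_rows * n_cols
  n_plates <- ceiling(n_strains / per_plate)

  pieces <- vector("list", n_plates)
  used <- 0L
  for (p in seq_len(n_plates)) {
    grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
    grid <- grid[order(grid$row, grid$col), ]
    bord <- is_border(grid$row, grid$col)
    strain <- rep("EMPTY", nrow(grid))
    strain[bord] <- "BORDER"
    slots <- which(!bord)
    take <- min(length(slots), n_strains - used)
    if (take > 0L) {
      strain[slots[seq_len(take)]] <- strains[used + seq_len(take)]
      used <- used + take
    }
    pieces[[p]] <- data.frame(
      plate_id = sprintf("P%02d", p),
      row = grid$row, col = grid$col, strain = strain,
      stringsAsFactors = FALSE
    )
  }
  screen_design(do.call(rbind, pieces), backgrounds, conditions, replicates)
}
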