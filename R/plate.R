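#' Colony-size grid for one pinned plate
#'
#' A `plate_grid` holds the quantified colony sizes of a single pinned agar
#' plate as an `n_rows x n_cols` numeric matrix, tagged with the screen
#' metadata needed to place it in a design: query background, growth
#' condition, and replicate number. Missing colonies (positions the
#' quantifier could not measure) are `NA`; a size of 0 is a measured dead
#' colony and is kept as data.
#'
#' Grid coordinates are 1-based and row-major: row 1 is the top of the plate,
#' column 1 the left, matching the convention of colony-quantification tools.
#'
#' @param size numeric matrix of colony sizes (pixel areas); `NA` marks a
#'   missing position. All finite values must be >= 0.
#' @param plate_id character scalar identifying the library plate layout this
#'   physical plate was pinned from.
#' @param background character scalar, query genotype label
#'   (e.g. `"sml1d_mec1d"`).
#' @param condition character scalar, growth condition (e.g. `"untreated"`,
#'   `"DON"`, `"HU"`).
#' @param replicate positive integer replicate number.
#' @return An object of class `plate_grid`.
#' @examples
#' p <- plate_grid(matrix(c(100, 200, 0, 150), 2, 2, byrow = TRUE),
#'                 plate_id = "P1", background = "sml1d",
#'                 condition = "untreated", replicate = 1)
#' p$size
#' @export
plate_grid <- function(size, plate_id, background, condition, replicate) {
  if (!is.matrix(size) || !is.numeric(size)) {
    stop("`size` must be a numeric matrix")
  }
  storage.mode(size) <- "double"
  bad <- which(!is.na(size) & (!is.finite(size) | size < 0), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "plate '%s': negative or non-finite colony size at row %d, col %d",
      plate_id, bad[1L, 1L], bad[1L, 2L]
    ))
  }
  replicate <- as.integer(replicate)
  stopifnot(length(replicate) == 1L, replicate >= 1L)
  structure(
    list(
      plate_id = as.character(plate_id),
      background = as.character(background),
      condition = as.character(condition),
      replicate = replicate,
      size = size
    ),
    class = "plate_grid"
  )
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf(
    "<plate_grid> %s | %s | %s | replicate %d | %d x %d (%d missing)\n",
    x$plate_id, x$background, x$condition, x$replicate,
    nrow(x$size), ncol(x$size), sum(is.na(x$size))
  ))
  invisible(x)
}

#' @export
dim.plate_grid <- function(x) dim(x$size)

#' Convert a plate to long format
#'
#' One row per grid position (including missing ones, whose `size` is `NA`),
#' with the plate's metadata repeated.
#'
#' @param x a `plate_grid`.
#' @param row.names,optional,... ignored; present for the generic.
#' @return A data.frame with columns `plate_id`, `background`, `condition`,
#'   `replicate`, `row`, `col`, `size`.
#' @export
as.data.frame.plate_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  nr <- nrow(x$size)
  nc <- ncol(x$size)
  data.frame(
    plate_id = x$plate_id,
    background = x$background,
    condition = x$condition,
    replicate = x$replicate,
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    size = as.vector(x$size),
    stringsAsFactors = FALSE
  )
}

# Long table for a list of plates.
plates_to_long <- function(plates) {
  do.call(rbind, lapply(plates, as.data.frame))
}
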