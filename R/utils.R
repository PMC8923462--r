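# Internal matrix helpers shared by the positional-normalization steps.

# Shift a matrix by (dr, dc), padding with NA. Positive dr moves content down,
# positive dc moves it right, so out[r, c] == m[r - dr, c - dc].
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Median over a square window of half-width `radius`, clipped at plate edges.
# The focal cell itself is excluded so a lone outlier cannot normalize itself
# away. Cells where the window holds no other finite value return NA.
window_median_excl <- function(m, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[!(offs$dr == 0L & offs$dc == 0L), , drop = FALSE]
  stack <- vapply(
    seq_len(nrow(offs)),
    function(i) shift_mat(m, offs$dr[i], offs$dc[i]),
    m
  )
  apply(stack, c(1L, 2L), stats::median, na.rm = TRUE)
}

# Median of the 4-connected (rook) neighbors of every cell; NA where no
# neighbor holds a finite value (corner of a 1xN plate, all neighbors missing).
neighbor4_median <- function(m) {
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  stack <- vapply(offs, function(o) shift_mat(m, o[1L], o[2L]), m)
  apply(stack, c(1L, 2L), stats::median, na.rm = TRUE)
}

# Fraction of existing 4-neighbors of each cell that are NA in `m`
# (edge cells have fewer neighbors; the denominator adjusts).
neighbor4_na_fraction <- function(m) {
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  present <- matrix(1, nrow(m), ncol(m))
  n_nbr <- Reduce(`+`, lapply(offs, function(o) {
    s <- shift_mat(present, o[1L], o[2L])
    s[is.na(s)] <- 0
    s
  }))
  n_na <- Reduce(`+`, lapply(offs, function(o) {
    s <- shift_mat(m, o[1L], o[2L])
    inb <- shift_mat(present, o[1L], o[2L])
    as.numeric(is.na(s) & !is.na(inb))
  }))
  out <- n_na / pmax(n_nbr, 1)
  out[n_nbr == 0] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
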