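# Fixtures built in code: tiny plates, designs and score tables.

# A plate with every position set to `value` (or a supplied matrix).
flat_plate <- function(value = 100, n_rows = 8, n_cols = 12,
                       plate_id = "P01", background = "bg",
                       condition = "untreated", replicate = 1) {
  m <- if (is.matrix(value)) value else matrix(value, n_rows, n_cols)
  plate_grid(m, plate_id, background, condition, replicate)
}

# Full-plate design (no border) with strains strain0001.. filling row-major.
tiny_design <- function(n_rows = 8, n_cols = 12,
                        backgrounds = "bg",
                        conditions = c("untreated", "DON"),
                        replicates = 4) {
  make_screen_design(n_rows * n_cols, n_rows = n_rows, n_cols = n_cols,
                     backgrounds = backgrounds, conditions = conditions,
                     replicates = replicates)
}

# Plates for one background where strain values per replicate are set
# directly (bypassing artifacts): `sizes` is a named list
# condition -> matrix [replicate x strain] of normalized-scale sizes.
plates_from_values <- function(sizes, design, n_rows, n_cols) {
  strains <- design$layout$strain[order(design$layout$row, design$layout$col)]
  lay <- design$layout
  plates <- list()
  for (cond in names(sizes)) {
    m <- sizes[[cond]]
    for (r in seq_len(nrow(m))) {
      size <- matrix(NA_real_, n_rows, n_cols)
      i <- match(lay$strain, colnames(m))
      ok <- !is.na(i)
      size[cbind(lay$row[ok], lay$col[ok])] <- m[r, i[ok]]
      plates[[length(plates) + 1L]] <-
        plate_grid(size, lay$plate_id[1L], design$backgrounds[1L], cond, r)
    }
  }
  plates
}

# Independent quantile oracle: linear interpolation between order statistics
# (the type-7 definition), written from the formula.
oracle_quantile <- function(x, q) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force BH step-up oracle from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Textbook pooled-variance two-sided t-test oracle.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}
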