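test_that("percentile normalization divides by the interpolated quantile", {
  # constant plate: everything becomes exactly 1
  p <- percentile_normalize(flat_plate(100))
  expect_true(all(p$size == 1))

  # against an independently coded sort-and-interpolate oracle
  sizes <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100), 2, 5)
  p <- flat_plate(sizes, 2, 5)
  denom <- oracle_quantile(as.vector(sizes), 0.70)
  out <- percentile_normalize(p, 0.70)
  expect_equal(out$size, sizes / denom, tolerance = 1e-12)
  expect_equal(oracle_quantile(as.vector(out$size), 0.70), 1, tolerance = 1e-12)

  # scale invariance and the fixed point (idempotence)
  set.seed(2)
  m <- matrix(runif(96, 20, 300), 8, 12)
  a <- percentile_normalize(flat_plate(m))
  b <- percentile_normalize(flat_plate(7 * m))
  expect_equal(a$size, b$size, tolerance = 1e-12)
  expect_equal(percentile_normalize(a)$size, a$size, tolerance = 1e-12)

  # all positions dead or missing is a hard error naming the plate
  dead <- flat_plate(0, 4, 4, plate_id = "Pbad")
  expect_error(percentile_normalize(dead), "Pbad")
})

test_that("quantile is computed over library positions but all are scaled", {
  d <- make_screen_design(6 * 10, n_rows = 8, n_cols = 12, border = TRUE)
  m <- matrix(100, 8, 12)
  ring <- row(m) %in% c(1, 8) | col(m) %in% c(1, 12)
  m[ring] <- 400  # border colonies systematically larger
  out <- percentile_normalize(flat_plate(m), design = d)
  expect_true(all(out$size[!ring] == 1))   # quantile anchored on library
  expect_true(all(out$size[ring] == 4))    # borders scaled, not anchored
})

test_that("row/column correction flattens gradients and spares flat plates", {
  # deterministic row gradient: row r uniformly 100 * (1 + 0.1 r)
  m <- matrix(0, 8, 12)
  for (r in 1:8) m[r, ] <- 100 * (1 + 0.1 * r)
  out <- row_col_normalize(flat_plate(m))
  row_med <- apply(out$size, 1, median)
  expect_lt(diff(range(row_med)) / mean(row_med), 1e-9)

  # separable row x column gradient: both axes flattened
  m2 <- outer(1 + 0.1 * (1:8), 1 + 0.05 * (1:12)) * 100
  out2 <- row_col_normalize(flat_plate(m2))
  expect_lt(diff(range(apply(out2$size, 1, median))), 1e-9)
  expect_lt(diff(range(apply(out2$size, 2, median))), 1e-9)

  # no gradient: i.i.d. sizes come out close to the input
  set.seed(5)
  m3 <- matrix(100 * 2^rnorm(384, 0, 0.1), 16, 24)
  out3 <- row_col_normalize(flat_plate(m3, 16, 24))
  expect_true(all(abs(out3$size / m3 - 1) < 0.15))

  # single-row plate, enumerated by hand: the row factor is
  # median(row)/median(plate) = 1, and each column's factor is its own
  # value / plate median
  m4 <- matrix(c(1, 2, 3, 4), 1, 4)
  out4 <- row_col_normalize(flat_plate(m4, 1, 4))
  expect_equal(as.vector(out4$size), rep(median(c(1, 2, 3, 4)), 4))
})

test_that("entirely dead rows get factor 1 with a warning", {
  m <- matrix(100, 4, 6)
  m[2, ] <- 0
  expect_warning(out <- row_col_normalize(flat_plate(m, 4, 6)), "row")
  expect_equal(out$size[2, ], rep(0, 6))
  expect_equal(out$size[1, ], rep(100, 6))
})

test_that("neighborhood correction removes smooth fields, keeps outliers", {
  # constant plate is untouched
  out <- neighborhood_normalize(flat_plate(100), radius = 2)
  expect_equal(out$size, matrix(100, 8, 12))

  # smooth radial field, factor 2 center-to-edge: residual local variation
  # of the corrected plate under 5%
  nr <- 32; nc <- 48
  rr <- matrix(1:nr, nr, nc); cc <- matrix(1:nc, nr, nc, byrow = TRUE)
  d <- sqrt((rr - (nr + 1) / 2)^2 + (cc - (nc + 1) / 2)^2)
  field <- 1 + exp(-d^2 / (2 * (max(d) / 3)^2))  # 2 at center, ~1 at edge
  out <- neighborhood_normalize(flat_plate(100 * field, nr, nc), radius = 2)
  local_med <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c_ in 1:nc) {
    win <- out$size[max(1, r - 2):min(nr, r + 2),
                    max(1, c_ - 2):min(nc, c_ + 2)]
    local_med[r, c_] <- median(win)
  }
  expect_lt(max(local_med) / min(local_med), 1.05)

  # a lone 10x colony on a flat plate survives largely intact: its window
  # median (which excludes it) equals the plate background, so its factor
  # is 1 and only the flat background can rescale it
  m <- matrix(100, 8, 12)
  m[4, 6] <- 1000
  out <- neighborhood_normalize(flat_plate(m), radius = 2)
  expect_equal(out$size[4, 6] / median(out$size), 10, tolerance = 1e-9)
  # hand-enumerated 5x5 patch: the outlier's window median excludes it, so
  # its correction factor is background/background = 1
  patch <- matrix(2, 5, 5)
  patch[3, 3] <- 20
  outp <- neighborhood_normalize(flat_plate(patch, 5, 5), radius = 2)
  expect_equal(outp$size[3, 3], 20 / (median(patch[-13]) / median(patch)))
})

test_that("competition shrinkage follows the neighbor-deficit rule", {
  # all neighbors at plate median: untouched
  out <- competition_normalize(flat_plate(100), gamma = 0.5)
  expect_equal(out$size, matrix(100, 8, 12))

  # all four neighbors dead: d = 1, focal size divided by 1 + gamma
  m <- matrix(100, 8, 12)
  m[3, 5] <- 120
  m[c(2, 4), 5] <- 0
  m[3, c(4, 6)] <- 0
  out <- competition_normalize(flat_plate(m), gamma = 0.5)
  expect_equal(out$size[3, 5], 120 / 1.5)

  # gamma 0 is the identity even next to dead neighbors
  out0 <- competition_normalize(flat_plate(m), gamma = 0)
  expect_identical(out0$size, m)
})

test_that("the full cascade is scale invariant and flattens position effects", {
  design <- tiny_design(16, 24)
  truth <- synthetic_truth(design, noise_sd = 0.15, missing_prob = 0.02,
                           seed = 9)
  sim <- generate_screen(design, truth)
  cfg <- normalization_config()
  p <- sim$plates[[1]]
  a <- normalize_plate(p, cfg, design)
  p7 <- p; p7$size <- p$size * 7
  b <- normalize_plate(p7, cfg, design)
  expect_equal(a$size, b$size, tolerance = 1e-10)
  # finished plate has its 70-percentile at exactly 1
  expect_equal(quantile(a$size, 0.7, na.rm = TRUE, names = FALSE), 1,
               tolerance = 1e-12)

  # positional spread (SD of per-position log2 size over identical-baseline
  # strains, no measurement noise, so it is purely position-attributable)
  # must drop by >= 80% for the gradient/smooth-field/competition artifacts
  design3 <- make_screen_design(1536, backgrounds = "bg",
                                conditions = c("untreated", "DON"),
                                replicates = 4)
  base <- setNames(rep(500, 1536), sort(unique(design3$layout$strain)))
  truth3 <- synthetic_truth(design3, baseline = base, noise_sd = 0,
                            missing_prob = 0.02, edge_factor = 1, seed = 9)
  sim3 <- generate_screen(design3, truth3)
  reps <- Filter(function(q) q$condition == "untreated", sim3$plates)
  pos_spread <- function(plates) {
    stack <- vapply(plates, function(q) as.vector(log2(q$size)),
                    numeric(1536))
    sd(rowMeans(stack, na.rm = TRUE), na.rm = TRUE)
  }
  before <- pos_spread(reps)
  after <- pos_spread(lapply(reps, normalize_plate, config = cfg,
                             design = design3))
  expect_lt(after, 0.2 * before)
})

test_that("planted strain effects survive the cascade within 0.1 log2 units", {
  design <- make_screen_design(1536, backgrounds = "bg",
                               conditions = c("untreated", "DON"),
                               replicates = 4)
  eff <- plant_effects(design, 8, "bg", "DON", effect_range = c(1.5, 2.5),
                       direction = "both", seed = 21)
  truth <- synthetic_truth(design, effects = eff, noise_sd = 0, seed = 13,
                           missing_prob = 0)
  sim <- generate_screen(design, truth)
  scores <- run_screen(sim$plates, design, "DON", "untreated")
  got <- scores$delta_mean[match(eff$strain, scores$strain)]
  expect_true(all(abs(got - eff$effect) < 0.1))
})
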