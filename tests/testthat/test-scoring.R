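test_that("log2 strain statistics match hand arithmetic", {
  design <- tiny_design(1, 2, conditions = "untreated", replicates = 4)
  strains <- c("strain0001", "strain0002")
  m <- cbind(c(1, 1, 1, 1), c(0.5, 2, 1, 1))
  colnames(m) <- strains
  plates <- plates_from_values(list(untreated = m), design, 1, 2)
  stats <- strain_stats(plates, design)

  s1 <- stats[stats$strain == "strain0001", ]
  expect_equal(s1$mean, 0)
  expect_equal(s1$sd, 0)
  expect_equal(s1$n, 4L)

  # two-replicate case: log2(0.5, 2) = (-1, +1) -> mean 0, sample SD sqrt(2)
  plates2 <- plates_from_values(
    list(untreated = m[1:2, , drop = FALSE]), design, 1, 2)
  s2 <- strain_stats(plates2, design)
  s2b <- s2[s2$strain == "strain0002", ]
  expect_equal(s2b$mean, 0)
  expect_equal(s2b$sd, sqrt(2))

  # dead colony hits the log2 floor
  m0 <- cbind(c(0, 0), c(1, 1))
  colnames(m0) <- strains
  plates3 <- plates_from_values(list(untreated = m0), design, 1, 2)
  s3 <- strain_stats(plates3, design, log2_floor = 0.01)
  expect_equal(s3$mean[s3$strain == "strain0001"], log2(0.01))
})

test_that("delta_mean combines means and sample SDs", {
  tr <- data.frame(strain = "x", background = "b", condition = "DON",
                   n = 2L, mean = -1, sd = 0.1)
  un <- data.frame(strain = "x", background = "b", condition = "untreated",
                   n = 2L, mean = 0, sd = 0.1)
  d <- delta_mean(tr, un)
  expect_equal(d$delta_mean, -1)
  expect_equal(d$sum_sd, 0.2)

  # hand computation from replicate values
  a <- c(-1.2, -0.8); b <- c(0.1, -0.1)
  tr$mean <- mean(a); tr$sd <- sd(a)
  un$mean <- mean(b); un$sd <- sd(b)
  d <- delta_mean(tr, un)
  expect_equal(d$delta_mean, -1.0)
  expect_equal(d$sum_sd, sd(a) + sd(b))
  expect_equal(d$sum_sd, 0.4243, tolerance = 1e-4)

  # identical distributions: no effect; single replicate: spread undefined
  expect_equal(delta_mean(un, un)$delta_mean, 0)
  tr$n <- 1L
  expect_true(is.na(delta_mean(tr, un)$sum_sd))
})

test_that("the SD-corrected score matches its closed form and properties", {
  expect_equal(sd_corrected_score(0.8, 0), 0.8)
  expect_equal(sd_corrected_score(0, 1.7), 0)
  expect_equal(sd_corrected_score(1.0, 0.5), 0.5)
  expect_equal(sd_corrected_score(-1.0, 0.5), -0.5)

  set.seed(8)
  dm <- runif(500, -3, 3)
  ss <- runif(500, 0, 2)
  s <- sd_corrected_score(dm, ss)
  expect_true(all(sign(s) == sign(dm)))
  expect_true(all(abs(s) <= abs(dm) + 1e-15))
  expect_equal(sd_corrected_score(-dm, ss), -s)            # odd in the effect
  expect_true(all(abs(sd_corrected_score(dm, ss + 0.1)) <
                    abs(sd_corrected_score(dm, ss))))       # shrinks toward 0
  worse <- sd_corrected_score(1.5, c(0, 0.2, 0.5, 1, 2))
  expect_true(all(diff(worse) < 0))                         # strictly monotone
})

test_that("interaction calls follow the two-SD rule with an effect floor", {
  cfg <- call_config(effect_floor = 0.05)
  s <- sd_corrected_score(-0.5, 0.2)
  expect_equal(s, -0.5 / 1.8, tolerance = 1e-12)
  expect_equal(call_interaction(-0.5, 0.2, s, cfg), "sensitive")
  expect_equal(call_interaction(-0.3, 0.2, sd_corrected_score(-0.3, 0.2), cfg),
               "none")
  expect_equal(call_interaction(0, 0.5, 0, cfg), "none")
  expect_equal(call_interaction(0.5, 0.1, sd_corrected_score(0.5, 0.1), cfg),
               "resistant")
  expect_true(is.na(call_interaction(0.5, NA, NA, cfg)))
  # effect floor vetoes significant but tiny effects
  big_floor <- call_config(effect_floor = 0.5)
  expect_equal(call_interaction(-0.5, 0.1, sd_corrected_score(-0.5, 0.1),
                                big_floor), "none")
})

test_that("the t-test matches a textbook oracle and handles degeneracy", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  expect_equal(two_sample_t_test(a, b), oracle_student_t(a, b),
               tolerance = 1e-10)
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), mean = runif(1))
    expect_equal(two_sample_t_test(a, b), oracle_student_t(a, b),
                 tolerance = 1e-10)
  }
  expect_equal(two_sample_t_test(c(1, 1), c(1, 1)), 1)
  expect_equal(two_sample_t_test(c(0, 0, 0), c(1, 1, 1)), 0)
  expect_lt(two_sample_t_test(c(0, 0, 1e-9), c(1, 1, 1 + 1e-9)), 1e-10)
})

test_that("BH adjustment matches the brute-force step-up on examples", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_screen makes no calls on a null screen", {
  design <- tiny_design(8, 12)
  truth <- synthetic_truth(design, noise_sd = 0, missing_prob = 0, seed = 1)
  sim <- generate_screen(design, truth)
  scores <- run_screen(sim$plates, design, "DON", "untreated")
  expect_true(all(scores$call == "none"))
  expect_equal(nrow(scores), 96L)
})

test_that("run_screen recovers a single planted sensitive strain", {
  design <- tiny_design(8, 12)
  eff <- data.frame(strain = "strain0042", background = "bg",
                    condition = "DON", effect = -2)
  truth <- synthetic_truth(design, effects = eff, noise_sd = 0.1,
                           missing_prob = 0, seed = 5)
  sim <- generate_screen(design, truth)
  scores <- run_screen(sim$plates, design, "DON", "untreated")
  called <- scores$strain[scores$call == "sensitive"]
  expect_equal(called, "strain0042")
  expect_equal(scores$strain[1], "strain0042")  # most sensitive ranks first
  expect_equal(scores$delta_mean[1], -2, tolerance = 0.3)
})

test_that("plate input order does not change the score table", {
  design <- tiny_design(8, 12)
  eff <- plant_effects(design, 5, "bg", "DON", seed = 2)
  truth <- synthetic_truth(design, effects = eff, seed = 6)
  sim <- generate_screen(design, truth)
  s1 <- run_screen(sim$plates, design, "DON", "untreated")
  set.seed(99)
  s2 <- run_screen(sample(sim$plates), design, "DON", "untreated")
  attributes(s1) <- attributes(s1)[c("names", "class", "row.names")]
  attributes(s2) <- attributes(s2)[c("names", "class", "row.names")]
  expect_identical(s1, s2)
})
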