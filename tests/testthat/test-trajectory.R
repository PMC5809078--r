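test_that("equidistant snapshot selection is deterministic", {
  prof <- kinked_profile(54)
  ens <- simulate_roll_ensemble(prof, roll_sd = 2, n_snapshots = 100, seed = 3)
  sub <- sample_snapshots(ens, 20)
  expect_equal(sub$metadata$snapshot_indices,
               as.integer(floor((0:19) * 100 / 20) + 1))
  expect_equal(sub$metadata$snapshot_indices[1], 1L)

  ident <- sample_snapshots(ens, 100)
  expect_equal(ident$metadata$snapshot_indices, 1:100)

  expect_warning(clamped <- sample_snapshots(ens, 150), "clamping")
  expect_equal(n_models(clamped), 100)
})

test_that("roll time course reproduces constant and fluctuating ensembles", {
  prof <- kinked_profile(54)
  const <- simulate_roll_ensemble(prof, roll_sd = 0, n_snapshots = 20, seed = 5)
  dup <- find_duplexes(get_model(const, 1))[[1]]
  ts <- roll_time_course(const, dup)
  expect_equal(nrow(ts$values), 20)
  expect_equal(ncol(ts$values), 10)
  expect_lt(max(abs(sweep(ts$values, 2, ts$values[1, ]))), 1e-9)
  expect_equal(unname(ts$average_profile[5]), 54, tolerance = 1e-6)

  # column means sit within 3 standard errors of the planted means
  n <- 200; sd <- 8
  ens <- simulate_roll_ensemble(prof, roll_sd = sd, n_snapshots = n, seed = 6)
  ts2 <- roll_time_course(ens, dup)
  se_bound <- 3 * sd / sqrt(n)
  mu <- c(rep(0, 4), 54, rep(0, 5))
  expect_true(all(abs(ts2$average_profile - mu) < se_bound))

  # snapshot order does not change the means
  rev_ens <- ens
  rev_ens$xyz <- ens$xyz[n:1, ]
  ts3 <- roll_time_course(rev_ens, dup)
  expect_equal(ts3$average_profile, ts2$average_profile, tolerance = 1e-12)
})

test_that("snapshots with unfittable steps are excluded from column means", {
  prof <- kinked_profile(54, n = 6, at = 3, sequence = "ACGTAC")
  ens <- simulate_roll_ensemble(prof, roll_sd = 0, n_snapshots = 4, seed = 9)
  models <- lapply(1:4, function(i) get_model(ens, i))
  dup <- find_duplexes(models[[1]])[[1]]
  # wreck the ring of pair 2's strand-I base in snapshot 3 only
  rt <- residue_table(models[[3]])
  rows <- rt$rows[[which(rt$chain == "A" & rt$resno == 2)]]
  drop <- rows[models[[3]]$atom$elety[rows] %in%
                 c("N1", "C2", "N3", "C4", "C5", "C6", "O2", "N4")]
  models[[3]]$atom <- models[[3]]$atom[-drop, ]
  ts <- roll_time_course(models, dup)
  expect_equal(unname(ts$n_missing[1:2]), c(1L, 1L))
  expect_equal(sum(ts$n_missing), 2L)
  expect_equal(unname(ts$average_profile[3]), 54, tolerance = 1e-6)
})

test_that("gaussian histogram fit recovers planted moments", {
  set.seed(61)
  vals <- rnorm(2000, mean = 48, sd = 8)
  fit <- fit_roll_histogram(vals)
  expect_lt(abs(fit$c - 48), 0.5)
  expect_lt(abs(-1 / (2 * fit$b) - 64) / 64, 0.15)
  expect_lt(fit$b, 0)

  # noiseless gaussian-shaped counts: exact recovery by the fitting core
  mids <- seq(-19, 79, by = 2)
  a <- 120; b <- -1 / (2 * 8^2); cc <- 48
  counts <- a * exp(b * (mids - cc)^2)
  exact <- dnakink:::fit_gauss_counts(mids, counts,
                                      list(a = 100, b = -0.01, c = 40))
  expect_equal(c(exact$a, exact$b, exact$c), c(a, b, cc), tolerance = 1e-6)
  expect_lt(exact$rss, 1e-9)

  expect_error(fit_roll_histogram(rep(48, 100)), "degenerate")
  expect_error(fit_roll_histogram(rnorm(10)), "at least 50")
})

test_that("stability classification follows occupancy and mean-roll rules", {
  ns <- 200
  # stable large kink: max always at reference, mean 54
  m1 <- matrix(c(rep(5, ns), rep(54, ns), rep(8, ns)), ncol = 3)
  s1 <- classify_stability(m1, reference_step = 2)
  expect_equal(s1$class, "stable_large_kink")
  expect_equal(s1$occupancy, 1)

  # stable reduced kink: max at reference but mean 28
  m2 <- matrix(c(rep(5, ns), rep(28, ns), rep(8, ns)), ncol = 3)
  expect_equal(classify_stability(m2, 2)$class, "stable_reduced_kink")

  # unstable: argmax alternates between reference and 3' neighbour
  m3 <- matrix(5, ns, 3)
  m3[, 2] <- 40
  odd <- seq(1, ns, by = 2)
  m3[odd, 3] <- 55   # neighbour wins in half the snapshots
  s3 <- classify_stability(m3, 2)
  expect_equal(s3$class, "unstable")
  expect_equal(s3$neighbor_occupancy, 0.5)

  # invariant to snapshot order and to a uniform roll offset
  perm <- sample(ns)
  expect_equal(classify_stability(m3[perm, ], 2)$class, "unstable")
  expect_equal(classify_stability(m1 + 10, 2)$class, "stable_large_kink")
})

test_that("trajectory analysis front-end ties the pieces together", {
  prof <- kinked_profile(54)
  ens <- simulate_roll_ensemble(prof, roll_sd = 8, n_snapshots = 150, seed = 8)
  res <- analyze_trajectory(ens, config = kink_config(n_snapshots = 150))
  expect_equal(res$reference_step, 5)
  expect_equal(res$stability$class, "stable_large_kink")
  expect_lt(abs(res$stability$mean_kink - 54), 3 * 8 / sqrt(150))
  expect_error(analyze_trajectory(
    structure_ensemble(list(kinked_model(54)))), "single-model")
})
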