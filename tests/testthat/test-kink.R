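profile_from_rolls <- function(rolls, sequence = NULL) {
  n <- length(rolls) + 1
  if (is.null(sequence))
    sequence <- paste(rep(c("A", "C", "G", "T"), length.out = n),
                      collapse = "")
  m <- build_duplex(step_profile(sequence, roll = rolls))
  roll_profile(generator_duplex(m), m)
}

test_that("kink calling applies the 35-degree rule and ranks by roll", {
  p <- profile_from_rolls(c(2, 5, 54, 3, 1))
  calls <- detect_kinks(p)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$step_index, 3)
  expect_equal(calls$roll, 54, tolerance = 1e-6)
  expect_equal(kink_angle(p), 54, tolerance = 1e-6)

  # nothing above threshold: no calls
  expect_equal(nrow(detect_kinks(profile_from_rolls(c(10, 34.9, 20, 5)))), 0)

  # two separated kinks: both called, kink angle is the larger
  p2 <- profile_from_rolls(c(0, 49, 0, 0, 43, 0, 0))
  calls2 <- detect_kinks(p2)
  expect_equal(nrow(calls2), 2)
  expect_equal(calls2$roll, c(49, 43), tolerance = 1e-6)
  expect_equal(kink_angle(p2), 49, tolerance = 1e-6)
})

test_that("raising the threshold never adds a kink call", {
  set.seed(41)
  for (rep in 1:20) {
    p <- profile_from_rolls(runif(7, -10, 60))
    thresholds <- sort(runif(3, 20, 55))
    calls <- lapply(thresholds, function(t) detect_kinks(p, t)$step_index)
    expect_true(all(calls[[2]] %in% calls[[1]]))
    expect_true(all(calls[[3]] %in% calls[[2]]))
  }
})

test_that("kink calls at steps flanking a flipped base carry the annotation", {
  mf <- flip_base(kinked_model(45, n = 11, at = 4), "A", 6, 120)
  dups <- find_duplexes(mf)
  # segment 1 holds pairs 1..5; the flip is flagged just beyond it, so the
  # terminal step of the segment (step 4, here also the kink) is annotated
  prof <- roll_profile(dups[[1]], mf)
  calls <- detect_kinks(prof)
  expect_equal(calls$step_index, 4)
  expect_true(calls$flip_adjacent)
  # an interior kink well away from any flip carries no annotation
  clean <- roll_profile(find_duplexes(kinked_model(45))[[1]], kinked_model(45))
  expect_false(any(detect_kinks(clean)$flip_adjacent))
})

test_that("intercalation detection is specific to the planted step", {
  set.seed(51)
  m <- kinked_model(50)
  dup <- find_duplexes(m)[[1]]
  for (rn in c("LEU", "MET", "PHE", "VAL")) {
    mi <- plant_intercalator(m, 5, rn, depth = 2.2)
    hits <- vapply(1:10, function(s)
      nrow(detect_intercalation(mi, dup, s)), integer(1))
    expect_equal(which(hits > 0), 5L)
    ic <- detect_intercalation(mi, dup, 5)
    expect_equal(ic$resid, rn)
    expect_gte(ic$n_inserted_atoms, 1)
  }
})

test_that("a single atom grazing the slab edge still counts", {
  m <- kinked_model(0)
  dup <- find_duplexes(m)[[1]]
  geo <- dnakink:::mid_step_geometry(m, dup, 5)
  # one CB at 4.4 Angstrom below the upper plane (inside), backbone far out
  up <- geo$mid$origin + as.vector(geo$mid$axes %*% c(-3.5, 0, 0.2))
  far <- geo$mid$origin + as.vector(geo$mid$axes %*% c(-12, 0, 0))
  add <- data.frame(elety = c("N", "CA", "C", "O", "CB"), resid = "ALA",
                    chain = "P", resno = 1,
                    x = c(rep(far[1], 4), up[1]) + c(0, 1, 2, 3, 0),
                    y = c(rep(far[2], 4), up[2]),
                    z = c(rep(far[3], 4), up[3]))
  mi <- structure_model(rbind(
    m$atom[, c("elety", "resid", "chain", "resno", "x", "y", "z")], add))
  ic <- detect_intercalation(mi, dup, 5)
  expect_equal(nrow(ic), 1)
  expect_equal(ic$n_inserted_atoms, 1)
  expect_equal(ic$classification, "partial")
})

test_that("clean duplex with distant protein yields no intercalation calls", {
  m <- plant_intercalator(kinked_model(50), 5, "LEU", depth = 2.2)
  m$atom[m$atom$chain == "P", c("x", "y", "z")] <-
    m$atom[m$atom$chain == "P", c("x", "y", "z")] + 25
  dup <- find_duplexes(m)[[1]]
  hits <- vapply(1:10, function(s)
    nrow(detect_intercalation(m, dup, s)), integer(1))
  expect_equal(sum(hits), 0)
})

test_that("full/partial classification follows fraction and depth rules", {
  call <- data.frame(n_inserted_atoms = 4, n_sidechain_atoms = 4,
                     insertion_depth = 3)
  expect_equal(classify_intercalation(call), "full")
  call2 <- data.frame(n_inserted_atoms = 2, n_sidechain_atoms = 7,
                      insertion_depth = 3)
  expect_equal(classify_intercalation(call2), "partial")
  call3 <- data.frame(n_inserted_atoms = 4, n_sidechain_atoms = 4,
                      insertion_depth = 0.8)
  expect_equal(classify_intercalation(call3), "partial")
})
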