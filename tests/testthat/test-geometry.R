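make_base_model <- function(base = "A", R = diag(3), t = c(0, 0, 0),
                            noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  std <- standard_base(base)
  xyz <- sweep(std %*% t(R), 2, t, "+")
  # noise = rms total displacement per atom (isotropic)
  if (noise > 0)
    xyz <- xyz + matrix(rnorm(length(xyz), 0, noise / sqrt(3)), ncol = 3)
  structure_model(data.frame(elety = rownames(std), resid = paste0("D", base),
                             chain = "A", resno = 1,
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

rotation_angle <- function(R) dnakink:::axis_angle(R)$angle

test_that("base-frame fitting recovers a planted rigid transform exactly", {
  set.seed(101)
  for (base in c("A", "C", "G", "T")) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    m <- make_base_model(base, R, t)
    fit <- fit_base_frame(m, seq_len(nrow(m$atom)), base)
    expect_lt(fit$rmsd, 1e-9)
    expect_lt(max(abs(fit$frame$axes - R)), 1e-9)
    expect_lt(max(abs(fit$frame$origin - t)), 1e-9)
  }
})

test_that("base-frame fitting is robust to coordinate noise", {
  set.seed(77)
  for (rep in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 5)
    m <- make_base_model("G", R, t, noise = 0.1)
    fit <- fit_base_frame(m, seq_len(nrow(m$atom)), "G")
    expect_lt(rotation_angle(t(R) %*% fit$frame$axes), 2)
    expect_lt(fit$rmsd, 0.15)
  }
})

test_that("mirror-image coordinates still give a proper rotation", {
  m <- make_base_model("A")
  m$atom$z <- -m$atom$z  # reflection; base is planar so also test with y
  m$atom$y <- -m$atom$y
  fit <- fit_base_frame(m, seq_len(nrow(m$atom)), "A")
  expect_equal(det(fit$frame$axes), 1, tolerance = 1e-9)
})

test_that("too few ring atoms is an error", {
  m <- make_base_model("A")
  keep <- m$atom$elety %in% c("N9", "C8", "N7", "C5", "C1'")
  m$atom <- m$atom[keep, ]
  expect_error(fit_base_frame(m, seq_len(nrow(m$atom)), "A"),
               "insufficient atoms")
})

test_that("pair frame is the halfway interpolation of the flipped triads", {
  f1 <- ref_frame(c(1, 2, 3), diag(3))
  flipped <- diag(c(1, -1, -1))
  # exactly complementary partner: pair frame equals frame I
  f2 <- ref_frame(c(1, 2, 3), diag(3) %*% flipped)
  pf <- base_pair_frame(f1, f2)
  expect_lt(max(abs(pf$axes - diag(3))), 1e-12)
  expect_equal(pf$origin, c(1, 2, 3))

  # planted 10-degree propeller-like relative rotation bisects to 5
  R10 <- dnakink:::rot_about(c(0, 1, 0), 10)
  f3 <- ref_frame(c(1, 2, 3), (R10 %*% diag(3)) %*% flipped)
  pf2 <- base_pair_frame(f1, f3)
  expect_equal(rotation_angle(t(f1$axes) %*% pf2$axes), 5, tolerance = 1e-9)

  # grossly non-complementary geometry is refused
  R120 <- dnakink:::rot_about(c(0, 0, 1), 120)
  f4 <- ref_frame(c(1, 2, 3), (R120 %*% diag(3)) %*% flipped)
  expect_error(base_pair_frame(f1, f4), "degenerate pair")
})

test_that("pure twist/rise step yields exactly (0,0,rise,0,0,twist)", {
  f1 <- ref_frame()
  f2 <- ref_frame(c(0, 0, 3.38), dnakink:::rot_about(c(0, 0, 1), 36))
  p <- compute_step_parameters(f1, f2)
  expect_equal(unname(p), c(0, 0, 3.38, 0, 0, 36), tolerance = 1e-12)
})

test_that("step_transform is the exact inverse of compute_step_parameters", {
  set.seed(303)
  for (rep in 1:50) {
    params <- c(shift = runif(1, -2, 2), slide = runif(1, -2, 2),
                rise = runif(1, 2.5, 4.5), tilt = runif(1, -60, 60),
                roll = runif(1, -60, 60), twist = runif(1, 20, 45))
    f1 <- ref_frame(rnorm(3, sd = 10), random_rotation())
    f2 <- step_transform(f1, params)
    expect_lt(max(abs(compute_step_parameters(f1, f2) - params)), 1e-9)
  }
})

test_that("step parameters are invariant under global rigid motion", {
  set.seed(404)
  params <- c(shift = 0.5, slide = -1, rise = 3.1, tilt = -20, roll = 54,
              twist = 32)
  f1 <- ref_frame(c(1, 2, 3), random_rotation())
  f2 <- step_transform(f1, params)
  for (rep in 1:20) {
    R <- random_rotation(); t <- rnorm(3, sd = 50)
    g1 <- ref_frame(as.vector(R %*% f1$origin) + t, R %*% f1$axes)
    g2 <- ref_frame(as.vector(R %*% f2$origin) + t, R %*% f2$axes)
    expect_lt(max(abs(compute_step_parameters(g1, g2) - params)), 1e-9)
  }
})

test_that("strand reversal negates tilt and shift only (frame level)", {
  set.seed(505)
  flip <- diag(c(1, -1, -1))
  for (rep in 1:100) {
    params <- c(shift = runif(1, -2, 2), slide = runif(1, -2, 2),
                rise = runif(1, 2.5, 4.5), tilt = runif(1, -60, 60),
                roll = runif(1, -60, 60), twist = runif(1, 20, 45))
    f1 <- ref_frame(rnorm(3, sd = 5), random_rotation())
    f2 <- step_transform(f1, params)
    # read the same step along the opposite strand: flip both pair frames
    # about x and traverse j -> i
    r1 <- ref_frame(f2$origin, f2$axes %*% flip)
    r2 <- ref_frame(f1$origin, f1$axes %*% flip)
    q <- compute_step_parameters(r1, r2)
    expect_equal(unname(q[c("slide", "rise", "roll", "twist")]),
                 unname(params[c("slide", "rise", "roll", "twist")]),
                 tolerance = 1e-9)
    expect_equal(unname(q[c("shift", "tilt")]),
                 unname(-params[c("shift", "tilt")]), tolerance = 1e-9)
  }
})

test_that("near-antiparallel frames are rejected", {
  f1 <- ref_frame()
  f2 <- ref_frame(c(0, 0, 3.38),
                  dnakink:::rot_about(c(0, 1, 0), 120))
  expect_error(compute_step_parameters(f1, f2), "antiparallel")
})

test_that("roll profile degrades gracefully when ring atoms are missing", {
  m <- kinked_model()
  dup <- generator_duplex(m)
  # delete the ring atoms of pair 6's strand-I base
  rt <- residue_table(m)
  rows <- rt$rows[[which(rt$chain == "A" & rt$resno == 6)]]
  drop <- rows[m$atom$elety[rows] %in% c("N9", "C8", "N7", "C5", "C6",
                                         "N1", "C2", "N3", "C4", "N6", "O6")]
  m$atom <- m$atom[-drop, ]
  prof <- roll_profile(dup, m)
  expect_true(all(prof$steps$missing[5:6]))
  expect_false(any(prof$steps$missing[-(5:6)]))
  expect_lt(max(abs(prof$rolls[-(4:6)])), 1e-6)
})
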