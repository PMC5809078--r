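# Synthetic B-DNA generator: exact inverse of the step-parameter
# measurement, plus snapshot-ensemble simulation and planted curation
# fixtures (intercalators, dangling overhangs, flipped-out bases). This is
# the oracle that makes every analysis stage verifiable by round-trip
# recovery without any deposited structure.

.default_step <- c(shift = 0, slide = 0, rise = 3.38,
                   tilt = 0, roll = 0, twist = 36)

#' Step-parameter profile for a duplex sequence
#'
#' One row per dinucleotide step; unspecified parameters take fiber
#' B-DNA defaults (rise 3.38 Angstrom, twist 36 degrees, all else zero).
#' Scalars are recycled across steps.
#'
#' @param sequence strand-I sequence, string or character vector over
#'   A/C/G/T.
#' @param shift,slide,rise,tilt,roll,twist per-step values (Angstrom /
#'   degrees), length 1 or `nchar(sequence) - 1`.
#' @return object of class `step_profile` (a data.frame with attribute
#'   `sequence`).
#' @export
step_profile <- function(sequence, shift = 0, slide = 0, rise = 3.38,
                         tilt = 0, roll = 0, twist = 36) {
  seq_v <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
  seq_v <- toupper(seq_v)
  if (!all(seq_v %in% c("A", "C", "G", "T")))
    stop("sequence error: letters outside A/C/G/T")
  n <- length(seq_v)
  if (n < 2) stop("sequence must have at least 2 bases")
  ns <- n - 1
  df <- data.frame(shift = rep_len(shift, ns), slide = rep_len(slide, ns),
                   rise = rep_len(rise, ns), tilt = rep_len(tilt, ns),
                   roll = rep_len(roll, ns), twist = rep_len(twist, ns))
  if (any(df$rise <= 0)) stop("rise must be positive")
  attr(df, "sequence") <- seq_v
  class(df) <- c("step_profile", "data.frame")
  df
}

profile_sequence <- function(profile) attr(profile, "sequence")

#' Build B-DNA coordinates from a step-parameter profile
#'
#' Pair frame 1 is the identity; each subsequent pair frame is generated
#' with [step_transform()]. Ideal Watson-Crick pairs (standard base
#' geometries, zero intra-pair parameters) are placed into each frame:
#' strand I with the frame itself, strand II flipped 180 degrees about
#' the frame x-axis. Atoms comprise the base ring, Watson-Crick
#' exocyclics and C1'. Strand I is chain A (resno 1..n, 5'->3'); strand
#' II is chain B numbered 1..n along its own 5'->3' direction.
#'
#' @param profile a [step_profile()].
#' @return a `structure_model`.
#' @export
build_duplex <- function(profile) {
  seq_v <- profile_sequence(profile)
  n <- length(seq_v)
  frames <- vector("list", n)
  frames[[1]] <- ref_frame()
  for (k in seq_len(n - 1))
    frames[[k + 1]] <- step_transform(frames[[k]], profile[k, ])
  flip <- diag(c(1, -1, -1))
  rows <- list()
  for (k in seq_len(n)) {
    b <- seq_v[k]
    std <- standard_base(b)
    xyz <- sweep(std %*% t(frames[[k]]$axes), 2, frames[[k]]$origin, "+")
    rows[[length(rows) + 1]] <- data.frame(
      elety = rownames(std), resid = paste0("D", b), chain = "A",
      resno = k, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  for (k in seq_len(n)) {
    bc <- unname(.wc_partner[seq_v[k]])
    std <- standard_base(bc)
    A <- frames[[k]]$axes %*% flip
    xyz <- sweep(std %*% t(A), 2, frames[[k]]$origin, "+")
    rows[[length(rows) + 1]] <- data.frame(
      elety = rownames(std), resid = paste0("D", bc), chain = "B",
      resno = n - k + 1, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  a <- do.call(rbind, rows)
  # file order: chain A 5'->3', then chain B 5'->3'
  a <- a[order(a$chain, a$resno), ]
  rownames(a) <- NULL
  structure_model(a)
}

#' Duplex object from generator topology
#'
#' For models built by [build_duplex()] (chain A = strand I resno 1..n,
#' chain B = strand II resno n..1) the pairing is known by construction;
#' this returns the corresponding `dna_duplex` without geometric pair
#' detection, so measurement round trips are not limited by the
#' pair-detection thresholds under extreme prescribed deformations.
#'
#' @param model a `structure_model` from [build_duplex()].
#' @return a `dna_duplex`.
#' @export
generator_duplex <- function(model) {
  rt <- residue_table(model)
  ia <- which(rt$chain == "A")[order(rt$resno[rt$chain == "A"])]
  ib <- which(rt$chain == "B")
  ib <- ib[order(rt$resno[rt$chain == "B"])]
  n <- length(ia)
  stopifnot(n >= 2, length(ib) == n)
  pr <- data.frame(res_I = ia, res_II = rev(ib),
                   base_I = rt$base[ia], base_II = rt$base[rev(ib)],
                   n_hbonds = ifelse(rt$base[ia] %in% c("G", "C"), 3L, 2L),
                   c1c1 = NA_real_, is_watson_crick = TRUE)
  structure(list(pairs = pr, sequence_I = pr$base_I, sequence_II = pr$base_II,
                 chain_I = "A", chain_II = "B",
                 trimmed_5p = 0L, trimmed_3p = 0L,
                 flipped_positions = integer(0),
                 paired_residues = c(pr$res_I, pr$res_II)),
            class = "dna_duplex")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a snapshot ensemble with fluctuating roll angles
#'
#' Emulates equidistant trajectory snapshots of a kinked duplex: for each
#' snapshot, every step's roll is drawn independently from a normal
#' distribution about the mean profile (other parameters fixed) and the
#' coordinates are rebuilt with [build_duplex()]. Fully reproducible from
#' `seed`; the caller's random-number state is untouched.
#'
#' @param mean_profile a [step_profile()] of per-step means.
#' @param roll_sd per-step roll standard deviation, degrees (recycled).
#' @param n_snapshots number of snapshots.
#' @param seed integer seed.
#' @return a trajectory `structure_ensemble`.
#' @export
simulate_roll_ensemble <- function(mean_profile, roll_sd = 8,
                                   n_snapshots = 2000, seed = 1) {
  stopifnot(n_snapshots >= 1, all(roll_sd >= 0))
  ns <- nrow(mean_profile)
  sd_v <- rep_len(roll_sd, ns)
  models <- with_seed(seed, {
    lapply(seq_len(n_snapshots), function(s) {
      p <- mean_profile
      p$roll <- stats::rnorm(ns, mean_profile$roll, sd_v)
      build_duplex(p)
    })
  })
  structure_ensemble(models,
                     metadata = list(method = "SYNTHETIC ENSEMBLE",
                                     identifier = sprintf("sim-seed%d", seed),
                                     format = "memory"),
                     trajectory = TRUE)
}

.sidechain_atoms <- list(
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))

#' Plant an intercalating sidechain at a base-pair step
#'
#' Adds one protein residue whose sidechain heavy atoms march into the
#' step slab from the minor-groove side: the tip atom sits `depth`
#' Angstrom past the C1'-C1' line toward the helix axis, preceding atoms
#' trail 1.3 Angstrom apart back out of the groove, and backbone atoms
#' (N, CA, C, O) are placed well outside the slab. A clash with any DNA
#' atom closer than 1.5 Angstrom is an error.
#'
#' @param model a `structure_model` (typically from [build_duplex()]).
#' @param step_index target step (1-based along the first duplex).
#' @param residue_name "LEU", "MET", "PHE" or "VAL".
#' @param depth insertion depth past the C1'-C1' line, Angstrom.
#' @param duplex optional pre-computed `dna_duplex`.
#' @param chain chain id for the added residue.
#' @return the model with the planted residue appended.
#' @export
plant_intercalator <- function(model, step_index,
                               residue_name = c("LEU", "MET", "PHE", "VAL"),
                               depth = 3, duplex = NULL, chain = "P") {
  residue_name <- match.arg(residue_name)
  if (is.null(duplex)) {
    dups <- find_duplexes(model)
    if (!length(dups)) stop("no duplex found in model")
    duplex <- dups[[1]]
  }
  if (step_index < 1 || step_index > nrow(duplex$pairs) - 1)
    stop("index error: step ", step_index, " outside duplex")
  geo <- mid_step_geometry(model, duplex, step_index)
  sc <- .sidechain_atoms[[residue_name]]
  nsc <- length(sc)
  tip_x <- geo$c1x + depth
  # atoms stay in the mid plane (z = 0): at a kinked step the slab opens
  # toward the minor groove, exactly where the wedge marches in
  local <- cbind(x = tip_x - 1.3 * rev(seq_len(nsc) - 1),
                 y = 0.4 * (-1)^seq_len(nsc),
                 z = rep(0, nsc))
  bb_x <- min(local[, "x"]) - c(1.8, 3.0, 4.2, 5.0)
  bb <- cbind(x = bb_x, y = c(0.8, 0, -0.8, 1.2), z = c(0.5, 0, -0.5, 0))
  local <- rbind(bb, local)
  names_all <- c("N", "CA", "C", "O", sc)
  Rm <- geo$mid$axes
  xyz <- sweep(local %*% t(Rm), 2, geo$mid$origin, "+")
  dna <- as.matrix(model$atom[, c("x", "y", "z")])
  for (i in seq_len(nrow(xyz))) {
    d2 <- rowSums(sweep(dna, 2, xyz[i, ])^2)
    if (min(d2) < 1.5^2)
      stop("placement error: atom ", names_all[i], " clashes with DNA (",
           round(sqrt(min(d2)), 2), " Angstrom)")
  }
  resno <- if (any(model$atom$chain == chain))
    max(model$atom$resno[model$atom$chain == chain]) + 1L else 1L
  add <- data.frame(elety = names_all, resid = residue_name, chain = chain,
                    resno = resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  a <- rbind(model$atom[, c("elety", "resid", "chain", "resno", "x", "y", "z")],
             add)
  structure_model(a, model_index = model$model_index)
}

# Mid-step frame and mean mid-frame x of the step's four C1' atoms
# (the C1'-C1' line datum from which insertion depth is measured).
mid_step_geometry <- function(model, duplex, step_index) {
  rt <- residue_table(model)
  pr <- duplex$pairs
  f <- lapply(c(step_index, step_index + 1), function(k) {
    fI <- try_fit(model, rt, pr$res_I[k])
    fII <- try_fit(model, rt, pr$res_II[k])
    if (is.null(fI) || is.null(fII)) stop("cannot fit pair frame at pair ", k)
    base_pair_frame(fI, fII)
  })
  geo <- step_geometry(f[[1]], f[[2]])
  res4 <- c(pr$res_I[step_index], pr$res_II[step_index],
            pr$res_I[step_index + 1], pr$res_II[step_index + 1])
  c1 <- t(vapply(res4, function(i)
    residue_coords(model, rt$rows[[i]], "C1'")[1, ], numeric(3)))
  c1m <- sweep(c1, 2, geo$mid$origin) %*% geo$mid$axes
  list(mid = geo$mid, params = geo$params,
       plane_i = f[[1]], plane_j = f[[2]], c1x = mean(c1m[, 1]))
}

# Inverse of step_transform: the frame of pair i given the frame of pair
# i+1 and the step parameters.
inverse_step_transform <- function(frame, params) {
  p <- as.list(params)
  gamma <- sqrt(p$roll^2 + p$tilt^2)
  phi <- atan2(p$tilt, p$roll) * DEG
  h <- c(-sin(phi / DEG), cos(phi / DEG), 0)
  R1m <- rot_about(h, -gamma / 2) %*% rot_about(c(0, 0, 1), -p$twist / 2)
  R2m <- rot_about(h, +gamma / 2) %*% rot_about(c(0, 0, 1), +p$twist / 2)
  Rm <- frame$axes %*% t(R2m)
  d <- c(p$shift, p$slide, p$rise)
  ref_frame(frame$origin - as.vector(Rm %*% d), Rm %*% R1m)
}

#' Append a dangling single-stranded overhang
#'
#' Extends one strand terminus by `n` unpaired nucleotides that continue
#' the helical path (fiber twist/rise), emulating the dangling ends that
#' shift pairing register in automated analysis.
#'
#' @param model a `structure_model` from [build_duplex()].
#' @param n number of nucleotides to append.
#' @param end which terminus: "5I" (5' of strand I), "3I", "5II", "3II".
#' @param bases base letters of the overhang (recycled), 5'->3' along the
#'   extended strand.
#' @param duplex optional pre-computed `dna_duplex`.
#' @return the extended `structure_model`.
#' @export
add_overhang <- function(model, n = 2, end = c("5I", "3I", "5II", "3II"),
                         bases = "T", duplex = NULL) {
  end <- match.arg(end)
  stopifnot(n >= 1)
  if (is.null(duplex)) {
    dups <- find_duplexes(model)
    if (!length(dups)) stop("no duplex found in model")
    duplex <- dups[[1]]
  }
  rt <- residue_table(model)
  pr <- duplex$pairs
  np <- nrow(pr)
  bases <- rep_len(toupper(if (length(bases) == 1) strsplit(bases, "")[[1]]
                           else bases), n)
  # terminal pair frame and walking direction (+1 = 3'-ward along strand I)
  k <- if (end %in% c("5I", "3II")) 1L else np
  fI <- try_fit(model, rt, pr$res_I[k]); fII <- try_fit(model, rt, pr$res_II[k])
  fr <- base_pair_frame(fI, fII)
  forward <- end %in% c("3I", "5II")
  onI <- end %in% c("5I", "3I")
  ch <- if (onI) duplex$chain_I else duplex$chain_II
  res0 <- if (onI) rt$resno[pr[[if (forward) "res_I" else "res_I"]][k]]
          else rt$resno[pr$res_II[k]]
  dir <- if (onI) (if (forward) +1L else -1L) else (if (forward) -1L else +1L)
  flip <- diag(c(1, -1, -1))
  rows <- list()
  for (i in seq_len(n)) {
    fr <- if (forward) step_transform(fr, .default_step)
          else inverse_step_transform(fr, .default_step)
    b <- bases[i]
    std <- standard_base(b)
    A <- if (onI) fr$axes else fr$axes %*% flip
    xyz <- sweep(std %*% t(A), 2, fr$origin, "+")
    rows[[i]] <- data.frame(elety = rownames(std), resid = paste0("D", b),
                            chain = ch, resno = res0 + i * dir,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  a <- rbind(model$atom[, c("elety", "resid", "chain", "resno", "x", "y", "z")],
             do.call(rbind, rows))
  a <- a[order(a$chain, a$resno), ]
  rownames(a) <- NULL
  structure_model(a, model_index = model$model_index)
}

#' Rotate a base out of the helix about its glycosidic bond
#'
#' Applies a rigid rotation (default 120 degrees) about the C1'-N9
#' (purine) or C1'-N1 (pyrimidine) axis to all base atoms of one residue,
#' emulating a base flip-out. Angle 0 returns the model unchanged.
#'
#' @param model a `structure_model`.
#' @param chain,resno residue to flip.
#' @param angle rotation angle, degrees.
#' @return the edited `structure_model`.
#' @export
flip_base <- function(model, chain, resno, angle = 120) {
  a <- model$atom
  sel <- which(a$chain == chain & a$resno == resno)
  if (!length(sel)) stop("index error: residue ", chain, ":", resno,
                         " not found")
  if (angle == 0) return(model)
  b <- base_letter(a$resid[sel[1]])
  if (is.na(b)) stop("residue ", chain, ":", resno, " is not a nucleotide")
  att <- if (b %in% c("A", "G")) "N9" else "N1"
  nm <- a$elety[sel]
  c1 <- as.numeric(a[sel[match("C1'", nm)], c("x", "y", "z")])
  natt <- as.numeric(a[sel[match(att, nm)], c("x", "y", "z")])
  if (anyNA(c1) || anyNA(natt)) stop("glycosidic atoms missing")
  R <- rot_about(natt - c1, angle)
  move <- sel[nm != "C1'"]
  m <- as.matrix(a[move, c("x", "y", "z")])
  m2 <- sweep(sweep(m, 2, c1) %*% t(R), 2, c1, "+")
  a$x[move] <- m2[, 1]; a$y[move] <- m2[, 2]; a$z[move] <- m2[, 3]
  structure_model(a, model_index = model$model_index)
}
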