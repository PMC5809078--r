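# Base reference frames and rigid-body base-pair-step parameters.
#
# The mid-step-frame scheme is used throughout: the two base-pair triads
# are symmetrised onto a common z-axis by rotating each halfway about the
# hinge (the cross product of their z-axes), twist is the angle between
# the symmetrised x-axes, the roll/tilt decomposition follows the phase
# angle of the hinge in the mid frame, and translations are expressed in
# mid-frame coordinates. This scheme is exactly invertible, which the
# synthetic B-DNA generator exploits (see build_duplex).

#' Fit the standard reference frame of a base
#'
#' Least-squares (Kabsch) superposition of the embedded standard base
#' geometry onto the observed ring atoms. The returned frame is the rigid
#' transform that carries the standard base, defined at the origin in its
#' own frame, onto the observed base: axes = fitted rotation, origin =
#' fitted translation. A proper rotation is enforced, so mirror-image
#' coordinates still give det +1.
#'
#' @param model a `structure_model`.
#' @param rows atom-row indices of the residue (from [residue_table()]).
#' @param base base letter "A", "C", "G" or "T".
#' @return list with `frame` ([ref_frame()]), `rmsd` (Angstrom) and
#'   `n_fit` (number of matched ring atoms).
#' @export
fit_base_frame <- function(model, rows, base) {
  std <- standard_base(base)
  ring <- .ring_atoms[[toupper(base)]]
  obs <- residue_coords(model, rows, ring)
  ok <- stats::complete.cases(obs)
  if (sum(ok) < 6)
    stop("insufficient atoms: ", sum(ok), " of ", length(ring),
         " ring atoms present for base ", base)
  fit <- kabsch(std[ring[ok], , drop = FALSE], obs[ok, , drop = FALSE])
  list(frame = ref_frame(fit$t, fit$R), rmsd = fit$rmsd, n_fit = sum(ok))
}

#' Mean (pair) frame of two paired bases
#'
#' The strand-II frame is first flipped 180 degrees about its x-axis
#' (y and z negated) so both triads share the strand-I sense, then the
#' pair frame is the half-way rotation between the two triads with origin
#' at the midpoint of the origins.
#'
#' @param frame_I,frame_II [ref_frame()] of the strand-I and strand-II
#'   bases (as fitted, before any flip).
#' @return a [ref_frame()].
#' @export
base_pair_frame <- function(frame_I, frame_II) {
  A1 <- frame_I$axes
  A2 <- frame_II$axes %*% diag(c(1, -1, -1))
  rel <- axis_angle(A2 %*% t(A1))
  if (rel$angle > 90)
    stop("degenerate pair: relative rotation ", round(rel$angle, 1),
         " degrees after strand-II flip (non-Watson-Crick geometry)")
  Rp <- rot_about(rel$axis, rel$angle / 2) %*% A1
  ref_frame((frame_I$origin + frame_II$origin) / 2, Rp)
}

#' Six rigid-body parameters of a base-pair step
#'
#' Mid-step-frame computation for two consecutive pair frames (`pair_i`
#' 5' of `pair_j` along strand I). Rotations in degrees, translations in
#' Angstrom; positive roll opens the step toward the minor groove.
#'
#' @param pair_i,pair_j consecutive [ref_frame()] pair frames.
#' @return named numeric vector (shift, slide, rise, tilt, roll, twist).
#' @export
compute_step_parameters <- function(pair_i, pair_j) {
  step_geometry(pair_i, pair_j)$params
}

# Full mid-step construction: returns the six parameters plus the mid-step
# frame itself (used by the intercalation slab test).
step_geometry <- function(pair_i, pair_j) {
  A1 <- pair_i$axes; A2 <- pair_j$axes
  z1 <- A1[, 3]; z2 <- A2[, 3]
  # atan2 form keeps full precision for near-parallel z-axes, where acos
  # of the dot product loses ~sqrt(eps)
  cr <- cross3(z1, z2)
  gamma <- atan2(sqrt(sum(cr^2)), sum(z1 * z2)) * DEG
  if (gamma >= 90)
    stop("antiparallel frames: bending angle ", round(gamma, 1), " degrees")
  if (gamma > 1e-9) {
    hinge <- cr / sqrt(sum(cr^2))
    T1 <- rot_about(hinge, +gamma / 2) %*% A1
    T2 <- rot_about(hinge, -gamma / 2) %*% A2
  } else {
    hinge <- NULL
    T1 <- A1; T2 <- A2
  }
  zc <- (T1[, 3] + T2[, 3]) / 2
  zc <- zc / sqrt(sum(zc^2))
  twist <- signed_angle(T1[, 1], T2[, 1], zc)
  Rm <- rot_about(zc, twist / 2) %*% T1
  if (!is.null(hinge)) {
    phi <- atan2(sum(cross3(Rm[, 2], hinge) * zc), sum(hinge * Rm[, 2])) * DEG
    roll <- gamma * cos(phi / DEG)
    tilt <- gamma * sin(phi / DEG)
  } else {
    roll <- 0; tilt <- 0
  }
  d <- as.vector(t(Rm) %*% (pair_j$origin - pair_i$origin))
  list(params = c(shift = d[1], slide = d[2], rise = d[3],
                  tilt = tilt, roll = roll, twist = twist),
       mid = ref_frame((pair_i$origin + pair_j$origin) / 2, Rm))
}

#' Advance a pair frame by prescribed step parameters
#'
#' Exact inverse of [compute_step_parameters()]: given the frame of pair
#' i and a step-parameter sextuple, returns the frame of pair i+1 such
#' that re-measuring the two frames recovers the parameters to machine
#' precision. This is the elementary move of the B-DNA generator.
#'
#' @param frame [ref_frame()] of pair i.
#' @param params named vector/list with shift, slide, rise, tilt, roll,
#'   twist (Angstrom / degrees).
#' @return [ref_frame()] of pair i+1.
#' @export
step_transform <- function(frame, params) {
  p <- as.list(params)
  gamma <- sqrt(p$roll^2 + p$tilt^2)
  phi <- atan2(p$tilt, p$roll) * DEG
  h <- c(-sin(phi / DEG), cos(phi / DEG), 0)      # hinge in mid-frame coords
  R1m <- rot_about(h, -gamma / 2) %*% rot_about(c(0, 0, 1), -p$twist / 2)
  R2m <- rot_about(h, +gamma / 2) %*% rot_about(c(0, 0, 1), +p$twist / 2)
  Rm <- frame$axes %*% t(R1m)
  d <- c(p$shift, p$slide, p$rise)
  ref_frame(frame$origin + as.vector(Rm %*% d), Rm %*% R2m)
}

#' Step-parameter table and roll profile of a duplex
#'
#' Fits a standard reference frame to every paired base, forms pair
#' frames, and computes the six step parameters for steps 1..N-1 of the
#' paired core (dangling overhangs never enter the indexing). Steps whose
#' frames cannot be fitted (missing ring atoms, degenerate pairing) are
#' reported as missing rather than aborting the profile; steps flanking a
#' flagged flipped-out position carry `flip_adjacent = TRUE`.
#'
#' @param duplex a `dna_duplex` (see [assemble_duplexes()]).
#' @param model the `structure_model` the duplex refers to.
#' @return object of class `roll_profile`: list with `steps` (data.frame:
#'   step_index, dinucleotide, shift, slide, rise, tilt, roll, twist,
#'   missing, flip_adjacent), `rolls`, `dinucleotides` and `n_steps`.
#' @export
roll_profile <- function(duplex, model) {
  stopifnot(inherits(duplex, "dna_duplex"))
  rt <- residue_table(model)
  np <- nrow(duplex$pairs)
  frames <- vector("list", np)
  for (k in seq_len(np)) {
    fI <- try_fit(model, rt, duplex$pairs$res_I[k])
    fII <- try_fit(model, rt, duplex$pairs$res_II[k])
    if (is.null(fI) || is.null(fII)) next
    frames[[k]] <- tryCatch(base_pair_frame(fI, fII), error = function(e) NULL)
  }
  n_steps <- np - 1
  out <- data.frame(step_index = seq_len(n_steps),
                    dinucleotide = paste0(duplex$sequence_I[seq_len(n_steps)],
                                          duplex$sequence_I[seq_len(n_steps) + 1]),
                    shift = NA_real_, slide = NA_real_, rise = NA_real_,
                    tilt = NA_real_, roll = NA_real_, twist = NA_real_,
                    missing = FALSE, flip_adjacent = FALSE,
                    stringsAsFactors = FALSE)
  for (s in seq_len(n_steps)) {
    f1 <- frames[[s]]; f2 <- frames[[s + 1]]
    if (is.null(f1) || is.null(f2)) { out$missing[s] <- TRUE; next }
    p <- tryCatch(compute_step_parameters(f1, f2), error = function(e) NULL)
    if (is.null(p)) { out$missing[s] <- TRUE; next }
    out[s, c("shift", "slide", "rise", "tilt", "roll", "twist")] <- p
  }
  flips <- duplex$flipped_positions
  if (length(flips)) {
    adj <- unique(pmax(1, pmin(n_steps, c(flips - 1, flips))))
    out$flip_adjacent[adj] <- TRUE
  }
  structure(list(steps = out, rolls = out$roll,
                 dinucleotides = out$dinucleotide, n_steps = n_steps),
            class = "roll_profile")
}

try_fit <- function(model, rt, res_idx) {
  base <- rt$base[res_idx]
  if (is.na(base)) return(NULL)
  tryCatch(fit_base_frame(model, rt$rows[[res_idx]], base)$frame,
           error = function(e) NULL)
}

#' @export
print.roll_profile <- function(x, ...) {
  cat(sprintf("roll_profile: %d steps, max roll %.1f deg at step %d\n",
              x$n_steps,
              if (all(is.na(x$rolls))) NA else max(x$rolls, na.rm = TRUE),
              if (all(is.na(x$rolls))) NA else which.max(x$rolls)))
  print(format(x$steps, digits = 3), ...)
  invisible(x)
}

#' Write a step-parameter table as TSV
#' @param profile a `roll_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_step_table <- function(profile, path) {
  utils::write.table(profile$steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
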