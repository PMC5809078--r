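# Kink calling and sidechain-intercalation geometry.

#' Call kinks from a roll profile
#'
#' A step is kinked when its roll exceeds the threshold (35 degrees by
#' default, the screening value for sharply kinked protein-DNA
#' complexes). Calls are sorted by descending roll; the first call's roll
#' is the complex's kink angle, i.e. the largest roll detected. Steps
#' flanking a flagged flipped-out base keep their annotation so such
#' calls are never reported silently. Pure function of the profile.
#'
#' @param profile a [roll_profile()].
#' @param threshold kink threshold, degrees.
#' @return data.frame with columns step_index, roll, dinucleotide,
#'   threshold_used, flip_adjacent; zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_kinks <- function(profile, threshold = 35) {
  st <- profile$steps
  hit <- which(!is.na(st$roll) & st$roll > threshold)
  out <- data.frame(step_index = st$step_index[hit], roll = st$roll[hit],
                    dinucleotide = st$dinucleotide[hit],
                    threshold_used = rep(threshold, length(hit)),
                    flip_adjacent = st$flip_adjacent[hit])
  out <- out[order(-out$roll), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kink angle of a profile
#'
#' The largest roll angle in the profile (reported whether or not it
#' exceeds the kink threshold).
#'
#' @param profile a [roll_profile()].
#' @return numeric scalar, degrees (NA if no step could be measured).
#' @export
kink_angle <- function(profile) {
  r <- profile$rolls
  if (all(is.na(r))) return(NA_real_)
  max(r, na.rm = TRUE)
}

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Detect protein sidechains intercalated at a base-pair step
#'
#' For every amino-acid residue, sidechain heavy atoms (CB and beyond;
#' CA and backbone excluded, so glycine can never intercalate) are tested
#' against the step slab: between the two base-pair mean planes (signed
#' distances of opposite sign, each at most `slab_half` Angstrom) and
#' within `radius` of the mid-step origin. Residues with at least one
#' inserted atom are reported with their insertion depth, measured past
#' the step's C1'-C1' line toward the helix axis.
#'
#' @param model a `structure_model` containing protein and DNA.
#' @param duplex a `dna_duplex`.
#' @param step_index target step, 1-based.
#' @param slab_half half-thickness tolerance of the step slab, Angstrom.
#' @param radius lateral cutoff from the mid-step origin, Angstrom.
#' @return data.frame with one row per intercalating residue: chain,
#'   resno, resid, n_inserted_atoms, n_sidechain_atoms, insertion_depth,
#'   classification ("full"/"partial").
#' @export
detect_intercalation <- function(model, duplex, step_index,
                                 slab_half = 4.5, radius = 7) {
  geo <- mid_step_geometry(model, duplex, step_index)
  rt <- residue_table(model)
  aa <- which(rt$kind == "amino_acid")
  out <- list()
  for (i in aa) {
    a <- model$atom[rt$rows[[i]], , drop = FALSE]
    sc <- a[!(a$elety %in% .backbone_atoms), , drop = FALSE]
    if (!nrow(sc)) next
    p <- as.matrix(sc[, c("x", "y", "z")])
    di <- as.vector((p - matrix(geo$plane_i$origin, nrow(p), 3, byrow = TRUE)) %*%
                      geo$plane_i$axes[, 3])
    dj <- as.vector((p - matrix(geo$plane_j$origin, nrow(p), 3, byrow = TRUE)) %*%
                      geo$plane_j$axes[, 3])
    r <- sqrt(rowSums(sweep(p, 2, geo$mid$origin)^2))
    inside <- di * dj < 0 & abs(di) <= slab_half & abs(dj) <= slab_half &
      r <= radius
    if (!any(inside)) next
    xm <- as.vector(sweep(p, 2, geo$mid$origin) %*% geo$mid$axes[, 1])
    depth <- max(xm[inside]) - geo$c1x
    call <- data.frame(chain = a$chain[1], resno = a$resno[1],
                       resid = a$resid[1], step_index = step_index,
                       n_inserted_atoms = sum(inside),
                       n_sidechain_atoms = nrow(sc),
                       insertion_depth = depth)
    call$classification <- classify_intercalation(call)
    out[[length(out) + 1]] <- call
  }
  if (!length(out))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), step_index = integer(),
                      n_inserted_atoms = integer(),
                      n_sidechain_atoms = integer(),
                      insertion_depth = numeric(),
                      classification = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify an intercalation as full or partial
#'
#' A residue intercalates fully when at least half of its sidechain heavy
#' atoms lie inside the step slab and the deepest atom reaches at least
#' `min_depth` past the C1'-C1' line; otherwise the insertion is partial
#' (a grazing contact). The quantitative surrogate for the visual
#' full/partial distinction; both cut-offs are tunable.
#'
#' @param call one-row data.frame from [detect_intercalation()].
#' @param frac_min minimum inserted fraction of sidechain atoms.
#' @param min_depth minimum insertion depth, Angstrom.
#' @return "full" or "partial".
#' @export
classify_intercalation <- function(call, frac_min = 0.5, min_depth = 1.5) {
  stopifnot(call$n_inserted_atoms >= 1)
  frac <- call$n_inserted_atoms / call$n_sidechain_atoms
  if (frac >= frac_min && call$insertion_depth >= min_depth) "full" else "partial"
}
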