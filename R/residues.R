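# Residue-level classification and editing.

.dna_names <- c("DA", "DC", "DG", "DT")
.rna_names <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU")
.legacy_nuc <- c(A = "A", C = "C", G = "G", T = "T", U = "U",
                 ADE = "A", CYT = "C", GUA = "G", THY = "T", URA = "U")
.aa_names <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
               "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
               "THR", "TRP", "TYR", "VAL")

#' Classify a residue by name and atom content
#'
#' Applies the duplex-screening residue rules: standard deoxynucleotides
#' (DA/DC/DG/DT, or legacy one-letter names without a ribose O2') are
#' `dna_nucleotide`; residues with an O2' atom or standard RNA names are
#' `rna_nucleotide`; base-like rings under any other name are
#' `modified_nucleotide`; the twenty standard amino-acid codes are
#' `amino_acid`; everything else falls through to `other`. Total and
#' deterministic: never errors on unknown names.
#'
#' @param resid 3-letter (or legacy) residue name.
#' @param atom_names character vector of the residue's atom names.
#' @return one of "dna_nucleotide", "rna_nucleotide",
#'   "modified_nucleotide", "amino_acid", "other".
#' @export
classify_residue <- function(resid, atom_names) {
  resid <- toupper(trimws(resid))
  atom_names <- normalize_atom_name(toupper(atom_names))
  has_o2p <- "O2'" %in% atom_names
  if (resid %in% .dna_names) return("dna_nucleotide")
  if (resid %in% .rna_names && has_o2p) return("rna_nucleotide")
  if (resid %in% c("U", "RA", "RC", "RG", "RU", "URA")) return("rna_nucleotide")
  if (resid %in% names(.legacy_nuc) && !has_o2p) return("dna_nucleotide")
  if (resid %in% .aa_names) return("amino_acid")
  # base-like ring present under a nonstandard name -> modified nucleotide
  pyr_ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  if (sum(pyr_ring %in% atom_names) >= 6) return("modified_nucleotide")
  "other"
}

# Base letter for a nucleotide residue name ("DA" -> "A", "THY" -> "T").
base_letter <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- rep(NA_character_, length(resid))
  out[resid %in% .dna_names] <- substring(resid[resid %in% .dna_names], 2, 2)
  leg <- resid %in% names(.legacy_nuc)
  out[leg] <- unname(.legacy_nuc[resid[leg]])
  out
}

#' Per-residue summary of a structure model
#'
#' One row per residue in file order, with the residue kind from
#' [classify_residue()] and the atom-row indices into `model$atom`.
#'
#' @param model a `structure_model`.
#' @return data.frame with columns chain, resno, insert, resid, kind,
#'   base (letter or NA) and a list-column `rows`.
#' @export
residue_table <- function(model) {
  a <- model$atom
  key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
               sep = "|")
  idx <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, integer(1), 1)
  rt <- data.frame(chain = a$chain[first], resno = a$resno[first],
                   insert = a$insert[first], resid = a$resid[first],
                   stringsAsFactors = FALSE)
  rt$kind <- vapply(seq_along(idx), function(i)
    classify_residue(rt$resid[i], a$elety[idx[[i]]]), character(1))
  rt$base <- base_letter(rt$resid)
  rt$rows <- unname(idx)
  rownames(rt) <- NULL
  rt
}

# Coordinates of named atoms in a residue; rows named by atom, NA rows for
# absent atoms when strict = FALSE.
residue_coords <- function(model, rows, atoms = NULL) {
  a <- model$atom[rows, , drop = FALSE]
  nm <- a$elety
  if (is.null(atoms)) {
    m <- as.matrix(a[, c("x", "y", "z")])
    rownames(m) <- nm
    return(m)
  }
  m <- matrix(NA_real_, length(atoms), 3, dimnames = list(atoms, c("x", "y", "z")))
  hit <- match(atoms, nm)
  ok <- !is.na(hit)
  m[ok, ] <- as.matrix(a[hit[ok], c("x", "y", "z")])
  m
}

#' Truncate an amino-acid sidechain to alanine or glycine
#'
#' Builds a mutant in silico the way intercalating-wedge mutants are
#' generated from a wildtype complex: all sidechain atoms beyond the
#' target are removed and the residue renamed, with retained atom
#' coordinates untouched. ALA keeps backbone plus CB; GLY keeps backbone
#' only. No geometry is ever constructed, so GLY -> ALA is refused.
#'
#' @param model a `structure_model`.
#' @param residue_id list or vector `(chain, resno)` or
#'   `(chain, resno, insert)`.
#' @param target "ALA" or "GLY".
#' @return edited `structure_model`.
#' @export
truncate_sidechain <- function(model, residue_id, target = c("ALA", "GLY")) {
  target <- match.arg(target)
  chain <- as.character(residue_id[[1]])
  resno <- as.integer(residue_id[[2]])
  insert <- if (length(residue_id) >= 3) as.character(residue_id[[3]]) else NA
  a <- model$atom
  sel <- a$chain == chain & a$resno == resno &
    (is.na(insert) | (!is.na(a$insert) & a$insert == insert))
  if (!any(sel)) stop("residue ", chain, ":", resno, " not found")
  kind <- classify_residue(a$resid[sel][1], a$elety[sel])
  if (kind != "amino_acid")
    stop("type error: residue ", chain, ":", resno, " is ", kind,
         ", not amino_acid")
  if (a$resid[sel][1] == "GLY" && target == "ALA")
    stop("unsupported: GLY -> ALA would require building CB geometry")
  keep_names <- c("N", "CA", "C", "O", "OXT", if (target == "ALA") "CB")
  if (target == "ALA" && !"CB" %in% a$elety[sel])
    stop("residue ", chain, ":", resno, " has no CB atom; cannot make ALA")
  drop <- sel & !(a$elety %in% keep_names)
  a <- a[!drop, , drop = FALSE]
  a$resid[a$chain == chain & a$resno == resno &
            (is.na(insert) | (!is.na(a$insert) & a$insert == insert))] <- target
  a$eleno <- seq_len(nrow(a))
  structure_model(a, model_index = model$model_index)
}

# Apply a global rigid motion (R x + t) to every atom. Used by tests and
# the synthetic generator.
#' Rigid-body transform of a structure model
#' @param model a `structure_model`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation, Angstrom.
#' @return transformed `structure_model`.
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  m <- as.matrix(model$atom[, c("x", "y", "z")])
  m2 <- sweep(m %*% t(R), 2, t, "+")
  model$atom$x <- m2[, 1]; model$atom$y <- m2[, 2]; model$atom$z <- m2[, 3]
  model
}
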