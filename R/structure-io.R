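# Structure containers and file I/O.
#
# A `structure_model` is a single coordinate model: a flat atom table in
# bio3d style (one row per heavy atom) with columns
#   type, eleno, elety, alt, resid, chain, resno, insert, x, y, z, o, elesy
# A `structure_ensemble` holds one shared atom topology plus an
# n_models x (3 n_atoms) coordinate block, the container used for
# multi-model crystal files and trajectory snapshots.

.atom_cols <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
                "insert", "x", "y", "z", "o", "elesy")

#' Create a single-model structure from an atom table
#'
#' @param atom data.frame with at least elety, resid, chain, resno, x, y, z.
#' @param model_index integer model number (0-based).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atom, model_index = 0L) {
  if (is.null(atom$type)) atom$type <- "ATOM"
  if (is.null(atom$eleno)) atom$eleno <- seq_len(nrow(atom))
  if (is.null(atom$alt)) atom$alt <- NA_character_
  if (is.null(atom$insert)) atom$insert <- NA_character_
  if (is.null(atom$o)) atom$o <- 1.0
  if (is.null(atom$elesy)) atom$elesy <- guess_element(atom$elety)
  atom$elety <- normalize_atom_name(atom$elety)
  stopifnot(all(c("elety", "resid", "chain", "resno", "x", "y", "z")
                %in% names(atom)))
  structure(list(atom = atom[, .atom_cols], model_index = as.integer(model_index)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("structure_model: %d atoms, %d residues, chains %s\n",
              nrow(x$atom), nrow(rt), paste(unique(rt$chain), collapse = " ")))
  invisible(x)
}

#' Create an ensemble from one or more structure models
#'
#' All models must share one atom topology (same atom count, names,
#' residue numbering) when `trajectory = TRUE`; otherwise only the atom
#' count is enforced, which multi-model coordinate blocks require anyway.
#'
#' @param models list of `structure_model` objects.
#' @param metadata list; recognised fields `method`, `identifier`, `format`.
#' @param trajectory enforce identical per-atom topology across models.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(models, metadata = list(), trajectory = FALSE) {
  stopifnot(length(models) >= 1)
  ref <- models[[1]]$atom
  key <- function(a) paste(a$chain, a$resno, a$insert, a$resid, a$elety)
  for (i in seq_along(models)) {
    a <- models[[i]]$atom
    if (nrow(a) != nrow(ref))
      stop("topology error: model ", i, " has ", nrow(a),
           " atoms, expected ", nrow(ref))
    if (trajectory && !identical(key(a), key(ref)))
      stop("topology error: model ", i, " atom identities differ from model 1")
  }
  xyz <- do.call(rbind, lapply(models, function(m)
    as.vector(t(as.matrix(m$atom[, c("x", "y", "z")])))))
  structure(list(atom = ref, xyz = xyz, metadata = metadata),
            class = "structure_ensemble")
}

#' Number of models in an ensemble
#' @param ensemble a `structure_ensemble`.
#' @export
n_models <- function(ensemble) nrow(ensemble$xyz)

#' Extract one model from an ensemble
#' @param ensemble a `structure_ensemble`.
#' @param i model number, 1-based.
#' @return `structure_model`.
#' @export
get_model <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_models(ensemble))
  a <- ensemble$atom
  m <- matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
  a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
  structure_model(a, model_index = i - 1L)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d model(s), %d atoms%s\n",
              n_models(x), nrow(x$atom),
              if (!is.null(x$metadata$identifier))
                paste0(" [", x$metadata$identifier, "]") else ""))
  invisible(x)
}

guess_element <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)))
  substr(nm, 1, 1)
}

is_hydrogen <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    known <- !is.na(e) & nzchar(e)
    out <- guess_element(elety) == "H"
    out[known] <- e[known] %in% c("H", "D")
    return(out)
  }
  guess_element(elety) == "H"
}

# Keep the highest-occupancy alternate location per atom (ties: first in
# file), then blank the altloc tag so downstream code sees one conformer.
resolve_altlocs <- function(atom) {
  alt <- atom$alt
  has_alt <- !is.na(alt) & nzchar(alt) & alt != " "
  if (!any(has_alt)) return(atom)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  keep <- rep(TRUE, nrow(atom))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    best <- idx[which.max(occ[idx])]   # which.max keeps first on ties
    keep[setdiff(idx, best)] <- FALSE
  }
  atom <- atom[keep, , drop = FALSE]
  atom$alt <- NA_character_
  atom
}

#' Read a macromolecular structure file
#'
#' Reads PDB or mmCIF coordinates into a [structure_ensemble()]: one model
#' per MODEL/ENDMDL block (PDB) or per model number (mmCIF); single-model
#' files yield a one-model ensemble. Hydrogens are dropped and alternate
#' locations resolved to the highest-occupancy conformer, so downstream
#' geometry always sees a single heavy-atom conformer. The experiment
#' method is captured from the header (EXPDTA / _exptl.method) when
#' present.
#'
#' @param path file path.
#' @param format_hint "pdb", "mmcif" or "auto" (extension, then content).
#' @param trajectory enforce identical topology across models.
#' @return a [structure_ensemble()].
#' @export
read_structure <- function(path, format_hint = c("auto", "pdb", "mmcif"),
                           trajectory = FALSE) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format_hint
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("cif", "mmcif")) "mmcif"
           else if (ext %in% c("pdb", "ent")) "pdb"
           else if (any(grepl("^data_|_atom_site\\.", readLines(path, n = 50))))
             "mmcif" else "pdb"
  }
  method <- read_experiment_method(path, fmt)
  if (fmt == "pdb") {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE)),
      error = function(e) stop("parse error reading PDB '", path, "': ",
                               conditionMessage(e)))
    models <- pdb_to_models(pdb)
  } else {
    cif <- tryCatch(
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
      error = function(e) stop("parse error reading mmCIF '", path, "': ",
                               conditionMessage(e)))
    models <- pdb_to_models(cif)
  }
  structure_ensemble(models,
                     metadata = list(method = method,
                                     identifier = basename(path),
                                     format = fmt),
                     trajectory = trajectory)
}

# Convert a bio3d pdb object (possibly multi-model) to a model list,
# dropping hydrogens and resolving altlocs on the first model's topology.
pdb_to_models <- function(pdb) {
  a <- pdb$atom
  a$insert <- if (is.null(a$insert)) NA_character_ else as.character(a$insert)
  a$alt <- if (is.null(a$alt)) NA_character_ else as.character(a$alt)
  a$elesy <- if (is.null(a$elesy)) guess_element(a$elety) else a$elesy
  a$elety <- normalize_atom_name(a$elety)
  keep <- !is_hydrogen(a$elety, a$elesy)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  a <- a[keep, , drop = FALSE]
  xyz <- xyz[, as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                               3 * which(keep))), drop = FALSE]
  # altloc resolution on the template; apply the same row selection per model
  a$row0 <- seq_len(nrow(a))
  a2 <- resolve_altlocs(a)
  sel <- a2$row0
  a2$row0 <- NULL
  lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)[sel, , drop = FALSE]
    b <- a2
    b$x <- m[, 1]; b$y <- m[, 2]; b$z <- m[, 3]
    structure_model(b, model_index = i - 1L)
  })
}

read_experiment_method <- function(path, fmt) {
  head <- tryCatch(readLines(path, n = 400), error = function(e) character())
  if (fmt == "pdb") {
    ln <- grep("^EXPDTA", head, value = TRUE)
    if (length(ln)) return(trimws(sub("^EXPDTA\\s*", "", ln[1])))
  } else {
    ln <- grep("_exptl\\.method", head, value = TRUE)
    if (length(ln))
      return(gsub("^['\"]|['\"]$", "",
                  trimws(sub(".*_exptl\\.method\\s*", "", ln[1]))))
  }
  NA_character_
}

#' Write a structure to PDB or mmCIF
#'
#' Multi-model ensembles are written as MODEL/ENDMDL blocks (PDB) or with
#' per-atom model numbers (mmCIF). Coordinates round-trip through
#' [read_structure()] to format precision (1e-3 Angstrom for PDB).
#'
#' @param x a `structure_ensemble` or `structure_model`.
#' @param path output file path.
#' @param format "pdb" or "mmcif".
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (inherits(x, "structure_model")) x <- structure_ensemble(list(x))
  stopifnot(inherits(x, "structure_ensemble"))
  if (format == "pdb") write_pdb_ensemble(x, path) else write_cif_ensemble(x, path)
  invisible(path)
}

write_pdb_ensemble <- function(ens, path) {
  M <- n_models(ens)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(M)) {
    m <- get_model(ens, i)
    tmp <- tempfile(fileext = ".pdb")
    a <- m$atom
    suppressWarnings(bio3d::write.pdb(
      file = tmp,
      xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
      type = a$type, resno = a$resno, resid = a$resid, eleno = a$eleno,
      elety = a$elety, chain = a$chain,
      insert = ifelse(is.na(a$insert), "", a$insert),
      o = ifelse(is.na(a$o), 1, a$o), b = rep(0, nrow(a)),
      elesy = a$elesy, end = FALSE))
    lines <- readLines(tmp)
    unlink(tmp)
    if (M > 1) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(lines, con)
    if (M > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

# Minimal mmCIF atom_site writer (bio3d reads mmCIF but does not write it).
write_cif_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_structure",
               "#",
               "loop_",
               "_atom_site.group_PDB",
               "_atom_site.id",
               "_atom_site.type_symbol",
               "_atom_site.label_atom_id",
               "_atom_site.label_alt_id",
               "_atom_site.label_comp_id",
               "_atom_site.label_asym_id",
               "_atom_site.label_entity_id",
               "_atom_site.label_seq_id",
               "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x",
               "_atom_site.Cartn_y",
               "_atom_site.Cartn_z",
               "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  id <- 0L
  for (i in seq_len(n_models(ens))) {
    a <- get_model(ens, i)$atom
    for (k in seq_len(nrow(a))) {
      id <- id + 1L
      writeLines(sprintf(
        "%s %d %s \"%s\" . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s \"%s\" %d",
        a$type[k], id, a$elesy[k], a$elety[k], a$resid[k], a$chain[k],
        a$resno[k], if (is.na(a$insert[k])) "?" else a$insert[k],
        a$x[k], a$y[k], a$z[k], if (is.na(a$o[k])) 1 else a$o[k],
        a$resno[k], a$resid[k], a$chain[k], a$elety[k], i), con)
    }
  }
  writeLines("#", con)
}
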