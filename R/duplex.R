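# Watson-Crick pair detection and duplex assembly/curation.

#' Detect Watson-Crick base pairs in a model
#'
#' Geometric pairing criteria: complementary base identities (A:T, G:C),
#' C1'-C1' distance in [8.0, 12.5] Angstrom, at least two canonical
#' donor-acceptor contacts within 3.6 Angstrom, and base-plane normals
#' within 65 degrees. Each base joins at most one pair; conflicts are
#' resolved greedily by hydrogen-bond count, then by smaller C1'-C1'
#' distance. Thresholds accept sharply kinked steps (roll up to ~55
#' degrees) without accepting stacked non-pairs.
#'
#' @param model a `structure_model`.
#' @param c1c1_range allowed C1'-C1' distance, Angstrom.
#' @param hbond_max donor-acceptor distance cutoff, Angstrom.
#' @param plane_max base-plane angle cutoff, degrees.
#' @return data.frame with one row per pair: res_I, res_II (row indices
#'   into [residue_table()]), base_I, base_II, n_hbonds, c1c1,
#'   is_watson_crick.
#' @export
detect_base_pairs <- function(model, c1c1_range = c(8.0, 12.5),
                              hbond_max = 3.6, plane_max = 65) {
  rt <- residue_table(model)
  nuc <- which(rt$kind == "dna_nucleotide" & !is.na(rt$base))
  empty <- data.frame(res_I = integer(), res_II = integer(),
                      base_I = character(), base_II = character(),
                      n_hbonds = integer(), c1c1 = numeric(),
                      is_watson_crick = logical())
  if (length(nuc) < 2) return(empty)
  c1 <- t(vapply(nuc, function(i)
    residue_coords(model, rt$rows[[i]], "C1'")[1, ], numeric(3)))
  usable <- stats::complete.cases(c1)
  nuc <- nuc[usable]; c1 <- c1[usable, , drop = FALSE]
  if (length(nuc) < 2) return(empty)
  frames <- lapply(nuc, function(i) try_fit(model, rt, i))

  cand <- list()
  for (a in seq_along(nuc)) {
    for (b in seq_along(nuc)) {
      if (b <= a) next
      ia <- nuc[a]; ib <- nuc[b]
      if (is.na(.wc_partner[rt$base[ia]]) ||
          .wc_partner[rt$base[ia]] != rt$base[ib]) next
      d <- sqrt(sum((c1[a, ] - c1[b, ])^2))
      if (d < c1c1_range[1] || d > c1c1_range[2]) next
      if (is.null(frames[[a]]) || is.null(frames[[b]])) next
      ang <- acos(min(1, abs(sum(frames[[a]]$axes[, 3] *
                                 frames[[b]]$axes[, 3])))) * DEG
      if (ang > plane_max) next
      nh <- count_wc_hbonds(model, rt, ia, ib, hbond_max)
      if (nh < 2) next
      cand[[length(cand) + 1]] <- data.frame(
        res_I = ia, res_II = ib, base_I = rt$base[ia], base_II = rt$base[ib],
        n_hbonds = nh, c1c1 = d, is_watson_crick = TRUE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$n_hbonds, cand$c1c1), , drop = FALSE]
  used <- integer()
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$res_I[k] %in% used || cand$res_II[k] %in% used) next
    keep[k] <- TRUE
    used <- c(used, cand$res_I[k], cand$res_II[k])
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$res_I), , drop = FALSE]
  rownames(out) <- NULL
  out
}

count_wc_hbonds <- function(model, rt, ia, ib, hbond_max) {
  ba <- rt$base[ia]; bb <- rt$base[ib]
  if (ba %in% c("A", "G")) { pur <- ia; pyr <- ib; key <- paste0(ba, bb) }
  else { pur <- ib; pyr <- ia; key <- paste0(bb, ba) }
  tab <- .wc_hbonds[[key]]
  if (is.null(tab)) return(0L)
  pc <- residue_coords(model, rt$rows[[pur]], tab[, 1])
  yc <- residue_coords(model, rt$rows[[pyr]], tab[, 2])
  d <- sqrt(rowSums((pc - yc)^2))
  sum(!is.na(d) & d <= hbond_max)
}

#' Assemble antiparallel duplexes from detected pairs
#'
#' Pairs are partitioned into maximal runs in which the strand-I residues
#' advance by one residue number along one chain while the strand-II
#' residues step back by one along another (antiparallel register). Each
#' run of two or more pairs becomes one duplex; several independent
#' duplexes in one model (separate double helices in a crystal cell, or a
#' helix broken by a flipped-out base) are returned separately.
#'
#' @param pairs output of [detect_base_pairs()].
#' @param model the source `structure_model`.
#' @return list of `dna_duplex` objects. Each holds `pairs`,
#'   `sequence_I`/`sequence_II`, `chain_I`/`chain_II`, trimming counters
#'   and `flipped_positions` (both empty until curation).
#' @export
assemble_duplexes <- function(pairs, model) {
  if (nrow(pairs) == 0) return(list())
  rt <- residue_table(model)
  ord <- order(rt$chain[pairs$res_I], rt$resno[pairs$res_I])
  p <- pairs[ord, , drop = FALSE]
  runs <- list(); cur <- 1L
  for (k in seq_len(nrow(p))[-1]) {
    prev <- p[k - 1, ]; this <- p[k, ]
    adj <- rt$chain[this$res_I] == rt$chain[prev$res_I] &&
      rt$resno[this$res_I] == rt$resno[prev$res_I] + 1 &&
      rt$chain[this$res_II] == rt$chain[prev$res_II] &&
      rt$resno[this$res_II] == rt$resno[prev$res_II] - 1
    if (adj) cur <- c(cur, k)
    else { runs[[length(runs) + 1]] <- cur; cur <- k }
  }
  runs[[length(runs) + 1]] <- cur
  runs <- Filter(function(r) length(r) >= 2, runs)
  all_paired <- c(pairs$res_I, pairs$res_II)
  lapply(runs, function(r) {
    pr <- p[r, , drop = FALSE]
    rownames(pr) <- NULL
    structure(list(pairs = pr,
                   sequence_I = rt$base[pr$res_I],
                   sequence_II = rt$base[pr$res_II],
                   chain_I = rt$chain[pr$res_I[1]],
                   chain_II = rt$chain[pr$res_II[1]],
                   trimmed_5p = 0L, trimmed_3p = 0L,
                   flipped_positions = integer(0),
                   paired_residues = all_paired),
              class = "dna_duplex")
  })
}

#' @export
print.dna_duplex <- function(x, ...) {
  cat(sprintf("dna_duplex: %d bp, strand I %s (%s) / strand II %s\n",
              nrow(x$pairs), paste(x$sequence_I, collapse = ""),
              x$chain_I, x$chain_II))
  if (x$trimmed_5p || x$trimmed_3p)
    cat(sprintf("  trimmed dangling nucleotides: %d (5') / %d (3')\n",
                x$trimmed_5p, x$trimmed_3p))
  if (length(x$flipped_positions))
    cat("  flipped-out positions:", x$flipped_positions, "\n")
  invisible(x)
}

#' Length of a duplex in base pairs
#' @param x a `dna_duplex`.
#' @param ... unused.
#' @export
length.dna_duplex <- function(x) nrow(x$pairs)

# Walk outward from a duplex end along one chain, counting contiguous
# unpaired DNA residues. Returns the count if the walk ends at the chain
# terminus (a dangling overhang) and 0 if it reaches a paired residue
# (an interior break, e.g. a flipped-out base).
count_overhang <- function(rt, chain, start_resno, dir, paired_rows) {
  n <- 0L
  resno <- start_resno + dir
  repeat {
    hit <- which(rt$chain == chain & rt$resno == resno &
                   rt$kind == "dna_nucleotide")
    if (!length(hit)) return(n)
    if (hit[1] %in% paired_rows) return(0L)
    n <- n + 1L
    resno <- resno + dir
  }
}

#' Record and exclude dangling single-stranded ends
#'
#' Unpaired nucleotides beyond the terminal base pairs of either strand
#' shift the pairing register in automated helical analysis; here they
#' are counted into `trimmed_5p`/`trimmed_3p` (per duplex end, 5'/3' of
#' strand I) and excluded from all downstream step indexing. The paired
#' core is untouched, so step index 1 always refers to the first paired
#' dinucleotide.
#'
#' @param duplex a `dna_duplex`.
#' @param model the source `structure_model`.
#' @return the duplex with trimming counters filled in.
#' @export
trim_dangling_ends <- function(duplex, model) {
  rt <- residue_table(model)
  pr <- duplex$pairs
  paired <- duplex$paired_residues
  first <- pr[1, ]; last <- pr[nrow(pr), ]
  duplex$trimmed_5p <-
    count_overhang(rt, rt$chain[first$res_I], rt$resno[first$res_I], -1L, paired) +
    count_overhang(rt, rt$chain[first$res_II], rt$resno[first$res_II], +1L, paired)
  duplex$trimmed_3p <-
    count_overhang(rt, rt$chain[last$res_I], rt$resno[last$res_I], +1L, paired) +
    count_overhang(rt, rt$chain[last$res_II], rt$resno[last$res_II], -1L, paired)
  duplex
}

ring_centroid <- function(model, rt, res_idx) {
  ring <- .ring_atoms[[rt$base[res_idx]]]
  m <- residue_coords(model, rt$rows[[res_idx]], ring)
  colMeans(m, na.rm = TRUE)
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- max(0, min(1, t))
  sqrt(sum((p - (a + t * ab))^2))
}

#' Flag flipped-out bases around a duplex
#'
#' Large roll angles caused by bases rotated out of the helix are
#' curation artefacts, not kinks. A position is flagged when (a) a
#' nominal pair has fewer than two canonical hydrogen bonds, (b) a paired
#' base's ring centroid lies more than `axis_max` from the local helix
#' axis interpolated between the flanking pair origins, or (c) an
#' unpaired nucleotide sits in an interior break of the helix (chain
#' continues to further paired residues on the far side). Flag indices
#' are pair positions; 0 and length+1 denote a flip immediately 5' / 3'
#' of the duplex's paired core. Kinks at steps adjacent to a flagged
#' position are annotated, never silently reported.
#'
#' @param model the source `structure_model`.
#' @param duplex a `dna_duplex`.
#' @param axis_max centroid-to-axis cutoff, Angstrom.
#' @return the duplex with `flipped_positions` filled in.
#' @export
detect_flipped_bases <- function(model, duplex, axis_max = 4.0) {
  rt <- residue_table(model)
  pr <- duplex$pairs
  np <- nrow(pr)
  flags <- integer(0)

  # (a) weakly bonded nominal pairs
  flags <- c(flags, which(pr$n_hbonds < 2))

  # (b) paired bases far off the local axis
  if (np >= 3) {
    origins <- lapply(seq_len(np), function(k) {
      fI <- try_fit(model, rt, pr$res_I[k]); fII <- try_fit(model, rt, pr$res_II[k])
      if (is.null(fI) || is.null(fII)) return(NULL)
      tryCatch(base_pair_frame(fI, fII)$origin, error = function(e) NULL)
    })
    for (k in 2:(np - 1)) {
      if (is.null(origins[[k - 1]]) || is.null(origins[[k]]) ||
          is.null(origins[[k + 1]])) next
      # piecewise local axis through the three pair origins: at a sharp
      # genuine kink the chord would cut the corner, so the middle origin
      # anchors the axis
      for (res in c(pr$res_I[k], pr$res_II[k])) {
        cen <- ring_centroid(model, rt, res)
        d <- min(point_segment_distance(cen, origins[[k - 1]], origins[[k]]),
                 point_segment_distance(cen, origins[[k]], origins[[k + 1]]))
        if (d > axis_max) flags <- c(flags, k)
      }
    }
  }

  # (c) unpaired nucleotides in interior breaks adjacent to the ends
  paired <- duplex$paired_residues
  ends <- list(list(pair = pr[1, ], dirI = -1L, dirII = +1L, pos = 0L),
               list(pair = pr[np, ], dirI = +1L, dirII = -1L, pos = np + 1L))
  for (e in ends) {
    for (side in c("res_I", "res_II")) {
      ch <- rt$chain[e$pair[[side]]]
      resno <- rt$resno[e$pair[[side]]] +
        (if (side == "res_I") e$dirI else e$dirII)
      hit <- which(rt$chain == ch & rt$resno == resno &
                     rt$kind == "dna_nucleotide")
      if (!length(hit) || hit[1] %in% paired) next
      beyond <- count_overhang(rt, ch, rt$resno[hit[1]],
                               if (side == "res_I") e$dirI else e$dirII, paired)
      if (beyond == 0L) flags <- c(flags, e$pos)  # paired beyond: interior flip
    }
  }
  duplex$flipped_positions <- sort(unique(flags))
  duplex
}

#' Detect, assemble and curate all duplexes of a model
#'
#' Convenience wrapper running [detect_base_pairs()],
#' [assemble_duplexes()], [trim_dangling_ends()] and
#' [detect_flipped_bases()] in order.
#'
#' @param model a `structure_model`.
#' @param ... passed to [detect_base_pairs()].
#' @return list of curated `dna_duplex` objects.
#' @export
find_duplexes <- function(model, ...) {
  pairs <- detect_base_pairs(model, ...)
  dup <- assemble_duplexes(pairs, model)
  lapply(dup, function(d)
    detect_flipped_bases(model, trim_dangling_ends(d, model)))
}

#' Write a duplex summary as TSV
#' @param duplex a `dna_duplex`.
#' @param model the source `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_duplex_table <- function(duplex, model, path) {
  rt <- residue_table(model)
  pr <- duplex$pairs
  out <- data.frame(
    pair_index = seq_len(nrow(pr)),
    chain_I = rt$chain[pr$res_I], resno_I = rt$resno[pr$res_I],
    base_I = pr$base_I,
    chain_II = rt$chain[pr$res_II], resno_II = rt$resno[pr$res_II],
    base_II = pr$base_II,
    n_hbonds = pr$n_hbonds, c1c1 = round(pr$c1c1, 3),
    flipped = seq_len(nrow(pr)) %in% duplex$flipped_positions)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
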