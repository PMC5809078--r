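# Batch screening workflow and trajectory analysis front-ends.

#' Default screening configuration
#'
#' All tunable thresholds of the pipeline in one list: kink threshold
#' (35 degrees, the screening value), pairing criteria, intercalation
#' slab geometry, flip-out axis cutoff, stability thresholds and the
#' snapshot budget (2000 equidistant snapshots per trajectory).
#'
#' @param ... overrides for individual fields.
#' @return named list of configuration values.
#' @export
kink_config <- function(...) {
  cfg <- list(
    kink_threshold = 35,        # deg; roll above this is called a kink
    c1c1_range = c(8.0, 12.5),  # Angstrom, C1'-C1' pairing window
    hbond_max = 3.6,            # Angstrom, donor-acceptor cutoff
    plane_max = 65,             # deg, base-plane angle cutoff
    slab_half = 4.5,            # Angstrom, intercalation slab half-width
    slab_radius = 7,            # Angstrom, lateral slab cutoff
    axis_max = 4.0,             # Angstrom, flip-out centroid cutoff
    neighbor_occupancy_max = 0.30,  # kink-shift occupancy for "unstable"
    large_kink = 35,            # deg, mean-roll cut for stable large kink
    n_snapshots = 2000,
    require_crystal = TRUE)     # exclude non-diffraction entries
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

is_crystal_method <- function(method) {
  if (is.na(method) || !nzchar(method)) return(NA)
  grepl("DIFFRACTION|X-RAY|CRYSTAL", toupper(method))
}

#' Analyze one structure model for kinks and intercalation
#'
#' Runs the single-complex pipeline: duplex detection and curation,
#' roll profiles, kink calls at the configured threshold, and
#' intercalating-sidechain detection at every kinked step.
#'
#' @param model a `structure_model`.
#' @param config a [kink_config()] list.
#' @return list with `duplexes`, `profiles`, `kinks` (data.frame across
#'   duplexes), `intercalations` (data.frame) and `kink_angle` (largest
#'   roll over all duplexes).
#' @export
analyze_structure <- function(model, config = kink_config()) {
  dups <- find_duplexes(model, c1c1_range = config$c1c1_range,
                        hbond_max = config$hbond_max,
                        plane_max = config$plane_max)
  profiles <- lapply(dups, roll_profile, model = model)
  kinks <- list(); inter <- list()
  for (d in seq_along(dups)) {
    kc <- detect_kinks(profiles[[d]], threshold = config$kink_threshold)
    if (nrow(kc)) {
      kc$duplex <- d
      kinks[[length(kinks) + 1]] <- kc
      for (s in kc$step_index) {
        ic <- detect_intercalation(model, dups[[d]], s,
                                   slab_half = config$slab_half,
                                   radius = config$slab_radius)
        if (nrow(ic)) { ic$duplex <- d; inter[[length(inter) + 1]] <- ic }
      }
    }
  }
  kinks <- if (length(kinks)) do.call(rbind, kinks) else
    data.frame(step_index = integer(), roll = numeric(),
               dinucleotide = character(), threshold_used = numeric(),
               flip_adjacent = logical(), duplex = integer())
  inter <- if (length(inter)) do.call(rbind, inter) else NULL
  rolls <- unlist(lapply(profiles, function(p) p$rolls))
  list(duplexes = dups, profiles = profiles, kinks = kinks,
       intercalations = inter,
       kink_angle = if (length(rolls) && any(!is.na(rolls)))
         max(rolls, na.rm = TRUE) else NA_real_)
}

#' Screen a batch of structure files for kinked B-DNA
#'
#' Applies the screening workflow to every file: residue-content
#' exclusion filters in fixed order (RNA present, modified nucleotide
#' present, no assemblable duplex, non-crystallographic experiment
#' method), then duplex curation, roll profiles, kink calls and
#' intercalation calls at each kink. Individual file failures become
#' row-level errors, never abort the batch, and every input file yields
#' exactly one report row carrying its first matching exclusion reason.
#'
#' @param paths character vector of PDB/mmCIF file paths.
#' @param config a [kink_config()] list.
#' @return object of class `screen_report`: list with `table` (one row
#'   per file: identifier, outcome, n_duplexes, n_kinks, kink_angle,
#'   kink_steps, intercalators, warnings) and `details` (per-file
#'   analysis results).
#' @export
screen_structures <- function(paths, config = kink_config()) {
  if (length(paths) < 1) stop("usage error: no input files given")
  rows <- list(); details <- list()
  for (path in paths) {
    id <- basename(path)
    row <- data.frame(identifier = id, outcome = "analyzed",
                      n_duplexes = 0L, n_kinks = 0L,
                      kink_angle = NA_real_, kink_steps = "",
                      intercalators = "", warnings = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      warn <- character()
      ens <- read_structure(path)
      model <- get_model(ens, 1)
      rt <- residue_table(model)
      outcome <- NULL
      if (any(rt$kind == "rna_nucleotide")) outcome <- "excluded_rna"
      else if (any(rt$kind == "modified_nucleotide"))
        outcome <- "excluded_modified"
      if (is.null(outcome)) {
        ana <- analyze_structure(model, config)
        if (!length(ana$duplexes)) outcome <- "excluded_single_stranded"
      }
      if (is.null(outcome) && isTRUE(config$require_crystal)) {
        cry <- is_crystal_method(ens$metadata$method)
        if (is.na(cry)) warn <- c(warn, "no experiment method in header")
        else if (!cry) outcome <- "excluded_non_crystal"
      }
      if (is.null(outcome)) {
        row$outcome <- "analyzed"
        row$n_duplexes <- length(ana$duplexes)
        if (length(ana$duplexes) > 1)
          warn <- c(warn, sprintf("%d separate duplexes analyzed independently",
                                  length(ana$duplexes)))
        trims <- vapply(ana$duplexes, function(d)
          d$trimmed_5p + d$trimmed_3p, numeric(1))
        if (any(trims > 0))
          warn <- c(warn, sprintf("trimmed %d dangling nucleotide(s)",
                                  sum(trims)))
        flips <- unlist(lapply(ana$duplexes, `[[`, "flipped_positions"))
        if (length(flips))
          warn <- c(warn, sprintf("%d flipped-out position(s) flagged",
                                  length(flips)))
        row$n_kinks <- nrow(ana$kinks)
        row$kink_angle <- ana$kink_angle
        if (nrow(ana$kinks))
          row$kink_steps <- paste(sprintf("%d:%s(%.1f)", ana$kinks$step_index,
                                          ana$kinks$dinucleotide,
                                          ana$kinks$roll), collapse = ",")
        if (!is.null(ana$intercalations))
          row$intercalators <- paste(
            sprintf("%s%d(%s)", ana$intercalations$resid,
                    ana$intercalations$resno,
                    ana$intercalations$classification), collapse = ",")
        details[[id]] <- ana
      } else {
        row$outcome <- outcome
      }
      row$warnings <- paste(warn, collapse = "; ")
      row
    }, error = function(e) {
      row$outcome <- "error"
      row$warnings <- conditionMessage(e)
      row
    })
    rows[[length(rows) + 1]] <- res
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, details = details, config = config),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report:", nrow(x$table), "file(s)\n")
  print(x$table, ...)
  invisible(x)
}

#' Write a screen report as TSV and JSON
#' @param report a `screen_report`.
#' @param tsv,json output paths (NULL to skip either).
#' @return invisibly, the report.
#' @export
write_screen_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report$table, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(report)
}

#' Analyze a multi-model trajectory ensemble
#'
#' The trajectory workflow: equidistant snapshot selection, roll time
#' course on a fixed duplex topology, average roll profile, Gaussian
#' histogram fit at the reference step (the largest-mean-roll step by
#' default) and the three-way stability classification.
#'
#' @param ensemble a `structure_ensemble` with more than one model, or a
#'   path to a multi-model file.
#' @param duplex optional `dna_duplex`; detected on the first model by
#'   default.
#' @param reference_step optional step index; defaults to the step with
#'   the largest mean roll.
#' @param config a [kink_config()] list.
#' @return list with `time_series`, `average_profile`, `histogram_fit`,
#'   `stability` and `reference_step`.
#' @export
analyze_trajectory <- function(ensemble, duplex = NULL,
                               reference_step = NULL,
                               config = kink_config()) {
  if (is.character(ensemble))
    ensemble <- read_structure(ensemble, trajectory = TRUE)
  if (n_models(ensemble) < 2)
    stop("single-model input: use screen_structures()/analyze_structure() ",
         "for static complexes")
  snaps <- sample_snapshots(ensemble, config$n_snapshots)
  model1 <- get_model(snaps, 1)
  if (is.null(duplex)) {
    dups <- find_duplexes(model1, c1c1_range = config$c1c1_range,
                          hbond_max = config$hbond_max,
                          plane_max = config$plane_max)
    if (!length(dups)) stop("no duplex found in first snapshot")
    duplex <- dups[[1]]
  }
  ts <- roll_time_course(snaps, duplex)
  if (is.null(reference_step))
    reference_step <- unname(which.max(ts$average_profile))
  fit <- tryCatch(fit_roll_histogram(ts$values[, reference_step]),
                  error = function(e) NULL)
  stab <- classify_stability(
    ts, reference_step,
    neighbor_occupancy_max = config$neighbor_occupancy_max,
    large_kink = config$large_kink)
  list(time_series = ts, average_profile = ts$average_profile,
       histogram_fit = fit, stability = stab,
       reference_step = reference_step)
}
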