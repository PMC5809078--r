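# Trajectory observables: roll time courses, average profiles, Gaussian
# histogram fits and the three-way conformational-stability
# classification.

#' Select equidistant snapshots from an ensemble
#'
#' Deterministic equidistant sampling: model indices
#' `floor(k * M / n) + 1` for k = 0..n-1 over M models, so the first
#' model is always included. When the ensemble holds fewer than `n`
#' models, all are used with a warning.
#'
#' @param ensemble a `structure_ensemble`.
#' @param n requested snapshot count (default 2000, the per-trajectory
#'   snapshot budget used throughout).
#' @return a `structure_ensemble` restricted to the selected snapshots,
#'   with the chosen indices in `metadata$snapshot_indices`.
#' @export
sample_snapshots <- function(ensemble, n = 2000) {
  M <- n_models(ensemble)
  if (M < 1) stop("empty ensemble")
  if (M < n) {
    warning("ensemble has ", M, " models; clamping snapshot count from ",
            n, " to ", M)
    n <- M
  }
  idx <- floor((seq_len(n) - 1) * M / n) + 1L
  ensemble$xyz <- ensemble$xyz[idx, , drop = FALSE]
  ensemble$metadata$snapshot_indices <- idx
  ensemble
}

#' Roll time-series matrix of a snapshot ensemble
#'
#' Computes the roll profile of every snapshot on a fixed duplex
#' topology. Row s holds the per-step rolls of snapshot s; the average
#' profile is the vector of column means. Steps that fail frame fitting
#' in a snapshot are stored as NA, excluded from that column's mean, and
#' counted in `n_missing`.
#'
#' @param ensemble a trajectory `structure_ensemble` (or list of
#'   `structure_model`s).
#' @param duplex a `dna_duplex` valid in every snapshot.
#' @return object of class `roll_time_series`: list with `values`
#'   (n_snapshots x n_steps), `average_profile`, `dinucleotides`,
#'   `n_missing` and `snapshot_indices`.
#' @export
roll_time_course <- function(ensemble, duplex) {
  models <- if (inherits(ensemble, "structure_ensemble"))
    lapply(seq_len(n_models(ensemble)), function(i) get_model(ensemble, i))
  else ensemble
  stopifnot(length(models) >= 1)
  first <- roll_profile(duplex, models[[1]])
  ns <- first$n_steps
  vals <- matrix(NA_real_, length(models), ns)
  vals[1, ] <- first$rolls
  if (length(models) > 1) {
    for (s in 2:length(models)) {
      prof <- tryCatch(roll_profile(duplex, models[[s]]),
                       error = function(e)
                         stop("snapshot ", s, ": ", conditionMessage(e)))
      if (prof$n_steps != ns)
        stop("topology mismatch in snapshot ", s, ": ", prof$n_steps,
             " steps, expected ", ns)
      vals[s, ] <- prof$rolls
    }
  }
  colnames(vals) <- first$dinucleotides
  idx <- if (inherits(ensemble, "structure_ensemble") &&
             !is.null(ensemble$metadata$snapshot_indices))
    ensemble$metadata$snapshot_indices else seq_len(nrow(vals))
  structure(list(values = vals,
                 average_profile = colMeans(vals, na.rm = TRUE),
                 dinucleotides = first$dinucleotides,
                 n_missing = colSums(is.na(vals)),
                 snapshot_indices = idx),
            class = "roll_time_series")
}

#' @export
print.roll_time_series <- function(x, ...) {
  cat(sprintf("roll_time_series: %d snapshots x %d steps\n",
              nrow(x$values), ncol(x$values)))
  cat("average profile (deg):",
      paste(sprintf("%.1f", x$average_profile), collapse = " "), "\n")
  invisible(x)
}

#' Gaussian fit to a roll-angle histogram
#'
#' Histograms the values (fixed-width bins, 2 degrees over [-20, 80] by
#' default, widened when data fall outside) and fits the bin counts by
#' nonlinear least squares to `y = a * exp(b * (x - c)^2)` with `b`
#' constrained negative, initialised from sample moments. The fitted
#' center `c` estimates the modal roll; `-1/(2b)` estimates the
#' variance.
#'
#' @param values roll angles, degrees (at least 50).
#' @param bin_width histogram bin width, degrees.
#' @param range histogram range, degrees (extended to cover the data).
#' @return object of class `roll_histogram_fit`: list with `a`, `b`,
#'   `c`, `rss`, `sd_equiv` and the histogram (`mids`, `counts`).
#' @export
fit_roll_histogram <- function(values, bin_width = 2, range = c(-20, 80)) {
  values <- values[!is.na(values)]
  if (length(values) < 50)
    stop("need at least 50 values to fit a histogram (got ",
         length(values), ")")
  if (stats::var(values) < 1e-8)
    stop("fit-degenerate: variance of values is ~0")
  lo <- min(range[1], floor(min(values) / bin_width) * bin_width)
  hi <- max(range[2], ceiling(max(values) / bin_width) * bin_width)
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  start <- list(a = max(h$counts), b = -1 / (2 * stats::var(values)),
                c = mean(values))
  out <- fit_gauss_counts(h$mids, h$counts, start)
  if (out$c < min(values) - bin_width || out$c > max(values) + bin_width)
    warning("fitted center outside the observed data range")
  out
}

# Nonlinear least-squares core on binned counts (b constrained negative).
fit_gauss_counts <- function(mids, counts, start) {
  fit <- minpack.lm::nlsLM(y ~ a * exp(b * (x - c)^2),
                           data = data.frame(x = mids, y = counts),
                           start = start,
                           upper = c(a = Inf, b = -1e-9, c = Inf),
                           lower = c(a = 0, b = -Inf, c = -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                 rss = sum(stats::resid(fit)^2),
                 sd_equiv = sqrt(-1 / (2 * cf[["b"]])),
                 mids = mids, counts = counts),
            class = "roll_histogram_fit")
}

#' @export
print.roll_histogram_fit <- function(x, ...) {
  cat(sprintf(
    "gaussian histogram fit: a=%.2f, b=%.4f, c=%.2f deg (sd %.2f), rss=%.2f\n",
    x$a, x$b, x$c, x$sd_equiv, x$rss))
  invisible(x)
}

#' Classify the conformational stability of a kinked step
#'
#' Mutants of intercalating residues fall into three groups: (a) stable
#' with a large kink retained, (b) stable with a reduced kink, (c)
#' conformationally unstable, with the kink wandering to an adjacent
#' step. Operationalised per snapshot: the step carrying the maximum
#' roll within `window` of the reference step is located; if a
#' neighbouring step carries the maximum in at least
#' `neighbor_occupancy_max` of snapshots the system is `unstable`;
#' otherwise the class follows the mean roll at the reference step
#' against `large_kink` (35 degrees).
#'
#' @param ts a `roll_time_series` (or plain snapshots x steps matrix).
#' @param reference_step column index of the kinked step.
#' @param window neighbourhood half-width in steps.
#' @param neighbor_occupancy_max occupancy fraction above which the kink
#'   is considered to have shifted.
#' @param large_kink mean-roll cut for a large kink, degrees.
#' @return object of class `stability_assessment`: list with
#'   `reference_step`, `occupancy`, `neighbor_occupancy`, `mean_kink`,
#'   `argmax_step` (modal step) and `class`.
#' @export
classify_stability <- function(ts, reference_step, window = 1,
                               neighbor_occupancy_max = 0.30,
                               large_kink = 35) {
  m <- if (inherits(ts, "roll_time_series")) ts$values else as.matrix(ts)
  ns <- ncol(m)
  stopifnot(reference_step >= 1, reference_step <= ns)
  win <- max(1, reference_step - window):min(ns, reference_step + window)
  sub <- m[, win, drop = FALSE]
  ok <- rowSums(is.na(sub)) == 0
  arg <- win[apply(sub[ok, , drop = FALSE], 1, which.max)]
  occupancy <- mean(arg == reference_step)
  neighbor_occupancy <- 1 - occupancy
  mean_kink <- mean(m[, reference_step], na.rm = TRUE)
  class <- if (neighbor_occupancy >= neighbor_occupancy_max) "unstable"
  else if (mean_kink >= large_kink) "stable_large_kink"
  else "stable_reduced_kink"
  structure(list(reference_step = reference_step, occupancy = occupancy,
                 neighbor_occupancy = neighbor_occupancy,
                 mean_kink = mean_kink,
                 argmax_step = as.integer(names(which.max(table(arg)))),
                 class = class),
            class = "stability_assessment")
}

#' @export
print.stability_assessment <- function(x, ...) {
  cat(sprintf(
    "stability: %s (ref step %d, occupancy %.2f, mean kink %.1f deg)\n",
    x$class, x$reference_step, x$occupancy, x$mean_kink))
  invisible(x)
}

#' Write a roll time-series matrix as TSV
#' @param ts a `roll_time_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(ts, path) {
  df <- data.frame(snapshot = ts$snapshot_indices, ts$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
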