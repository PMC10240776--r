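# Ensemble benchmarking: per-complex TM-score and L-rms summaries,
# fraction-vs-threshold curves, and performance as a function of ensemble
# size. All statistics are pure functions of the per-frame metric lists.

#' Score an ensemble against a reference structure
#'
#' Computes per-frame TM-score (protein C-alpha trace) and L-rms (ligand
#' heavy-atom RMSD after protein superposition) against the reference, and
#' records medians and bests.
#'
#' @param ensemble A `structure_ensemble` (or plain list of
#'   [coordinate_frame()]s).
#' @param reference A [coordinate_frame()] with the same atom roles.
#' @param system_id Optional identifier carried into the result.
#' @return An `ensemble_metrics` object: lists `tm_score`, `l_rms`, plus
#'   `median_tm`, `best_tm`, `median_lrms`, `best_lrms`, `system_id`.
#' @export
score_ensemble <- function(ensemble, reference, system_id = NA_character_) {
  frames <- if (inherits(ensemble, "structure_ensemble")) ensemble$frames
            else ensemble
  stopifnot(inherits(reference, "coordinate_frame"))
  for (fr in frames)
    if (!identical(fr$roles, reference$roles))
      stop("frame atom roles do not match the reference")
  ip <- reference$roles == "protein"
  tm <- vapply(frames, function(fr)
    tm_score(fr$coords[ip, , drop = FALSE],
             reference$coords[ip, , drop = FALSE]), 1.0)
  lr <- vapply(frames, function(fr) ligand_rms(fr, reference), 1.0)
  structure(list(tm_score = tm, l_rms = lr,
                 median_tm = stats::median(tm), best_tm = max(tm),
                 median_lrms = stats::median(lr), best_lrms = min(lr),
                 system_id = system_id),
            class = "ensemble_metrics")
}

#' @export
print.ensemble_metrics <- function(x, ...) {
  cat(sprintf(
    "<ensemble_metrics %d frames  TM med %.3f best %.3f  L-rms med %.2f best %.2f>\n",
    length(x$tm_score), x$median_tm, x$best_tm, x$median_lrms, x$best_lrms))
  invisible(x)
}

#' Fraction-of-complexes threshold curve
#'
#' For each threshold, the fraction of complexes whose best ensemble frame
#' passes: TM-score above the threshold, or L-rms below it. Non-increasing in
#' the TM threshold and non-decreasing in the L-rms threshold.
#'
#' @param metrics_list List of [score_ensemble()] results (one per complex).
#' @param metric `"tm"` or `"lrms"`.
#' @param thresholds Numeric grid (defaults: 0.5..1 for TM, 0..5 angstroms
#'   for L-rms).
#' @return A data.frame with columns `threshold`, `fraction`.
#' @export
threshold_curve <- function(metrics_list, metric = c("tm", "lrms"),
                            thresholds = NULL) {
  metric <- match.arg(metric)
  if (length(metrics_list) == 0L) stop("no complexes to evaluate")
  if (is.null(thresholds))
    thresholds <- if (metric == "tm") seq(0.5, 1, by = 0.02)
                  else seq(0, 5, by = 0.1)
  best <- vapply(metrics_list, function(m)
    if (metric == "tm") m$best_tm else m$best_lrms, 1.0)
  frac <- vapply(thresholds, function(th)
    mean(if (metric == "tm") best > th else best < th), 1.0)
  data.frame(threshold = thresholds, fraction = frac)
}

#' Success fraction as a function of ensemble size
#'
#' Mean over `n_reps` seeded random `k`-subsets (without replacement) of the
#' fraction of complexes with any subset frame under each L-rms cutoff
#' (2 and 5 angstroms by default, the conventional docking success bands).
#'
#' @param metrics_list List of [score_ensemble()] results.
#' @param k Subset size (`<=` frame count).
#' @param n_reps Number of random subsets.
#' @param seed RNG seed.
#' @param cutoffs L-rms cutoffs in angstroms.
#' @return A data.frame with columns `cutoff`, `k`, `success`.
#' @export
subsample_performance <- function(metrics_list, k, n_reps = 20L, seed = 1L,
                                  cutoffs = c(2, 5)) {
  if (length(metrics_list) == 0L) stop("no complexes to evaluate")
  n_frames <- length(metrics_list[[1L]]$l_rms)
  if (k > n_frames) stop("k exceeds the ensemble size")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  succ <- matrix(0, n_reps, length(cutoffs))
  for (r in seq_len(n_reps)) {
    idx <- if (k == n_frames) seq_len(n_frames) else sample(n_frames, k)
    for (ci in seq_along(cutoffs)) {
      hit <- vapply(metrics_list, function(m)
        any(m$l_rms[idx] < cutoffs[ci]), TRUE)
      succ[r, ci] <- mean(hit)
    }
  }
  data.frame(cutoff = rep(cutoffs, each = 1L),
             k = k, success = colMeans(succ))
}

#' Group success fractions by a per-complex annotation
#'
#' Generic group-by tooling for stratified views (ligand rotatable-bond
#' counts, related-training-data counts, and similar): the fraction of
#' complexes per annotation level whose best L-rms is under the cutoff.
#'
#' @param metrics_list List of [score_ensemble()] results.
#' @param annotations Vector of group labels, one per complex.
#' @param cutoff L-rms cutoff in angstroms.
#' @return A data.frame with columns `group`, `n`, `success`.
#' @export
stratified_success <- function(metrics_list, annotations, cutoff = 2) {
  stopifnot(length(annotations) == length(metrics_list))
  best <- vapply(metrics_list, function(m) m$best_lrms, 1.0)
  agg <- tapply(best < cutoff, annotations, mean)
  cnt <- tapply(best, annotations, length)
  data.frame(group = names(agg), n = as.integer(cnt),
             success = as.numeric(agg), row.names = NULL)
}
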