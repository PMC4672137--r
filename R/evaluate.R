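# Five-metric evaluation (VOE, RVD, ASD, RMSD, MSD) and the linear
# 100/75-calibrated scoring used by the public liver segmentation challenges.

#' Volumetric overlap error
#'
#' `100 * (1 - |A intersect B| / |A union B|)` in percent; 0 for identical
#' masks, 100 for disjoint ones.
#'
#' @param a,b [segmentation_mask]s or logical arrays of identical dimension.
#' @return Percentage in \[0, 100\].
#' @export
volume_overlap_error <- function(a, b) {
  A <- as_mask_array(a); B <- as_mask_array(b)
  if (!identical(dim(A), dim(B))) stop("masks must be congruent")
  un <- sum(A | B)
  if (un == 0) stop("both masks are empty")
  100 * (1 - sum(A & B) / un)
}

#' Relative volume difference
#'
#' Signed `100 * (|A| - |B|) / |B|` against the reference mask `B`; the
#' absolute value is used for scoring.
#'
#' @param a segmentation under test.
#' @param b reference mask (non-empty).
#' @return Signed percentage.
#' @export
relative_volume_difference <- function(a, b) {
  A <- as_mask_array(a); B <- as_mask_array(b)
  if (!identical(dim(A), dim(B))) stop("masks must be congruent")
  nb <- sum(B)
  if (nb == 0) stop("reference mask is empty")
  100 * (sum(A) - nb) / nb
}

#' Symmetric surface distances
#'
#' Border voxels are mask voxels with at least one background 6-neighbour
#' (the array boundary counts as background); distances are voxel-centre
#' Euclidean distances in mm. ASD is the mean over both surfaces of the
#' distance to the other surface, RMSD the root mean square, MSD the maximum
#' (symmetric Hausdorff).
#'
#' @param a,b non-empty masks ([segmentation_mask] or logical array).
#' @param spacing voxel spacing in mm; taken from `a` when it is a
#'   [segmentation_mask].
#' @return Named vector `c(asd, rmsd, msd)` in mm.
#' @export
surface_distances <- function(a, b, spacing = NULL) {
  if (is.null(spacing) && inherits(a, "segmentation_mask"))
    spacing <- a$spacing
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  A <- as_mask_array(a); B <- as_mask_array(b)
  if (!identical(dim(A), dim(B))) stop("masks must be congruent")
  if (!any(A) || !any(B)) stop("empty mask has no surface")
  d <- .surface_dists_cpp(as.vector(A), as.vector(B), as.integer(dim(A)),
                          as.numeric(spacing))
  c(asd = mean(d), rmsd = sqrt(mean(d^2)), msd = max(d))
}

#' Reference per-metric errors of the scoring calibration
#'
#' The average manual-segmentation errors worth 75 score points per metric:
#' VOE 6.4 %, RVD 4.7 %, ASD 1.0 mm, RMSD 1.8 mm, MSD 19.0 mm.
#'
#' @return Named numeric vector.
#' @export
reference_errors <- function() {
  c(voe = 6.4, rvd = 4.7, asd = 1.0, rmsd = 1.8, msd = 19.0)
}

#' Per-metric score
#'
#' Linear interpolation through the two calibration anchors - zero error is
#' worth 100, the reference error 75 - clamped at 0:
#' `score = max(0, 100 - 25 * error / reference)`.
#'
#' @param error nonnegative error value(s) (use the absolute value of the
#'   signed RVD).
#' @param reference positive reference error(s).
#' @return Score value(s) in \[0, 100\].
#' @export
metric_score <- function(error, reference) {
  if (any(reference <= 0)) stop("reference errors must be positive")
  if (any(error < 0)) stop("errors must be nonnegative (take |RVD|)")
  pmax(0, 100 - 25 * error / reference)
}

#' Total score from the five error metrics
#'
#' @param errors named vector or list with `voe`, `rvd`, `asd`, `rmsd`,
#'   `msd` (RVD may be signed; its absolute value is scored).
#' @param refs reference errors (default [reference_errors()]).
#' @return A `score_report` list: `errors`, `scores` (per metric) and
#'   `total` (their mean).
#' @export
total_score <- function(errors, refs = reference_errors()) {
  e <- unlist(errors)[names(refs)]
  if (any(is.na(e))) stop("errors must contain voe, rvd, asd, rmsd, msd")
  scores <- setNames(metric_score(abs(e), refs), names(refs))
  structure(list(errors = e, scores = scores, total = mean(scores)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report>\n")
  for (m in names(x$scores))
    cat(sprintf("  %-5s error %8.3f  score %6.2f\n", m, x$errors[m],
                x$scores[m]))
  cat(sprintf("  total score %.2f\n", x$total))
  invisible(x)
}

#' Full evaluation of a segmentation against a reference
#'
#' @param pred predicted [segmentation_mask].
#' @param ref reference mask.
#' @param spacing voxel spacing in mm (default from `pred`).
#' @param refs scoring reference errors.
#' @return A `score_report` (see [total_score]).
#' @export
evaluate_segmentation <- function(pred, ref, spacing = NULL,
                                  refs = reference_errors()) {
  sd3 <- surface_distances(pred, ref, spacing)
  total_score(c(voe = volume_overlap_error(pred, ref),
                rvd = relative_volume_difference(pred, ref),
                sd3),
              refs = refs)
}

#' Recompute total scores from a table of printed errors
#'
#' @param errors data frame with columns `voe`, `rvd`, `asd`, `rmsd`, `msd`
#'   (one row per dataset).
#' @param refs scoring reference errors.
#' @return The input with an added `score` column (per-row total score).
#' @export
score_table <- function(errors, refs = reference_errors()) {
  need <- names(refs)
  if (!all(need %in% names(errors)))
    stop("error table must have columns ", paste(need, collapse = ", "))
  errors$score <- vapply(seq_len(nrow(errors)), function(i)
    total_score(unlist(errors[i, need]), refs = refs)$total, 0.0)
  errors
}

#' Published per-dataset evaluation errors
#'
#' Printed five-metric error values for the ten MICCAI 2007 training volumes
#' and the ten 3D-IRCAD volumes, used as inputs to the scoring scheme (the
#' printed per-dataset scores are kept for cross-checking).
#'
#' @param which `"miccai"` or `"ircad"`.
#' @return Data frame with columns `dataset`, `voe`, `rvd`, `asd`, `rmsd`,
#'   `msd`, `printed_score`.
#' @export
liver_benchmark_errors <- function(which = c("miccai", "ircad")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_errors.csv"),
                      package = "swarmcut", mustWork = TRUE)
  read.csv(path)
}
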