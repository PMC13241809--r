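# Tract-level feature aggregation and lateralization-index computation.
#
# Features are tract-level scalars: four diffusion-tensor indices (FA, MD, AD,
# RD) aggregated over the tract mask, plus two macrostructural features
# (volume in mm^3, mean streamline length in mm). Asymmetry is quantified by
# the lateralization index LI = (R - L) / (R + L), positive when the right
# hemisphere carries the larger value.

#' Tract and feature vocabularies
#'
#' The 30 bilateral tract labels and 6 tract-level features handled by the
#' package. Tracts follow the TractSeg-style bundle nomenclature (arcuate
#' fasciculus, cingulum, corticospinal tract, thalamo- and striato-cortical
#' projections, ...).
#'
#' @return character vector of labels.
#' @export
tract_labels <- function() {
  c("AF", "ATR", "CG", "CST", "FPT", "FX", "ICP", "IFOF", "ILF", "MLF",
    "OR", "POPT", "SCP", "SLF_I", "SLF_II", "SLF_III",
    "ST_FO", "ST_OCC", "ST_PAR", "ST_POSTC", "ST_PREC", "ST_PREF", "ST_PREM",
    "T_OCC", "T_PAR", "T_POSTC", "T_PREC", "T_PREF", "T_PREM", "UF")
}

#' @rdname tract_labels
#' @export
feature_labels <- function() {
  c("FA", "MD", "AD", "RD", "volume", "length")
}

#' Lateralization index of a bilateral measure
#'
#' Computes `LI = (right - left) / (right + left)`, the normalized left-right
#' contrast. The index is bounded in (-1, 1) for strictly positive inputs; 0
#' means perfect symmetry, positive values mean rightward asymmetry (larger
#' right-hemisphere value). Being a within-subject ratio, it is invariant to
#' any global scaling that affects both hemispheres equally.
#'
#' @param left,right strictly positive, finite feature values (vectorized).
#' @return numeric vector of indices in (-1, 1).
#' @examples
#' laterality_index(0.5, 0.5)  # 0: perfect symmetry
#' laterality_index(1, 3)      # 0.5: rightward
#' @export
laterality_index <- function(left, right) {
  if (length(left) != length(right)) {
    stop("'left' and 'right' must have equal length")
  }
  bad_l <- !is.finite(left) | left <= 0
  bad_r <- !is.finite(right) | right <= 0
  if (any(bad_l)) {
    stop("non-positive or non-finite left-hemisphere value at position ",
         which(bad_l)[1])
  }
  if (any(bad_r)) {
    stop("non-positive or non-finite right-hemisphere value at position ",
         which(bad_r)[1])
  }
  (right - left) / (right + left)
}

#' Streamline-weighted tract mean of a voxelwise scalar
#'
#' Aggregates per-voxel scalar samples (e.g. FA) to a single tract value as a
#' weighted average, each voxel weighted by the number of streamlines passing
#' through it.
#'
#' @param values finite per-voxel scalar samples.
#' @param weights non-negative per-voxel streamline counts; positive sum.
#' @return scalar weighted mean, guaranteed within `range(values)`.
#' @export
weighted_tract_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("'values' and 'weights' must have equal length")
  }
  if (!all(is.finite(values))) stop("non-finite values")
  if (!all(is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  sw <- sum(weights)
  if (sw <= 0) stop("weights sum to zero")
  sum(weights * values) / sw
}

#' Tract volume from voxel count
#'
#' @param voxel_count non-negative voxel count of the tract mask.
#' @param voxel_dims voxel dimensions in mm, length-3 positive vector.
#' @return volume in mm^3.
#' @export
tract_volume <- function(voxel_count, voxel_dims) {
  stopifnot(length(voxel_dims) == 3L, all(voxel_dims > 0))
  if (any(voxel_count < 0)) stop("negative voxel count")
  voxel_count * prod(voxel_dims)
}

#' Mean streamline length
#'
#' @param lengths non-empty vector of per-streamline lengths in mm, all > 0.
#' @return arithmetic mean length in mm.
#' @export
mean_streamline_length <- function(lengths) {
  if (length(lengths) == 0L) stop("empty streamline set")
  if (any(!is.finite(lengths) | lengths <= 0)) {
    stop("streamline lengths must be positive and finite")
  }
  mean(lengths)
}

#' Build a laterality table from bilateral measures
#'
#' Joins bilateral measures to subject covariates and computes one LI
#' observation per (subject, tract, feature). Rows with a non-positive
#' hemispheric value - degenerate extractions for which the LI is undefined -
#' are dropped rather than clamped, and the exclusions are counted in the
#' `"exclusions"` attribute of the result.
#'
#' @param measures data.frame with columns `subject_id`, `tract`, `feature`,
#'   `left_value`, `right_value`.
#' @param covariates data.frame with columns `subject_id`, `age_years`,
#'   `sex`, `cohort_id` and optionally `handedness`; one row per subject.
#' @return data.frame with covariates plus `tract`, `feature`, `li`;
#'   attribute `"exclusions"` is a data.frame of the dropped rows.
#' @export
build_laterality_table <- function(measures, covariates) {
  need_m <- c("subject_id", "tract", "feature", "left_value", "right_value")
  need_c <- c("subject_id", "age_years", "sex", "cohort_id")
  if (!all(need_m %in% names(measures))) {
    stop("measures must have columns: ", paste(need_m, collapse = ", "))
  }
  if (!all(need_c %in% names(covariates))) {
    stop("covariates must have columns: ", paste(need_c, collapse = ", "))
  }
  if (anyDuplicated(covariates$subject_id)) {
    stop("covariates must have one row per subject_id")
  }
  idx <- match(measures$subject_id, covariates$subject_id)
  if (anyNA(idx)) {
    orphan <- measures$subject_id[which(is.na(idx))[1]]
    stop("measure references unknown subject_id: ", orphan)
  }
  ok <- is.finite(measures$left_value) & measures$left_value > 0 &
    is.finite(measures$right_value) & measures$right_value > 0
  excl <- measures[!ok, , drop = FALSE]

  m <- measures[ok, , drop = FALSE]
  idx <- idx[ok]
  out <- data.frame(
    subject_id = m$subject_id,
    age_years  = covariates$age_years[idx],
    sex        = covariates$sex[idx],
    cohort_id  = covariates$cohort_id[idx],
    handedness = if ("handedness" %in% names(covariates)) {
      covariates$handedness[idx]
    } else {
      rep("unknown", nrow(m))
    },
    tract      = m$tract,
    feature    = m$feature,
    li         = laterality_index(m$left_value, m$right_value),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  if (nrow(excl) > 0) {
    message(nrow(excl), " row(s) with non-positive hemispheric values excluded")
  }
  out
}
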