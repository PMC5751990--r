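## Response labelling from clinical/pathological rules, change-from-baseline
## features, and assembly of the 65-entry per-patient feature vector.

#' Classify treatment response from clinical and pathological findings
#'
#' Complete responder (CR): no clinical evidence of tumor and no histological
#' evidence of invasive carcinoma. Partial responder (PR): at least a 50%
#' decrease in tumor size together with a significant decrease in tumor
#' cellularity. Non-responder (NR): otherwise.
#'
#' @param preSize pre-treatment tumor size, cm (> 0).
#' @param postSize post-treatment tumor size, cm (>= 0).
#' @param invasiveResidual logical, invasive carcinoma present in the
#'   surgical specimen.
#' @param cellularityDecreased logical, significant decrease in tumor
#'   cellularity (pathology-derived input, not computed here).
#' @param clinicalTumorEvidence logical, clinical evidence of residual tumor.
#' @return one of "CR", "PR", "NR".
#' @examples
#' classifyResponse(4.9, 0, FALSE, TRUE, FALSE)   # CR
#' classifyResponse(6.2, 2.6, TRUE, TRUE, TRUE)   # PR
#' classifyResponse(6.1, 5.9, TRUE, FALSE, TRUE)  # NR
#' @export
classifyResponse <- function(preSize, postSize, invasiveResidual,
                             cellularityDecreased, clinicalTumorEvidence) {
  if (!isScalarNumber(preSize) || preSize <= 0)
    stopf("preSize must be a positive size in cm")
  if (!isScalarNumber(postSize) || postSize < 0)
    stopf("postSize must be a nonnegative size in cm")
  if (!clinicalTumorEvidence && !invasiveResidual) return("CR")
  decrease <- (preSize - postSize) / preSize
  if (decrease >= 0.5 && cellularityDecreased) return("PR")
  "NR"
}

#' Change-from-baseline features
#'
#' Computes `delta x = x_week - x_baseline` for every shared QUS/texture
#' feature. Molecular markers are not differenced.
#'
#' @param baseline,week named numeric vectors (or one-row data frames) of the
#'   31 per-scan features, same names.
#' @return named numeric vector of differences, names prefixed with "d".
#' @export
deltaFeatures <- function(baseline, week) {
  baseline <- unlist(baseline); week <- unlist(week)
  if (is.null(names(baseline)) || !setequal(names(baseline), names(week)))
    stopf("baseline and week scans must share feature names")
  nm <- names(baseline)
  d <- week[nm] - baseline[nm]
  names(d) <- paste0("d", nm)
  d
}

#' Assemble the 65-entry classification feature vector
#'
#' Fixed, documented order: the 7 baseline mean QUS parameters and 24 baseline
#' texture features (suffix "0"), the 7 + 24 changes from baseline at the
#' requested scan time (prefix "d"), and the three molecular indicators
#' ER/PR/HER2 coded +1 (positive) / 0 (negative). See [featureVectorNames()].
#'
#' @param baseline named numeric vector of the 31 baseline scan features.
#' @param scan named numeric vector of the 31 features at the on-treatment
#'   scan time.
#' @param molecular named vector or list with elements ER, PR, HER2 (0/1 or
#'   logical).
#' @param scanTime label of the scan time (e.g. "week4").
#' @return named numeric vector of length 65 with attribute `scanTime`.
#' @export
assembleFeatureVector <- function(baseline, scan, molecular, scanTime = NA_character_) {
  baseline <- unlist(baseline); scan <- unlist(scan)
  need <- scanFeatureNames()
  missBase <- setdiff(need, names(baseline))
  missScan <- setdiff(need, names(scan))
  mol <- unlist(molecular)
  missMol <- setdiff(c("ER", "PR", "HER2"), names(mol))
  miss <- c(missBase, paste0("d", missScan, recycle0 = TRUE), missMol)
  if (length(miss))
    stopf("missing feature components: %s", paste(unique(miss), collapse = ", "))
  if (any(!is.finite(baseline[need])) || any(!is.finite(scan[need])))
    stopf("non-finite feature values")
  v <- c(stats::setNames(baseline[need], paste0(need, "0")),
         deltaFeatures(baseline[need], scan[need]),
         ER = as.numeric(mol[["ER"]] > 0),
         PR = as.numeric(mol[["PR"]] > 0),
         HER2 = as.numeric(mol[["HER2"]] > 0))
  v <- v[featureVectorNames()]
  attr(v, "scanTime") <- scanTime
  v
}

#' Feature table for a cohort at one scan time
#'
#' Assembles the 65-feature vector for every patient of a simulated (or
#' otherwise tabulated) cohort at the requested on-treatment scan time.
#'
#' @param cohort a `qusCohort` from [simulateCohort()], or a list with
#'   `patients` and `features` data frames of the same layout.
#' @param scanTime one of "week1", "week4", "week8".
#' @return data frame with columns `id`, `label`, the 65 features.
#' @export
cohortFeatureTable <- function(cohort, scanTime = "week4") {
  stopifnot(scanTime %in% c("week1", "week4", "week8"))
  pats <- cohort$patients
  feats <- cohort$features
  nm <- scanFeatureNames()
  rows <- lapply(seq_len(nrow(pats)), function(i) {
    id <- pats$id[i]
    base <- feats[feats$id == id & feats$scanTime == "week0", nm]
    scan <- feats[feats$id == id & feats$scanTime == scanTime, nm]
    if (nrow(base) != 1L || nrow(scan) != 1L)
      stopf("patient %s: missing %s or baseline scan", id, scanTime)
    v <- assembleFeatureVector(unlist(base), unlist(scan),
                               c(ER = pats$ER[i], PR = pats$PRrec[i],
                                 HER2 = pats$HER2[i]), scanTime)
    cbind(data.frame(id = id, label = pats$label[i], stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature-set columns for a classification mode
#'
#' @param mode one of "combined" (all 65), "qus_texture" (62, no molecular),
#'   "molecular" (ER/PR/HER2 only).
#' @return character vector of feature names.
#' @export
featureModeColumns <- function(mode = c("combined", "qus_texture", "molecular")) {
  mode <- match.arg(mode)
  all65 <- featureVectorNames()
  mol <- c("ER", "PR", "HER2")
  switch(mode,
         combined = all65,
         qus_texture = setdiff(all65, mol),
         molecular = mol)
}
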