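#' Median-normalize each array to 1
#'
#' Divides every sample column by its own median so that the per-sample
#' median intensity is exactly 1, the convention used for cross-array
#' comparison of single-channel oligonucleotide arrays. Idempotent.
#'
#' @param em `expr_matrix` on the raw (or already normalized) scale.
#' @return `expr_matrix` with `scale = "normalized"`.
#' @export
median_normalize <- function(em) {
  if (em$scale == "log2") stop("cannot median-normalize log2 data")
  med <- apply(em$intensities, 2, stats::median)
  bad <- which(med <= 0)
  if (length(bad)) {
    stop("zero or negative median in sample(s): ",
         paste(colnames(em$intensities)[bad], collapse = ", "))
  }
  norm <- sweep(em$intensities, 2, med, `/`)
  expr_matrix(norm, probe_to_gene = em$probe_to_gene,
              negative_control_probes = em$negative_control_probes,
              scale = "normalized")
}

#' Detection calling from negative-control probes
#'
#' Per-sample detection threshold = mean + `k_sd` * SD (sample SD, n-1
#' denominator) of that sample's normalized negative-control intensities.
#' A probe is "present" in a sample iff its normalized intensity strictly
#' exceeds the sample's threshold; otherwise it is "absent".
#'
#' @param em normalized `expr_matrix` with at least one control probe.
#' @param k_sd multiplier on the control SD (default 2).
#' @return list of class `detection_result`: `threshold_per_sample` (named
#'   numeric) and `present` (probe x sample logical matrix).
#' @export
detection_call <- function(em, k_sd = 2) {
  if (em$scale != "normalized") stop("detection requires a normalized matrix")
  ctrl <- em$negative_control_probes
  if (!length(ctrl)) {
    stop("no negative-control probes: supply an explicit threshold instead")
  }
  cm <- em$intensities[ctrl, , drop = FALSE]
  thr <- colMeans(cm) + k_sd * apply(cm, 2, stats::sd)
  if (length(ctrl) == 1) thr <- colMeans(cm)  # SD undefined for one control
  present <- sweep(em$intensities, 2, thr, `>`)
  structure(list(threshold_per_sample = thr, present = present, k_sd = k_sd),
            class = "detection_result")
}

#' Log2-transform a normalized matrix
#'
#' `log2(max(intensity, floor))`; the floor guards zero intensities from
#' producing -Inf.
#'
#' @param em normalized `expr_matrix`.
#' @param floor positive lower bound applied before the log (default 2^-10).
#' @return `expr_matrix` with `scale = "log2"`.
#' @export
log2_transform <- function(em, floor = 2^-10) {
  if (em$scale != "normalized") stop("log2 transform requires a normalized matrix")
  if (floor <= 0) stop("floor must be positive")
  vals <- log2(pmax(em$intensities, floor))
  expr_matrix(vals, probe_to_gene = em$probe_to_gene,
              negative_control_probes = em$negative_control_probes,
              scale = "log2")
}
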