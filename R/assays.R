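#' Competitive sgRNA depletion normalization
#'
#' In a competitive depletion assay the marker-positive (guide-bearing)
#' fraction of a knockout-background culture is divided by the matching
#' wild-type fraction at each timepoint, and the ratio series is anchored
#' to 100% at the first timepoint:
#' `out_t = 100 * (ko_t / wt_t) / (ko_1 / wt_1)`.
#'
#' @param ko,wt data frames with columns `timepoint_days` and
#'   `fraction_positive` (fractions in \[0, 1\]), matching timepoints.
#' @return Data frame `timepoint_days`, `percent` (first row always 100).
#' @export
competitive_depletion_normalize <- function(ko, wt) {
  for (d in list(ko, wt)) {
    stopifnot(all(c("timepoint_days", "fraction_positive") %in% names(d)))
    if (nrow(d) < 1) {
      stop_iso("need >= 1 timepoint", class = "isoscreen_validation_error")
    }
    if (any(d$fraction_positive < 0 | d$fraction_positive > 1)) {
      stop_iso("fractions must lie in [0, 1]", class = "isoscreen_validation_error")
    }
  }
  if (!identical(as.numeric(ko$timepoint_days), as.numeric(wt$timepoint_days))) {
    stop_iso("knockout and wild-type series have mismatched timepoints",
             class = "isoscreen_validation_error")
  }
  if (any(wt$fraction_positive == 0)) {
    stop_iso("wild-type fraction of 0 makes the ratio undefined",
             class = "isoscreen_validation_error")
  }
  r <- ko$fraction_positive / wt$fraction_positive
  data.frame(timepoint_days = as.numeric(ko$timepoint_days),
             percent = 100 * r / r[1])
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddct = (ct_target_sample - ct_ref_sample) -
#'         (ct_target_control - ct_ref_control)`; fold change
#' `= 2^(-ddct)`. One qPCR cycle equals one doubling of template.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   threshold-cycle values (target gene and reference/housekeeping gene,
#'   in the test sample and the control condition). Vectorized.
#' @return Fold expression change(s).
#' @export
delta_delta_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_control,
               ct_ref_control)
  if (any(!is.finite(cts))) {
    stop_iso("all Ct values must be finite", class = "isoscreen_validation_error")
  }
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' ChIP recovery by the percent-input method
#'
#' `percent = 100 * input_fraction * 2^(ct_input - ct_ip)`: the input Ct is
#' adjusted for the fraction of chromatin set aside as input (as a
#' multiplicative factor, identical to subtracting `log2(1/fraction)`
#' cycles), then the IP/input template ratio is read off the Ct difference.
#'
#' @param ct_input,ct_ip threshold cycles of the input and IP qPCR.
#'   Vectorized.
#' @param input_fraction fraction of chromatin used as input, in (0, 1].
#' @return Percent of input recovered.
#' @export
percent_input <- function(ct_input, ct_ip, input_fraction) {
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    stop_iso("input_fraction must be in (0, 1]", class = "isoscreen_validation_error")
  }
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' Promoter-luciferase fold activity vs empty vector
#'
#' Fold activity is the mean reporter signal over the mean empty-vector
#' control signal; per-replicate folds against the control mean are also
#' returned.
#'
#' @param signals numeric reporter signals (replicates).
#' @param empty_vector_signals numeric control signals.
#' @return List with `fold` (scalar) and `per_replicate`.
#' @export
luciferase_normalize <- function(signals, empty_vector_signals) {
  ctrl <- mean(empty_vector_signals)
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop_iso("empty-vector control mean must be positive",
             class = "isoscreen_validation_error")
  }
  list(fold = mean(signals) / ctrl, per_replicate = signals / ctrl)
}
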