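# Shift-stratified sampling of tests, expanded to whole admission episodes.

#' Draw a shift-stratified sample of meter records
#'
#' Within each working-shift stratum of the test time, draws
#' `floor(fraction * stratum size)` records uniformly without replacement.
#' Deterministic under `seed`.
#'
#' @param meters meter record `data.frame`.
#' @param fraction sampling fraction in (0, 1].
#' @param shift a [shift_config()]; the stratum of a test is the shift of
#'   its `test_time` (the workload context in which the transcription act
#'   happens).
#' @param seed integer RNG seed.
#' @return the sampled rows of `meters`, in original order.
#' @export
stratified_sample <- function(meters, fraction, shift = shift_config(), seed) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (nrow(meters) == 0) return(meters)
  set.seed(seed)
  strata <- assign_shift(meters$test_time, shift)
  keep <- logical(nrow(meters))
  for (s in c("day", "night")) {
    idx <- which(strata == s)
    k <- floor(fraction * length(idx))
    if (k > 0) keep[sample(idx, k)] <- TRUE
  }
  out <- meters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a sample to full admission episodes
#'
#' Returns every record of `all_meters` whose VIN appears in `sampled`:
#' once any test of a patient episode is selected, all tests of that
#' episode enter the audit, so per-patient error rates are well defined.
#' Idempotent; never shrinks the VIN set.
#'
#' @param sampled a subset of `all_meters`.
#' @param all_meters the full meter stream.
#' @return the episode-closed record set, in `all_meters` order.
#' @export
expand_episodes <- function(sampled, all_meters) {
  if (!all(sampled$record_id %in% all_meters$record_id))
    stop("sampled records must be a subset of all_meters")
  out <- all_meters[all_meters$vin %in% unique(sampled$vin), , drop = FALSE]
  rownames(out) <- NULL
  out
}
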