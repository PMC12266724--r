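#' Stimulus trial-type vocabulary
#'
#' The in vivo stimulation protocol draws trials from eight types: the three
#' single modalities, their pairwise and triple combinations, and a blank
#' (no-stimulus) trial.
#'
#' @return Character vector of the eight trial-type labels.
#' @export
#' @examples
#' trial_types()
trial_types <- function() {
  c("sound", "light", "whisker",
    "sound+light", "sound+whisker", "light+whisker",
    "sound+light+whisker", "blank")
}

#' The three sensory modalities
#' @return Character vector `c("sound", "light", "whisker")`.
#' @export
modalities <- function() c("sound", "light", "whisker")

## split a trial-type label into its component modalities ("blank" -> none)
type_components <- function(types) {
  out <- strsplit(types, "+", fixed = TRUE)
  lapply(out, function(x) setdiff(x, "blank"))
}

## TRUE where the trial type contains the given modality
type_contains <- function(types, modality) {
  vapply(type_components(types), function(p) modality %in% p, logical(1))
}

## number of modalities in each trial-type label (blank -> 0)
type_arity <- function(types) {
  lengths(type_components(types))
}

assert_trial_types <- function(types) {
  bad <- setdiff(types, trial_types())
  if (length(bad) > 0) {
    stop("unknown trial type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(types)
}
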