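#' @include resources.R utils.R
NULL

#' Assign three-state secondary structure from propensity scales
#'
#' Smooths per-residue Chou-Fasman helix and sheet propensities with a
#' centred moving average (truncated at the termini, no padding) and calls
#' each position helix (H) when the smoothed helix propensity reaches
#' `helixCutoff` and exceeds the smoothed sheet propensity, sheet (E) when
#' the smoothed sheet propensity reaches `sheetCutoff` and exceeds the
#' helix value, and coil (C) otherwise. The cutoffs 1.03 and 1.05 are the
#' classical former/breaker boundaries of the Chou-Fasman scales.
#'
#' This in-package assigner supplies the structural context for the
#' secondary-structure feature block without requiring an external
#' predictor; a pre-computed H/E/C string from any other source can be
#' substituted wherever an [SSEAssignment-class] is accepted.
#'
#' @param sequence Amino-acid string over the standard alphabet,
#'   length >= 1.
#' @param window Odd smoothing window size (default 5).
#' @param helixCutoff,sheetCutoff Propensity thresholds (defaults 1.03 and
#'   1.05).
#' @param propensities Propensity matrix as from [chouFasmanTable()].
#' @return An [SSEAssignment-class].
#' @examples
#' sseStates(assignSSE("AAAAAAAAAA"))  # strong helix former
#' sseStates(assignSSE("GGGGGGGGGG"))  # helix/sheet breaker -> coil
#' @export
assignSSE <- function(sequence, window = 5L,
                      helixCutoff = 1.03, sheetCutoff = 1.05,
                      propensities = chouFasmanTable()) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  assert_standard(sequence)
  chars <- strsplit(sequence, "")[[1]]
  ph <- rolling_mean_truncated(propensities["helix", chars], window)
  pe <- rolling_mean_truncated(propensities["sheet", chars], window)
  states <- rep("C", length(chars))
  states[ph >= helixCutoff & ph > pe] <- "H"
  states[pe >= sheetCutoff & pe > ph] <- "E"
  content <- c(helix = mean(states == "H"),
               sheet = mean(states == "E"),
               coil = mean(states == "C"))
  new("SSEAssignment", states = paste(states, collapse = ""),
      content = content)
}
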