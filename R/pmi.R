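#' Pain Mapping Intensity
#'
#' Intensity-weighted sum of the four painted pain-surface areas drawn on
#' a body map: \code{PMI = 1*low + 2*medium + 3*intense + 4*very intense},
#' areas in cm2. The intensity coefficients are fixed by the instrument.
#'
#' @param low,medium,intense,very_intense nonnegative areas in cm2;
#'   vectors are recycled to common length. \code{NA} propagates.
#' @return PMI in cm2-weighted units.
#' @export
#' @examples
#' compute_pmi(100, 50, 20, 10)  # 300
compute_pmi <- function(low, medium, intense, very_intense) {
  a <- cbind(low, medium, intense, very_intense)
  if (any(a < 0, na.rm = TRUE)) stop("pain surface areas must be nonnegative")
  as.numeric(a %*% c(1, 2, 3, 4))
}

#' Improvement-oriented PMI change
#'
#' \code{baseline - followup}, so a decrease in painted intensity is a
#' positive change and "change >= cutoff" always reads as improvement
#' (the same orientation used for NPRS, ODI and HADS changes; MCRI and
#' EQ-5D use followup - baseline because higher is better there).
#'
#' @param baseline,followup PMI scores (>= 0).
#' @return \code{baseline - followup}.
#' @export
pmi_change <- function(baseline, followup) {
  if (any(baseline < 0, na.rm = TRUE) || any(followup < 0, na.rm = TRUE))
    stop("PMI scores must be nonnegative")
  baseline - followup
}

# Adds/overwrites a pmi column computed from the four surface columns.
add_pmi <- function(table) {
  table$pmi <- compute_pmi(table$surface_low, table$surface_medium,
                           table$surface_intense, table$surface_very_intense)
  table
}
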