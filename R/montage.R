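## 64-channel 10-10 montage (Brain Products actiCAP layout) used by the
## synthetic generator.  Contains all 16 lateral parieto-occipital
## candidate electrodes.
MONTAGE64 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
  "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
  "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
  "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
  "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8"
)

#' Candidate parieto-occipital electrode pools
#'
#' The 16 lateral parieto-occipital electrodes from which per-session
#' individualized electrodes are selected: 8 over each hemisphere.
#'
#' @return A list with character vectors `left` and `right`.
#' @examples
#' candidatePools()
#' @export
candidatePools <- function() {
  list(
    left  = c("P1", "P3", "P5", "P7", "PO3", "PO7", "PO9", "O1"),
    right = c("P2", "P4", "P6", "P8", "PO4", "PO8", "PO10", "O2")
  )
}

#' Hemisphere of a lateral 10-10 electrode
#'
#' Odd-numbered labels lie over the left hemisphere, even-numbered over
#' the right.  Midline (z) electrodes have no hemisphere and raise an
#' error, since lateralised analyses are undefined for them.
#'
#' @param labels character vector of 10-10 labels.
#' @return Character vector `"left"`/`"right"`.
#' @examples
#' electrodeHemisphere(c("PO7", "PO8"))
#' @export
electrodeHemisphere <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  if (anyNA(num))
    stop("midline or unparsable electrode label(s): ",
         paste(labels[is.na(num)], collapse = ", "),
         " (only lateral electrodes have a hemisphere)")
  ifelse(num %% 2L == 1L, "left", "right")
}

## Default "true" alpha-source electrodes of the synthetic scalp
## topography: source weight 1.0 here, 0.5 at the remaining candidates.
trueElectrodes <- function() {
  list(left = c("P5", "P7", "PO7", "O1"),
       right = c("P6", "P8", "PO8", "O2"))
}
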