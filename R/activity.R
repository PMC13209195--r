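#' Convert IC50 (nM) to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50; 1000 nM (1 uM)
#' maps to 6.0, the threshold used throughout to separate actives from
#' inactives.
#'
#' @param activity_nM positive IC50 value(s) in nanomolar.
#' @return pIC50 value(s).
#' @examples
#' to_pIC50(1000)  # 6.0
#' to_pIC50(54)    # 7.27
#' @export
to_pIC50 <- function(activity_nM) {
  if (any(is.na(activity_nM)) || any(activity_nM <= 0)) {
    stop("activity_nM must be positive and non-missing")
  }
  -log10(activity_nM * 1e-9)
}

#' Convert pIC50 back to IC50 in nM
#'
#' Inverse of [to_pIC50()]; round-trips within 1e-9 relative error.
#'
#' @param pIC50 pIC50 value(s).
#' @return IC50 in nanomolar.
#' @export
from_pIC50 <- function(pIC50) {
  10^(-pIC50) * 1e9
}

#' Activity threshold separating actives from inactives (pIC50 units)
#' @export
ACTIVE_PIC50_THRESHOLD <- 6.0
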