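#' Maximum photochemical quantum yield of photosystem II
#'
#' Fv/Fm = (Fm - Fo) / Fm from minimal (`fo`) and maximal (`fm`) chlorophyll
#' fluorescence of a dark-adapted leaf. Always in \[0, 1\].
#'
#' @param fo Minimal fluorescence, >= 0.
#' @param fm Maximal fluorescence, > 0 and >= `fo`. Vectorized.
#' @return Numeric vector of quantum yields.
#' @examples
#' fv_fm(0.2, 1.0) # 0.8
#' @export
fv_fm <- function(fo, fm) {
  if (any(!is.finite(fo) | !is.finite(fm))) {
    abort("fluorescence readings must be finite", class = "stressmodes_validation_error")
  }
  if (any(fm <= 0)) {
    abort("Fm must be positive", class = "stressmodes_validation_error")
  }
  if (any(fo < 0 | fo > fm)) {
    abort("Fo must satisfy 0 <= Fo <= Fm", class = "stressmodes_validation_error")
  }
  (fm - fo) / fm
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' Livak relative quantification from qPCR cycle thresholds: per sample,
#' dCt = Ct(target) - Ct(reference); ddCt = dCt(treated) - dCt(control);
#' fold change = 2^(-ddCt). A one-cycle drop in ddCt doubles the fold change.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Cycle-threshold values (finite, positive). Vectorized.
#' @return Positive numeric vector of relative fold changes.
#' @examples
#' ddct_fold_change(20, 18, 22, 18) # ddCt = -2, fold 4
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  ct <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(ct) | ct <= 0)) {
    abort("Ct values must be finite and positive", class = "stressmodes_validation_error")
  }
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
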