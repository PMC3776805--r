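#' 3':5' amplification integrity ratio
#'
#' With oligo-dT-primed cDNA, degraded RNA under-represents 5' amplicons; the
#' ratio of 3' to 5' template abundance, from the comparative-Cq model, is
#' `amplification_factor^(cq_5 - cq_3)`. Ratios near 1 indicate intact
#' full-length cDNA; values well above 1 indicate 3' bias from degradation.
#' The classical factor 2 (perfect doubling) is the default; measured primer
#' efficiencies can be substituted via `amplification_factor = 1 + E`.
#'
#' @param cq_5,cq_3 Cq of the 5' and 3' amplicons (cycles).
#' @param amplification_factor per-cycle amplification factor (default 2).
#' @return The ratio (vectorized); `NA` when either Cq is missing.
#' @export
three_five_ratio <- function(cq_5, cq_3, amplification_factor = 2.0) {
  if (amplification_factor <= 1) stop("amplification_factor must exceed 1", call. = FALSE)
  ifelse(is.na(cq_5) | is.na(cq_3), NA_real_,
         amplification_factor^(cq_5 - cq_3))
}

#' RNA-integrity gate on the 3':5' ratio
#'
#' Fails only when the ratio strictly exceeds `max_ratio` (default 4.43);
#' a missing ratio fails closed.
#'
#' @param ratio a 3':5' ratio from [three_five_ratio()].
#' @param max_ratio largest acceptable ratio (strict).
#' @return Logical pass flag (vectorized).
#' @export
integrity_gate <- function(ratio, max_ratio = 4.43) {
  !is.na(ratio) & ratio <= max_ratio
}

#' Spectrophotometric purity gates
#'
#' Panel-specific inclusive bounds on the A260/A280 ratio (1.9-2.1 for floral
#' buds, 1.75-2.1 for fruits; leaves use the bud bounds) and a strict
#' A260/A230 > 2.0 requirement.
#'
#' @param a260_280,a260_230 absorbance ratios (non-negative).
#' @param panel one of `"bud"`, `"fruit"`, `"leaf"` (vectorized).
#' @return Data frame with logical columns `pass_260_280`, `pass_260_230`
#'   and `pass` (both).
#' @export
purity_gate <- function(a260_280, a260_230, panel) {
  panel <- as.character(panel)
  bad <- !panel %in% c("bud", "fruit", "leaf")
  if (any(bad)) stop("unknown panel: ", paste(unique(panel[bad]), collapse = ", "),
                     call. = FALSE)
  lo <- ifelse(panel == "fruit", 1.75, 1.9)
  p280 <- !is.na(a260_280) & a260_280 >= lo & a260_280 <= 2.1
  p230 <- !is.na(a260_230) & a260_230 > 2.0
  data.frame(pass_260_280 = p280, pass_260_230 = p230, pass = p280 & p230)
}

#' Sample-level RNA quality report
#'
#' Applies the 3':5' integrity gate and the purity gates to a QC table and
#' returns per-sample pass flags. A sample passes overall only when every
#' gate passes (missing measurements fail closed).
#'
#' @param qc data frame with columns `sample`, `cq_5prime`, `cq_3prime`,
#'   `a260_280`, `a260_230`, `panel`.
#' @param max_ratio integrity cutoff passed to [integrity_gate()].
#' @param amplification_factor passed to [three_five_ratio()].
#' @return The input with added `ratio_3to5`, `pass_integrity`,
#'   `pass_260_280`, `pass_260_230`, `pass` columns.
#' @export
qc_report <- function(qc, max_ratio = 4.43, amplification_factor = 2.0) {
  need <- c("sample", "cq_5prime", "cq_3prime", "a260_280", "a260_230", "panel")
  stopifnot(is.data.frame(qc), all(need %in% names(qc)))
  qc$ratio_3to5 <- three_five_ratio(qc$cq_5prime, qc$cq_3prime,
                                    amplification_factor)
  qc$pass_integrity <- integrity_gate(qc$ratio_3to5, max_ratio)
  pg <- purity_gate(qc$a260_280, qc$a260_230, qc$panel)
  qc$pass_260_280 <- pg$pass_260_280
  qc$pass_260_230 <- pg$pass_260_230
  qc$pass <- qc$pass_integrity & pg$pass
  qc
}
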