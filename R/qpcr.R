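#' qPCR amplification efficiency from a standard-curve slope
#'
#' For a dilution-series standard curve (Cq regressed on log10 input), the
#' per-cycle amplification efficiency is `10^(-1/slope) - 1`: a slope of
#' `-1/log10(2) ~ -3.32` corresponds to perfect doubling (efficiency 1).
#'
#' @param slope regression slope of Cq vs log10 dilution; must be negative.
#' @return efficiency as a fraction (0 = no amplification, 1 = doubling).
#' @export
primer_efficiency <- function(slope) {
  if (!is.numeric(slope) || anyNA(slope)) {
    stop("primer_efficiency: slope must be numeric")
  }
  if (any(slope >= 0)) {
    stop("primer_efficiency: slope must be negative for a valid curve")
  }
  10^(-1 / slope) - 1
}

#' Reference-normalized relative expression from Cq values
#'
#' Efficiency-corrected relative quantification: the target quantity
#' `(1 + E_target)^(-Cq_target)` divided by the geometric mean over
#' reference genes of `(1 + E_ref)^(-Cq_ref)`. With all efficiencies at 1
#' this reduces to `2^(Cq_ref - Cq_target)` (delta-Cq). Samples with a
#' missing reference Cq are reported `NA`.
#'
#' @param cq_target numeric vector of per-sample target Cq values.
#' @param cq_refs numeric matrix (samples x reference genes) or vector of
#'   reference Cq values.
#' @param eff_target target amplification efficiency, in `[0, 1]`.
#' @param eff_refs per-reference efficiencies, in `[0, 1]` (recycled).
#' @return numeric vector of per-sample relative expression levels.
#' @export
relative_expression <- function(cq_target, cq_refs, eff_target = 1,
                                eff_refs = 1) {
  cq_refs <- as.matrix(cq_refs)
  if (nrow(cq_refs) != length(cq_target)) {
    stop("relative_expression: cq_refs rows must match cq_target length")
  }
  if (any(eff_target < 0 | eff_target > 1) ||
      any(eff_refs < 0 | eff_refs > 1)) {
    stop("relative_expression: efficiencies must lie in [0, 1]")
  }
  if (any(!is.finite(cq_target))) {
    stop("relative_expression: target Cq must be finite")
  }
  eff_refs <- rep_len(eff_refs, ncol(cq_refs))
  q_target <- (1 + eff_target)^(-cq_target)
  lq_ref <- sweep(-cq_refs, 2, log(1 + eff_refs), "*")
  ref_geo <- exp(rowMeans(lq_ref))       # NA propagates for missing refs
  q_target / ref_geo
}
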