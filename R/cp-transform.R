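#' Efficiency-adjusted Cp transformation
#'
#' Converts quantification-cycle values to log2-scale expression
#' quantities: `y = -log2(E^-cp) = cp * log2(E)`, where `E` is the
#' per-gene amplification factor (2 = perfect doubling).  Larger `y`
#' means later threshold crossing, i.e. lower expression.  The
#' product form is used rather than literal exponentiation to avoid
#' underflow of `E^-cp` at large cycle numbers.
#'
#' @param cp Quantification cycle(s), non-negative.
#' @param efficiency Amplification factor(s) `E` in (1, 2]; recycled
#'   against `cp`.
#' @return Numeric vector of transformed values (log2 units).
#' @export
cp_transform <- function(cp, efficiency) {
  if (any(efficiency <= 1))
    stop("amplification factor must exceed 1 (non-amplifying reaction)")
  if (any(efficiency > 2))
    stop("amplification factor cannot exceed 2 (perfect doubling)")
  if (any(cp < 0)) stop("cp must be non-negative")
  cp * log2(efficiency)
}

#' Transform all wells of a Cp table
#'
#' Applies [cp_transform()] per well using each gene's amplification
#' factor, preserving all labels.
#'
#' @param wells data.frame of well measurements (see [validate_wells()]).
#' @param efficiencies Named amplification factors covering every gene.
#' @return The input data.frame with an extra `y` column.
#' @export
transform_wells <- function(wells, efficiencies) {
  if (nrow(wells) == 0) {
    wells$y <- numeric(0)
    return(wells)
  }
  wells <- validate_wells(wells)
  orphan <- setdiff(unique(wells$gene), names(efficiencies))
  if (length(orphan) > 0)
    stop("gene(s) without amplification efficiency: ", paste(orphan, collapse = ", "))
  wells$y <- cp_transform(wells$cp, unname(efficiencies[wells$gene]))
  wells
}
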