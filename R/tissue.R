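#' Per-element tissue field
#'
#' A vector of per-element scalar time-maxima from a finite-element
#' impact solution — e.g. each brain element's maximum 1st principal
#' Green-Lagrange strain over the impact, or each skull element's maximum
#' von-Mises stress. The time maximum is taken first, per element; scalar
#' summaries ([mps_95()], [peak_stress()]) then reduce over elements.
#'
#' @param values Finite numeric vector, one value per element; strains
#'   must be >= 0.
#' @param kind `"strain"` (dimensionless, non-negative) or `"stress"` (Pa).
#' @return An object of class `element_field`.
#' @export
element_field <- function(values, kind = c("strain", "stress")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("an element_field needs at least one element", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all element values must be finite", call. = FALSE)
  if (kind == "strain" && any(values < 0))
    stop("strain values must be >= 0", call. = FALSE)
  structure(list(values = values, element_count = length(values),
                 kind = kind), class = "element_field")
}

#' 95th-percentile maximum principal strain (MPS)
#'
#' The brain-injury metric used in place of the raw element maximum, which
#' is prone to numerical artefacts in a handful of elements: the 95th
#' percentile over brain elements of each element's peak 1st principal
#' Green-Lagrange strain. The percentile uses linear interpolation between
#' closest ranks, rank `1 + 0.95 * (n - 1)` on the sorted values
#' (R's default quantile type 7).
#'
#' @param strain An [element_field()] of kind `"strain"`.
#' @return The 95th-percentile strain (dimensionless).
#' @examples
#' mps_95(element_field(1:100))  # 95.05
#' @export
mps_95 <- function(strain) {
  if (!inherits(strain, "element_field"))
    stop("`strain` must be an element_field", call. = FALSE)
  stats::quantile(strain$values, probs = 0.95, type = 7, names = FALSE)
}

#' Peak stress of an element field
#'
#' Maximum over elements of the per-element time-maximum — the peak
#' von-Mises skull stress screening metric for fracture risk.
#'
#' @param stress An [element_field()].
#' @return The field maximum (Pa for a stress field).
#' @export
peak_stress <- function(stress) {
  if (!inherits(stress, "element_field"))
    stop("`stress` must be an element_field", call. = FALSE)
  max(stress$values)
}

#' Mild-TBI strain risk flag
#'
#' Compares an MPS value against the strain threshold associated with a
#' 50% risk of mild traumatic brain injury (0.3 by default).
#'
#' @param mps MPS value, >= 0.
#' @param threshold Strain threshold (default 0.3).
#' @return `"below"` or `"at_or_above"`.
#' @export
mtbi_risk_flag <- function(mps, threshold = 0.3) {
  if (!is.numeric(mps) || length(mps) != 1L || !is.finite(mps) || mps < 0)
    stop("`mps` must be a single non-negative number", call. = FALSE)
  if (mps >= threshold) "at_or_above" else "below"
}
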