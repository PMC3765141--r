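#' Published reference distribution for West Kalimantan
#'
#' The per-class areas (hectares) of the published province-wide suitability
#' classification: one row per indicator layer, plus the combined Risk
#' Indicator Map (RIM) and its cross-tabulations with existing oil palm
#' concessions (RIM & C) and with the provincial land-use plan's "other use"
#' land outside concessions (RIM & LUP). These printed values serve two
#' purposes: they are the reference marginal class proportions for the
#' synthetic landscape generator, and they are the worked example against
#' which the package's percentage arithmetic and the maximum-risk
#' consistency bound are checked.
#'
#' @return A data.frame with columns \code{label}, \code{low_ha},
#'   \code{medium_ha}, \code{high_ha}, \code{very_high_ha}.
#' @examples
#' ref <- reference_distribution()
#' area_table("RIM", as.numeric(ref[ref$label == "RIM", -1]))
#' @export
reference_distribution <- function() {
  data.frame(
    label = c("1.1.1", "1.1.2", "1.1.3", "1.2.1", "1.2.2", "1.2.4", "3.1.1",
              "RIM", "RIM & C", "RIM & LUP"),
    low_ha       = c(10264750, 8002697, 6180760, 4888399, 8820942, 8411319,
                     7369502, 2615081, 916000, 521802),
    medium_ha    = c(171285, 0, 1531902, 7866970, 3181400, 0, 10780,
                     0, 0, 0),
    high_ha      = c(0, 4975900, 4093223, 307058, 814944, 2738594, 594496,
                     1256493, 523886, 180936),
    very_high_ha = c(2542545, 0, 1411301, 156690, 401832, 2061619, 5244338,
                     9107006, 2054963, 1068394),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_distribution
#' @return \code{reference_layer_proportions()}: a named list of 4-vectors
#'   (LOW/MEDIUM/HIGH/VERY_HIGH proportions, each summing to 1) for the seven
#'   indicator layers, computed from the printed areas.
#' @export
reference_layer_proportions <- function() {
  ref <- reference_distribution()
  ref <- ref[!grepl("^RIM", ref$label), ]
  out <- lapply(seq_len(nrow(ref)), function(i) {
    a <- as.numeric(ref[i, c("low_ha", "medium_ha", "high_ha",
                             "very_high_ha")])
    a / sum(a)
  })
  stats::setNames(out, ref$label)
}
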