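#' Ordinal risk classes
#'
#' The suitability classification uses four ordered risk classes for
#' non-compliance with the sustainability standards:
#' \code{LOW < MEDIUM < HIGH < VERY_HIGH}. \code{VERY_HIGH} is the
#' "unsuitable" class; the two names are synonyms and both are accepted on
#' input. Internally classes are stored as integer ranks 0--3; \code{NA}
#' encodes NODATA and never participates in comparisons.
#'
#' @return \code{risk_levels()} returns the four labels in rank order.
#' @examples
#' risk_levels()
#' risk_rank(c("LOW", "VERY_HIGH"))
#' risk_label(c(0L, 3L, NA))
#' @export
risk_levels <- function() c("LOW", "MEDIUM", "HIGH", "VERY_HIGH")

#' @rdname risk_levels
#' @param label character vector of class labels (case-insensitive;
#'   "UNSUITABLE" is accepted as a synonym for "VERY_HIGH", "NODATA" as NA).
#' @return \code{risk_rank()} returns integer ranks 0--3 (NA for NODATA).
#' @export
risk_rank <- function(label) {
  lab <- toupper(trimws(as.character(label)))
  lab[lab == "UNSUITABLE"] <- "VERY_HIGH"
  lab[lab %in% c("NODATA", "NA", "")] <- NA_character_
  rk <- match(lab, risk_levels()) - 1L
  bad <- !is.na(lab) & is.na(rk)
  if (any(bad)) {
    stop("unknown risk label(s): ", paste(unique(lab[bad]), collapse = ", "))
  }
  rk
}

#' @rdname risk_levels
#' @param rank integer vector of ranks 0--3 (NA allowed).
#' @return \code{risk_label()} returns the labels ("NODATA" for NA).
#' @export
risk_label <- function(rank) {
  stopifnot(all(is.na(rank) | (rank >= 0 & rank <= 3)))
  out <- rep("NODATA", length(rank))
  ok <- !is.na(rank)
  out[ok] <- risk_levels()[as.integer(rank[ok]) + 1L]
  out
}

#' @rdname risk_levels
#' @param x character vector of labels.
#' @return \code{risk_factor()} returns an ordered factor over the four
#'   levels.
#' @export
risk_factor <- function(x) {
  factor(risk_label(risk_rank(x)), levels = risk_levels(), ordered = TRUE)
}
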