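#' Round half up
#'
#' Integer rounding with ties away from zero toward the next integer
#' (round-half-up), the convention used for all printed percentages.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @examples round_half_up(c(0.5, 1.49, 2.5))
#' @export
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Maximum-risk overlay (Liebig's law of the minimum)
#'
#' Combines indicator layers cell-wise: the combined class is the highest
#' (worst) risk class among the layers, so a single very-high-risk indicator
#' overrules any number of low-risk ones — the land is only as usable as its
#' most limiting factor. Under \code{nodata_policy = "ignore"} a cell is
#' NODATA only where every layer is NODATA (layers with partial coverage
#' still contribute elsewhere); under \code{"propagate"} NODATA in any layer
#' makes the cell NODATA. The operation is commutative, associative and
#' idempotent in the layer list.
#'
#' @param layers list of grid-congruent \code{pr_indicator_layer}s (>= 1).
#' @param nodata_policy "ignore" (default) or "propagate".
#' @return A \code{pr_indicator_layer} with indicator id "RIM".
#' @examples
#' a <- indicator_layer(matrix(c(0L, 2L), 1), "a")
#' b <- indicator_layer(matrix(c(3L, 1L), 1), "b")
#' combine_liebig(list(a, b))$cells
#' @export
combine_liebig <- function(layers, nodata_policy = c("ignore", "propagate")) {
  nodata_policy <- match.arg(nodata_policy)
  if (!is.list(layers) || length(layers) < 1) {
    stop("combine_liebig needs a non-empty list of indicator layers")
  }
  check_congruent(layers, "indicator layers")
  ref <- layers[[1]]
  stack <- vapply(layers, function(l) as.vector(l$cells),
                  numeric(length(ref$cells)))
  stack <- matrix(stack, ncol = length(layers))
  if (nodata_policy == "ignore") {
    comb <- apply(stack, 1, function(r) {
      if (all(is.na(r))) NA_integer_ else max(r, na.rm = TRUE)
    })
  } else {
    comb <- apply(stack, 1, max)
  }
  out <- pr_grid(matrix(as.integer(comb), nrow(ref$cells), ncol(ref$cells)),
                 origin = ref$origin, cell_size = ref$cell_size,
                 crs = ref$crs)
  indicator_layer(out, indicator_id = "RIM")
}

#' Area table for a risk layer
#'
#' Per-class areas in hectares (cell count times cell area) and integer
#' percentages. NODATA cells are excluded from the total. Percentages are
#' computed against \code{denominator_ha} — by default the row's own total,
#' which is how the per-indicator rows of a published distribution table are
#' laid out; pass the full map area to express a sub-region's share of the
#' whole map instead.
#'
#' @param layer a \code{pr_indicator_layer}.
#' @param label row label.
#' @param denominator_ha percentage denominator in hectares (default: the
#'   layer's own mapped total).
#' @return A one-row data.frame of class \code{pr_area_table} with columns
#'   \code{label}, \code{low_ha}, \code{medium_ha}, \code{high_ha},
#'   \code{very_high_ha}, \code{total_ha}, \code{low_pct}, \code{medium_pct},
#'   \code{high_pct}, \code{very_high_pct}.
#' @export
tabulate_areas <- function(layer, label = layer$indicator_id,
                           denominator_ha = NULL) {
  stopifnot(inherits(layer, "pr_grid"))
  cnt <- vapply(0:3, function(k) sum(layer$cells == k, na.rm = TRUE),
                numeric(1))
  area_table(label, cnt * cell_area_ha(layer),
             denominator_ha = denominator_ha)
}

#' @rdname tabulate_areas
#' @param areas_ha numeric length-4: LOW/MEDIUM/HIGH/VERY_HIGH areas (ha).
#' @export
area_table <- function(label, areas_ha, denominator_ha = NULL) {
  stopifnot(length(areas_ha) == 4, all(areas_ha >= 0))
  total <- sum(areas_ha)
  denom <- if (is.null(denominator_ha)) total else denominator_ha
  pct <- if (denom > 0) round_half_up(100 * areas_ha / denom)
         else rep(0L, 4)
  out <- data.frame(label = as.character(label),
                    low_ha = areas_ha[1], medium_ha = areas_ha[2],
                    high_ha = areas_ha[3], very_high_ha = areas_ha[4],
                    total_ha = total,
                    low_pct = pct[1], medium_pct = pct[2],
                    high_pct = pct[3], very_high_pct = pct[4],
                    stringsAsFactors = FALSE)
  class(out) <- c("pr_area_table", "data.frame")
  out
}

#' Cross-tabulate a risk map against analysis zones
#'
#' For every zone code of the zone map, tabulates the risk-class areas of
#' the cells carrying that code. Zones partition the mapped area, so the
#' per-zone totals sum to the map total.
#'
#' @param rim a \code{pr_indicator_layer} (typically the combined Risk
#'   Indicator Map).
#' @param zones a \code{pr_zone_map}, grid-congruent with \code{rim}.
#' @param percent_denominator "zone" (each row's percentages against its own
#'   zone total) or "map" (against the rim's full mapped area, the layout of
#'   published concession / land-use-plan rows).
#' @return A \code{pr_area_table} data.frame with one row per zone code (in
#'   code order), labelled with the zone dictionary labels.
#' @export
cross_tabulate <- function(rim, zones,
                           percent_denominator = c("zone", "map")) {
  percent_denominator <- match.arg(percent_denominator)
  stopifnot(inherits(rim, "pr_grid"), inherits(zones, "pr_zone_map"))
  if (!grid_congruent(rim, zones)) {
    stop("risk map and zone map are not grid-congruent")
  }
  denom <- if (percent_denominator == "map") mapped_area_ha(rim) else NULL
  codes <- sort(as.integer(names(zones$zone_dict)))
  rows <- lapply(codes, function(code) {
    sel <- !is.na(zones$cells) & zones$cells == code
    cnt <- vapply(0:3, function(k)
      sum(rim$cells[sel] == k, na.rm = TRUE), numeric(1))
    area_table(zones$zone_dict[[as.character(code)]],
               cnt * cell_area_ha(rim), denominator_ha = denom)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pr_area_table", "data.frame")
  out
}

# canonical legal-class priority for expansion recommendations, from
# highest to lowest potential
expansion_priority <- function() {
  c("other use", "conversion forest", "production forest",
    "protection forest")
}

#' Ranked expansion recommendations
#'
#' Reports the low-risk area per land-use-plan legal class outside active
#' concessions, ordered by the fixed legal-practicality priority: land for
#' other use (APL, where concessions are legally allowed) first, then
#' conversion forest (HPK), production forest (HP/HPT), and protection
#' forest last. Low-risk land inside inactive concessions (license
#' applications in process) is reported as the first-call option, priority 0.
#'
#' @param rim combined risk map (\code{pr_indicator_layer}).
#' @param land_use_plan \code{pr_zone_map} whose labels include the four
#'   legal classes named above (matching is case-insensitive).
#' @param concessions \code{pr_zone_map} with labels "none", "active",
#'   "inactive".
#' @return A data.frame of class \code{pr_recommendation_table} with columns
#'   \code{priority}, \code{zone}, \code{low_risk_ha}, sorted by priority.
#' @export
rank_expansion_options <- function(rim, land_use_plan, concessions) {
  stopifnot(inherits(rim, "pr_grid"),
            inherits(land_use_plan, "pr_zone_map"),
            inherits(concessions, "pr_zone_map"))
  check_congruent(list(rim, land_use_plan, concessions),
                  "expansion-ranking inputs")
  lup_lab <- tolower(land_use_plan$zone_dict)
  con_lab <- tolower(concessions$zone_dict)
  unknown <- c(setdiff(lup_lab, expansion_priority()),
               setdiff(con_lab, c("none", "active", "inactive")))
  if (length(unknown)) {
    stop("unknown zone label(s): ", paste(unknown, collapse = ", "))
  }
  ca <- cell_area_ha(rim)
  low <- !is.na(rim$cells) & rim$cells == 0L
  code_of <- function(dict, label) {
    as.integer(names(dict)[match(label, tolower(dict))])
  }
  inactive_code <- code_of(con_lab, "inactive")
  active_code <- code_of(con_lab, "active")
  in_zone <- function(zmap, code) {
    if (is.na(code)) matrix(FALSE, nrow(rim$cells), ncol(rim$cells))
    else !is.na(zmap$cells) & zmap$cells == code
  }
  inactive_ha <- sum(low & in_zone(concessions, inactive_code)) * ca
  outside_active <- !in_zone(concessions, active_code)
  rows <- data.frame(priority = 0L,
                     zone = "inactive concessions (first call)",
                     low_risk_ha = inactive_ha, stringsAsFactors = FALSE)
  for (i in seq_along(expansion_priority())) {
    cls <- expansion_priority()[i]
    code <- code_of(land_use_plan$zone_dict, cls)
    ha <- sum(low & outside_active & in_zone(land_use_plan, code)) * ca
    rows <- rbind(rows, data.frame(priority = i, zone = cls,
                                   low_risk_ha = ha,
                                   stringsAsFactors = FALSE))
  }
  class(rows) <- c("pr_recommendation_table", "data.frame")
  rows
}

#' Write an area table as CSV
#'
#' Column layout: \code{label, low_ha, medium_ha, high_ha, very_high_ha,
#' low_pct, medium_pct, high_pct, very_high_pct, total_ha}.
#'
#' @param path output file.
#' @param at a \code{pr_area_table} (any number of rows).
#' @return \code{path}, invisibly.
#' @export
write_area_table_csv <- function(path, at) {
  cols <- c("label", "low_ha", "medium_ha", "high_ha", "very_high_ha",
            "low_pct", "medium_pct", "high_pct", "very_high_pct", "total_ha")
  utils::write.csv(as.data.frame(at)[, cols], path, row.names = FALSE)
  invisible(path)
}
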