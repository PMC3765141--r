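#' Run configuration
#'
#' The pipeline stages share one structured YAML config with fields:
#' \describe{
#'   \item{inputs}{named by indicator id: \code{path} (an ASCII-grid raster)
#'     and \code{kind} ("values" for raw indicator values to classify via the
#'     rule registry, "classes" for rank-encoded, already-classified
#'     rasters).}
#'   \item{rules}{optional path to a rule-registry YAML; omitted = built-in
#'     defaults.}
#'   \item{zones}{named zone maps (\code{concessions},
#'     \code{land_use_plan}), each with \code{path} and a \code{labels}
#'     code-to-label mapping.}
#'   \item{nodata_policy}{"ignore" or "propagate" for the overlay.}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{integer seed (simulate stage).}
#' }
#'
#' @param path YAML config file.
#' @return The config as a validated list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$nodata_policy)) cfg$nodata_policy <- "ignore"
  if (!cfg$nodata_policy %in% c("ignore", "propagate")) {
    stop("nodata_policy must be 'ignore' or 'propagate'")
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- "palmrisk_out"
  if (is.null(cfg$base_dir)) cfg$base_dir <- "."
  cfg
}

resolve_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(cfg$base_dir, p)
}

load_config_registry <- function(cfg) {
  load_rule_registry(resolve_path(cfg, cfg$rules))
}

#' Pipeline stage: simulate
#'
#' Generates a synthetic scenario bundle and writes it to \code{out_dir}:
#' rank-encoded class rasters under \code{layers/}, raw value rasters under
#' \code{values/}, zone rasters under \code{zones/}, protected-area and
#' concession polygons as GeoJSON, a \code{manifest.yaml}, and a ready-made
#' \code{config.yaml} for the downstream stages. Reruns with the same spec
#' and seed are byte-identical.
#'
#' @param spec a \code{pr_scenario_spec} (or path to a YAML spec with the
#'   same fields).
#' @param out_dir output directory (created if needed).
#' @return The generated \code{pr_scenario_bundle}, invisibly.
#' @export
run_simulate <- function(spec = scenario_spec(), out_dir) {
  if (is.character(spec)) {
    doc <- yaml::read_yaml(spec)
    spec <- do.call(scenario_spec, doc)
  }
  stopifnot(inherits(spec, "pr_scenario_spec"))
  bundle <- generate_scenario(spec)
  dir.create(file.path(out_dir, "layers"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "values"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "zones"), showWarnings = FALSE)
  inputs <- list()
  for (id in names(bundle$values)) {
    rel <- file.path("values", paste0(id, ".asc"))
    write_ascii_grid(file.path(out_dir, rel), bundle$values[[id]])
    inputs[[id]] <- list(path = rel, kind = "values")
  }
  for (id in names(bundle$layers)) {
    rel <- file.path("layers", paste0(id, ".asc"))
    write_ascii_grid(file.path(out_dir, rel), bundle$layers[[id]])
    if (is.null(inputs[[id]])) {
      inputs[[id]] <- list(path = rel, kind = "classes")
    }
  }
  zone_entry <- function(zm, rel) {
    write_ascii_grid(file.path(out_dir, rel), zm)
    list(path = rel, labels = as.list(zm$zone_dict))
  }
  zones <- list(
    concessions = zone_entry(bundle$zones$concessions,
                             file.path("zones", "concessions.asc")),
    land_use_plan = zone_entry(bundle$zones$land_use_plan,
                               file.path("zones", "land_use_plan.asc"))
  )
  write_geojson(file.path(out_dir, "protected.geojson"),
                bundle$protected_polygons)
  write_geojson(file.path(out_dir, "concessions.geojson"),
                bundle$concession_polygons)
  yaml::write_yaml(bundle$manifest, file.path(out_dir, "manifest.yaml"))
  cfg <- list(inputs = inputs, zones = zones, nodata_policy = "ignore",
              out_dir = ".", seed = spec$seed,
              resolution = spec$cell_size_m)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(bundle)
}

#' Pipeline stage: classify
#'
#' Produces one rank-encoded class raster per configured indicator: inputs
#' of kind "values" are classified through the rule registry; inputs of
#' kind "classes" are validated and passed through. A per-layer class-count
#' summary is written as \code{classified/class_counts.csv}.
#'
#' @param config a config list (see \code{\link{read_run_config}}) or a path
#'   to one.
#' @return Named list of \code{pr_indicator_layer}s, invisibly.
#' @export
run_classify <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  if (is.null(cfg$inputs) || !length(cfg$inputs)) {
    stop("config has no 'inputs' block")
  }
  reg <- load_config_registry(cfg)
  out_dir <- resolve_path(cfg, cfg$out_dir)
  dir.create(file.path(out_dir, "classified"), recursive = TRUE,
             showWarnings = FALSE)
  layers <- list()
  counts <- NULL
  for (id in names(cfg$inputs)) {
    inp <- cfg$inputs[[id]]
    path <- resolve_path(cfg, inp$path)
    if (!file.exists(path)) {
      stop("input raster for indicator ", id, " not found: ", path)
    }
    g <- read_ascii_grid(path)
    kind <- if (is.null(inp$kind)) "values" else inp$kind
    if (kind == "values") {
      if (is.null(reg$tables[[id]])) {
        stop("unknown indicator id '", id, "': no rule table in the registry")
      }
      lyr <- classify_grid(reg$tables[[id]], g)
    } else {
      lyr <- indicator_layer(g, indicator_id = id)
    }
    layers[[id]] <- lyr
    write_ascii_grid(file.path(out_dir, "classified",
                               paste0(id, ".asc")), lyr)
    counts <- rbind(counts, tabulate_areas(lyr, label = id))
  }
  write_area_table_csv(file.path(out_dir, "classified", "class_counts.csv"),
                       counts)
  invisible(layers)
}

#' Pipeline stage: combine
#'
#' Reads the classified rasters and superimposes them with the maximum-risk
#' overlay into the Risk Indicator Map; writes \code{rim.asc} and its area
#' table \code{rim_areas.csv}.
#'
#' @inheritParams run_classify
#' @return The combined \code{pr_indicator_layer}, invisibly.
#' @export
run_combine <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  out_dir <- resolve_path(cfg, cfg$out_dir)
  cls_dir <- file.path(out_dir, "classified")
  files <- sort(list.files(cls_dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) {
    stop("no classified rasters found under ", cls_dir,
         " (run the classify stage first)")
  }
  layers <- lapply(files, function(f) {
    indicator_layer(read_ascii_grid(f),
                    indicator_id = tools::file_path_sans_ext(basename(f)))
  })
  rim <- combine_liebig(layers, nodata_policy = cfg$nodata_policy)
  write_ascii_grid(file.path(out_dir, "rim.asc"), rim)
  write_area_table_csv(file.path(out_dir, "rim_areas.csv"),
                       tabulate_areas(rim, label = "RIM"))
  invisible(rim)
}

read_config_zone_map <- function(cfg, name) {
  z <- cfg$zones[[name]]
  if (is.null(z)) stop("config has no '", name, "' zone map")
  path <- resolve_path(cfg, z$path)
  if (!file.exists(path)) stop("zone raster not found: ", path)
  labels <- unlist(z$labels)
  zone_map(read_ascii_grid(path), labels)
}

#' Pipeline stage: report
#'
#' Cross-tabulates the Risk Indicator Map against the concession and
#' land-use-plan zone maps and writes the area tables
#' (\code{crosstab_concessions.csv}, \code{crosstab_land_use_plan.csv};
#' percentages against the full mapped area, the layout of the published
#' distribution table), the ranked expansion recommendations
#' (\code{recommendations.csv}) and a human-readable \code{report.md}. The
#' report flags the MEDIUM-collapse discrepancy explicitly: under a pure
#' per-cell maximum, a combined map can only lose its MEDIUM cells if every
#' one of them is overridden by a HIGH or VERY_HIGH elsewhere, so a non-zero
#' MEDIUM row is reported as-is rather than collapsed.
#'
#' @inheritParams run_classify
#' @return A list with the cross-tabulations and recommendation table,
#'   invisibly.
#' @export
run_report <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  out_dir <- resolve_path(cfg, cfg$out_dir)
  rim_path <- file.path(out_dir, "rim.asc")
  if (!file.exists(rim_path)) {
    stop("rim.asc not found under ", out_dir, " (run the combine stage first)")
  }
  rim <- indicator_layer(read_ascii_grid(rim_path), indicator_id = "RIM")
  zc <- read_config_zone_map(cfg, "concessions")
  zl <- read_config_zone_map(cfg, "land_use_plan")
  check_congruent(list(rim, zc, zl), "report inputs")
  ct_c <- cross_tabulate(rim, zc, percent_denominator = "map")
  ct_l <- cross_tabulate(rim, zl, percent_denominator = "map")
  rec <- rank_expansion_options(rim, zl, zc)
  write_area_table_csv(file.path(out_dir, "crosstab_concessions.csv"), ct_c)
  write_area_table_csv(file.path(out_dir, "crosstab_land_use_plan.csv"), ct_l)
  utils::write.csv(rec, file.path(out_dir, "recommendations.csv"),
                   row.names = FALSE)
  rim_tab <- tabulate_areas(rim, label = "RIM")
  cls_counts <- file.path(out_dir, "classified", "class_counts.csv")
  per_layer <- if (file.exists(cls_counts)) {
    utils::read.csv(cls_counts, stringsAsFactors = FALSE)
  } else NULL
  md <- c("# Risk Indicator Map report", "",
          "## Combined risk distribution", "",
          md_area_table(rim_tab))
  if (!is.null(per_layer)) {
    md <- c(md, "", "## Per-indicator distribution", "",
            md_area_table(per_layer))
  }
  md <- c(md, "", "## Concession cross-tabulation (percent of mapped area)",
          "", md_area_table(ct_c),
          "", "## Land-use-plan cross-tabulation (percent of mapped area)",
          "", md_area_table(ct_l),
          "", "## Ranked expansion options (low-risk land)", "",
          "| priority | zone | low-risk ha |", "|---|---|---|",
          sprintf("| %d | %s | %.0f |", rec$priority, rec$zone,
                  rec$low_risk_ha),
          "", "## Notes", "")
  medium_inputs <- !is.null(per_layer) && any(per_layer$medium_ha > 0)
  if (rim_tab$medium_ha == 0 && medium_inputs) {
    md <- c(md, paste("- The combined map has no MEDIUM cells although some",
                      "input layers contain MEDIUM: every MEDIUM cell was",
                      "overridden by a HIGH or VERY_HIGH class in another",
                      "layer (pure per-cell maximum; no post-hoc collapse",
                      "applied)."))
  } else if (rim_tab$medium_ha > 0) {
    md <- c(md, paste("- The combined map retains MEDIUM cells; the overlay",
                      "is a pure per-cell maximum with no post-hoc collapse",
                      "of the MEDIUM class."))
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(list(rim = rim_tab, concessions = ct_c, land_use_plan = ct_l,
                 recommendations = rec))
}

md_area_table <- function(at) {
  at <- as.data.frame(at)
  c("| layer | low ha (%) | medium ha (%) | high ha (%) | very high ha (%) | total ha |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %.0f (%d%%) | %.0f (%d%%) | %.0f (%d%%) | %.0f (%d%%) | %.0f |",
            at$label, at$low_ha, at$low_pct, at$medium_ha, at$medium_pct,
            at$high_ha, at$high_pct, at$very_high_ha, at$very_high_pct,
            at$total_ha))
}

#' Run the whole pipeline
#'
#' Convenience wrapper: simulate (optional) then classify, combine, report.
#'
#' @param config config list or path (see \code{\link{read_run_config}}).
#' @return The report stage's result, invisibly.
#' @export
run_pipeline <- function(config) {
  run_classify(config)
  run_combine(config)
  invisible(run_report(config))
}
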