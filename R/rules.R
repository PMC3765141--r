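#' Rule tables: per-indicator suitability classification
#'
#' A rule table maps one indicator's values to the four ordinal risk classes.
#' Continuous tables hold an ordered set of value intervals with explicit
#' open/closed endpoints that must partition the declared domain; categorical
#' tables hold pairwise-disjoint category sets with a default class for
#' unlisted categories.
#'
#' Boundary convention for the built-in tables: intervals are half-open,
#' closed at the lower-risk end, so a printed boundary value takes the less
#' risky class (slope exactly 15\% is MEDIUM, rainfall exactly 1750 mm/yr is
#' LOW, carbon exactly 80 t/ha is HIGH).
#'
#' @param indicator_id dotted indicator code, e.g. "3.1.1".
#' @param kind "continuous" or "categorical".
#' @param units measurement units (continuous tables), e.g. "mm/yr".
#' @param rules for continuous tables a data.frame (or list of lists) with
#'   columns \code{min}, \code{max}, \code{min_closed}, \code{max_closed},
#'   \code{class}; for categorical tables a list of
#'   \code{list(categories = c(...), class = ...)}.
#' @param default_class class assigned to unlisted categories (categorical
#'   only); may be "NODATA".
#' @param domain numeric length-2 value domain for continuous tables
#'   (closed at finite endpoints); \code{Inf} upper bound allowed.
#' @param metadata named list (e.g. principle/criterion text).
#' @return An object of class \code{pr_rule_table}.
#' @export
rule_table <- function(indicator_id, kind = c("continuous", "categorical"),
                       units = NULL, rules, default_class = NULL,
                       domain = c(0, Inf), metadata = list()) {
  kind <- match.arg(kind)
  id <- as.character(indicator_id)
  if (kind == "continuous") {
    if (is.list(rules) && !is.data.frame(rules)) {
      rules <- do.call(rbind, lapply(rules, function(r) {
        r <- as.list(r)
        if (is.null(names(r)) || !all(c("min", "max", "class") %in% names(r))) {
          # positional triple [min, max, class]: default closedness is the
          # built-in convention (open lower, closed upper; -Inf/domain-min
          # lower closed)
          names(r)[1:3] <- c("min", "max", "class")
        }
        data.frame(min = as.numeric(r$min), max = as.numeric(r$max),
                   min_closed = if (is.null(r$min_closed)) NA else r$min_closed,
                   max_closed = if (is.null(r$max_closed)) NA else r$max_closed,
                   class = as.character(r$class))
      }))
    }
    rules <- as.data.frame(rules)
    rules$min <- as.numeric(rules$min)
    rules$max <- as.numeric(rules$max)
    if (is.null(rules$min_closed)) rules$min_closed <- NA
    if (is.null(rules$max_closed)) rules$max_closed <- NA
    rules$min_closed <- ifelse(is.na(rules$min_closed),
                               rules$min <= domain[1] | !is.finite(rules$min),
                               as.logical(rules$min_closed))
    rules$max_closed <- ifelse(is.na(rules$max_closed),
                               is.finite(rules$max),
                               as.logical(rules$max_closed))
    bad <- rules$min >= rules$max
    if (any(bad)) {
      stop("rule table ", id, ": malformed interval (lower >= upper): ",
           paste(sprintf("(%g, %g)", rules$min[bad], rules$max[bad]),
                 collapse = ", "))
    }
    rules$rank <- risk_rank(rules$class)   # errors on unknown labels
    if (any(is.na(rules$rank))) {
      stop("rule table ", id, ": continuous rules may not map to NODATA")
    }
    rules$class <- risk_label(rules$rank)
  } else {
    rules <- lapply(rules, function(r) {
      stopifnot(!is.null(r$categories), !is.null(r$class))
      rk <- risk_rank(r$class)
      list(categories = tolower(trimws(as.character(unlist(r$categories)))),
           class = risk_label(rk), rank = rk)
    })
    if (is.null(default_class)) default_class <- "NODATA"
    default_class <- risk_label(risk_rank(default_class))
    domain <- NULL
    units <- NULL
  }
  structure(list(indicator_id = id, kind = kind, units = units,
                 rules = rules, default_class = default_class,
                 domain = domain, metadata = metadata),
            class = "pr_rule_table")
}

#' @export
print.pr_rule_table <- function(x, ...) {
  cat(sprintf("<pr_rule_table> %s (%s%s)\n", x$indicator_id, x$kind,
              if (!is.null(x$units)) paste0(", ", x$units) else ""))
  if (x$kind == "continuous") {
    for (i in seq_len(nrow(x$rules))) {
      r <- x$rules[i, ]
      cat(sprintf("  %s%g, %g%s -> %s\n",
                  if (r$min_closed) "[" else "(", r$min, r$max,
                  if (r$max_closed) "]" else ")", r$class))
    }
  } else {
    for (r in x$rules) {
      cat(sprintf("  {%s} -> %s\n", paste(r$categories, collapse = "; "),
                  r$class))
    }
    cat("  default ->", x$default_class, "\n")
  }
  invisible(x)
}

interval_contains <- function(rules, v) {
  # logical matrix: length(v) x nrow(rules)
  sapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    lo <- if (r$min_closed) v >= r$min else v > r$min
    hi <- if (r$max_closed) v <= r$max else v < r$max
    lo & hi
  })
}

#' Validate a rule table
#'
#' Checks that a continuous table's intervals partition the declared value
#' domain (no gaps, no overlaps) or that a categorical table's category sets
#' are pairwise disjoint. Validation never throws: it returns a report.
#'
#' @param table a \code{pr_rule_table}.
#' @return A data.frame report with one row per problem (columns
#'   \code{issue} = "gap"/"overlap", \code{from}, \code{to},
#'   \code{from_closed}, \code{to_closed}, \code{detail}); zero rows iff the
#'   table is a clean partition.
#' @examples
#' validate_rule_table(default_rule_registry()$tables[["3.1.1"]])
#' @export
validate_rule_table <- function(table) {
  stopifnot(inherits(table, "pr_rule_table"))
  empty <- data.frame(issue = character(), from = numeric(), to = numeric(),
                      from_closed = logical(), to_closed = logical(),
                      detail = character(), stringsAsFactors = FALSE)
  if (table$kind == "categorical") {
    seen <- unlist(lapply(table$rules, `[[`, "categories"))
    dup <- unique(seen[duplicated(seen)])
    if (!length(dup)) return(empty)
    return(data.frame(issue = "overlap", from = NA_real_, to = NA_real_,
                      from_closed = NA, to_closed = NA,
                      detail = paste("duplicate category:", dup),
                      stringsAsFactors = FALSE))
  }
  rules <- table$rules
  dmin <- table$domain[1]; dmax <- table$domain[2]
  pts <- sort(unique(c(dmin, dmax, rules$min, rules$max)))
  pts <- pts[is.finite(pts) & pts >= dmin & pts <= dmax]
  # elementary pieces in sweep order: breakpoint, open interval to the next
  # breakpoint, next breakpoint, ... (plus the tail to an infinite domain)
  ends <- pts
  if (!is.finite(dmax)) ends <- c(ends, Inf)
  pieces <- list()
  for (i in seq_along(ends)) {
    if (is.finite(ends[i])) {
      pieces[[length(pieces) + 1]] <- list(kind = "point", at = ends[i])
    }
    if (i < length(ends)) {
      lo <- ends[i]; hi <- ends[i + 1]
      probe <- if (is.finite(hi)) (lo + hi) / 2 else lo + 1
      pieces[[length(pieces) + 1]] <-
        list(kind = "open", lo = lo, hi = hi, probe = probe)
    }
  }
  n_match <- function(v) {
    m <- interval_contains(rules, v)
    sum(m)
  }
  rows <- empty
  flush <- function(run, rows) {
    if (is.null(run)) return(rows)
    rbind(rows, data.frame(issue = run$issue, from = run$from, to = run$to,
                           from_closed = run$from_closed,
                           to_closed = run$to_closed,
                           detail = sprintf("%d matching rule(s)", run$count),
                           stringsAsFactors = FALSE))
  }
  run <- NULL
  for (pc in pieces) {
    v <- if (pc$kind == "point") pc$at else pc$probe
    cnt <- n_match(v)
    issue <- if (cnt == 0) "gap" else if (cnt > 1) "overlap" else NA
    if (is.na(issue)) { rows <- flush(run, rows); run <- NULL; next }
    lo <- if (pc$kind == "point") pc$at else pc$lo
    hi <- if (pc$kind == "point") pc$at else pc$hi
    loc <- pc$kind == "point"    # closed end iff the piece is a point
    if (!is.null(run) && run$issue == issue && run$count == cnt &&
        isTRUE(all.equal(run$to, lo))) {
      run$to <- hi; run$to_closed <- loc
    } else {
      rows <- flush(run, rows)
      run <- list(issue = issue, from = lo, to = hi, from_closed = loc,
                  to_closed = loc, count = cnt)
    }
  }
  rows <- flush(run, rows)
  rows
}

#' Classify indicator values into risk classes
#'
#' Applies one indicator's rule table to values. Missing input (NA/NaN, or a
#' blank category) yields NODATA — never silently LOW. For categorical
#' tables an unlisted category falls to the table's default class with a
#' warning.
#'
#' @param table a \code{pr_rule_table}.
#' @param value numeric vector (continuous tables) or character vector
#'   (categorical tables; matching is exact, case-insensitive).
#' @return Character vector of class labels ("LOW", "MEDIUM", "HIGH",
#'   "VERY_HIGH", "NODATA").
#' @examples
#' reg <- default_rule_registry()
#' classify_value(reg$tables[["3.1.1"]], c(1600, 1100, NA))
#' classify_value(reg$tables[["3.3.2"]], "sand")
#' @export
classify_value <- function(table, value) {
  stopifnot(inherits(table, "pr_rule_table"))
  if (table$kind == "continuous") {
    v <- as.numeric(value)
    out <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    if (any(ok)) {
      inside <- v >= table$domain[1] & v <= table$domain[2]
      if (any(ok & !inside)) {
        warning("rule table ", table$indicator_id, ": ",
                sum(ok & !inside), " value(s) outside the declared domain ",
                sprintf("[%g, %g]", table$domain[1], table$domain[2]),
                " -> NODATA")
      }
      idx <- which(ok & inside)
      if (length(idx)) {
        m <- interval_contains(table$rules, v[idx])
        if (length(idx) == 1) m <- matrix(m, nrow = 1)
        first <- apply(m, 1, function(r) which(r)[1])
        out[idx] <- table$rules$rank[first]
      }
    }
  } else {
    v <- tolower(trimws(as.character(value)))
    v[v == ""] <- NA_character_
    out <- rep(NA_integer_, length(v))
    matched <- is.na(v)
    for (r in table$rules) {
      hit <- !matched & v %in% r$categories
      out[hit] <- r$rank
      matched <- matched | hit
    }
    if (any(!matched)) {
      warning("rule table ", table$indicator_id, ": unknown categories (",
              paste(unique(v[!matched]), collapse = ", "),
              ") -> default class ", table$default_class)
      out[!matched] <- risk_rank(table$default_class)
    }
  }
  risk_label(out)
}

#' Classify a raster grid cell-wise
#'
#' Cell-for-cell application of \code{\link{classify_value}}; georeferencing
#' is preserved and nodata propagates to NODATA.
#'
#' @param table a \code{pr_rule_table}.
#' @param grid a \code{pr_grid} of values (numeric or categorical).
#' @return A \code{pr_indicator_layer} tagged with the table's indicator id.
#' @export
classify_grid <- function(table, grid) {
  stopifnot(inherits(table, "pr_rule_table"), inherits(grid, "pr_grid"))
  labels <- classify_value(table, as.vector(grid$cells))
  ranks <- matrix(risk_rank(replace(labels, labels == "NODATA", NA)),
                  nrow = nrow(grid$cells), ncol = ncol(grid$cells))
  out <- pr_grid(ranks, origin = grid$origin, cell_size = grid$cell_size,
                 crs = grid$crs)
  indicator_layer(out, indicator_id = table$indicator_id)
}
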