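#' Validate input tables without mutating them
#'
#' Schema, unit and group-size checks on the delimited input tables with
#' actionable messages. Failures are collected in the report, never thrown.
#'
#' @param region_file optional path to a region-activity CSV.
#' @param marker_file optional path to a marker-count CSV.
#' @return object of class `validation_report`: data.frame with columns
#'   `input`, `level` (`"error"`/`"warning"`), `message`; zero rows means
#'   the inputs are clean.
#' @export
validate_inputs <- function(region_file = NULL, marker_file = NULL) {
  rows <- list()
  add <- function(input, level, msg)
    rows[[length(rows) + 1L]] <<- data.frame(input = input, level = level,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  check_meta <- function(tab, input) {
    miss <- setdiff(.meta_cols, names(tab))
    if (length(miss))
      add(input, "error", sprintf("missing required column(s): %s",
                                  paste(miss, collapse = ", ")))
    length(miss) == 0L
  }

  if (!is.null(region_file)) {
    if (!file.exists(region_file)) {
      add("regions", "error", sprintf("file not found: %s", region_file))
    } else {
      tab <- utils::read.csv(region_file, check.names = FALSE,
                             stringsAsFactors = FALSE)
      if (check_meta(tab, "regions")) {
        regions <- setdiff(names(tab), .meta_cols)
        if (length(regions) < 3L)
          add("regions", "error",
              sprintf("need >= 3 region columns, found %d (%s)",
                      length(regions), paste(regions, collapse = ", ")))
        for (r in regions) {
          if (!is.numeric(tab[[r]]))
            add("regions", "error", sprintf("region '%s' is not numeric", r))
          else if (any(tab[[r]] < 0, na.rm = TRUE))
            add("regions", "error",
                sprintf("region '%s' has negative densities", r))
        }
        ns <- table(group_label(tab$treatment, tab$age, tab$sex))
        for (g in names(ns)) {
          if (ns[[g]] < 3L)
            add("regions", "error",
                sprintf("group '%s' has n = %d, below the n >= 3 correlation floor",
                        g, ns[[g]]))
          else if (ns[[g]] < 5L)
            add("regions", "warning",
                sprintf("group '%s' has n = %d (< 5): correlations will be unstable",
                        g, ns[[g]]))
        }
      }
    }
  }

  if (!is.null(marker_file)) {
    if (!file.exists(marker_file)) {
      add("markers", "error", sprintf("file not found: %s", marker_file))
    } else {
      tab <- utils::read.csv(marker_file, stringsAsFactors = FALSE)
      if (check_meta(tab, "markers")) {
        miss <- setdiff(c("marker", "count", "area_mm2"), names(tab))
        if (length(miss)) {
          add("markers", "error",
              sprintf("missing required column(s): %s",
                      paste(miss, collapse = ", ")))
        } else {
          if (!.is_count(tab$count))
            add("markers", "error", "counts must be non-negative integers")
          bad <- !is.finite(tab$area_mm2) | tab$area_mm2 <= 0
          if (any(bad))
            add("markers", "error",
                sprintf("non-positive traced area(s) for subject(s): %s",
                        paste(unique(tab$subject_id[bad]), collapse = ", ")))
          nsec <- table(interaction(tab$subject_id, tab$marker, drop = TRUE))
          if (any(nsec < 1L))
            add("markers", "error", "subject/marker with no section records")
        }
      }
    }
  }

  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(input = character(0), level = character(0),
               message = character(0), stringsAsFactors = FALSE)
  class(res) <- c("validation_report", "data.frame")
  res
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("validation: clean (no failures)\n")
  } else {
    cat(sprintf("validation: %d error(s), %d warning(s)\n",
                sum(x$level == "error"), sum(x$level == "warning")))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s: %s\n", x$level[i], x$input[i], x$message[i]))
  }
  invisible(x)
}
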