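#' Assemble a pipeline run configuration
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"tables"` (read
#'   existing delimited tables).
#' @param region_file,marker_file input CSV paths (tables mode).
#' @param out_dir output directory for all run artifacts.
#' @param seed master seed (synthetic mode; also recorded in the manifest).
#' @param design,structure,profile generator settings (synthetic mode);
#'   defaults are [cohort_design()] with the given seed,
#'   [default_planted_structure()] and [neurogenesis_profile()].
#' @param policy a [threshold_policy()].
#' @param baseline_age baseline age for percent change (weeks).
#' @param focal_region focal region label.
#' @param network_sexes sexes included in the connectivity stage; defaults
#'   to `"male"` (the connectivity analysis uses males only because female
#'   behaviour was too variable in the source design); set to both sexes to
#'   analyse all strata.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "tables"),
                       region_file = NULL, marker_file = NULL,
                       out_dir = tempfile("fosnet_run_"),
                       seed = 0L,
                       design = NULL, structure = NULL, profile = NULL,
                       policy = threshold_policy(),
                       baseline_age = 4,
                       focal_region = "DG",
                       network_sexes = "male") {
  mode <- match.arg(mode)
  if (mode == "tables") {
    for (f in c(region_file, marker_file))
      if (!is.null(f) && !file.exists(f)) .err("input file not found: %s", f)
    if (is.null(region_file) && is.null(marker_file))
      .err("tables mode needs region_file and/or marker_file")
  }
  if (is.null(design)) design <- suppressWarnings(cohort_design(seed = seed))
  if (is.null(structure)) structure <- default_planted_structure(design)
  if (is.null(profile)) profile <- neurogenesis_profile()
  stopifnot(inherits(policy, "threshold_policy"))
  structure(list(mode = mode, region_file = region_file,
                 marker_file = marker_file, out_dir = out_dir,
                 seed = as.integer(seed), design = design,
                 structure = structure, profile = profile, policy = policy,
                 baseline_age = baseline_age, focal_region = focal_region,
                 network_sexes = network_sexes),
            class = "run_config")
}

# 31-bit content hash of the JSON-serialized configuration
.config_hash <- function(config) {
  drop <- c("out_dir", "region_file", "marker_file")  # paths don't change results
  cfg <- unclass(config)[setdiff(names(unclass(config)), drop)]
  txt <- jsonlite::toJSON(lapply(cfg, unclass), auto_unbox = TRUE,
                          digits = 10, dataframe = "columns", force = TRUE)
  sprintf("%08x", hash31(as.character(txt)))
}

# deterministic matrix CSV writer (region labels as first column)
.write_matrix <- function(m, path) {
  df <- data.frame(region = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) -> quantify -> connect -> measure -> infer
#' and writes every stage artifact under `config$out_dir`: cohort tables,
#' density and percent-change tables, per-group r/p/n/adjacency matrices
#' and edge lists, a network summary table, ANOVA and post hoc tables per
#' marker and sex, the focal-degree/DCX correlation, a human-readable
#' report and a JSON manifest (config hash, seed, package version,
#' aggregated warnings). Identical config + seed reproduce byte-identical
#' artifacts.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  note <- function(w) notes[[length(notes) + 1L]] <<- conditionMessage(w)

  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        .err("stage '%s' failed: %s", name, conditionMessage(e))),
      warning = function(w) { note(w); invokeRestart("muffleWarning") },
      message = function(m) { note(m); invokeRestart("muffleMessage") })
  }

  ## -- simulate or ingest ---------------------------------------------
  if (config$mode == "synthetic") {
    regions <- stage("simulate",
                     sample_region_densities(config$design, config$structure))
    markers <- stage("simulate",
                     sample_marker_counts(config$design, config$profile))
    write_cohort(out, regions, markers, config$design, config$structure,
                 config$profile)
  } else {
    regions <- if (!is.null(config$region_file))
      stage("ingest", {
        x <- utils::read.csv(config$region_file, check.names = FALSE,
                             stringsAsFactors = FALSE)
        class(x) <- c("region_activity", "data.frame"); x
      })
    markers <- if (!is.null(config$marker_file))
      stage("ingest", {
        x <- utils::read.csv(config$marker_file, check.names = FALSE,
                             stringsAsFactors = FALSE)
        class(x) <- c("marker_counts", "data.frame"); x
      })
  }

  ## -- quantify --------------------------------------------------------
  densities <- pct <- NULL
  if (!is.null(markers)) {
    densities <- stage("quantify", compute_density(markers))
    pct <- stage("quantify",
                 percent_change_from_baseline(densities, config$baseline_age))
    utils::write.csv(densities, file.path(out, "densities.csv"),
                     row.names = FALSE)
    utils::write.csv(pct, file.path(out, "percent_change.csv"),
                     row.names = FALSE)
  }

  ## -- connect + measure ----------------------------------------------
  networks <- list()
  if (!is.null(regions)) {
    cells <- unique(regions[regions$sex %in% config$network_sexes,
                            c("treatment", "age", "sex")])
    cells <- cells[order(cells$treatment, cells$age, cells$sex), ]
    for (i in seq_len(nrow(cells))) {
      grp <- list(treatment = cells$treatment[i], age = cells$age[i],
                  sex = cells$sex[i])
      lab <- group_label(grp$treatment, grp$age, grp$sex)
      corr <- stage(paste0("connect:", lab),
                    pairwise_correlations(regions, grp))
      adj <- stage(paste0("connect:", lab),
                   threshold_adjacency(corr, config$policy))
      summ <- stage(paste0("metrics:", lab),
                    network_summary(adj, group = lab,
                                    focal = config$focal_region))
      .write_matrix(round(corr$r, 10), file.path(out, paste0(lab, "_r.csv")))
      .write_matrix(signif(corr$p, 10), file.path(out, paste0(lab, "_p.csv")))
      .write_matrix(corr$n, file.path(out, paste0(lab, "_n.csv")))
      .write_matrix(unclass(adj), file.path(out, paste0(lab, "_adjacency.csv")))
      export_graph(adj, config$focal_region,
                   file = file.path(out, paste0(lab, "_edges.csv")))
      networks[[lab]] <- list(correlation = corr, adjacency = adj,
                              summary = summ)
    }
    if (length(networks)) {
      st <- do.call(rbind, lapply(networks, function(x) data.frame(
        group = x$summary$group, n_edges = x$summary$n_edges,
        density = x$summary$density, focal_degree = x$summary$focal_degree,
        stringsAsFactors = FALSE)))
      rownames(st) <- NULL
      utils::write.csv(st, file.path(out, "network_summary.csv"),
                       row.names = FALSE)
    }
  }

  ## -- infer -----------------------------------------------------------
  stats_out <- list()
  report <- c("fosnet run report", "==================", "")
  if (!is.null(densities)) {
    for (m in unique(densities$marker)) for (s in unique(densities$sex)) {
      d <- densities[densities$marker == m & densities$sex == s, ]
      if (nrow(d) < 4L || length(unique(d$treatment)) < 2L ||
          length(unique(d$age)) < 2L) next
      an <- stage("stats", two_way_anova(d$density, d$treatment, d$age,
                                         c("treatment", "age")))
      cm <- tapply(d$density, group_label(d$treatment, d$age, d$sex), mean)
      cn <- tapply(d$density, group_label(d$treatment, d$age, d$sex), length)
      ph <- stage("stats", snk_posthoc(cm, as.vector(cn),
                                       attr(an, "ms_error"),
                                       attr(an, "df_error")))
      key <- paste(m, s, sep = "_")
      stats_out[[key]] <- list(anova = an, posthoc = ph)
      utils::write.csv(as.data.frame(an),
                       file.path(out, paste0("anova_", key, ".csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(ph),
                       file.path(out, paste0("snk_", key, ".csv")),
                       row.names = FALSE)
      report <- c(report, sprintf("%s (%s): treatment %s; age %s; interaction %s",
                                  m, s, format_effect(an, "treatment"),
                                  format_effect(an, "age"),
                                  format_effect(an, "treatment:age")))
    }
  }
  degree_corr <- NULL
  if (length(networks) >= 3L && !is.null(densities) &&
      "DCX" %in% densities$marker) {
    dcx <- densities[densities$marker == "DCX" &
                       densities$sex %in% config$network_sexes, ]
    dcx_means <- tapply(dcx$density, group_label(dcx$treatment, dcx$age,
                                                 dcx$sex), mean)
    degs <- vapply(networks, function(x) as.numeric(x$summary$focal_degree), 0)
    common <- intersect(names(degs), names(dcx_means))
    if (length(common) >= 3L) {
      degree_corr <- stage("stats",
                           degree_neurogenesis_correlation(
                             degs[common], dcx_means[common]))
      jsonlite::write_json(
        list(r = degree_corr$r, df = degree_corr$df, p = degree_corr$p,
             r_squared = degree_corr$r_squared,
             points = degree_corr$points),
        file.path(out, "degree_dcx_correlation.json"),
        auto_unbox = TRUE, digits = 10, dataframe = "columns")
      report <- c(report, "",
                  sprintf("focal (%s) degree vs mean DCX density: r(%d) = %.2f, p = %.3g, r^2 = %.2f",
                          config$focal_region, degree_corr$df,
                          degree_corr$r, degree_corr$p,
                          degree_corr$r_squared))
    }
  }
  writeLines(report, file.path(out, "report.txt"))

  ## -- manifest ---------------------------------------------------------
  manifest <- list(
    package = "fosnet",
    version = as.character(utils::packageVersion("fosnet")),
    seed = config$seed,
    config_hash = .config_hash(config),
    mode = config$mode,
    policy = unclass(config$policy),
    baseline_age = config$baseline_age,
    focal_region = config$focal_region,
    network_sexes = config$network_sexes,
    warnings = notes,
    files = sort(setdiff(list.files(out), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(regions = regions, markers = markers,
                 densities = densities, percent_change = pct,
                 networks = networks, stats = stats_out,
                 degree_correlation = degree_corr, manifest = manifest))
}
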