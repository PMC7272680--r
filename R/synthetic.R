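#' Sample per-subject regional densities with planted correlation
#'
#' For every (treatment, age, sex) cell of the design, draws `n` subject
#' vectors from a multivariate normal with the group's planted correlation
#' matrix, the structure's region means and common noise SD. Negative draws
#' are truncated at zero; truncation perturbs the planted correlations, so
#' every clip event is counted and attached to the result (attribute
#' `clip_events`) rather than silently absorbed.
#'
#' Each group consumes its own RNG stream derived from the design seed and
#' the group label, so adding a group never reshuffles another group's
#' subjects; the same design + structure + seed reproduce the table exactly.
#'
#' @param design a [cohort_design()].
#' @param structure a [planted_structure()] whose regions match the design.
#' @return a `region_activity` data.frame: `subject_id`, `treatment`, `age`,
#'   `sex`, then one density column (cells/mm^2) per region.
#' @export
sample_region_densities <- function(design, structure) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(structure, "planted_structure"))
  cells <- group_cells(design)
  regions <- design$region_labels
  sdv <- structure$density_noise_sd
  out <- vector("list", nrow(cells))
  clips <- 0L
  for (g in seq_len(nrow(cells))) {
    grp <- cells$group[g]
    R <- build_group_correlation(structure, grp)
    if (!setequal(rownames(R), regions))
      .err("block assignment regions for '%s' do not match the design panel", grp)
    R <- R[regions, regions]
    mu <- .for_group(structure$region_mean_density, grp)[regions]
    if (anyNA(mu) || any(mu <= 0))
      .err("region mean densities for '%s' must be positive for all regions", grp)
    n <- cells$n[g]
    set.seed(derive_seed(design$seed, grp))
    # chol of the correlation can fail only at exact singularity; lift the
    # diagonal by the PSD tolerance in that case
    ch <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-9, nrow(R))))
    X <- matrix(stats::rnorm(n * length(regions)), n) %*% ch * sdv +
      matrix(mu, n, length(regions), byrow = TRUE)
    clips <- clips + sum(X < 0)
    X[X < 0] <- 0
    colnames(X) <- regions
    out[[g]] <- data.frame(
      subject_id = sprintf("%s_%02d", grp, seq_len(n)),
      treatment = cells$treatment[g], age = cells$age[g], sex = cells$sex[g],
      X, stringsAsFactors = FALSE, check.names = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (clips > 0L)
    warning(sprintf("%d negative density draw(s) truncated at 0; planted correlations are perturbed", clips),
            call. = FALSE)
  attr(res, "clip_events") <- clips
  class(res) <- c("region_activity", "data.frame")
  res
}

#' Construct a neurogenesis effect profile
#'
#' Encodes the expected density (cells/mm^2) of each marker for every
#' (treatment, age, sex) cell as
#' `baseline * age_factor(age) * offset(treatment, age, sex)`.
#' Control age factors must be strictly decreasing with age — the
#' established postnatal decline in neurogenesis. The default offsets plant
#' the qualitative germ-free pattern: a male deficit at 4 weeks, a female
#' elevation at 8 weeks, and consequently a delayed 4-to-8-week decline in
#' germ-free animals of both sexes.
#'
#' @param baseline_density named numeric, density at the youngest control
#'   age per marker.
#' @param age_decline_fraction named numeric (names = ages in weeks),
#'   multiplicative control factors, strictly decreasing.
#' @param treatment_offsets data.frame with columns `treatment`, `age`,
#'   `sex`, `offset`; cells not listed default to offset 1 (controls need
#'   not be listed).
#' @param dispersion non-negative subject-level dispersion (variance of a
#'   mean-one gamma random effect); 0 selects a deterministic degenerate
#'   limit used in tests.
#' @param section_area_mm2 mean traced dentate gyrus area per section.
#' @return object of class `neurogenesis_profile`.
#' @export
neurogenesis_profile <- function(
    baseline_density = c(DCX = 2400, BrdU = 180, pyknotic = 20),
    age_decline_fraction = c(`4` = 1, `8` = 0.55, `12` = 0.30),
    treatment_offsets = data.frame(
      treatment = c("germ_free", "germ_free"),
      age = c(4, 8),
      sex = c("male", "female"),
      offset = c(0.65, 1.9)),
    dispersion = 0.06,
    section_area_mm2 = 0.35) {
  stopifnot(is.numeric(baseline_density), all(baseline_density > 0),
            !is.null(names(baseline_density)),
            is.numeric(age_decline_fraction),
            !is.null(names(age_decline_fraction)),
            is.numeric(dispersion), dispersion >= 0,
            section_area_mm2 > 0)
  if (is.unsorted(rev(age_decline_fraction), strictly = TRUE))
    .err("control age factors must be strictly decreasing across ages")
  stopifnot(is.data.frame(treatment_offsets),
            all(c("treatment", "age", "sex", "offset") %in% names(treatment_offsets)),
            all(treatment_offsets$offset > 0))
  structure(list(baseline_density = baseline_density,
                 age_decline_fraction = age_decline_fraction,
                 treatment_offsets = treatment_offsets,
                 dispersion = dispersion,
                 section_area_mm2 = section_area_mm2),
            class = "neurogenesis_profile")
}

#' Expected marker density for a cell of the design
#'
#' @param profile a [neurogenesis_profile()].
#' @param marker marker name present in the profile's baselines.
#' @param treatment,age,sex scalar cell coordinates.
#' @return expected density in cells/mm^2.
#' @export
expected_density <- function(profile, marker, treatment, age, sex) {
  stopifnot(inherits(profile, "neurogenesis_profile"))
  base <- profile$baseline_density[[marker]]
  if (is.null(base)) .err("unknown marker '%s'", marker)
  af <- profile$age_decline_fraction[[as.character(age)]]
  if (is.null(af)) .err("no age factor for age %s", age)
  off <- profile$treatment_offsets
  hit <- off$treatment == treatment & off$age == age & off$sex == sex
  base * af * (if (any(hit)) off$offset[which(hit)[1L]] else 1)
}

#' Sample per-section marker counts and traced areas
#'
#' For every subject and marker: 7–10 sections are sampled; each section
#' gets a traced area (gamma, mean `section_area_mm2`) and a count drawn as
#' Poisson around `area * target_density * subject_effect`, where the
#' subject effect is a mean-one gamma with variance `dispersion`. The count
#' distribution is therefore negative binomial around area times the target
#' density, and the implied per-subject density has expectation
#' `baseline * age_factor * offset`. With `dispersion = 0` the generator
#' degenerates to fixed areas and `round(area * target)` counts, a
#' noiseless limit used to verify the planted trajectories.
#'
#' @param design a [cohort_design()].
#' @param profile a [neurogenesis_profile()].
#' @return a `marker_counts` data.frame: `subject_id`, `treatment`, `age`,
#'   `sex`, `marker`, `section`, `count`, `area_mm2`.
#' @export
sample_marker_counts <- function(design, profile) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(profile, "neurogenesis_profile"))
  cells <- group_cells(design)
  markers <- names(profile$baseline_density)
  disp <- profile$dispersion
  abar <- profile$section_area_mm2
  out <- vector("list", nrow(cells))
  for (g in seq_len(nrow(cells))) {
    grp <- cells$group[g]
    n <- cells$n[g]
    set.seed(derive_seed(design$seed, paste0(grp, ":markers")))
    rows <- vector("list", n * length(markers))
    k <- 0L
    for (i in seq_len(n)) {
      sid <- sprintf("%s_%02d", grp, i)
      for (m in markers) {
        target <- expected_density(profile, m, cells$treatment[g],
                                   cells$age[g], cells$sex[g])
        ns <- sample(7:10, 1L)
        if (disp == 0) {
          areas <- rep(abar, ns)
          counts <- round(areas * target)
        } else {
          areas <- stats::rgamma(ns, shape = 20, rate = 20 / abar)
          eff <- stats::rgamma(1L, shape = 1 / disp, rate = 1 / disp)
          counts <- stats::rpois(ns, lambda = areas * target * eff)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = sid, treatment = cells$treatment[g],
          age = cells$age[g], sex = cells$sex[g], marker = m,
          section = seq_len(ns), count = as.integer(counts),
          area_mm2 = areas, stringsAsFactors = FALSE)
      }
    }
    out[[g]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_counts", "data.frame")
  res
}

#' Write a simulated cohort with replay metadata
#'
#' Writes the region-activity and marker-count tables as comma-separated
#' text plus a JSON metadata file recording design, structure, profile and
#' seed, enough to regenerate the cohort exactly.
#'
#' @param dir output directory (created if needed).
#' @param regions `region_activity` table.
#' @param markers `marker_counts` table.
#' @param design,structure,profile the generating objects.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(dir, regions, markers, design, structure, profile) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("region_activity.csv", "marker_counts.csv",
                            "cohort_meta.json"))
  utils::write.csv(regions, paths[1L], row.names = FALSE)
  utils::write.csv(markers, paths[2L], row.names = FALSE)
  meta <- list(design = unclass(design),
               structure = unclass(structure),
               profile = unclass(profile),
               seed = design$seed)
  jsonlite::write_json(meta, paths[3L], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
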