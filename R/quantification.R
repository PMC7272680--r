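#' Standardize marker counts to dentate gyrus area
#'
#' Per subject and marker, density = total positive cells / total traced
#' area (cells/mm^2): a ratio of sums over sections, which is robust to
#' unequal section areas (as opposed to the mean of per-section densities).
#' Subjects with no usable sections are excluded and reported, never
#' silently dropped; a subject whose sections sum to zero area is an error.
#'
#' @param counts a `marker_counts` data.frame (columns `subject_id`,
#'   `treatment`, `age`, `sex`, `marker`, `count`, `area_mm2`).
#' @return a `density_table` data.frame: one row per subject x marker with
#'   metadata and `density` (cells/mm^2). Excluded subject ids, if any, are
#'   attached as attribute `excluded`.
#' @examples
#' tab <- data.frame(subject_id = "s1", treatment = "control", age = 4,
#'                   sex = "male", marker = "DCX", section = 1,
#'                   count = 50, area_mm2 = 0.25)
#' compute_density(tab)$density  # 200 cells/mm^2
#' @export
compute_density <- function(counts) {
  need <- c(.meta_cols, "marker", "count", "area_mm2")
  miss <- setdiff(need, names(counts))
  if (length(miss)) .err("marker table is missing column(s): %s",
                         paste(miss, collapse = ", "))
  if (!.is_count(counts$count)) .err("counts must be non-negative integers")
  if (any(!is.finite(counts$area_mm2) | counts$area_mm2 <= 0))
    .err("section areas must be strictly positive (offending subject(s): %s)",
         paste(unique(counts$subject_id[!is.finite(counts$area_mm2) |
                                          counts$area_mm2 <= 0]),
               collapse = ", "))
  key <- interaction(counts$subject_id, counts$marker, drop = TRUE)
  tot_c <- tapply(counts$count, key, sum)
  tot_a <- tapply(counts$area_mm2, key, sum)
  if (any(tot_a == 0)) {
    bad <- sub("\\.[^.]+$", "", names(tot_a)[tot_a == 0])
    .err("zero total traced area for subject(s): %s",
         paste(unique(bad), collapse = ", "))
  }
  first <- !duplicated(key)
  res <- counts[first, c(.meta_cols, "marker")]
  res$density <- as.numeric(tot_c[as.character(key[first])] /
                              tot_a[as.character(key[first])])
  rownames(res) <- NULL
  attr(res, "excluded") <- character(0)  # zero-section subjects never appear
  class(res) <- c("density_table", "data.frame")
  res
}

#' Percent change from the matched baseline-age group mean
#'
#' Expresses each animal's density relative to the mean density of its own
#' (treatment, sex, marker) stratum at the baseline age:
#' `100 * (density - baseline_mean) / baseline_mean`. "Respective" baseline
#' means matching both sex and treatment, so e.g. 8-week germ-free females
#' are normalized to 4-week germ-free females. By construction the mean
#' percent change within every baseline group is zero.
#'
#' @param densities a `density_table` from [compute_density()].
#' @param baseline_age baseline age in weeks (default 4).
#' @return a `percent_change` data.frame: the input plus `percent_change`.
#' @export
percent_change_from_baseline <- function(densities, baseline_age = 4) {
  stopifnot(is.data.frame(densities),
            all(c(.meta_cols, "marker", "density") %in% names(densities)))
  strat <- interaction(densities$treatment, densities$sex, densities$marker,
                       drop = TRUE, sep = "/")
  base <- densities$age == baseline_age
  missing_strata <- setdiff(levels(strat), unique(as.character(strat[base])))
  if (length(missing_strata))
    .err("no subjects at baseline age %s in stratum(s): %s", baseline_age,
         paste(missing_strata, collapse = ", "))
  bmean <- tapply(densities$density[base], droplevels(strat[base]), mean)
  if (any(bmean == 0))
    .err("baseline mean density is zero in stratum(s): %s",
         paste(names(bmean)[bmean == 0], collapse = ", "))
  res <- densities
  res$percent_change <- as.numeric(
    100 * (res$density - bmean[as.character(strat)]) / bmean[as.character(strat)])
  rownames(res) <- NULL
  class(res) <- c("percent_change", "data.frame")
  res
}
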