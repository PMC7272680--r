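#' Default brain region labels
#'
#' Eight generic region labels with the dentate gyrus (`"DG"`) as the focal
#' region: hippocampal subfields, parahippocampal cortices and two
#' extra-hippocampal regions commonly included in immediate-early-gene
#' co-activation networks.
#'
#' @return character vector of region labels.
#' @export
default_regions <- function() {
  c("DG", "CA1", "CA3", "SUB", "EC", "PRH", "RSC", "BLA")
}

#' Default per-group sample sizes
#'
#' Group sizes typical of a germ-free/control developmental cohort: male
#' control 11/11/8 and germ-free 11/11/6 at 4/8/12 weeks; five (four at
#' 12 weeks) females per cell in both lines.
#'
#' @return data.frame with columns `treatment`, `age`, `sex`, `n`.
#' @export
default_group_sizes <- function() {
  data.frame(
    treatment = rep(c("control", "germ_free"), each = 6L),
    age       = rep(c(4, 8, 12), times = 4L),
    sex       = rep(rep(c("male", "female"), each = 3L), times = 2L),
    n         = c(11, 11, 8, 5, 5, 4, 11, 11, 6, 5, 5, 4),
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort design
#'
#' A cohort design fixes the factorial layout of a simulated experiment:
#' treatments, ordered ages in weeks, sexes, the number of subjects per
#' (treatment, age, sex) cell, the region panel with its focal region, and
#' the master seed. Pairwise correlation needs at least three subjects per
#' group; cells below five subjects are allowed but trigger a warning.
#'
#' @param treatments character vector of treatment labels.
#' @param ages numeric vector of ages in weeks, increasing.
#' @param sexes character vector of sex labels.
#' @param n_per_group either a single integer applied to every cell, or a
#'   data.frame with columns `treatment`, `age`, `sex`, `n` covering every
#'   cell (the default mirrors [default_group_sizes()]).
#' @param region_labels unique region names, length >= 3.
#' @param focal_region focal region label, must appear in `region_labels`.
#' @param seed non-negative integer master seed.
#' @return object of class `cohort_design`.
#' @examples
#' d <- cohort_design(seed = 7)
#' nrow(group_cells(d))
#' @export
cohort_design <- function(treatments = c("control", "germ_free"),
                          ages = c(4, 8, 12),
                          sexes = c("male", "female"),
                          n_per_group = default_group_sizes(),
                          region_labels = default_regions(),
                          focal_region = "DG",
                          seed = 0L) {
  stopifnot(length(treatments) >= 1, length(ages) >= 1, length(sexes) >= 1,
            is.numeric(ages), !is.unsorted(ages, strictly = TRUE),
            is.numeric(seed), length(seed) == 1L, seed >= 0)
  if (anyDuplicated(region_labels))
    .err("region labels must be unique")
  if (length(region_labels) < 3L)
    .err("need at least 3 region labels, got %d", length(region_labels))
  if (!focal_region %in% region_labels)
    .err("focal region '%s' is not among the region labels", focal_region)

  cells <- expand.grid(treatment = treatments, age = ages, sex = sexes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.data.frame(n_per_group)) {
    stopifnot(all(c("treatment", "age", "sex", "n") %in% names(n_per_group)))
    key  <- group_label(cells$treatment, cells$age, cells$sex)
    keyn <- group_label(n_per_group$treatment, n_per_group$age, n_per_group$sex)
    idx <- match(key, keyn)
    if (anyNA(idx))
      .err("n_per_group is missing cells: %s",
           paste(key[is.na(idx)], collapse = ", "))
    cells$n <- as.integer(n_per_group$n[idx])
  } else {
    stopifnot(is.numeric(n_per_group), length(n_per_group) == 1L)
    cells$n <- as.integer(n_per_group)
  }
  if (any(cells$n < 3L))
    .err("every group cell needs n >= 3 (pairwise correlation floor); got n = %d in %s",
         min(cells$n),
         group_label(cells$treatment, cells$age, cells$sex)[which.min(cells$n)])
  if (any(cells$n < 5L))
    warning(sprintf("%d group cell(s) have n < 5; correlations will be unstable",
                    sum(cells$n < 5L)), call. = FALSE)

  structure(list(treatments = treatments, ages = ages, sexes = sexes,
                 cells = cells, region_labels = region_labels,
                 focal_region = focal_region, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Group cells of a design
#'
#' @param design a `cohort_design`.
#' @return data.frame with one row per (treatment, age, sex) cell, columns
#'   `treatment`, `age`, `sex`, `n`, `group`.
#' @export
group_cells <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  cells <- design$cells
  cells$group <- group_label(cells$treatment, cells$age, cells$sex)
  cells
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("cohort_design: %d treatment(s) x %d age(s) x %d sex(es), %d subjects total\n",
              length(x$treatments), length(x$ages), length(x$sexes),
              sum(x$cells$n)))
  cat(sprintf("  regions: %s (focal: %s); seed %d\n",
              paste(x$region_labels, collapse = ", "), x$focal_region, x$seed))
  invisible(x)
}
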