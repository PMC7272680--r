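#' Construct a planted covariance structure
#'
#' The region-density sampler draws each group's subject vectors from a
#' multivariate normal whose correlation matrix is block structured:
#' `within_block_r` inside a block, `between_block_r` across blocks, unit
#' diagonal. Block membership may differ between groups, which is how the
#' generator plants group-specific connectivity (e.g. an age-shrinking
#' dentate gyrus block in controls).
#'
#' @param block_assignment either a named integer vector (region -> block id,
#'   applied to every group) or a named list of such vectors keyed by group
#'   label, with an optional `"default"` entry used for groups not listed.
#' @param within_block_r correlation within a block, in `[0, 1)`.
#' @param between_block_r correlation across blocks, in `[0, 1)` and
#'   strictly less than `within_block_r` (equality allowed only at 0).
#' @param region_mean_density named numeric vector of mean densities
#'   (cells/mm^2, positive), or a named list of such vectors keyed by group
#'   label with a `"default"` entry.
#' @param density_noise_sd positive noise standard deviation (cells/mm^2).
#' @return object of class `planted_structure`.
#' @seealso [build_group_correlation()], [sample_region_densities()]
#' @export
planted_structure <- function(block_assignment,
                              within_block_r = 0.9,
                              between_block_r = 0.1,
                              region_mean_density = NULL,
                              density_noise_sd = 40) {
  stopifnot(within_block_r >= 0, within_block_r < 1,
            between_block_r >= 0, between_block_r < 1,
            density_noise_sd > 0)
  if (between_block_r > within_block_r)
    .err("between_block_r (%.3f) must not exceed within_block_r (%.3f)",
         between_block_r, within_block_r)
  regions <- if (is.list(block_assignment))
    names(block_assignment[[1L]]) else names(block_assignment)
  if (is.null(regions)) .err("block_assignment must be named by region")
  if (is.null(region_mean_density))
    region_mean_density <- stats::setNames(rep(150, length(regions)), regions)
  structure(list(block_assignment = block_assignment,
                 within_block_r = within_block_r,
                 between_block_r = between_block_r,
                 region_mean_density = region_mean_density,
                 density_noise_sd = density_noise_sd),
            class = "planted_structure")
}

# resolve a per-group field that may be a plain vector or a list keyed by
# group label with a "default" fallback
.for_group <- function(field, group) {
  if (!is.list(field)) return(field)
  if (!is.null(field[[group]])) return(field[[group]])
  if (!is.null(field[["default"]])) return(field[["default"]])
  .err("no entry (and no 'default') for group '%s'", group)
}

#' Default planted structure: refining control networks, flat germ-free ones
#'
#' In male controls the dentate gyrus sits in a correlated block that shrinks
#' with age (6 -> 4 -> 2 regions), so DG node degree and network density fall
#' as the network refines; in male germ-free groups the DG block is fixed at
#' 3 regions, so connectivity starts lower and stays flat. Groups without an
#' explicit layout (females) use the germ-free layout as default.
#'
#' @param design a [cohort_design()]; its regions must include the default
#'   eight-region panel.
#' @return a `planted_structure`.
#' @export
default_planted_structure <- function(design = cohort_design()) {
  r <- design$region_labels
  blk <- function(...) {
    groups <- list(...)
    a <- stats::setNames(seq_along(r), r)  # singletons: own block
    for (i in seq_along(groups)) a[groups[[i]]] <- length(r) + i
    a
  }
  layouts <- list(
    control_4_male    = blk(c("DG", "CA1", "CA3", "SUB", "EC", "PRH"),
                            c("RSC", "BLA")),
    control_8_male    = blk(c("DG", "CA1", "CA3", "SUB"), c("EC", "PRH"),
                            c("RSC", "BLA")),
    control_12_male   = blk(c("DG", "CA1"), c("CA3", "SUB"), c("EC", "PRH"),
                            c("RSC", "BLA")),
    germ_free_4_male  = blk(c("DG", "CA1", "CA3"), c("EC", "PRH")),
    germ_free_8_male  = blk(c("DG", "CA1", "CA3"), c("EC", "PRH")),
    germ_free_12_male = blk(c("DG", "CA1", "CA3"), c("EC", "PRH")),
    default           = blk(c("DG", "CA1", "CA3"), c("EC", "PRH"))
  )
  planted_structure(block_assignment = layouts)
}

#' Build the planted correlation matrix for one group
#'
#' Entry (i, j) is `within_block_r` if regions i and j share a block,
#' `between_block_r` otherwise, with unit diagonal. The implied matrix must
#' be positive semi-definite; it is rejected otherwise with the offending
#' eigenvalue in the message.
#'
#' @param structure a [planted_structure()].
#' @param group group label (used to resolve per-group block assignments).
#' @return symmetric correlation matrix with region dimnames.
#' @examples
#' st <- planted_structure(c(A = 1, B = 1, C = 2), 0.9, 0.2)
#' build_group_correlation(st, "any")
#' @export
build_group_correlation <- function(structure, group) {
  stopifnot(inherits(structure, "planted_structure"))
  a <- .for_group(structure$block_assignment, group)
  if (is.null(names(a)) || anyNA(a))
    .err("block assignment for group '%s' must be a complete named vector", group)
  same <- outer(a, a, `==`)
  R <- ifelse(same, structure$within_block_r, structure$between_block_r)
  diag(R) <- 1
  dimnames(R) <- list(names(a), names(a))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9)
    .err("implied correlation matrix for group '%s' is not positive semi-definite (smallest eigenvalue %.3e)",
         group, min(ev))
  R
}
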