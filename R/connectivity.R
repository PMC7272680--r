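#' Two-tailed p-value for a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` referred
#' to a t distribution with `n - 2` degrees of freedom, two-tailed; `|r| = 1`
#' yields p = 0. Vectorized over `r` and `n`; `NA` correlations propagate.
#'
#' @param r Pearson correlation(s) in `[-1, 1]`.
#' @param n number of subjects per correlation, all >= 3.
#' @return two-tailed p-value(s) in `[0, 1]`.
#' @examples
#' correlation_pvalue(0, 10)        # 1
#' correlation_pvalue(0.8, 5)       # ~0.104: not significant despite r >= 0.8
#' @export
correlation_pvalue <- function(r, n) {
  stopifnot(is.numeric(r), is.numeric(n))
  if (any(n < 3)) .err("correlation p-value needs n >= 3 (got n = %s)",
                       min(n))
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) .err("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  p
}

#' Per-group pairwise region correlations
#'
#' Computes the Pearson correlation of every unordered region pair across
#' the subjects of one group, with the matching two-tailed p-values and
#' per-pair subject counts. Missing values are handled pairwise-complete;
#' pairs with fewer than 3 complete subjects or zero variance in either
#' region are undefined and carried as `NA` (never as 0), with a logged
#' warning.
#'
#' @param table a `region_activity` data.frame (metadata columns plus one
#'   numeric column per region).
#' @param group named list selecting the group, e.g.
#'   `list(treatment = "control", age = 4, sex = "male")`; entries are
#'   matched against the metadata columns. `NULL` uses all rows.
#' @return object of class `group_correlation`: list with `group` (label),
#'   `regions`, `r`, `p`, `n` matrices and `n_subjects`.
#' @export
pairwise_correlations <- function(table, group = NULL) {
  stopifnot(is.data.frame(table))
  miss <- setdiff(.meta_cols, names(table))
  if (length(miss)) .err("region table is missing column(s): %s",
                         paste(miss, collapse = ", "))
  rows <- rep(TRUE, nrow(table))
  if (!is.null(group)) {
    stopifnot(is.list(group), all(names(group) %in% .meta_cols))
    for (f in names(group)) rows <- rows & table[[f]] == group[[f]]
  }
  sub <- table[rows, , drop = FALSE]
  label <- if (is.null(group)) "all" else
    paste(unlist(group, use.names = FALSE), collapse = "_")
  if (nrow(sub) < 3L)
    .err("group '%s' has n = %d subjects; pairwise correlation needs >= 3",
         label, nrow(sub))
  regions <- setdiff(names(sub), .meta_cols)
  X <- as.matrix(sub[, regions, drop = FALSE])
  storage.mode(X) <- "double"

  # pairwise-complete n per pair
  obs <- !is.na(X)
  nmat <- crossprod(obs)
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  # zero-variance columns: cor() returns NA; make the reason explicit
  zv <- apply(X, 2L, function(v) stats::var(v, na.rm = TRUE) == 0 ||
                all(is.na(v)))
  if (any(zv))
    warning(sprintf("group '%s': zero variance in region(s) %s; their pairs are undefined",
                    label, paste(regions[zv], collapse = ", ")), call. = FALSE)
  r[zv, ] <- NA_real_
  r[, zv] <- NA_real_
  r[nmat < 3L] <- NA_real_
  diag(r) <- 1
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  ok <- upper.tri(r) & !is.na(r) & nmat >= 3L
  p[ok] <- correlation_pvalue(r[ok], nmat[ok])
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  structure(list(group = label, regions = regions, r = r, p = p,
                 n = nmat, n_subjects = nrow(sub)),
            class = "group_correlation")
}

#' @export
print.group_correlation <- function(x, ...) {
  cat(sprintf("group_correlation '%s': %d regions, %d subjects, %d undefined pair(s)\n",
              x$group, length(x$regions), x$n_subjects,
              sum(is.na(x$r[upper.tri(x$r)]))))
  invisible(x)
}

#' Dual-threshold edge filter policy
#'
#' The defaults reproduce the connectivity filter this package implements:
#' a correlation becomes an edge only if it is statistically significant at
#' the 95% confidence level (two-tailed p < 0.05) AND its Pearson r is at
#' least 0.8. `sign_mode` chooses between the literal positive-only reading
#' (`r >= r_min`) and an absolute-value variant (`|r| >= r_min`). An
#' optional Benjamini-Hochberg correction across region pairs is available
#' but off by default.
#'
#' @param alpha_level significance level in (0, 1); edges require p strictly
#'   below it.
#' @param r_min minimum correlation magnitude; compared with `>=`.
#' @param sign_mode `"positive_only"` (default) or `"absolute"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return object of class `threshold_policy`.
#' @export
threshold_policy <- function(alpha_level = 0.05, r_min = 0.8,
                             sign_mode = c("positive_only", "absolute"),
                             p_adjust = c("none", "BH")) {
  stopifnot(alpha_level > 0, alpha_level < 1, r_min >= 0, r_min <= 1)
  structure(list(alpha_level = alpha_level, r_min = r_min,
                 sign_mode = match.arg(sign_mode),
                 p_adjust = match.arg(p_adjust)),
            class = "threshold_policy")
}

#' Binarize a correlation result into an adjacency matrix
#'
#' `a_ij = 1` iff the pair's p-value is below `alpha_level` and its
#' correlation passes `r_min` under the policy's sign mode; everything
#' else — including undefined pairs — is 0 (undefined pairs are noted).
#' The result is symmetric with zero diagonal.
#'
#' @param result a `group_correlation`.
#' @param policy a [threshold_policy()].
#' @return a `binary_adjacency`: symmetric 0/1 integer matrix with region
#'   dimnames and zero diagonal; attribute `n_undefined` counts pairs that
#'   were undefined.
#' @export
threshold_adjacency <- function(result, policy = threshold_policy()) {
  stopifnot(inherits(result, "group_correlation"),
            inherits(policy, "threshold_policy"))
  r <- result$r; p <- result$p
  if (policy$p_adjust == "BH") {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  rpass <- if (policy$sign_mode == "absolute") abs(r) >= policy$r_min
           else r >= policy$r_min
  a <- (p < policy$alpha_level) & rpass
  a[is.na(a)] <- FALSE
  n_undef <- sum(is.na(r[upper.tri(r)]))
  if (n_undef > 0L)
    message(sprintf("group '%s': %d undefined pair(s) set to 0 in the adjacency",
                    result$group, n_undef))
  a <- a | t(a)          # symmetry guard (r, p are symmetric already)
  diag(a) <- FALSE
  adj <- matrix(as.integer(a), nrow(a), dimnames = dimnames(r))
  attr(adj, "n_undefined") <- n_undef
  class(adj) <- c("binary_adjacency", class(adj))
  adj
}
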