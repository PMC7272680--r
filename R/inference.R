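#' Unbalanced two-way factorial ANOVA (Type-III sums of squares)
#'
#' Fits `y ~ A * B` with sum-to-zero contrasts and computes marginal
#' (Type-III) sums of squares for each effect by the residual-sum-of-squares
#' difference between the full model and the model with that effect's
#' columns removed, all other columns retained. F ratios use the residual
#' mean square. Type III with sum-to-zero coding matches the conventional
#' default of mainstream commercial ANOVA software for unequal cell sizes;
#' in a balanced design it coincides with the classical sequential
#' decomposition and the effect sums of squares partition the total.
#'
#' @param y numeric response (densities or percent-change values).
#' @param a,b factors (or vectors coerced to factors), >= 2 levels each,
#'   every cell of the cross non-empty.
#' @param factor_names length-2 character, labels for the two effects.
#' @return object of class `anova_result`: data.frame with rows for the two
#'   main effects, the interaction and residuals; columns `effect`, `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p`. Attribute `ss_total` carries the total
#'   (corrected) sum of squares.
#' @examples
#' set.seed(1)
#' d <- expand.grid(g = c("ctrl", "gf"), age = c(4, 8, 12))
#' d <- d[rep(1:6, each = 5), ]
#' y <- rnorm(30, mean = ifelse(d$g == "ctrl", 12 - d$age/2, 10))
#' two_way_anova(y, d$g, d$age, c("group", "age"))
#' @export
two_way_anova <- function(y, a, b, factor_names = c("A", "B")) {
  stopifnot(is.numeric(y), length(factor_names) == 2L)
  a <- factor(a); b <- factor(b)
  if (length(y) != length(a) || length(y) != length(b))
    .err("y, a and b must have equal length")
  if (anyNA(y) || anyNA(a) || anyNA(b)) .err("missing values are not supported")
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    .err("each factor needs >= 2 levels")
  tab <- table(a, b)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    .err("empty cell(s): %s",
         paste(sprintf("(%s, %s)", rownames(tab)[empty[, 1L]],
                       colnames(tab)[empty[, 2L]]), collapse = ", "))
  }
  contrasts(a) <- stats::contr.sum(nlevels(a))
  contrasts(b) <- stats::contr.sum(nlevels(b))
  X <- stats::model.matrix(~ a * b)
  asg <- attr(X, "assign")   # 0 = intercept, 1 = a, 2 = b, 3 = a:b
  rss <- function(cols) {
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(seq_len(ncol(X)))
  df_err <- length(y) - ncol(X)
  if (df_err < 1L) .err("residual degrees of freedom < 1")
  ms_err <- rss_full / df_err
  eff <- lapply(1:3, function(k) {
    ss <- rss(which(asg != k)) - rss_full
    df <- sum(asg == k)
    c(ss = max(ss, 0), df = df)
  })
  ss <- vapply(eff, `[[`, 0, "ss")
  df <- vapply(eff, `[[`, 0, "df")
  res <- data.frame(
    effect = c(factor_names, paste(factor_names, collapse = ":"), "Residuals"),
    df = c(df, df_err),
    sum_sq = c(ss, rss_full),
    stringsAsFactors = FALSE)
  res$mean_sq <- res$sum_sq / res$df
  res$F <- c(ss / df / ms_err, NA)
  res$p <- c(stats::pf(res$F[1:3], df, df_err, lower.tail = FALSE), NA)
  attr(res, "ss_total") <- sum((y - mean(y))^2)
  attr(res, "ms_error") <- ms_err
  attr(res, "df_error") <- df_err
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Format an ANOVA effect in F(df1, df2) convention
#'
#' @param result an `anova_result`.
#' @param effect effect label as in the result's `effect` column.
#' @return string like `"F(2,51) = 44.97, p < 0.0001"`.
#' @export
format_effect <- function(result, effect) {
  stopifnot(inherits(result, "anova_result"))
  i <- match(effect, result$effect)
  if (is.na(i) || effect == "Residuals") .err("unknown effect '%s'", effect)
  df_err <- attr(result, "df_error")
  p <- result$p[i]
  ptxt <- if (p < 1e-4) "p < 0.0001" else sprintf("p = %.4g", p)
  sprintf("F(%d,%d) = %.2f, %s", result$df[i], df_err, result$F[i], ptxt)
}

#' Student-Newman-Keuls stepwise post hoc comparisons
#'
#' Sorts the cell means, computes for each pair the studentized-range
#' statistic `q = |m_i - m_j| / sqrt(MS_error / n_h)` with `n_h` the
#' harmonic mean of the pair's group sizes (Tukey-Kramer-style adaptation
#' for unequal n), and refers it to the studentized-range distribution with
#' the pair's stretch `k` (number of means spanned in the ordering) and the
#' error degrees of freedom. Testing proceeds stepwise from the widest
#' stretch inward: once a span is non-significant, every comparison nested
#' inside it is sealed non-significant regardless of its own q. Ties among
#' means keep their input order (no effect on q).
#'
#' @param cell_means named numeric vector of group means.
#' @param cell_ns group sizes, same length/order as `cell_means`.
#' @param ms_error residual mean square from the ANOVA, > 0.
#' @param df_error residual degrees of freedom, >= 1.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `posthoc_result`: data.frame with one row per
#'   unordered pair: `group_i`, `group_j`, `mean_diff`, `k`, `q`, `p`,
#'   `significant`, `sealed`.
#' @export
snk_posthoc <- function(cell_means, cell_ns, ms_error, df_error,
                        alpha = 0.05) {
  stopifnot(is.numeric(cell_means), length(cell_means) >= 2L,
            length(cell_ns) == length(cell_means), all(cell_ns >= 1))
  if (!is.numeric(ms_error) || length(ms_error) != 1L || ms_error <= 0)
    .err("ms_error must be a positive scalar")
  if (!is.numeric(df_error) || df_error < 1) .err("df_error must be >= 1")
  if (is.null(names(cell_means)))
    names(cell_means) <- paste0("group", seq_along(cell_means))
  ord <- order(cell_means)  # stable: ties keep original order
  m <- cell_means[ord]; n <- cell_ns[ord]
  K <- length(m)
  rows <- list()
  sealed <- matrix(FALSE, K, K)
  for (k in K:2) {
    for (i in seq_len(K - k + 1L)) {
      j <- i + k - 1L
      nh <- 2 / (1 / n[i] + 1 / n[j])
      q <- (m[j] - m[i]) / sqrt(ms_error / nh)
      p <- stats::ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
      is_sealed <- sealed[i, j]
      sig <- !is_sealed && p < alpha
      if (!sig) {
        # seal every nested span
        for (ii in i:j) for (jj in ii:j) sealed[ii, jj] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_i = names(m)[i], group_j = names(m)[j],
        mean_diff = m[j] - m[i], k = k, q = q, p = p,
        significant = sig, sealed = is_sealed, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  class(res) <- c("posthoc_result", "data.frame")
  res
}

#' Correlate focal-region node degree with group mean neurogenesis
#'
#' Because network properties are computed per group rather than per
#' animal, the link between connectivity and neurogenesis is assessed at
#' the group level: Pearson correlation between each group's focal-region
#' (dentate gyrus) node degree and its mean doublecortin density, with the
#' two-tailed p from the t transform and the `r(df)` reporting convention
#' where `df = points - 2` (six groups report as `r(4)`).
#'
#' @param degrees named numeric vector: focal node degree per group.
#' @param dcx_means named numeric vector: mean DCX density per group; names
#'   must match `degrees` as a set.
#' @return object of class `degree_correlation`: list with `points`
#'   (data.frame), `r`, `df`, `p`, `r_squared`.
#' @export
degree_neurogenesis_correlation <- function(degrees, dcx_means) {
  if (is.null(names(degrees)) || is.null(names(dcx_means)))
    .err("both inputs must be named by group")
  if (!setequal(names(degrees), names(dcx_means)))
    .err("group sets differ: %s vs %s",
         paste(names(degrees), collapse = ","),
         paste(names(dcx_means), collapse = ","))
  dcx_means <- dcx_means[names(degrees)]
  npts <- length(degrees)
  if (npts < 3L) .err("need >= 3 group points (got %d)", npts)
  r <- stats::cor(degrees, dcx_means)
  structure(list(
    points = data.frame(group = names(degrees), focal_degree = degrees,
                        dcx_mean = dcx_means, row.names = NULL,
                        stringsAsFactors = FALSE),
    r = r, df = npts - 2L, p = correlation_pvalue(r, npts),
    r_squared = r^2), class = "degree_correlation")
}

#' @export
print.degree_correlation <- function(x, ...) {
  cat(sprintf("focal degree vs neurogenesis: r(%d) = %.2f, p = %.3g, r^2 = %.2f\n",
              x$df, x$r, x$p, x$r_squared))
  invisible(x)
}
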