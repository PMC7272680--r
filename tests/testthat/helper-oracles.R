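# Independent oracles used across the suite. Each reimplements its target
# from first principles (textbook formulas, numerical integration, direct
# enumeration) and never calls the package code path it checks.

# textbook Pearson correlation: covariance over the product of SDs
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# two-tailed p for a correlation via numerical integration of the t density
# (the density is written out; stats::pt is never used here)
t_tail_p_oracle <- function(r, n) {
  if (abs(r) >= 1) return(0)
  nu <- n - 2
  tstat <- abs(r) * sqrt(nu / (1 - r^2))
  dens <- function(t) {
    exp(lgamma((nu + 1) / 2) - lgamma(nu / 2)) / sqrt(nu * pi) *
      (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  2 * stats::integrate(dens, tstat, Inf, rel.tol = 1e-10)$value
}

# studentized-range CDF by direct double numerical integration:
# P(Q <= q) = E_s[ k * Int phi(z) (Phi(z) - Phi(z - q s))^(k-1) dz ]
# where s = sqrt(chisq_df / df). Never calls ptukey/qtukey.
ptukey_oracle <- function(q, k, df) {
  range_cdf <- function(w) {
    f <- function(z) k * stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  }
  s_dens <- function(s) {
    exp((df / 2) * log(df) - (df / 2 - 1) * log(2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  out <- stats::integrate(function(s) {
    vapply(s, function(si) s_dens(si) * range_cdf(q * si), 0)
  }, 0, Inf, rel.tol = 1e-7)
  out$value
}

qtukey_oracle <- function(p, k, df) {
  stats::uniroot(function(q) ptukey_oracle(q, k, df) - p,
                 interval = c(0.2, 30), tol = 1e-7)$root
}

# random symmetric 0/1 adjacency with zero diagonal
rand_adjacency <- function(n, p = 0.3, labels = NULL) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  dimnames(a) <- list(labels, labels)
  a
}

# random region-activity table for one group
rand_region_table <- function(n_subj, regions, treatment = "control",
                              age = 4, sex = "male") {
  X <- matrix(stats::rnorm(n_subj * length(regions), 150, 40), n_subj)
  colnames(X) <- regions
  data.frame(subject_id = sprintf("s%02d", seq_len(n_subj)),
             treatment = treatment, age = age, sex = sex, X,
             stringsAsFactors = FALSE, check.names = FALSE)
}

# brute-force connectivity: per-pair Pearson + t-transform p + dual filter,
# computed pair by pair with none of the package's connectivity code
brute_connectivity <- function(tab, regions, alpha = 0.05, r_min = 0.8) {
  X <- as.matrix(tab[, regions])
  K <- length(regions)
  r <- diag(1, K); p <- matrix(NA_real_, K, K); a <- matrix(0L, K, K)
  dimnames(r) <- dimnames(p) <- dimnames(a) <- list(regions, regions)
  n <- nrow(X)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    rij <- pearson_brute(X[, i], X[, j])
    tij <- abs(rij) * sqrt((n - 2) / (1 - rij^2))
    pij <- 2 * stats::pt(tij, df = n - 2, lower.tail = FALSE)
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- pij
    if (pij < alpha && rij >= r_min) a[i, j] <- a[j, i] <- 1L
  }
  list(r = r, p = p, adjacency = a)
}

# balanced two-way cell-means ANOVA decomposition (textbook formulas)
anova_brute_balanced <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  na <- tapply(y, a, length); nb <- tapply(y, b, length)
  nab <- tapply(y, interaction(a, b), length)
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  cell_a <- ma[sub("\\..*", "", names(mab))]
  cell_b <- mb[sub(".*\\.", "", names(mab))]
  ss_ab <- sum(nab * (mab - cell_a - cell_b + gm)^2)
  ss_tot <- sum((y - gm)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
       ss_err = ss_tot - ss_a - ss_b - ss_ab, ss_total = ss_tot)
}

# small marker-count table builder
make_counts <- function(subject_id, counts, areas, marker = "DCX",
                        treatment = "control", age = 4, sex = "male") {
  data.frame(subject_id = subject_id, treatment = treatment, age = age,
             sex = sex, marker = marker, section = seq_along(counts),
             count = counts, area_mm2 = areas, stringsAsFactors = FALSE)
}
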