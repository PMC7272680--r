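test_that("cohort_design enforces its invariants", {
  expect_error(cohort_design(n_per_group = 2), "n >= 3")
  expect_warning(cohort_design(n_per_group = 4), "n < 5")
  expect_error(cohort_design(region_labels = c("DG", "DG", "CA1")), "unique")
  expect_error(cohort_design(region_labels = c("A", "B", "C"),
                             focal_region = "DG"), "focal region")
  expect_error(cohort_design(region_labels = c("DG", "CA1")), "at least 3")
  d <- cohort_design(n_per_group = 6, seed = 3)
  cells <- group_cells(d)
  expect_equal(nrow(cells), 12L)  # 2 treatments x 3 ages x 2 sexes
  expect_true(all(cells$n == 6L))
})

test_that("build_group_correlation matches closed forms and a constructed oracle", {
  # independence: within_r = 0, every region its own block -> identity
  st0 <- planted_structure(c(A = 1, B = 2, C = 3), within_block_r = 0,
                           between_block_r = 0)
  expect_equal(build_group_correlation(st0, "g"),
               diag(3) |> `dimnames<-`(list(c("A", "B", "C"), c("A", "B", "C"))))

  # equicorrelation: one block at 0.9 -> all off-diagonals 0.9,
  # smallest eigenvalue 1 - 0.9 = 0.1
  st1 <- planted_structure(c(A = 1, B = 1, C = 1, D = 1),
                           within_block_r = 0.9, between_block_r = 0)
  R1 <- build_group_correlation(st1, "g")
  expect_true(all(R1[upper.tri(R1)] == 0.9))
  expect_equal(min(eigen(R1, symmetric = TRUE)$values), 0.1)

  # 2 blocks of 3 at 0.9 / 0.2: element-by-element constructed oracle
  assign6 <- c(r1 = 1, r2 = 1, r3 = 1, r4 = 2, r5 = 2, r6 = 2)
  st2 <- planted_structure(assign6, within_block_r = 0.9,
                           between_block_r = 0.2)
  R2 <- build_group_correlation(st2, "g")
  oracle <- matrix(NA_real_, 6, 6, dimnames = list(names(assign6),
                                                   names(assign6)))
  for (i in 1:6) for (j in 1:6)
    oracle[i, j] <- if (i == j) 1 else
      if (assign6[i] == assign6[j]) 0.9 else 0.2
  expect_identical(R2, oracle)
})

test_that("non-PSD implied matrices are rejected with the eigenvalue", {
  st <- planted_structure(c(A = 1, B = 1, C = 2, D = 2),
                          within_block_r = 0.9, between_block_r = 0.2)
  st$within_block_r <- 0; st$between_block_r <- 0.9  # bypass constructor guard
  expect_error(build_group_correlation(st, "g"),
               "not positive semi-definite.*eigenvalue")
  expect_error(planted_structure(c(A = 1, B = 2), within_block_r = 0.2,
                                 between_block_r = 0.9), "must not exceed")
})

test_that("sample_region_densities: degenerate noise, determinism, group-stream independence", {
  d <- cohort_design(treatments = "control", ages = 4, sexes = "male",
                     n_per_group = 5, region_labels = c("DG", "CA1", "CA3"),
                     seed = 11)
  mu <- c(DG = 200, CA1 = 150, CA3 = 100)
  st <- planted_structure(c(DG = 1, CA1 = 1, CA3 = 2),
                          region_mean_density = mu,
                          density_noise_sd = 1e-9)
  tab <- sample_region_densities(d, st)
  for (r in names(mu)) expect_equal(tab[[r]], rep(mu[[r]], 5), tolerance = 1e-6)

  st$density_noise_sd <- 40
  t1 <- sample_region_densities(d, st)
  t2 <- sample_region_densities(d, st)
  expect_identical(t1, t2)

  # adding an age group must not reshuffle the existing group's subjects
  d2 <- cohort_design(treatments = "control", ages = c(4, 8), sexes = "male",
                      n_per_group = 5, region_labels = c("DG", "CA1", "CA3"),
                      seed = 11)
  t3 <- sample_region_densities(d2, st)
  expect_equal(t1, t3[t3$age == 4, ], ignore_attr = TRUE)
})

test_that("empirical correlations recover the planted matrix (law of large numbers)", {
  regions <- paste0("R", 1:4)
  d <- cohort_design(treatments = "t", ages = 4, sexes = "m",
                     n_per_group = 5000, region_labels = regions,
                     focal_region = "R1", seed = 5)
  st <- planted_structure(stats::setNames(rep(1L, 4), regions),
                          within_block_r = 0.9, between_block_r = 0,
                          region_mean_density = stats::setNames(rep(500, 4),
                                                                regions),
                          density_noise_sd = 40)
  tab <- sample_region_densities(d, st)
  emp <- stats::cor(as.matrix(tab[, regions]))
  expect_true(all(abs(emp[upper.tri(emp)] - 0.9) < 0.02))

  # Frobenius distance to the planted matrix shrinks with n
  dist_at_n <- function(n, seed) {
    dn <- cohort_design(treatments = "t", ages = 4, sexes = "m",
                        n_per_group = n, region_labels = regions,
                        focal_region = "R1", seed = seed)
    tn <- sample_region_densities(dn, st)
    sqrt(sum((stats::cor(as.matrix(tn[, regions])) -
                build_group_correlation(st, "t_4_m"))^2))
  }
  d_small <- mean(vapply(1:5, function(s) dist_at_n(10, s), 0))
  d_large <- mean(vapply(1:5, function(s) dist_at_n(320, s), 0))
  expect_lt(d_large, d_small)
})

test_that("marker counts respect section range, integrality and positivity", {
  d <- suppressWarnings(cohort_design(n_per_group = 4, seed = 2))
  mk <- sample_marker_counts(d, neurogenesis_profile())
  nsec <- tapply(mk$section, interaction(mk$subject_id, mk$marker, drop = TRUE),
                 max)
  expect_true(all(nsec >= 7 & nsec <= 10))   # ~7-10 sections per brain
  expect_true(all(mk$count >= 0))
  expect_true(all(mk$count == round(mk$count)))
  expect_true(all(mk$area_mm2 > 0))
  expect_identical(mk, sample_marker_counts(d, neurogenesis_profile()))
})

test_that("noiseless limit reproduces the planted monotone age decline", {
  d <- suppressWarnings(
    cohort_design(treatments = "control", sexes = "male", n_per_group = 3,
                  seed = 1))
  pr <- neurogenesis_profile(dispersion = 0)
  dens <- compute_density(sample_marker_counts(d, pr))
  for (m in c("DCX", "BrdU")) {
    gm <- tapply(dens$density[dens$marker == m], dens$age[dens$marker == m],
                 mean)
    gm <- gm[order(as.numeric(names(gm)))]
    expect_true(all(diff(gm) < 0))
    planted <- vapply(as.numeric(names(gm)), function(a)
      expected_density(pr, m, "control", a, "male"), 0)
    expect_equal(as.vector(gm), planted, tolerance = 0.02)
  }
})

test_that("profile validation: control age factors must strictly decrease", {
  expect_error(neurogenesis_profile(
    age_decline_fraction = c(`4` = 1, `8` = 1, `12` = 0.3)),
    "strictly decreasing")
  pr <- neurogenesis_profile()
  # male germ-free deficit at 4 wk, female germ-free elevation at 8 wk
  expect_lt(expected_density(pr, "DCX", "germ_free", 4, "male"),
            expected_density(pr, "DCX", "control", 4, "male"))
  expect_gt(expected_density(pr, "DCX", "germ_free", 8, "female"),
            expected_density(pr, "DCX", "control", 8, "female"))
})

test_that("simulated male DCX recovers the age effect with power >= 0.8", {
  d <- cohort_design(treatments = c("control", "germ_free"),
                     sexes = "male", n_per_group = 10, seed = 0)
  pr <- neurogenesis_profile(baseline_density = c(DCX = 2400))
  hits <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    d$seed <- i
    dens <- compute_density(sample_marker_counts(d, pr))
    an <- two_way_anova(dens$density, dens$treatment, dens$age,
                        c("treatment", "age"))
    if (an$p[an$effect == "age"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})

test_that("write_cohort emits replayable delimited text plus metadata", {
  dir <- withr::local_tempdir()
  d <- cohort_design(treatments = "control", ages = 4, sexes = "male",
                     n_per_group = 5, region_labels = c("DG", "CA1", "CA3"),
                     seed = 9)
  st <- planted_structure(c(DG = 1, CA1 = 1, CA3 = 2))
  pr <- neurogenesis_profile()
  paths <- write_cohort(dir, sample_region_densities(d, st),
                        sample_marker_counts(d, pr), d, st, pr)
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(file.path(dir, "cohort_meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 9)
  back <- utils::read.csv(file.path(dir, "region_activity.csv"),
                          check.names = FALSE)
  expect_equal(nrow(back), 5L)
  expect_true(all(c("DG", "CA1", "CA3") %in% names(back)))
})
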