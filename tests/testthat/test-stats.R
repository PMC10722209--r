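test_that("summary statistics follow the stated conventions", {
  s <- summarize_thickness(c(3, 4, 5))
  expect_equal(s$mean_mm, 4)
  expect_equal(s$median_mm, 4)
  expect_equal(s$q25_mm, 3.5)             # type-7 linear interpolation
  expect_equal(s$q75_mm, 4.5)
  expect_equal(s$std_mm, sqrt(2 / 3))     # population STD
  sc <- summarize_thickness(rep(2.5, 10))
  expect_equal(unlist(sc[c("mean_mm", "median_mm", "q25_mm", "q75_mm")]),
               rep(2.5, 4), ignore_attr = TRUE)
  expect_equal(sc$std_mm, 0)
  set.seed(2)
  x <- runif(1e4, 2, 6)
  su <- summarize_thickness(x)
  expect_lt(abs(su$mean_mm - 4), 3 * (4 / sqrt(12)) / 100)
  expect_lt(abs(su$q25_mm - 3), 0.05)
  expect_error(summarize_thickness(numeric(0)), "empty")
})

test_that("summaries are permutation-invariant and scale-equivariant", {
  set.seed(3)
  x <- rnorm(500, 4, 1.5)
  a <- summarize_thickness(x)
  b <- summarize_thickness(sample(x))
  expect_equal(a, b)
  cs <- summarize_thickness(2.5 * x)
  for (f in c("mean_mm", "std_mm", "median_mm", "q25_mm", "q75_mm"))
    expect_equal(cs[[f]], 2.5 * a[[f]])
})

test_that("fraction_above uses a strict threshold on the masked voxels", {
  expect_equal(fraction_above(c(1, 2, 3), 5), 0)
  expect_equal(fraction_above(c(1, 2, 3), 0.5), 100)
  expect_equal(fraction_above(c(1, 2, 3, 4), 2), 50)  # strict: 3 and 4 only
  ph <- fx_ridged()
  th <- fx_ridged_pde()
  truth_frac <- 100 * mean(ph$truth_thickness$data[
    is.finite(ph$truth_thickness$data)] > 7.2)
  expect_lt(abs(fraction_above(th, 7.2) - truth_frac), 3)
})

test_that("group comparison reproduces reference t- and F-tests", {
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(sample(5:60, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    cg <- compare_groups(a, b)
    tt <- t.test(a, b)
    vt <- var.test(a, b)
    expect_equal(cg$t_statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(cg$t_pvalue, tt$p.value, tolerance = 1e-10)
    expect_equal(cg$t_df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(cg$f_pvalue, vt$p.value, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1, F = 1
  x <- rnorm(100)
  cg <- compare_groups(x, x)
  expect_equal(cg$t_statistic, 0)
  expect_equal(cg$t_pvalue, 1)
  expect_equal(cg$f_statistic, 1)
  # degenerate zero-variance group reported as undefined F
  cg0 <- compare_groups(rep(1, 5), rnorm(5))
  expect_true(is.na(cg0$f_statistic))
  expect_error(compare_groups(1, rnorm(5)), ">= 2")
  # pooled-variance option matches the classical Student test
  a <- rnorm(20); b <- rnorm(25, 0.5)
  cg2 <- compare_groups(a, b, var_equal = TRUE)
  tt2 <- t.test(a, b, var.equal = TRUE)
  expect_equal(cg2$t_statistic, unname(tt2$statistic), tolerance = 1e-10)
  expect_equal(cg2$t_pvalue, tt2$p.value, tolerance = 1e-10)
})

test_that("volume-weighted pooling obeys its closed forms and identities", {
  r <- pooled_cohort_summary(5, 2, 30)
  expect_equal(r$mean_mm, 5); expect_equal(r$std_mm, 2)
  r2 <- pooled_cohort_summary(c(3, 5), c(0, 0), c(1, 1))
  expect_equal(r2$mean_mm, 4); expect_equal(r2$std_mm, 1)
  # equal weights + equal n equals voxel-pooled statistics exactly
  set.seed(6)
  g1 <- rnorm(400, 4, 1); g2 <- rnorm(400, 5, 2)
  pool <- c(g1, g2)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  r3 <- pooled_cohort_summary(c(mean(g1), mean(g2)), c(psd(g1), psd(g2)), c(1, 1))
  expect_equal(r3$mean_mm, mean(pool), tolerance = 1e-12)
  expect_equal(r3$std_mm, psd(pool), tolerance = 1e-12)
  expect_error(pooled_cohort_summary(c(1, 2), 1, c(1, 1)), "equal length")
  expect_error(pooled_cohort_summary(1, 1, -1), "positive")
})

test_that("the bundled cohort table pools to the published chamber means", {
  tab <- human_awt_cohort()
  expect_equal(nrow(tab), 14)
  ra <- tab[tab$atrium == "RA", ]
  pooled <- pooled_cohort_summary(ra$mean_mm, ra$std_mm, ra$tissue_cm3)
  expect_equal(round(pooled$mean_mm, 1), 4.8)
  expect_equal(sum(ra$driver), 4)                  # drivers in four hearts
  expect_equal(sum(tab$atrium == "LA" & tab$driver), 3)
})

test_that("driver-region subgroup report mirrors the ridge construction", {
  ph <- fx_ridged()
  th <- fx_ridged_pde()
  dims <- dim(ph$tissue$data)
  # region patch centred on the ridge equator
  eq <- which(ph$tissue$data == 1L & ph$transition$data == 0L &
                is.finite(ph$truth_thickness$data) &
                ph$truth_thickness$data > 7, arr.ind = TRUE)
  ctr <- eq[which.min(abs(eq[, 3] - dims[3] / 2)), ]
  region <- make_region_mask(ph, ctr, 12)
  hearts <- list(
    list(id = "P1", W = th, mask = ph$tissue, driver = TRUE, region = region),
    list(id = "P2", W = th, mask = ph$tissue, driver = FALSE))
  rep <- region_subgroup_report(hearts, subsample = 7L)
  expect_equal(nrow(rep$summaries), 2)
  rc <- rep$region_comparisons[["P1"]]
  expect_gt(rc$group_a$mean, rc$group_b$mean)      # ridge region thicker
  expect_gt(rc$f_statistic, 1)
  # identical phantom "hearts", one flagged driver: between-group p ~ 1
  expect_gt(rep$driver_comparison$t_pvalue, 0.9)
  # region covering the whole chamber leaves no rest group
  full <- list(list(id = "F", W = th, mask = ph$tissue, driver = TRUE,
                    region = ph$tissue))
  expect_error(region_subgroup_report(full), "whole chamber")
  out <- tempfile()
  write_cohort_report(rep, out)
  expect_true(file.exists(file.path(out, "summaries.csv")))
  expect_true(file.exists(file.path(out, "comparisons.json")))
})
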