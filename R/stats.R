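#' Summary statistics of a wall-thickness field
#'
#' Mean, population standard deviation (the voxel set is the whole
#' population of the map), median and the 25th/75th percentiles (type-7
#' linear interpolation) of the thickness values over a mask, plus voxel
#' counts and tissue/cavity volumes.
#'
#' @param thickness an `awt_thickness`, a thickness `awt_volume`, or a bare
#'   numeric vector of thickness values.
#' @param mask optional binary `awt_volume` restricting the voxels; default
#'   is the finite support of the field.
#' @param cavity_volume_cm3 optional cavity volume (from
#'   [label_boundaries()] diagnostics) carried into the row.
#' @return A one-row `data.frame` with columns `n_voxels`, `mean_mm`,
#'   `std_mm`, `median_mm`, `q25_mm`, `q75_mm`, `tissue_volume_cm3`,
#'   `cavity_volume_cm3`.
#' @export
summarize_thickness <- function(thickness, mask = NULL, cavity_volume_cm3 = NA_real_) {
  if (is.numeric(thickness) && is.null(dim(thickness))) {
    w <- thickness[is.finite(thickness)]
    vvol <- NA_real_
  } else {
    Wvol <- if (inherits(thickness, "awt_thickness")) thickness$W else thickness
    W <- Wvol$data
    keep <- if (is.null(mask)) is.finite(W) else vol_mask(mask) & is.finite(W)
    w <- W[keep]
    vvol <- prod(Wvol$spacing)
  }
  if (length(w) == 0L) stop("empty mask: no thickness values to summarize")
  q <- unname(quantile(w, c(0.25, 0.5, 0.75), type = 7))
  data.frame(n_voxels = length(w),
             mean_mm = mean(w),
             std_mm = sqrt(mean((w - mean(w))^2)),
             median_mm = q[2], q25_mm = q[1], q75_mm = q[3],
             tissue_volume_cm3 = length(w) * vvol / 1000,
             cavity_volume_cm3 = cavity_volume_cm3)
}

#' Percentage of wall voxels above a thickness threshold
#'
#' `100 * #(W > threshold) / #mask` with a strict inequality.
#'
#' @param thickness as in [summarize_thickness()].
#' @param threshold_mm threshold in mm.
#' @param mask optional binary `awt_volume`.
#' @return percentage in `[0, 100]`.
#' @export
fraction_above <- function(thickness, threshold_mm, mask = NULL) {
  if (is.numeric(thickness) && is.null(dim(thickness))) {
    w <- thickness[is.finite(thickness)]
  } else {
    Wvol <- if (inherits(thickness, "awt_thickness")) thickness$W else thickness
    W <- Wvol$data
    keep <- if (is.null(mask)) is.finite(W) else vol_mask(mask) & is.finite(W)
    w <- W[keep]
  }
  if (length(w) == 0L) stop("empty mask")
  100 * sum(w > threshold_mm) / length(w)
}

#' Two-sample comparison of thickness distributions (t- and F-test)
#'
#' Welch's two-sample two-tailed t-test for the difference in means
#' (pooled-variance Student's t available via `var_equal = TRUE`), and a
#' two-tailed variance-ratio F-test with the larger sample variance in the
#' numerator. Sample (n-1) variances are used for the test statistics.
#'
#' @param a,b numeric vectors of thickness values (each of length >= 2).
#' @param alpha significance level for the `significant` flags.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return An `awt_comparison` object: group summaries, `t_statistic`,
#'   `t_df`, `t_pvalue`, `f_statistic`, `f_df`, `f_pvalue`, and logical
#'   `t_significant` / `f_significant`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    tdf <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    tdf <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tp <- 2 * pt(-abs(tstat), tdf)
  if (va == 0 && vb == 0) {
    fstat <- if (isTRUE(all.equal(ma, mb))) 1 else NA_real_
    fdf <- c(NA_real_, NA_real_); fp <- NA_real_
    if (identical(fstat, 1)) fp <- 1
  } else if (va == 0 || vb == 0) {
    fstat <- NA_real_; fdf <- c(NA_real_, NA_real_); fp <- NA_real_
  } else {
    if (va >= vb) { fstat <- va / vb; fdf <- c(na - 1, nb - 1) }
    else { fstat <- vb / va; fdf <- c(nb - 1, na - 1) }
    fp <- min(1, 2 * pf(fstat, fdf[1], fdf[2], lower.tail = FALSE))
  }
  structure(list(
    group_a = data.frame(n = na, mean = ma, sd = sqrt(va)),
    group_b = data.frame(n = nb, mean = mb, sd = sqrt(vb)),
    t_statistic = tstat, t_df = tdf, t_pvalue = tp,
    f_statistic = fstat, f_df = fdf, f_pvalue = fp,
    alpha = alpha,
    t_significant = is.finite(tp) && tp < alpha,
    f_significant = is.finite(fp) && fp < alpha,
    var_equal = var_equal), class = "awt_comparison")
}

#' @export
print.awt_comparison <- function(x, ...) {
  cat(sprintf("<awt_comparison> %.2f +/- %.2f (n=%d) vs %.2f +/- %.2f (n=%d)\n",
              x$group_a$mean, x$group_a$sd, x$group_a$n,
              x$group_b$mean, x$group_b$sd, x$group_b$n))
  cat(sprintf("  t = %.3f (df %.1f), p = %.3g%s\n", x$t_statistic, x$t_df,
              x$t_pvalue, if (x$t_significant) " *" else ""))
  if (is.finite(x$f_statistic))
    cat(sprintf("  F = %.3f (df %g, %g), p = %.3g%s\n", x$f_statistic,
                x$f_df[1], x$f_df[2], x$f_pvalue,
                if (x$f_significant) " *" else ""))
  else cat("  F undefined (zero-variance group)\n")
  invisible(x)
}

#' Volume-weighted pooling of per-heart summaries
#'
#' Pooled mean `sum(w_i m_i)/sum(w_i)` and pooled standard deviation from
#' `sum(w_i (s_i^2 + m_i^2))/sum(w_i) - mean^2`, the mixture moments of the
#' per-heart distributions weighted by tissue volume. With equal weights and
#' equal per-row voxel counts this reproduces the voxel-pooled statistics
#' exactly.
#'
#' @param means,stds per-row mean and standard deviation (mm).
#' @param weights positive pooling weights (tissue volumes).
#' @return `data.frame` with `mean_mm`, `std_mm`, `weight_total`.
#' @export
pooled_cohort_summary <- function(means, stds, weights) {
  if (length(means) != length(stds) || length(means) != length(weights))
    stop("means, stds and weights must have equal length")
  if (length(means) < 1L) stop("at least one row required")
  if (any(weights <= 0)) stop("weights must be positive")
  pm <- sum(weights * means) / sum(weights)
  pv <- sum(weights * (stds^2 + means^2)) / sum(weights) - pm^2
  data.frame(mean_mm = pm, std_mm = sqrt(max(pv, 0)), weight_total = sum(weights))
}

#' Bundled human cohort summary table
#'
#' Published per-heart wall-thickness statistics for seven ex vivo human
#' atria (per chamber: quartiles, mean, population SD, cavity and tissue
#' volumes, and whether an AF driver was optically mapped in that chamber).
#' Used for cohort-level pooling checks.
#'
#' @return `data.frame` with one row per heart and chamber.
#' @export
human_awt_cohort <- function() {
  path <- system.file("extdata", "human_awt_cohort.csv", package = "atriawall")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Driver-region subgroup report
#'
#' Reproduces the cohort subgroup analysis: per-heart chamber summaries,
#' a voxel-pooled comparison of chambers with versus without mapped
#' drivers, and within-heart comparisons of the driver region against the
#' rest of the chamber.
#'
#' @param hearts a list; each element is a list with `id` (label), `W`
#'   (thickness volume or `awt_thickness`), `mask` (binary chamber mask),
#'   `driver` (logical flag), and optionally `region` (binary driver-region
#'   mask, a strict subset of `mask`).
#' @param alpha significance level.
#' @param subsample keep every k-th voxel of each pooled voxel set before
#'   testing (`1` = all voxels); a crude guard against spatial
#'   autocorrelation inflating the tests.
#' @return An `awt_cohort` object: `summaries` (per-heart rows),
#'   `driver_comparison` (with- vs without-driver chambers, or NULL if one
#'   group is absent), `region_comparisons` (per heart with a region).
#' @export
region_subgroup_report <- function(hearts, alpha = 0.05, subsample = 1L) {
  stopifnot(length(hearts) >= 1L)
  get_w <- function(h) {
    Wvol <- if (inherits(h$W, "awt_thickness")) h$W$W else h$W
    W <- Wvol$data
    m <- vol_mask(h$mask) & is.finite(W)
    list(vals = W[m], vol = Wvol, inmask = m)
  }
  thin <- function(x) if (subsample > 1L) x[seq(1L, length(x), by = subsample)] else x
  rows <- list()
  pool_drv <- numeric(0); pool_non <- numeric(0)
  region_cmp <- list()
  for (h in hearts) {
    gw <- get_w(h)
    row <- summarize_thickness(gw$vals)
    row$tissue_volume_cm3 <- sum(gw$inmask) * prod(gw$vol$spacing) / 1000
    row <- cbind(data.frame(heart = h$id, driver = isTRUE(h$driver)), row)
    rows[[length(rows) + 1L]] <- row
    if (isTRUE(h$driver)) pool_drv <- c(pool_drv, gw$vals)
    else pool_non <- c(pool_non, gw$vals)
    if (!is.null(h$region)) {
      rm_ <- vol_mask(h$region) & gw$inmask
      if (!any(rm_)) stop(sprintf("heart %s: region mask empty after intersection", h$id))
      rest <- gw$inmask & !rm_
      if (!any(rest)) stop(sprintf("heart %s: region covers the whole chamber, no 'rest' group", h$id))
      W <- gw$vol$data
      region_cmp[[as.character(h$id)]] <-
        compare_groups(thin(W[rm_]), thin(W[rest]), alpha = alpha)
    }
  }
  drv_cmp <- NULL
  if (length(pool_drv) >= 2L && length(pool_non) >= 2L)
    drv_cmp <- compare_groups(thin(pool_drv), thin(pool_non), alpha = alpha)
  structure(list(summaries = do.call(rbind, rows),
                 driver_comparison = drv_cmp,
                 region_comparisons = region_cmp),
            class = "awt_cohort")
}

comparison_as_list <- function(x) {
  list(n_a = x$group_a$n, mean_a = x$group_a$mean, sd_a = x$group_a$sd,
       n_b = x$group_b$n, mean_b = x$group_b$mean, sd_b = x$group_b$sd,
       t_statistic = x$t_statistic, t_pvalue = x$t_pvalue,
       f_statistic = x$f_statistic, f_pvalue = x$f_pvalue)
}

#' Write a cohort report to CSV + JSON
#'
#' @param report an `awt_cohort` from [region_subgroup_report()].
#' @param dir output directory (created if needed); writes
#'   `summaries.csv` and `comparisons.json`.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  cmp <- list()
  if (!is.null(report$driver_comparison))
    cmp$driver_vs_nondriver <- comparison_as_list(report$driver_comparison)
  if (length(report$region_comparisons))
    cmp$region_vs_rest <- lapply(report$region_comparisons, comparison_as_list)
  jsonlite::write_json(cmp, file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
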