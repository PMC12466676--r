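ztest_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Z-test for equality of two posterior means
#'
#' `Z = (mean_a - mean_b) / sqrt(var_a / n_a + var_b / n_b)` with a
#' two-sided standard-normal tail probability. In the heritability
#' comparison the variances are those associated with the posterior means
#' and the `n` are the retained-draw counts of the chains.
#'
#' @param mean_a,mean_b Posterior means.
#' @param var_a,var_b Variances associated with the means (>= 0, not both
#'   zero).
#' @param n_a,n_b Sample sizes (> 0).
#' @return Named vector `c(Z = ..., p = ...)`.
#' @export
z_test <- function(mean_a, var_a, n_a, mean_b, var_b, n_b) {
  stopifnot(var_a >= 0, var_b >= 0, n_a > 0, n_b > 0)
  den <- sqrt(var_a / n_a + var_b / n_b)
  if (den == 0) stop("zero denominator in Z-test", call. = FALSE)
  z <- (mean_a - mean_b) / den
  c(Z = z, p = ztest_p(z))
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks with average ranks for ties.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Ordinary least-squares regression of one EBV set on another
#'
#' @param y,x Numeric vectors of equal length >= 3.
#' @return Named vector `c(intercept, slope, r2)` where `r2` is the
#'   squared Pearson correlation.
#' @export
ebv_regression <- function(y, x) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  c(intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r2 = stats::cor(x, y)^2)
}

#' Sire breeding-value table across analyses
#'
#' A sire is any animal appearing in the sire column of at least one
#' retained record. Every pedigree member has a breeding value in every
#' analysis (pedigree propagation), so sires without offspring in a class
#' still get that class's EBV rather than a missing value.
#'
#' @param prep A `prepared_dataset`.
#' @param ped Sorted pedigree used for the fits.
#' @param fit_general Single-trait `varhet_fit` on all records.
#' @param fit_bivariate Bivariate `varhet_fit` on the two classes.
#' @return An `ebv_table` `data.frame`: `sire`, `ebv_general`, `ebv_low`,
#'   `ebv_high` (kg), `n_offspring`, `n_offspring_low`, `n_offspring_high`,
#'   `positive_in_general`.
#' @export
sire_ebv_table <- function(prep, ped, fit_general, fit_bivariate) {
  kept <- prep[prep$retained, , drop = FALSE]
  pidx <- match(as.character(kept$animal), ped$animal)
  sires <- ped$sire[pidx]
  sire_ids <- sort(unique(sires[!is.na(sires)]))
  if (!length(sire_ids)) stop("no sires among retained records", call. = FALSE)
  cnt <- function(cls) {
    s <- sires[!is.na(sires) & kept$sd_class == cls]
    tab <- table(s)
    out <- as.vector(tab[sire_ids])
    out[is.na(out)] <- 0L
    out
  }
  tab_all <- table(sires[!is.na(sires)])
  n_all <- as.vector(tab_all[sire_ids]); n_all[is.na(n_all)] <- 0L
  out <- data.frame(
    sire = sire_ids,
    ebv_general = unname(fit_general$a_mean[sire_ids]),
    ebv_low = unname(fit_bivariate$a_mean[sire_ids, "low"]),
    ebv_high = unname(fit_bivariate$a_mean[sire_ids, "high"]),
    n_offspring = n_all,
    n_offspring_low = cnt("LOW"),
    n_offspring_high = cnt("HIGH"),
    stringsAsFactors = FALSE
  )
  out$positive_in_general <- out$ebv_general > 0
  class(out) <- c("ebv_table", "data.frame")
  out
}

spearman_matrix <- function(ebvs) {
  m <- stats::cor(as.matrix(ebvs[, c("ebv_general", "ebv_low", "ebv_high")]),
                  method = "spearman")
  dimnames(m) <- list(c("general", "low", "high"), c("general", "low", "high"))
  m
}

#' Cross-analysis comparison report
#'
#' The statistics that diagnose heterogeneity of variance and its impact
#' on sire ranking: (i) 3x3 Spearman matrices of sire EBVs over all sires
#' and over the subset with positive general-analysis EBVs; (ii) OLS
#' regressions between general and class-specific EBVs in both
#' orientations and directions; (iii) the Z-test on posterior heritability
#' means of the two classes (default inputs: posterior mean, squared
#' Monte-Carlo standard error of the mean, retained-draw count; a variant
#' using the raw posterior variance is also reported); (iv) credible-
#' interval overlap verdicts for the genetic and residual variances
#' between classes. The `heterogeneity_detected` flag is on when both
#' variance-component intervals are disjoint and the default Z-test has
#' `p < 0.05`.
#'
#' @param ebvs An `ebv_table`.
#' @param summary_bivariate Output of [posterior_summary()] on the
#'   bivariate fit.
#' @param alpha Significance level for the Z-test (default 0.05).
#' @return A `comparison_report` list with elements `spearman_all`,
#'   `spearman_positive`, `regressions`, `ztest`, `ci_checks`,
#'   `heterogeneity_detected`.
#' @export
compare_analyses <- function(ebvs, summary_bivariate, alpha = 0.05) {
  stopifnot(inherits(ebvs, "data.frame"))
  sp_all <- spearman_matrix(ebvs)
  pos <- ebvs[ebvs$positive_in_general, , drop = FALSE]
  sp_pos <- NULL
  if (nrow(pos) >= 2) {
    sp_pos <- spearman_matrix(pos)
  } else {
    warning("no (or a single) sire with positive general EBV; ",
            "positive-subset statistics skipped", call. = FALSE)
  }
  regs <- rbind(
    data.frame(y = "general", x = "low",
               t(ebv_regression(ebvs$ebv_general, ebvs$ebv_low))),
    data.frame(y = "general", x = "high",
               t(ebv_regression(ebvs$ebv_general, ebvs$ebv_high))),
    data.frame(y = "low", x = "general",
               t(ebv_regression(ebvs$ebv_low, ebvs$ebv_general))),
    data.frame(y = "high", x = "general",
               t(ebv_regression(ebvs$ebv_high, ebvs$ebv_general)))
  )

  s <- summary_bivariate
  row <- function(p) s[s$parameter == p, , drop = FALSE]
  hl <- row("h2_low"); hh <- row("h2_high")
  if (nrow(hl) != 1 || nrow(hh) != 1) {
    stop("summary_bivariate must contain h2_low and h2_high rows", call. = FALSE)
  }
  ## mc_sd is already the standard error of the posterior mean, so the
  ## default variant enters the Z expression with n = 1; the second variant
  ## uses the raw posterior variance of the draws with n = retained draws.
  ndr <- attr(s, "n_draws") %||% 27000
  zt_mc <- z_test(hh$mean, hh$mc_sd^2, 1, hl$mean, hl$mc_sd^2, 1)
  zt_sd <- z_test(hh$mean, hh$posterior_sd^2, ndr,
                  hl$mean, hl$posterior_sd^2, ndr)
  ztest <- data.frame(
    variant = c("mcse", "posterior_sd"),
    Z = c(zt_mc["Z"], zt_sd["Z"]),
    p = c(zt_mc["p"], zt_sd["p"])
  )

  civ <- function(p) {
    lo <- row(paste0(p, "_low")); hi <- row(paste0(p, "_high"))
    ci_overlap(c(lo$ci_low, lo$ci_high), c(hi$ci_low, hi$ci_high))
  }
  ci_checks <- data.frame(
    parameter = c("sigma2_a", "sigma2_e"),
    overlap = c(civ("sigma2_a"), civ("sigma2_e"))
  )
  flag <- all(!ci_checks$overlap) && ztest$p[1] < alpha
  structure(list(spearman_all = sp_all, spearman_positive = sp_pos,
                 regressions = regs, ztest = ztest, ci_checks = ci_checks,
                 heterogeneity_detected = flag),
            class = "comparison_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.comparison_report <- function(x, ...) {
  cat("Heterogeneity-of-variance comparison report\n")
  cat("  Spearman (all sires):\n")
  print(round(x$spearman_all, 3))
  if (!is.null(x$spearman_positive)) {
    cat("  Spearman (positive general EBVs):\n")
    print(round(x$spearman_positive, 3))
  }
  cat("  EBV regressions:\n")
  print(x$regressions, row.names = FALSE, digits = 4)
  cat("  Heritability Z-test:\n")
  print(x$ztest, row.names = FALSE, digits = 4)
  cat("  CI overlap between classes:\n")
  print(x$ci_checks, row.names = FALSE)
  cat("  heterogeneity detected:", x$heterogeneity_detected, "\n")
  invisible(x)
}
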