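#' Read a run configuration file
#'
#' YAML key-value configuration with keys `chain.cycles`, `chain.burnin`,
#' `chain.thin`, `chain.seed`, `mode` (`reestimate` or `replication`) and
#' `analyses` (subset of `general`, `by_class`). Unknown keys raise an
#' error listing the valid ones.
#'
#' @param path Path to a YAML file.
#' @return A list of configuration values merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  valid <- c("chain", "mode", "analyses", "priors")
  bad <- setdiff(names(cfg), valid)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$chain)) {
    vc <- c("cycles", "burnin", "thin", "seed")
    badc <- setdiff(names(cfg$chain), vc)
    if (length(badc)) {
      stop("unknown chain key(s): ", paste(badc, collapse = ", "),
           "; valid keys: ", paste(vc, collapse = ", "), call. = FALSE)
    }
  }
  cfg
}

stage_log <- function(stage, t0) {
  message(sprintf("[varhet] %-10s %6.1f s", stage,
                  as.numeric(Sys.time()) - t0))
}

write_output <- function(df, path, seed, hash, what) {
  con <- file(path, "w")
  writeLines(sprintf("# varhet %s; seed=%d; config_hash=%s; units: kg, kg^2 for variances",
                     what, seed, hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  path
}

#' Run the full heterogeneity-of-variance evaluation
#'
#' Executes prepare -> fit (general single-trait) -> fit (bivariate over
#' the LOW/HIGH classes) -> posterior summaries -> sire comparison, and
#' writes every stage's output as commented CSV under `outdir`:
#' `prepared.csv`, `draws_general.csv`, `draws_byclass.csv`,
#' `summary.csv`, `ebv_table.csv`, `spearman_all.csv`,
#' `spearman_positive.csv`, `regressions.csv`, `ztest.csv` and a
#' plain-text `verdict.txt`.
#'
#' @param records Records `data.frame` or path to a records file.
#' @param pedigree Pedigree `data.frame` or path to a pedigree file.
#' @param outdir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param chain A [chain_config()].
#' @param mode Slope handling for the 305-day adjustment (see
#'   [prepare_records()]).
#' @param priors A [gibbs_priors()] list.
#' @param analyses Character subset of `c("general", "by_class")`.
#' @return Invisibly, a list with `prep`, `fit_general`, `fit_bivariate`,
#'   `summary`, `ebvs`, `report`.
#' @export
run_pipeline <- function(records, pedigree, outdir = NULL,
                         chain = chain_config(), mode = "reestimate",
                         priors = gibbs_priors(),
                         analyses = c("general", "by_class")) {
  stopifnot(length(analyses) >= 1,
            all(analyses %in% c("general", "by_class")))
  t0 <- as.numeric(Sys.time())
  if (is.character(records)) records <- read_records(records)
  if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
  pedigree <- ensure_sorted(pedigree)
  message(sprintf("[varhet] run: %d records, %d pedigree entries, seed %d",
                  nrow(records), nrow(pedigree), chain$seed))

  prep <- prepare_records(records, mode = mode)
  rs <- a_inverse(pedigree)
  Ainv <- rs$Ainv
  stage_log("prepare", t0)

  hash <- config_hash(list(chain = unclass(chain), mode = mode))
  seed <- chain$seed
  fit_general <- fit_biv <- NULL
  summaries <- list()
  if ("general" %in% analyses) {
    dg <- build_design(prep, pedigree$animal, "ALL")
    fit_general <- gibbs_single_trait(dg, Ainv, chain, priors)
    summaries$general <- posterior_summary(fit_general, "general")
    stage_log("fit general", t0)
  }
  if ("by_class" %in% analyses) {
    dl <- build_design(prep, pedigree$animal, "LOW")
    dh <- build_design(prep, pedigree$animal, "HIGH")
    biv_chain <- chain_config(chain$cycles, chain$burnin, chain$thin,
                              chain$seed + 1L, chain$block_every)
    fit_biv <- gibbs_bivariate(dl, dh, Ainv, biv_chain, priors)
    summaries$by_class <- posterior_summary(fit_biv, "by_class")
    stage_log("fit by_class", t0)
  }
  summary_all <- do.call(rbind, summaries)
  rownames(summary_all) <- NULL
  if (!is.null(summaries$by_class)) {
    attr(summary_all, "n_draws") <- attr(summaries$by_class, "n_draws")
  }

  ebvs <- report <- NULL
  if (!is.null(fit_general) && !is.null(fit_biv)) {
    ebvs <- sire_ebv_table(prep, pedigree, fit_general, fit_biv)
    sb <- summaries$by_class
    report <- compare_analyses(ebvs, sb)
    stage_log("compare", t0)
  }

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    w <- function(df, name, what) write_output(df, file.path(outdir, name),
                                               seed, hash, what)
    w(as.data.frame(prep), "prepared.csv", "prepared dataset")
    if (!is.null(fit_general)) w(fit_general$draws, "draws_general.csv",
                                 "general-analysis draws")
    if (!is.null(fit_biv)) w(fit_biv$draws, "draws_byclass.csv",
                             "bivariate draws")
    w(summary_all, "summary.csv", "posterior summary")
    if (!is.null(report)) {
      w(ebvs, "ebv_table.csv", "sire EBVs")
      w(as.data.frame(report$spearman_all), "spearman_all.csv",
        "Spearman, all sires")
      if (!is.null(report$spearman_positive)) {
        w(as.data.frame(report$spearman_positive), "spearman_positive.csv",
          "Spearman, positive sires")
      }
      w(report$regressions, "regressions.csv", "EBV regressions")
      w(report$ztest, "ztest.csv", "heritability Z-test")
      verdict <- c(
        sprintf("# varhet verdict; seed=%d; config_hash=%s", seed, hash),
        sprintf("sigma2_a CIs overlap between classes: %s",
                report$ci_checks$overlap[1]),
        sprintf("sigma2_e CIs overlap between classes: %s",
                report$ci_checks$overlap[2]),
        sprintf("heritability Z-test (mcse variant): Z = %.3f, p = %.4f",
                report$ztest$Z[1], report$ztest$p[1]),
        sprintf("heterogeneity detected: %s", report$heterogeneity_detected)
      )
      writeLines(verdict, file.path(outdir, "verdict.txt"))
    }
    stage_log("write", t0)
  }
  invisible(list(prep = prep, fit_general = fit_general,
                 fit_bivariate = fit_biv, summary = summary_all,
                 ebvs = ebvs, report = report))
}

#' Scatter plot of sire EBVs between analyses
#'
#' General-analysis breeding values against the class-specific ones, with
#' the fitted regression lines; visualises under- or over-estimation of
#' the best sires when heterogeneity of variance is ignored.
#'
#' @param ebvs An `ebv_table`.
#' @param file Optional path; when given, a PNG is written there.
#' @return Invisibly, the regression table.
#' @export
plot_ebv_regressions <- function(ebvs, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 450)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 2))
  # restore par before the device closes; par() on a closed device
  # would silently open Rplots.pdf in the working directory
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  for (cls in c("low", "high")) {
    x <- ebvs[[paste0("ebv_", cls)]]
    y <- ebvs$ebv_general
    r <- ebv_regression(y, x)
    graphics::plot(x, y, pch = 19, cex = 0.6,
                   xlab = sprintf("EBV, %s-SD class (kg)", cls),
                   ylab = "EBV, general analysis (kg)")
    graphics::abline(r["intercept"], r["slope"], col = "steelblue")
    graphics::abline(0, 1, lty = 2, col = "grey50")
    graphics::mtext(sprintf("slope %.3f, R2 %.2f", r["slope"], r["r2"]),
                    cex = 0.8)
  }
  invisible(ebvs)
}
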