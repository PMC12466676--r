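#' Simulation configuration
#'
#' Defaults emulate the study population the package targets: roughly
#' 2400 single-record first lactations spread over herd x year x season
#' contemporary groups (about 160, a few deliberately smaller than the
#' minimum-size filter), 77 sires shared across herds, age at calving
#' about 73.8 +/- 36.6 months, and class-heterogeneous genetic and
#' residual variances with a cross-class genetic correlation of 0.61.
#' Contemporary-group effects follow a right-skewed (gamma) distribution
#' so that slightly under half of the groups fall above the standardised
#' mean and form the HIGH class, and LOW-class groups hold more records
#' than HIGH-class ones, reproducing the roughly 65/35 record split of the
#' target population structure.
#'
#' @param n_sires Number of founder sires (default 77).
#' @param n_dams Number of founder dams.
#' @param n_herds,years Herd count and calving-year range; with the four
#'   seasons they define the potential contemporary groups.
#' @param cg_size_low,cg_size_high Mean (Poisson) records per LOW/HIGH
#'   group.
#' @param small_cg_prob Probability a group is instead given 1-2 records,
#'   exercising the minimum-size filter.
#' @param cg_sd Standard deviation (kg) of contemporary-group effects.
#' @param cg_shape Gamma shape of the group-effect distribution (skew).
#' @param mu Overall mean 305-day yield, kg.
#' @param sigma2_a_low,sigma2_a_high Additive genetic variances per class.
#' @param rg Cross-class additive genetic correlation.
#' @param sigma2_e_low,sigma2_e_high Residual variances per class.
#' @param beta_htz,beta_age Heterozygosity (kg) and age (kg/month) fixed
#'   regression coefficients.
#' @param age_mean,age_sd,age_min Age-at-calving distribution, months
#'   (normal truncated above `age_min`).
#' @param ll_mean,ll_sd,ll_range Lactation-length distribution, days.
#' @param ll_slope True kg/day used to back-compute total yield from the
#'   305-day yield.
#' @param sire_purebred_prob Probability a sire is purebred Murrah
#'   (otherwise fraction 0.5); dams draw their Murrah fraction from a
#'   Beta(5, 2).
#' @param class_rule `"emergent"`: a group's class follows the sign of its
#'   standardised group effect, as the downstream classifier will
#'   rediscover it; `"forced"`: classes alternate deterministically over
#'   groups, for clean two-trait recovery checks free of class/group-mean
#'   confounding.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sires = 77, n_dams = 700, n_herds = 8,
                       years = 2010:2014,
                       cg_size_low = 18.5, cg_size_high = 13,
                       small_cg_prob = 0.05,
                       cg_sd = 570, cg_shape = 3, mu = 2270,
                       sigma2_a_low = 353.51, sigma2_a_high = 1134.22,
                       rg = 0.61,
                       sigma2_e_low = 1480.62, sigma2_e_high = 2180.15,
                       beta_htz = 150, beta_age = 2,
                       age_mean = 73.80, age_sd = 36.61, age_min = 20,
                       ll_mean = 270, ll_sd = 35, ll_range = c(120, 380),
                       ll_slope = 5.47111,
                       sire_purebred_prob = 0.8,
                       class_rule = c("emergent", "forced")) {
  class_rule <- match.arg(class_rule)
  stopifnot(n_sires >= 1, n_dams >= 1, n_herds >= 1,
            sigma2_a_low > 0, sigma2_a_high > 0,
            sigma2_e_low > 0, sigma2_e_high > 0,
            rg > -1, rg < 1, cg_sd > 0, cg_shape > 0)
  cfg <- as.list(environment())
  cfg$G0 <- matrix(c(sigma2_a_low,
                     rg * sqrt(sigma2_a_low * sigma2_a_high),
                     rg * sqrt(sigma2_a_low * sigma2_a_high),
                     sigma2_a_high), 2, 2,
                   dimnames = list(c("low", "high"), c("low", "high")))
  structure(cfg, class = "sim_config")
}

## Population skeleton: contemporary groups with effects, true classes and
## sizes; one record row per animal with herd/year/season/sire/dam.
sim_skeleton <- function(config, seed) {
  set.seed(seed)
  cg <- expand.grid(herd = sprintf("H%02d", seq_len(config$n_herds)),
                    year = config$years, cs = 1:4,
                    stringsAsFactors = FALSE)
  ncg <- nrow(cg)
  shape <- config$cg_shape
  raw <- stats::rgamma(ncg, shape = shape, rate = 1)
  cg$effect <- (raw - shape) / sqrt(shape) * config$cg_sd
  std <- (cg$effect - mean(cg$effect)) / stats::sd(cg$effect)
  cg$class <- switch(config$class_rule,
    emergent = ifelse(std > 0, "HIGH", "LOW"),
    forced = ifelse(seq_len(ncg) %% 2 == 0, "HIGH", "LOW"))
  size_mean <- ifelse(cg$class == "LOW", config$cg_size_low,
                      config$cg_size_high)
  cg$n <- stats::rpois(ncg, size_mean)
  small <- stats::runif(ncg) < config$small_cg_prob
  cg$n[small] <- sample(1:2, sum(small), replace = TRUE)
  cg <- cg[cg$n > 0, , drop = FALSE]
  cg$cg_id <- paste(cg$herd, cg$year, cg$cs, sep = "_")

  n <- sum(cg$n)
  rec <- data.frame(
    animal = sprintf("C%04d", seq_len(n)),
    herd = rep(cg$herd, cg$n),
    year = rep(cg$year, cg$n),
    cs = rep(cg$cs, cg$n),
    cg_id = rep(cg$cg_id, cg$n),
    cg_effect = rep(cg$effect, cg$n),
    true_class = rep(cg$class, cg$n),
    stringsAsFactors = FALSE
  )
  sires <- sprintf("S%03d", seq_len(config$n_sires))
  dams <- sprintf("D%04d", seq_len(config$n_dams))
  rec$sire <- sample(sires, n, replace = TRUE)
  rec$dam <- sample(dams, n, replace = TRUE)
  rec$month <- (rec$cs - 1L) * 3L + sample(1:3, n, replace = TRUE)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  while (any(age <= config$age_min)) {
    k <- age <= config$age_min
    age[k] <- stats::rnorm(sum(k), config$age_mean, config$age_sd)
  }
  rec$age_months <- round(age, 1)
  ll <- stats::rnorm(n, config$ll_mean, config$ll_sd)
  rec$ll_days <- round(pmin(pmax(ll, config$ll_range[1]), config$ll_range[2]))
  rec$sire_mf <- ifelse(stats::runif(n) < config$sire_purebred_prob, 1, 0.5)
  rec$dam_mf <- round(stats::rbeta(n, 5, 2), 3)

  ped <- data.frame(
    animal = c(sires, dams, rec$animal),
    sire = c(rep(NA_character_, length(sires) + length(dams)), rec$sire),
    dam = c(rep(NA_character_, length(sires) + length(dams)), rec$dam),
    stringsAsFactors = FALSE
  )
  list(cg = cg, records = rec, pedigree = sort_pedigree(ped))
}

#' Simulate a pedigree
#'
#' Founder sires and dams followed by one recorded animal per lactation
#' record, each with one sire and one dam; sires are used across herds so
#' that genetic links connect the variance classes. Acyclic by
#' construction and returned sorted.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A sorted pedigree `data.frame`.
#' @export
simulate_pedigree <- function(config = sim_config(), seed = 1) {
  sim_skeleton(config, seed)$pedigree
}

#' Simulate breeding-value pairs down a pedigree
#'
#' Founders draw from a bivariate normal with covariance `G0`; each
#' non-founder is the parent average plus a Mendelian-sampling deviation
#' with covariance `0.5 (1 - (F_s + F_d) / 2) G0` (parental inbreeding
#' from the pedigree; an unknown parent contributes zero average and its
#' share of the full founder variance).
#'
#' @param ped Sorted pedigree.
#' @param G0 2x2 positive-(semi)definite genetic covariance matrix.
#' @param seed Integer seed.
#' @return Matrix (animals x 2, columns `low`, `high`) of true breeding
#'   values, rows named and ordered by the pedigree.
#' @export
simulate_breeding_values <- function(ped, G0, seed = 1) {
  ped <- ensure_sorted(ped)
  if (!isTRUE(all.equal(G0, t(G0))) || any(diag(G0) < 0) || det(G0) < -1e-12) {
    stop("G0 must be symmetric positive (semi)definite", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(ped)
  pi <- parent_indices(ped)
  s <- pi$s; d <- pi$d
  f <- inbreeding_coefficients(ped)
  ev <- eigen(G0, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) # G0 = L L'
  bv <- matrix(0, n, 2, dimnames = list(ped$animal, c("low", "high")))
  z <- matrix(stats::rnorm(2 * n), n, 2)
  for (i in seq_len(n)) {
    pa <- c(0, 0)
    msw <- 1  # founder: full variance
    if (s[i] > 0L && d[i] > 0L) {
      pa <- 0.5 * (bv[s[i], ] + bv[d[i], ])
      msw <- 0.5 * (1 - 0.5 * (f[s[i]] + f[d[i]]))
    } else if (s[i] > 0L) {
      pa <- 0.5 * bv[s[i], ]
      msw <- 0.75 - 0.25 * f[s[i]]
    } else if (d[i] > 0L) {
      pa <- 0.5 * bv[d[i], ]
      msw <- 0.75 - 0.25 * f[d[i]]
    }
    bv[i, ] <- pa + sqrt(msw) * as.vector(L %*% z[i, ])
  }
  bv
}

#' Simulate lactation records with known truth
#'
#' The 305-day yield of each record is
#' `mu + cg_effect + beta_htz * htz + beta_age * (age - mean age) +
#' a_class + e_class`, with the breeding value and residual of the
#' record's class; total yield is then back-computed through the true
#' kg/day slope so the preparation stage can recover it.
#'
#' @param skeleton A population skeleton from [sim_skeleton] (internal) —
#'   most users call [simulate_dataset()] instead.
#' @param bvs Breeding-value matrix from [simulate_breeding_values()].
#' @param config The [sim_config()].
#' @param seed Integer seed for the residuals.
#' @return List with `records` (the raw input table), `truth` (true
#'   breeding values, group effects/classes, coefficients, variances and
#'   noiseless phenotypes) and `pedigree`.
#' @keywords internal
simulate_records <- function(skeleton, bvs, config, seed = 1) {
  set.seed(seed)
  rec <- skeleton$records
  n <- nrow(rec)
  htz <- heterozygosity(rec$sire_mf, rec$dam_mf)
  a <- ifelse(rec$true_class == "LOW", bvs[rec$animal, "low"],
              bvs[rec$animal, "high"])
  se <- ifelse(rec$true_class == "LOW", sqrt(config$sigma2_e_low),
               sqrt(config$sigma2_e_high))
  e <- stats::rnorm(n, 0, se)
  noiseless <- config$mu + rec$cg_effect + config$beta_htz * htz +
    config$beta_age * (rec$age_months - mean(rec$age_months)) + a
  mp305 <- noiseless + e
  tmp <- mp305 - config$ll_slope * (305 - rec$ll_days)

  records <- data.frame(
    animal = rec$animal, herd = rec$herd, year = rec$year,
    month = rec$month, age_months = rec$age_months,
    tmp_kg = round(tmp, 2), ll_days = rec$ll_days,
    sire_mf = rec$sire_mf, dam_mf = rec$dam_mf,
    stringsAsFactors = FALSE
  )
  truth <- list(
    bvs = bvs,
    cg = skeleton$cg,
    record_class = rec$true_class,
    noiseless = noiseless,
    betas = c(htz = config$beta_htz, age = config$beta_age),
    variances = c(sigma2_a_low = config$sigma2_a_low,
                  sigma2_a_high = config$sigma2_a_high,
                  sigma_a_lh = config$G0[1, 2],
                  sigma2_e_low = config$sigma2_e_low,
                  sigma2_e_high = config$sigma2_e_high,
                  rg = config$rg),
    ll_slope = config$ll_slope
  )
  list(records = records, truth = truth, pedigree = skeleton$pedigree)
}

#' Simulate a complete study dataset
#'
#' Orchestrates [simulate_pedigree()], [simulate_breeding_values()] and
#' the record generator under sub-seeds derived deterministically from
#' `seed`: same config and seed give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return List with `records`, `pedigree`, `truth` (see
#'   [simulate_records()]).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  sk <- sim_skeleton(config, seed)
  bvs <- simulate_breeding_values(sk$pedigree, config$G0, seed + 1000L)
  out <- simulate_records(sk, bvs, config, seed + 2000L)
  out$config <- config
  out$seed <- seed
  out
}

#' Write a simulated dataset to delimited text files
#'
#' Emits `records.csv`, `pedigree.csv`, `truth_variances.csv` and
#' `truth_bvs.csv` in the formats the preparation and pedigree readers
#' consume. Each file starts with a comment header naming the generating
#' seed and configuration hash.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# varhet simulated dataset; seed=%d; config_hash=%s; units: kg, days, months",
                 sim$seed, config_hash(sim$config))
  wr <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    path
  }
  paths <- c(
    wr(sim$records, "records.csv"),
    wr(sim$pedigree, "pedigree.csv"),
    wr(data.frame(parameter = names(sim$truth$variances),
                  value = unname(sim$truth$variances)),
       "truth_variances.csv"),
    wr(data.frame(animal = rownames(sim$truth$bvs),
                  bv_low = sim$truth$bvs[, "low"],
                  bv_high = sim$truth$bvs[, "high"]),
       "truth_bvs.csv")
  )
  invisible(paths)
}

## deterministic djb2-style hash of the serialised configuration
config_hash <- function(config) {
  cfg <- unclass(config)
  raw <- serialize(cfg[order(names(cfg))], NULL, version = 2)
  h <- 5381
  for (b in as.integer(raw)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
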