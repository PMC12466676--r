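# Animal-model module: design assembly, MME oracle, Gibbs sampler checks.

# Shared small dataset with pedigree structure and varying covariates.
am_data <- local({
  cfg <- sim_config(n_sires = 8, n_dams = 40, n_herds = 3,
                    years = 2010:2011, cg_size_low = 7, cg_size_high = 7,
                    small_cg_prob = 0)
  sim <- simulate_dataset(cfg, seed = 515)
  prep <- prepare_records(sim$records, mode = "replication")
  list(sim = sim, prep = prep, ped = sim$pedigree,
       rs = a_inverse(sim$pedigree))
})

test_that("build_design dimensions and structure", {
  prep <- am_data$prep; ped <- am_data$ped
  d <- build_design(prep, ped$animal, "ALL")
  n <- sum(prep$retained)
  cgt <- attr(prep, "cg_table")
  expect_equal(dim(d$W), c(n, nrow(cgt) + 2L + nrow(ped)))
  expect_equal(d$n_fixed, nrow(cgt) + 2L)
  expect_equal(d$q, nrow(ped))
  # each record row: one CG indicator, htz, centred age, one genetic 1
  rs1 <- Matrix::rowSums(d$W != 0)
  expect_true(all(rs1 >= 3 & rs1 <= 4))  # age can be exactly at the centre
  # CG indicator columns sum to group sizes
  kept <- prep[prep$retained, ]
  expect_equal(as.vector(Matrix::colSums(d$W[, seq_along(d$cg_levels)])),
               as.numeric(table(factor(kept$cg_id))[d$cg_levels]))
  # age column is centred
  age_col <- d$W[, length(d$cg_levels) + 2L]
  expect_lt(abs(sum(age_col)), 1e-6)
  # subsets partition the records
  dl <- build_design(prep, ped$animal, "LOW")
  dh <- build_design(prep, ped$animal, "HIGH")
  expect_equal(length(dl$y) + length(dh$y), n)
  expect_length(intersect(dl$animals, dh$animals), 0)
  # dropping a recorded animal's pedigree slot must be caught
  rec1 <- prep$animal[prep$retained][1]
  expect_error(build_design(prep, setdiff(ped$animal, rec1), "ALL"),
               "missing from pedigree")
})

test_that("mme_solve matches a dense generalized-least-squares oracle", {
  # BLUP identity: solutions of Henderson's MME equal GLS fixed effects
  # and a = sigma2_a A Z' Vinv (y - X beta) with V = ZAZ' s2a + I s2e
  # dense oracle
  prep <- am_data$prep; ped <- am_data$ped
  d <- build_design(prep, ped$animal, "ALL")
  A <- relationship_matrix(ped)$A
  s2a <- 400; s2e <- 1600
  sol <- mme_solve(d, am_data$rs$Ainv, s2a, s2e)
  W <- as.matrix(d$W)
  X <- W[, seq_len(d$n_fixed)]
  Z <- W[, (d$n_fixed + 1):ncol(W)]
  V <- Z %*% A %*% t(Z) * s2a + diag(length(d$y)) * s2e
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
  a <- s2a * A %*% t(Z) %*% Vi %*% (d$y - X %*% beta)
  expect_equal(unname(sol$beta), as.vector(beta), tolerance = 1e-6)
  expect_equal(unname(sol$a), as.vector(a), tolerance = 1e-6)
})

test_that("frozen-variance Gibbs means converge to the MME solutions", {
  # with variance updates disabled the chain means must equal the
  # mme_solve solutions within Monte-Carlo error
  prep <- am_data$prep; ped <- am_data$ped
  d <- build_design(prep, ped$animal, "ALL")
  s2a <- 400; s2e <- 1600
  sol <- mme_solve(d, am_data$rs$Ainv, s2a, s2e)
  fit <- gibbs_single_trait(d, am_data$rs$Ainv,
                            chain_config(4000, 500, 1, seed = 12),
                            start = list(sigma2_a = s2a, sigma2_e = s2e),
                            update_variances = FALSE)
  expect_equal(unname(fit$draws$sigma2_a[1]), s2a)  # frozen
  r <- cor(fit$a_mean, sol$a)
  expect_gt(r, 0.99)
  expect_lt(max(abs(fit$a_mean - sol$a)), 0.15 * sd(sol$a) + 2)
  expect_lt(max(abs(fit$beta_mean - sol$beta)), 30)
})

test_that("bivariate frozen-variance means converge to the coupled MME", {
  prep <- am_data$prep; ped <- am_data$ped
  dl <- build_design(prep, ped$animal, "LOW")
  dh <- build_design(prep, ped$animal, "HIGH")
  Ainv <- as.matrix(am_data$rs$Ainv)
  G <- matrix(c(360, 230, 230, 1130), 2)
  s2e <- c(1480, 2180)
  fit <- gibbs_bivariate(dl, dh, am_data$rs$Ainv,
                         chain_config(4000, 500, 1, seed = 5),
                         start = list(G = G, sigma2_e = s2e),
                         update_variances = FALSE)
  # dense coupled MME oracle
  Gi <- solve(G)
  W1 <- as.matrix(dl$W); W2 <- as.matrix(dh$W)
  p1 <- ncol(W1); p2 <- ncol(W2); q <- dl$q
  gi1 <- (dl$n_fixed + 1):(dl$n_fixed + q)
  gi2 <- p1 + (dh$n_fixed + 1):(dh$n_fixed + q)
  C <- matrix(0, p1 + p2, p1 + p2)
  C[1:p1, 1:p1] <- crossprod(W1) / s2e[1]
  C[p1 + (1:p2), p1 + (1:p2)] <- crossprod(W2) / s2e[2]
  C[gi1, gi1] <- C[gi1, gi1] + Gi[1, 1] * Ainv
  C[gi2, gi2] <- C[gi2, gi2] + Gi[2, 2] * Ainv
  C[gi1, gi2] <- C[gi1, gi2] + Gi[1, 2] * Ainv
  C[gi2, gi1] <- C[gi2, gi1] + Gi[1, 2] * Ainv
  rhs <- c(crossprod(W1, dl$y) / s2e[1], crossprod(W2, dh$y) / s2e[2])
  sol <- solve(C, rhs)
  a1 <- sol[gi1]; a2 <- sol[gi2]
  expect_gt(cor(fit$a_mean[, "low"], a1), 0.99)
  expect_gt(cor(fit$a_mean[, "high"], a2), 0.99)
  expect_lt(max(abs(fit$a_mean[, "low"] - a1)), 0.2 * sd(a1) + 2)
  expect_lt(max(abs(fit$a_mean[, "high"] - a2)), 0.2 * sd(a2) + 2)
})

test_that("chain bookkeeping follows the retention rule", {
  # ChainConfig(600000, 60000, 20) -> 27000 retained
  expect_equal(chain_config(600000, 60000, 20)$n_retained, 27000L)
  expect_equal(chain_config(100, 10, 7)$n_retained, (100L - 10L) %/% 7L)
  expect_error(chain_config(100, 100, 1), "burnin")
  # retained rows in an actual fit
  prep <- am_data$prep; ped <- am_data$ped
  d <- build_design(prep, ped$animal, "ALL")
  fit <- gibbs_single_trait(d, am_data$rs$Ainv, chain_config(230, 30, 8, seed = 1))
  expect_equal(nrow(fit$draws), 25L)
})

test_that("the sampler is deterministic given the seed", {
  prep <- am_data$prep; ped <- am_data$ped
  d <- build_design(prep, ped$animal, "ALL")
  ch <- chain_config(400, 100, 2, seed = 77)
  f1 <- gibbs_single_trait(d, am_data$rs$Ainv, ch)
  f2 <- gibbs_single_trait(d, am_data$rs$Ainv, ch)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$a_mean, f2$a_mean)
  f3 <- gibbs_single_trait(d, am_data$rs$Ainv,
                           chain_config(400, 100, 2, seed = 78))
  expect_false(identical(f1$draws, f3$draws))
  # bivariate likewise
  dl <- build_design(prep, ped$animal, "LOW")
  dh <- build_design(prep, ped$animal, "HIGH")
  b1 <- gibbs_bivariate(dl, dh, am_data$rs$Ainv, ch)
  b2 <- gibbs_bivariate(dl, dh, am_data$rs$Ainv, ch)
  expect_identical(b1$draws, b2$draws)
})

test_that("all sampled variances are positive and finite", {
  prep <- am_data$prep; ped <- am_data$ped
  d <- build_design(prep, ped$animal, "ALL")
  fit <- gibbs_single_trait(d, am_data$rs$Ainv, chain_config(500, 100, 1, seed = 2))
  expect_true(all(is.finite(as.matrix(fit$draws))))
  expect_true(all(fit$draws$sigma2_a > 0))
  expect_true(all(fit$draws$sigma2_e > 0))
  dl <- build_design(prep, ped$animal, "LOW")
  dh <- build_design(prep, ped$animal, "HIGH")
  fb <- gibbs_bivariate(dl, dh, am_data$rs$Ainv, chain_config(500, 100, 1, seed = 2))
  m <- as.matrix(fb$draws)
  expect_true(all(is.finite(m)))
  expect_true(all(fb$draws$sigma2_a_low > 0))
  expect_true(all(fb$draws$sigma2_a_high > 0))
  # covariance draws respect positive-definiteness of G
  expect_true(all(fb$draws$sigma_a_lh^2 <
                    fb$draws$sigma2_a_low * fb$draws$sigma2_a_high))
})

test_that("95% credible intervals cover the true variances across seeds", {
  # full-scale simulated designs at the default truth, reduced chains;
  # pooled coverage of the four variance components over 20 seeds must
  # reach ~90%
  truth <- c(353.51, 1134.22, 1480.62, 2180.15)
  pars <- c("sigma2_a_low", "sigma2_a_high", "sigma2_e_low", "sigma2_e_high")
  hits <- matrix(NA, 20, 4)
  for (s in 1:20) {
    sim <- simulate_dataset(sim_config(), seed = s)
    prep <- prepare_records(sim$records, mode = "replication")
    rs <- a_inverse(sim$pedigree)
    dl <- build_design(prep, sim$pedigree$animal, "LOW")
    dh <- build_design(prep, sim$pedigree$animal, "HIGH")
    fit <- gibbs_bivariate(dl, dh, rs$Ainv,
                           chain_config(12000, 2000, 10, seed = s))
    for (j in 1:4) {
      ci <- quantile(fit$draws[[pars[j]]], c(0.025, 0.975))
      hits[s, j] <- truth[j] >= ci[1] && truth[j] <= ci[2]
    }
  }
  expect_gte(mean(hits), 0.9)
  expect_true(all(colMeans(hits) >= 0.8))
})

test_that("degenerate same-trait case: rg near 1 is recovered", {
  # equal variances and near-unit genetic correlation: the two classes
  # are effectively the same trait, so the posterior must concentrate at
  # high rg. Forced labels with the generator's true classes keep the
  # two-trait structure clean.
  cfg <- sim_config(rg = 0.98, sigma2_a_low = 800, sigma2_a_high = 800,
                    sigma2_e_low = 1600, sigma2_e_high = 1600,
                    class_rule = "forced", small_cg_prob = 0)
  sim <- simulate_dataset(cfg, seed = 101)
  prep <- prepare_records(sim$records, mode = "replication")
  prep$sd_class[prep$retained] <- sim$truth$record_class[prep$retained]
  rs <- a_inverse(sim$pedigree)
  dl <- build_design(prep, sim$pedigree$animal, "LOW")
  dh <- build_design(prep, sim$pedigree$animal, "HIGH")
  fit <- gibbs_bivariate(dl, dh, rs$Ainv, chain_config(20000, 4000, 10, seed = 101))
  expect_gt(mean(derived_parameters(fit)$rg), 0.9)
})

test_that("genetically independent traits: rg near 0 is recovered", {
  cfg <- sim_config(rg = 0, sigma2_a_low = 800, sigma2_a_high = 800,
                    sigma2_e_low = 1600, sigma2_e_high = 1600,
                    class_rule = "forced", small_cg_prob = 0)
  sim <- simulate_dataset(cfg, seed = 101)
  # the premise must hold in the realization: simulated breeding-value
  # pairs are uncorrelated
  bv <- sim$truth$bvs
  expect_lt(abs(cor(bv[, 1], bv[, 2])), 0.05)
  prep <- prepare_records(sim$records, mode = "replication")
  prep$sd_class[prep$retained] <- sim$truth$record_class[prep$retained]
  rs <- a_inverse(sim$pedigree)
  dl <- build_design(prep, sim$pedigree$animal, "LOW")
  dh <- build_design(prep, sim$pedigree$animal, "HIGH")
  fit <- gibbs_bivariate(dl, dh, rs$Ainv, chain_config(20000, 4000, 10, seed = 101))
  expect_lt(abs(mean(derived_parameters(fit)$rg)), 0.15)
})

test_that("gibbs_bivariate rejects animals recorded in both classes", {
  prep <- am_data$prep; ped <- am_data$ped
  dl <- build_design(prep, ped$animal, "LOW")
  dh <- build_design(prep, ped$animal, "LOW")  # same class twice
  expect_error(gibbs_bivariate(dl, dh, am_data$rs$Ainv, chain_config(10, 1, 1)),
               "both SD classes")
})
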