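#' Gibbs chain configuration
#'
#' @param cycles Total Gibbs cycles.
#' @param burnin Initial cycles discarded.
#' @param thin Save interval: cycle `c` (1-indexed) is retained iff
#'   `c > burnin` and `(c - burnin) %% thin == 0`.
#' @param seed RNG seed (integer).
#' @param block_every Every `block_every` cycles the whole genetic vector
#'   is redrawn in one exact multivariate-normal block (sparse Cholesky of
#'   its conditional precision) in addition to the per-cycle single-site
#'   scan. Both moves sample full conditionals of the same posterior; the
#'   block move is required for adequate mixing of the genetic variance
#'   components, whose single-site updates move a long pedigree-correlated
#'   vector far too slowly. `0` disables block moves (scan only).
#' @return A `chain_config` list with the derived `n_retained`.
#' @export
chain_config <- function(cycles = 600000, burnin = 60000, thin = 20,
                         seed = 1, block_every = 10) {
  stopifnot(cycles >= 1, thin >= 1, block_every >= 0)
  if (burnin >= cycles) stop("burnin must be smaller than cycles", call. = FALSE)
  structure(list(cycles = as.integer(cycles), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 block_every = as.integer(block_every),
                 n_retained = as.integer((cycles - burnin) %/% thin)),
            class = "chain_config")
}

#' Prior settings for the variance-component conditionals
#'
#' Defaults are the flat-prior convention for scaled-inverse-chi-square
#' variance conditionals (`nu = -2`, `S = 0`, so the posterior degrees of
#' freedom are `n - 2`), and its exact 2x2 analogue for the genetic
#' covariance block of the bivariate model: `nu_g = -(p + 1) = -3`,
#' `S_g = 0`, which makes the inverse-Wishart density exponent
#' `-(nu + p + 1)/2` vanish, i.e. a uniform prior over positive-definite
#' matrices (for `p = 1` the same rule gives `nu = -2`, matching the
#' univariate convention).
#'
#' A proper low-scale alternative such as `nu_g = 3, S_g = diag(2) * eps`
#' is configurable but not the default: its density rises like
#' `|G|^-(nu+p+1)/2` toward singular `G`, which places a quasi-absorbing
#' posterior mode at the rank-1 boundary (genetic correlation pinned at
#' 1) that long chains enter and practically never leave.
#'
#' @param nu_e,s_e Residual-variance prior df and scale.
#' @param nu_a,s_a Genetic-variance prior df and scale (single trait).
#' @param nu_g,S_g Genetic-covariance prior df and 2x2 scale matrix
#'   (bivariate model).
#' @return A list of prior constants.
#' @export
gibbs_priors <- function(nu_e = -2, s_e = 0, nu_a = -2, s_a = 0,
                         nu_g = -3, S_g = matrix(0, 2, 2)) {
  list(nu_e = nu_e, s_e = s_e, nu_a = nu_a, s_a = s_a,
       nu_g = nu_g, S_g = S_g)
}

## within-contemporary-group phenotypic variance: sensible scale for
## start values (the between-group spread belongs to the fixed effects)
within_cg_var <- function(design) {
  r <- design$y - stats::ave(design$y, design$cg)
  n <- length(r)
  k <- length(unique(design$cg))
  if (n - k < 2) return(stats::var(design$y))
  sum(r^2) / (n - k)
}

spmat_parts <- function(m) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  list(p = m@p, i = m@i, x = m@x, ncol = ncol(m))
}

trait_parts <- function(design) {
  WtW <- Matrix::crossprod(design$W)
  list(W = spmat_parts(design$W),
       WtW = spmat_parts(WtW),
       WtWdiag = Matrix::diag(WtW),
       y = design$y,
       Wty = as.vector(Matrix::crossprod(design$W, design$y)),
       n_fixed = design$n_fixed)
}

#' Single-trait animal model by Gibbs sampling
#'
#' Fits `y = X beta + Z a + e` with `a ~ N(0, A sigma2_a)` and
#' `e ~ N(0, I sigma2_e)` by single-site Gibbs sampling: each location
#' effect from its normal full conditional, then `sigma2_a` from a scaled
#' inverse chi-square with scale `a' Ainv a + nu0 S0` and df `q + nu0`,
#' and `sigma2_e` likewise with `e'e + nu0 S0` and df `n + nu0`. The chain
#' is deterministic given `chain$seed`.
#'
#' @param design A `model_design` from [build_design()].
#' @param Ainv Sparse A-inverse over the pedigree (from [a_inverse()]).
#' @param chain A [chain_config()].
#' @param priors A [gibbs_priors()] list.
#' @param start Optional list with `sigma2_a`, `sigma2_e` start values.
#' @param update_variances Set `FALSE` to freeze variances at the start
#'   values (location-conditional checks against the MME oracle).
#' @return A `varhet_fit`: `draws` (`data.frame`, one row per retained
#'   cycle, columns `sigma2_a`, `sigma2_e`), posterior-mean location
#'   effects `beta_mean` and `a_mean` (named by pedigree order), the chain
#'   config, and `model` tag.
#' @export
gibbs_single_trait <- function(design, Ainv, chain = chain_config(),
                               priors = gibbs_priors(), start = NULL,
                               update_variances = TRUE) {
  stopifnot(inherits(chain, "chain_config"))
  vw <- within_cg_var(design)
  if (is.null(start)) start <- list()
  s2a <- if (!is.null(start$sigma2_a)) start$sigma2_a else vw / 3
  s2e <- if (!is.null(start$sigma2_e)) start$sigma2_e else 2 * vw / 3
  stopifnot(s2a > 0, s2e > 0)
  set.seed(chain$seed)
  res <- gibbs_sampler_cpp(
    traits = list(trait_parts(design)),
    ainv = spmat_parts(Ainv), adiag = Matrix::diag(Ainv),
    chain = chain, priors = priors,
    start = list(sigma2_e = s2e, G = matrix(s2a, 1, 1)),
    update_variances = update_variances, bivariate = FALSE)
  draws <- as.data.frame(res$draws)
  names(draws) <- c("sigma2_a", "sigma2_e")
  loc <- res$location_means[[1]]
  nf <- design$n_fixed
  a_mean <- loc[(nf + 1):(nf + design$q)]
  if (!is.null(rownames(Ainv))) names(a_mean) <- rownames(Ainv)
  structure(list(draws = draws, beta_mean = loc[seq_len(nf)],
                 a_mean = a_mean, chain = chain, priors = priors,
                 model = if (design$subset == "ALL") "GENERAL" else design$subset,
                 n_records = length(design$y)),
            class = "varhet_fit")
}

#' Bivariate animal model by Gibbs sampling
#'
#' Treats the trait recorded in the LOW- and HIGH-variance classes as two
#' characters: every pedigree animal carries a breeding-value pair with
#' covariance `G0 %x% A`; `G0` is sampled from its inverse-Wishart full
#' conditional with scale `[a_t' Ainv a_u] + S0` and df `q + nu0`.
#' Residual variances are sampled independently per class; the residual
#' covariance is fixed at zero because no animal has records in both
#' classes (single first-lactation record each), making it inestimable.
#'
#' @param design_low,design_high `model_design`s for the two classes. The
#'   record sets must be disjoint by animal.
#' @param Ainv Sparse A-inverse over the shared pedigree.
#' @param chain A [chain_config()].
#' @param priors A [gibbs_priors()] list.
#' @param start Optional list with `G` (2x2) and `sigma2_e` (length 2).
#' @param update_variances Set `FALSE` to freeze (co)variances.
#' @return A `varhet_fit` with draws columns `sigma2_a_low`,
#'   `sigma2_a_high`, `sigma_a_lh`, `sigma2_e_low`, `sigma2_e_high`,
#'   posterior-mean `a_mean` (q x 2 matrix, columns `low`, `high`) and
#'   `beta_mean` (list per class).
#' @export
gibbs_bivariate <- function(design_low, design_high, Ainv,
                            chain = chain_config(), priors = gibbs_priors(),
                            start = NULL, update_variances = TRUE) {
  stopifnot(inherits(chain, "chain_config"))
  both <- intersect(design_low$animals, design_high$animals)
  if (length(both)) {
    stop("animal(s) with records in both SD classes: ",
         paste(utils::head(both, 3), collapse = ", "), call. = FALSE)
  }
  if (design_low$q != design_high$q) {
    stop("designs disagree on pedigree size", call. = FALSE)
  }
  if (is.null(start)) start <- list()
  vw <- c(within_cg_var(design_low), within_cg_var(design_high))
  G <- if (!is.null(start$G)) start$G else diag(vw / 3)
  s2e <- if (!is.null(start$sigma2_e)) start$sigma2_e else 2 * vw / 3
  stopifnot(all(dim(G) == c(2, 2)), all(s2e > 0))
  if (det(G) <= 0 || G[1, 1] <= 0) stop("start G not positive definite", call. = FALSE)
  set.seed(chain$seed)
  res <- gibbs_sampler_cpp(
    traits = list(trait_parts(design_low), trait_parts(design_high)),
    ainv = spmat_parts(Ainv), adiag = Matrix::diag(Ainv),
    chain = chain, priors = priors,
    start = list(sigma2_e = s2e, G = G),
    update_variances = update_variances, bivariate = TRUE)
  draws <- as.data.frame(res$draws)
  names(draws) <- c("sigma2_a_low", "sigma2_a_high", "sigma_a_lh",
                    "sigma2_e_low", "sigma2_e_high")
  q <- design_low$q
  amat <- cbind(
    low = res$location_means[[1]][(design_low$n_fixed + 1):(design_low$n_fixed + q)],
    high = res$location_means[[2]][(design_high$n_fixed + 1):(design_high$n_fixed + q)])
  if (!is.null(rownames(Ainv))) rownames(amat) <- rownames(Ainv)
  structure(list(draws = draws,
                 beta_mean = list(
                   low = res$location_means[[1]][seq_len(design_low$n_fixed)],
                   high = res$location_means[[2]][seq_len(design_high$n_fixed)]),
                 a_mean = amat, chain = chain, priors = priors,
                 model = "BIVARIATE",
                 n_records = c(low = length(design_low$y),
                               high = length(design_high$y))),
            class = "varhet_fit")
}

#' @export
print.varhet_fit <- function(x, ...) {
  cat("Animal-model Gibbs fit [", x$model, "]\n", sep = "")
  cat(sprintf("  chain: %d cycles, burn-in %d, thin %d, seed %d -> %d retained\n",
              x$chain$cycles, x$chain$burnin, x$chain$thin, x$chain$seed,
              nrow(x$draws)))
  cat("  posterior means:\n")
  pm <- colMeans(x$draws)
  for (nm in names(pm)) cat(sprintf("    %-14s %10.3f\n", nm, pm[nm]))
  invisible(x)
}
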