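#' Per-draw genetic parameters
#'
#' Computes heritability `h2 = sigma2_a / (sigma2_a + sigma2_e)` for each
#' retained draw and trait, and for bivariate fits the cross-class genetic
#' correlation `rg = sigma_a_lh / sqrt(sigma2_a_low * sigma2_a_high)`.
#'
#' @param draws A `varhet_fit` or its `draws` data.frame.
#' @return A `data.frame` of derived chains: `h2` (single trait) or
#'   `h2_low`, `h2_high`, `rg` (bivariate).
#' @export
derived_parameters <- function(draws) {
  if (inherits(draws, "varhet_fit")) draws <- draws$draws
  stopifnot(is.data.frame(draws))
  if (all(c("sigma2_a", "sigma2_e") %in% names(draws))) {
    tot <- draws$sigma2_a + draws$sigma2_e
    if (any(tot <= 0)) stop("nonpositive total variance in draws", call. = FALSE)
    return(data.frame(h2 = draws$sigma2_a / tot))
  }
  need <- c("sigma2_a_low", "sigma2_a_high", "sigma_a_lh",
            "sigma2_e_low", "sigma2_e_high")
  if (!all(need %in% names(draws))) {
    stop("draws must come from a single-trait or bivariate fit", call. = FALSE)
  }
  tl <- draws$sigma2_a_low + draws$sigma2_e_low
  th <- draws$sigma2_a_high + draws$sigma2_e_high
  if (any(tl <= 0) || any(th <= 0)) {
    stop("nonpositive total variance in draws", call. = FALSE)
  }
  data.frame(
    h2_low = draws$sigma2_a_low / tl,
    h2_high = draws$sigma2_a_high / th,
    rg = draws$sigma_a_lh / sqrt(draws$sigma2_a_low * draws$sigma2_a_high)
  )
}

## Monte-Carlo variance of the chain mean by nonoverlapping batch means,
## batch count ~ sqrt(chain length).
batch_means_var <- function(x) {
  m <- length(x)
  nb <- max(2L, floor(sqrt(m)))
  bs <- m %/% nb
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  stats::var(bm) / nb
}

#' Summarise one posterior chain
#'
#' Mean, Monte-Carlo standard error of the mean (batch means), posterior
#' standard deviation, median, equal-tailed 95% credible interval
#' (empirical 2.5/97.5 quantiles) and the Geweke diagnostic.
#'
#' @param x Numeric chain of retained draws (length >= 2).
#' @return One-row `data.frame` with columns `mean`, `mc_sd`,
#'   `posterior_sd`, `median`, `ci_low`, `ci_high`, `geweke_z`, `geweke_p`.
#' @export
summarize_draws <- function(x) {
  if (length(x) < 2) stop("need at least 2 draws", call. = FALSE)
  ci <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  gz <- tryCatch(geweke_z(x), error = function(e) c(z = NA_real_, p = NA_real_))
  data.frame(
    mean = mean(x),
    mc_sd = sqrt(batch_means_var(x)),
    posterior_sd = stats::sd(x),
    median = stats::median(x),
    ci_low = ci[1],
    ci_high = ci[2],
    geweke_z = unname(gz[1]),
    geweke_p = unname(gz[2])
  )
}

#' Geweke convergence diagnostic
#'
#' Compares the means of an early and a late window of the chain:
#' `z = (mean_first - mean_last) / sqrt(v_first + v_last)` where each `v`
#' is the window's estimate of the variance of its mean, obtained from the
#' spectral density at zero via nonoverlapping batch means (batch count
#' about the square root of the window length). Under stationarity `z` is
#' approximately standard normal; `p` is the two-sided tail.
#'
#' @param x Numeric chain.
#' @param first_frac,last_frac Fractions of the chain forming the early
#'   and late windows (defaults 0.1 and 0.5).
#' @return Named vector `c(z = ..., p = ...)`.
#' @export
geweke_z <- function(x, first_frac = 0.1, last_frac = 0.5) {
  stopifnot(first_frac > 0, last_frac > 0, first_frac + last_frac <= 1)
  m <- length(x)
  n1 <- floor(first_frac * m)
  n2 <- floor(last_frac * m)
  if (min(floor(sqrt(n1)), floor(sqrt(n2))) < 10) {
    stop("chain too short: each Geweke window needs at least 10 batches",
         call. = FALSE)
  }
  w1 <- x[seq_len(n1)]
  w2 <- x[(m - n2 + 1):m]
  d <- mean(w1) - mean(w2)
  if (d == 0) return(c(z = 0, p = 1))
  v1 <- batch_means_var(w1)
  v2 <- batch_means_var(w2)
  if (v1 == 0 || v2 == 0) {
    stop("zero-variance Geweke window", call. = FALSE)
  }
  z <- d / sqrt(v1 + v2)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Do two intervals intersect?
#'
#' Touching endpoints count as intersecting. Disjoint credible intervals
#' for a variance component between classes are the interval-based
#' evidence for heterogeneity of variance.
#'
#' @param a,b Numeric length-2 intervals `c(lower, upper)`.
#' @return `TRUE` iff `max(lowers) <= min(uppers)`.
#' @export
ci_overlap <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2)
  if (a[1] > a[2] || b[1] > b[2]) {
    stop("interval lower bound exceeds upper bound", call. = FALSE)
  }
  max(a[1], b[1]) <= min(a[2], b[2])
}

#' Posterior summary table for a fit
#'
#' Summarises each variance component and each derived genetic parameter
#' chain of a fit into one row (see [summarize_draws()]).
#'
#' @param fit A `varhet_fit`.
#' @param analysis Label recorded in the `analysis` column (defaults to
#'   the fit's model tag).
#' @return A `data.frame` with columns `parameter`, `analysis` and the
#'   [summarize_draws()] columns.
#' @export
posterior_summary <- function(fit, analysis = fit$model) {
  stopifnot(inherits(fit, "varhet_fit"))
  chains <- cbind(fit$draws, derived_parameters(fit$draws))
  out <- do.call(rbind, lapply(names(chains), function(nm) {
    cbind(data.frame(parameter = nm, analysis = analysis,
                     stringsAsFactors = FALSE),
          summarize_draws(chains[[nm]]))
  }))
  rownames(out) <- NULL
  attr(out, "n_draws") <- nrow(fit$draws)
  out
}
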