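#' Build design matrices for an animal model
#'
#' Assembles the combined design `W = [X, Z]` for one trait: contemporary-
#' group indicator columns (no intercept), the heterozygosity covariate,
#' the age-at-calving covariate centred at its subset mean, and the
#' genetic incidence mapping records to pedigree positions. All pedigree
#' animals get a breeding-value slot, including parents without records.
#'
#' @param prep A `prepared_dataset`.
#' @param ped_order Character vector of animal ids in the (sorted) pedigree
#'   order used for the relationship matrix.
#' @param subset `"ALL"`, `"LOW"` or `"HIGH"`: which records enter.
#' @return A `model_design` list: sparse `W` (records x (n_fixed + q)),
#'   response `y` (305-day yield, kg), `n_fixed`, `q`, `cg_levels`,
#'   `animal_index` (record -> pedigree position), `animals` (record ids),
#'   `subset`, `age_center`.
#' @export
build_design <- function(prep, ped_order, subset = c("ALL", "LOW", "HIGH")) {
  subset <- match.arg(subset)
  rec <- prep[prep$retained, , drop = FALSE]
  if (subset != "ALL") rec <- rec[rec$sd_class == subset, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records in subset ", subset, call. = FALSE)

  ai <- match(as.character(rec$animal), ped_order)
  if (anyNA(ai)) {
    stop("record animal(s) missing from pedigree: ",
         paste(utils::head(rec$animal[is.na(ai)], 3), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(rec)
  q <- length(ped_order)
  cg <- factor(rec$cg_id)
  ncg <- nlevels(cg)
  age_center <- mean(rec$age_months)

  rows <- rep(seq_len(n), 4L)
  cols <- c(as.integer(cg),                 # CG indicator
            rep(ncg + 1L, n),               # heterozygosity
            rep(ncg + 2L, n),               # centred age
            ncg + 2L + ai)                  # genetic effect
  vals <- c(rep(1, n), rec$htz, rec$age_months - age_center, rep(1, n))
  W <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(n, ncg + 2L + q))
  structure(list(W = W, y = rec$mp305, n_fixed = ncg + 2L, q = q,
                 cg_levels = levels(cg), cg = as.integer(cg),
                 animal_index = ai,
                 animals = as.character(rec$animal), subset = subset,
                 age_center = age_center),
            class = "model_design")
}

#' Solve Henderson's mixed-model equations
#'
#' Direct sparse solve of
#' `[X'X, X'Z; Z'X, Z'Z + Ainv * lambda] (beta, a) = (X'y, Z'y)` with
#' `lambda = sigma2_e / sigma2_a`, giving BLUE fixed effects and BLUP
#' breeding values at fixed variance components. Used as the exact oracle
#' for the Gibbs sampler's location conditionals.
#'
#' @param design A `model_design` from [build_design()].
#' @param Ainv Sparse inverse relationship matrix over the pedigree.
#' @param sigma2_a,sigma2_e Additive and residual variances.
#' @return List with `beta` (fixed-effect solutions) and `a` (breeding
#'   values, named by pedigree order when `Ainv` has dimnames).
#' @export
mme_solve <- function(design, Ainv, sigma2_a, sigma2_e) {
  stopifnot(sigma2_a > 0, sigma2_e > 0)
  W <- design$W
  nf <- design$n_fixed
  q <- design$q
  lambda <- sigma2_e / sigma2_a
  C <- Matrix::crossprod(W)
  gi <- (nf + 1L):(nf + q)
  C[gi, gi] <- C[gi, gi] + lambda * Ainv
  rhs <- Matrix::crossprod(W, design$y)
  sol <- tryCatch(
    as.vector(Matrix::solve(C, rhs)),
    error = function(e) {
      stop("mixed-model equations are singular (check contemporary-group ",
           "collinearity with covariates): ", conditionMessage(e),
           call. = FALSE)
    }
  )
  a <- sol[gi]
  if (!is.null(rownames(Ainv))) names(a) <- rownames(Ainv)
  list(beta = sol[seq_len(nf)], a = a)
}
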