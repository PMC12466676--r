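#' Read a pedigree file
#'
#' Reads a delimited text file with header columns `animal,sire,dam` and an
#' optional `murrah_fraction` column giving the proportion of Murrah genes
#' per animal. The tokens `"0"`, `""` and `"NA"` in the parent columns mean
#' unknown. The result is topologically sorted (see [sort_pedigree()]).
#'
#' @param path Path to the pedigree file.
#' @param sep Field separator (default comma).
#' @return A sorted pedigree `data.frame` with character columns `animal`,
#'   `sire`, `dam` (parents `NA` when unknown) and, when present,
#'   numeric `murrah_fraction` in \[0, 1\].
#' @export
read_pedigree <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop("pedigree file not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "#", strip.white = TRUE)
  need <- c("animal", "sire", "dam")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("pedigree file %s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ped <- df[, need]
  if ("murrah_fraction" %in% names(df)) {
    mf <- suppressWarnings(as.numeric(df$murrah_fraction))
    bad <- which(!is.na(df$murrah_fraction) & df$murrah_fraction != "" &
                   (is.na(mf) | mf < 0 | mf > 1))
    if (length(bad)) {
      stop(sprintf(
        "pedigree file %s: column murrah_fraction, line %d: value '%s' not in [0, 1]",
        path, bad[1] + 1L, df$murrah_fraction[bad[1]]), call. = FALSE)
    }
    ped$murrah_fraction <- mf
  }
  sort_pedigree(ped)
}

#' Topologically sort a pedigree
#'
#' Orders animals so that parents precede offspring, inserting founder rows
#' for parents that lack their own entry. Ties at equal pedigree depth are
#' broken lexicographically by animal id, so the order is stable.
#'
#' @param ped A `data.frame` with columns `animal`, `sire`, `dam`
#'   (character; unknown parents as `NA`, `"0"` or `""`), and optionally
#'   `murrah_fraction`.
#' @return The sorted pedigree with attribute `sorted = TRUE`.
#' @export
sort_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  if (!all(c("animal", "sire", "dam") %in% names(ped))) {
    stop("pedigree must have columns animal, sire, dam", call. = FALSE)
  }
  animal <- as.character(ped$animal)
  sire <- normalize_unknown(as.character(ped$sire))
  dam <- normalize_unknown(as.character(ped$dam))
  if (anyDuplicated(animal)) {
    stop("duplicate animal id in pedigree: ",
         animal[duplicated(animal)][1], call. = FALSE)
  }
  if (any(is.na(animal) | animal == "")) {
    stop("empty animal id in pedigree", call. = FALSE)
  }
  mf <- if ("murrah_fraction" %in% names(ped)) as.numeric(ped$murrah_fraction) else NULL
  if (!is.null(mf) && any(!is.na(mf) & (mf < 0 | mf > 1))) {
    stop("murrah_fraction outside [0, 1]", call. = FALSE)
  }

  ## ancestor closure: parents without a row become founders
  extra <- setdiff(unique(c(sire, dam)), c(animal, NA))
  if (length(extra)) {
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    if (!is.null(mf)) mf <- c(mf, rep(NA_real_, length(extra)))
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])

  ## iterative DFS computing generation depth, detecting cycles
  depth <- rep(NA_integer_, n)
  state <- integer(n)  # 0 unvisited, 1 on stack, 2 done
  for (root in seq_len(n)) {
    if (state[root] == 2L) next
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]
      if (state[v] == 0L) {
        state[v] <- 1L
        for (p in c(si[v], di[v])) {
          if (p > 0L) {
            if (state[p] == 1L) {
              stop("pedigree cycle detected involving animal ", animal[p],
                   call. = FALSE)
            }
            if (state[p] == 0L) stack <- c(stack, p)
          }
        }
      } else {
        stack <- stack[-length(stack)]
        if (state[v] == 1L) {
          state[v] <- 2L
          dpar <- c(if (si[v] > 0L) depth[si[v]] else 0L,
                    if (di[v] > 0L) depth[di[v]] else 0L, 0L)
          depth[v] <- max(dpar) + 1L
        }
      }
    }
  }
  ord <- order(depth, animal, method = "radix")
  out <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(mf)) out$murrah_fraction <- mf[ord]
  rownames(out) <- NULL
  attr(out, "sorted") <- TRUE
  out
}

normalize_unknown <- function(x) {
  x[!is.na(x) & x %in% c("0", "", "NA")] <- NA_character_
  x
}

ensure_sorted <- function(ped) {
  if (!isTRUE(attr(ped, "sorted"))) ped <- sort_pedigree(ped)
  ped
}

parent_indices <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  list(
    s = ifelse(is.na(ped$sire), 0L, idx[ped$sire]),
    d = ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  )
}

#' Dense additive relationship matrix (tabular method)
#'
#' Builds the numerator relationship matrix A by the tabular method:
#' `A[i,i] = 1 + 0.5 A[s,d]` and `A[i,j] = 0.5 (A[j,s] + A[j,d])`, unknown
#' parents contributing zero. Intended as the exact small-scale oracle for
#' the sparse A-inverse used by the samplers; refuses pedigrees beyond
#' 2000 animals.
#'
#' @param ped A pedigree (sorted automatically if needed).
#' @return An object of class `relationship_structure`: list with `order`
#'   (animal ids), dense matrix `A`, and inbreeding coefficients `F`
#'   (`diag(A) - 1`).
#' @export
relationship_matrix <- function(ped) {
  ped <- ensure_sorted(ped)
  n <- nrow(ped)
  if (n > 2000) {
    stop("dense relationship matrix is limited to 2000 animals; ",
         "use a_inverse() for larger pedigrees", call. = FALSE)
  }
  pi <- parent_indices(ped)
  s <- pi$s; d <- pi$d
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      av <- 0.5 * ((if (s[i] > 0L) A[j, s[i]] else 0) +
                     (if (d[i] > 0L) A[j, d[i]] else 0))
      A[j, i] <- av
      A[i, j] <- av
    }
  }
  structure(list(order = ped$animal, A = A, F = diag(A) - 1),
            class = "relationship_structure")
}

#' Inbreeding coefficients from a pedigree
#'
#' Exact per-animal inbreeding `F[i] = kinship(sire, dam)`, computed by
#' memoised recursion on the sorted pedigree. Founders and animals with an
#' unknown parent have `F = 0`.
#'
#' @param ped A pedigree.
#' @return Named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding_coefficients <- function(ped) {
  ped <- ensure_sorted(ped)
  pi <- parent_indices(ped)
  s <- pi$s; d <- pi$d
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { k <- i; i <- j; j <- k }
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(s[i], d[i]))
    } else {
      ## j is the later-born animal, so condition on j's parents
      0.5 * (phi(i, s[j]) + phi(i, d[j]))
    }
    memo[[key]] <- v
    v
  }
  f <- vapply(seq_len(nrow(ped)), function(k) phi(s[k], d[k]), numeric(1))
  names(f) <- ped$animal
  f
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules: each animal contributes `alpha = 1 / m_i` to the
#' inverse, where `m_i` is the Mendelian-sampling variance
#' `0.5 - 0.25 (F_s + F_d)` with both parents known, `0.75 - 0.25 F_p` with
#' one known, and `1` with none. With `use_inbreeding = FALSE` parental
#' inbreeding is ignored (`F` forced to zero in the weights), recovering
#' Henderson's original noninbred rules.
#'
#' @param ped A pedigree.
#' @param use_inbreeding Account for parental inbreeding in the
#'   Mendelian-sampling weights (default `TRUE`).
#' @return An object of class `relationship_structure`: list with `order`,
#'   sparse symmetric `Ainv` (a `dgCMatrix`), and `F` (the exact inbreeding
#'   coefficients regardless of `use_inbreeding`).
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  ped <- ensure_sorted(ped)
  n <- nrow(ped)
  pi <- parent_indices(ped)
  s <- pi$s; d <- pi$d
  f <- inbreeding_coefficients(ped)
  fw <- if (use_inbreeding) f else rep(0, n)

  ## per animal: up to 9 triplet contributions
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(n)) {
    sk <- s[k]; dk <- d[k]
    m <- if (sk > 0L && dk > 0L) {
      0.5 - 0.25 * (fw[sk] + fw[dk])
    } else if (sk > 0L) {
      0.75 - 0.25 * fw[sk]
    } else if (dk > 0L) {
      0.75 - 0.25 * fw[dk]
    } else 1
    alpha <- 1 / m
    par <- c(sk, dk)
    par <- par[par > 0L]
    ri <- c(k, par, rep(par, each = length(par)))
    rj <- c(k, rep(k, length(par)), rep(par, times = length(par)))
    rv <- c(alpha, rep(-alpha / 2, length(par)),
            rep(alpha / 4, length(par)^2))
    ## k-parent entries appear in both triangles
    ii <- c(ii, ri, rep(k, length(par)))
    jj <- c(jj, rj, par)
    xx <- c(xx, rv, rep(-alpha / 2, length(par)))
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- methods::as(Ainv, "generalMatrix")
  structure(list(order = ped$animal, Ainv = Ainv, F = f),
            class = "relationship_structure")
}

#' @export
print.relationship_structure <- function(x, ...) {
  cat("Relationship structure over", length(x$order), "animals\n")
  if (!is.null(x$A)) cat("  dense A:", nrow(x$A), "x", ncol(x$A), "\n")
  if (!is.null(x$Ainv)) {
    cat("  sparse A-inverse, nnz =", length(x$Ainv@x), "\n")
  }
  cat("  mean inbreeding:", format(mean(x$F), digits = 4), "\n")
  invisible(x)
}
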