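#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm runif rbinom var setNames
#' @importFrom utils head
NULL

# Moore-Penrose pseudo-inverse of a symmetric matrix via eigendecomposition.
# Eigenvalues below `tol` * max(|eigenvalue|) are treated as zero.
ginv_sym <- function(M, tol = 1e-10) {
  M <- (M + t(M)) / 2
  if (nrow(M) == 0L) return(M)
  e <- eigen(M, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

check_simplex <- function(p, tol = 1e-8, what = "frequencies") {
  if (any(!is.finite(p)) || any(p < -tol)) {
    abort(sprintf("%s must be finite and nonnegative", what))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("%s must sum to 1 (got %.10g)", what, sum(p)))
  }
  invisible(p)
}

# Unordered heterozygote pairs k < f in canonical row-major order.
het_pairs <- function(h) {
  if (h < 2L) return(tibble::tibble(k = integer(), f = integer()))
  idx <- which(upper.tri(matrix(0, h, h)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(k = as.integer(idx[, 1L]), f = as.integer(idx[, 2L]))
}

# All h(h+1)/2 unordered genotypes, homozygotes first then heterozygotes.
genotype_pairs <- function(h) {
  hp <- het_pairs(h)
  tibble::tibble(
    i = c(seq_len(h), hp$k),
    j = c(seq_len(h), hp$f)
  )
}

pair_label <- function(i, j, alleles = NULL) {
  if (is.null(alleles)) {
    paste0(pmin(i, j), "/", pmax(i, j))
  } else {
    paste0(alleles[pmin(i, j)], "/", alleles[pmax(i, j)])
  }
}
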