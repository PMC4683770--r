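#' Genomic relationship matrices from coding matrices
#'
#' Scales a coding matrix `W` by the square root of the average diagonal of
#' `W W'` (so `T = W / sqrt(k)`) and forms the relationship matrix
#' `T T'`, whose diagonal then averages exactly 1. Applied to the additive
#' coding this yields the (haplotype or SNP) genomic additive relationship
#' matrix; applied to the dominance coding, the genomic dominance
#' relationship matrix.
#'
#' @param coding A [haplotype_coding()] or [snp_coding()] object, or a plain
#'   numeric coding matrix (rows = individuals).
#' @return For a coding object, a `grm_set` with elements `A`, `D`
#'   (relationship matrices), `T_alpha`, `T_delta` (scaled coding), and
#'   scale constants `k_alpha`, `k_delta`. For a plain matrix, a list with
#'   `S`, `T`, `k`.
#' @examples
#' g <- simulate_haplotypes(50, list(list(alleles = c("00", "11"),
#'                                        freq = c(0.6, 0.4))), seed = 1)
#' cat <- enumerate_haplotypes(g, plan_blocks(g, n_snps = 2))
#' grms <- genomic_relationship(haplotype_coding(g, cat))
#' mean(diag(grms$A))
#' @export
genomic_relationship <- function(coding) {
  if (is.matrix(coding)) {
    sc <- scale_coding(coding)
    return(list(S = tcrossprod(sc$T), T = sc$T, k = sc$k))
  }
  stopifnot(inherits(coding, c("hap_coding", "snp_coding")))
  a <- scale_coding(coding$W_alpha)
  d <- scale_coding(coding$W_delta, required = FALSE)
  out <- list(
    A = tcrossprod(a$T), T_alpha = a$T, k_alpha = a$k,
    D = if (!is.null(d)) tcrossprod(d$T) else NULL,
    T_delta = if (!is.null(d)) d$T else NULL,
    k_delta = if (!is.null(d)) d$k else NULL,
    alpha_block = coding$alpha_block,
    delta_block = coding$delta_block,
    samples = coding$samples
  )
  structure(out, class = "grm_set")
}

scale_coding <- function(W, required = TRUE) {
  if (ncol(W) == 0L || all(W == 0)) {
    if (required) abort("coding matrix has no polymorphic columns; nothing to relate")
    return(NULL)
  }
  k <- mean(rowSums(W^2))
  list(T = W / sqrt(k), k = k)
}

#' @export
print.grm_set <- function(x, ...) {
  cat(sprintf("<grm_set> %d individuals; A (%d additive columns)%s\n",
              nrow(x$A), ncol(x$T_alpha),
              if (!is.null(x$D)) sprintf(", D (%d dominance columns)", ncol(x$T_delta)) else ""))
  invisible(x)
}

#' Relationship matrix between validation and training individuals
#'
#' Codes the validation individuals against the training catalog (training
#' frequencies and training scale constant `k`) and forms
#' `S01 = T0 T'`, the q0 x q block of genomic relationships used to carry
#' training predictions over to the validation population.
#'
#' @param W0 Validation coding matrix (built with training frequencies; for
#'   haplotypes via [haplotype_coding()] with the training catalog).
#' @param W Training coding matrix.
#' @param k Training scale constant (`mean(diag(W W'))`); computed from `W`
#'   when omitted.
#' @return q0 x q numeric matrix.
#' @export
cross_relationship <- function(W0, W, k = NULL) {
  if (ncol(W0) != ncol(W)) {
    abort("validation and training coding matrices must share their columns")
  }
  k <- k %||% mean(rowSums(W^2))
  tcrossprod(W0 / sqrt(k), W / sqrt(k))
}

#' Write / read a relationship matrix as delimited text
#'
#' The square format is a tab-separated matrix with a sample-ID header line
#' and sample IDs in the first column; the long format has columns
#' `id1`, `id2`, `value` over the lower triangle including the diagonal.
#'
#' @param S Symmetric relationship matrix with sample dimnames.
#' @param path Output path.
#' @param format `"square"` or `"long"`.
#' @return `write_grm` invisibly returns `path`; `read_grm` returns the
#'   matrix with dimnames.
#' @export
write_grm <- function(S, path, format = c("square", "long")) {
  format <- match.arg(format)
  ids <- rownames(S) %||% paste0("ind", seq_len(nrow(S)))
  if (format == "square") {
    df <- tibble::as_tibble(S, .name_repair = ~ids)
    df <- dplyr::bind_cols(tibble::tibble(id = ids), df)
    readr::write_tsv(df, path)
  } else {
    idx <- which(lower.tri(S, diag = TRUE), arr.ind = TRUE)
    readr::write_tsv(tibble::tibble(
      id1 = ids[idx[, 1L]], id2 = ids[idx[, 2L]],
      value = S[idx]
    ), path)
  }
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path, format = c("square", "long")) {
  format <- match.arg(format)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (format == "square") {
    ids <- df[[1L]]
    S <- as.matrix(df[, -1L, drop = FALSE])
    dimnames(S) <- list(ids, colnames(df)[-1L])
  } else {
    ids <- unique(c(df$id1, df$id2))
    S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    S[cbind(match(df$id1, ids), match(df$id2, ids))] <- df$value
    S[cbind(match(df$id2, ids), match(df$id1, ids))] <- df$value
  }
  S
}

#' Heatmap of a genomic relationship matrix
#'
#' @param object A `grm_set`.
#' @param which `"A"` (additive) or `"D"` (dominance).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grm_set <- function(object, which = c("A", "D"), ...) {
  which <- match.arg(which)
  S <- object[[which]]
  if (is.null(S)) abort(sprintf("this grm_set holds no %s matrix", which))
  ids <- object$samples %||% paste0("ind", seq_len(nrow(S)))
  df <- tidyr::expand_grid(id1 = factor(ids, ids), id2 = factor(ids, ids))
  df$value <- as.vector(S)
  ggplot2::ggplot(df, ggplot2::aes(.data$id1, .data$id2, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (which == "A") "additive" else "dominance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
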