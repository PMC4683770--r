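# ---- model terms -----------------------------------------------------------

#' Declare a random genetic term for GBLUP / GREML
#'
#' A random term is defined either by its scaled coding matrix `T` (q
#' individuals x t effects; enables both solving routes) or by its
#' relationship matrix `S = T T'` alone (conditional-expectation route only,
#' singular `S` permitted).
#'
#' @param T Scaled coding matrix (q x t), e.g. `grm$T_alpha`.
#' @param S Relationship matrix (q x q); computed from `T` when omitted.
#' @param blocks Optional integer vector of length t assigning each effect
#'   column to a block (used for per-block heritabilities).
#' @return A `genetic_term` list.
#' @export
genetic_term <- function(T = NULL, S = NULL, blocks = NULL) {
  if (is.null(T) && is.null(S)) abort("a term needs `T` or `S`")
  if (!is.null(T) && !is.null(blocks) && length(blocks) != ncol(T)) {
    abort("`blocks` must assign every column of `T`")
  }
  structure(list(T = T, S = S %||% if (!is.null(T)) tcrossprod(T),
                 blocks = blocks, t = if (!is.null(T)) ncol(T) else NA_integer_),
            class = "genetic_term")
}

#' Random terms from a set of relationship matrices
#'
#' Convenience constructor turning a [genomic_relationship()] result into
#' the additive (and, when present, dominance) random terms of the mixed
#' model.
#'
#' @param grm A `grm_set`.
#' @param prefix Term-name prefix (e.g. `"hap"` or `"snp"`).
#' @return Named list of [genetic_term()] objects.
#' @export
grm_terms <- function(grm, prefix = "hap") {
  stopifnot(inherits(grm, "grm_set"))
  out <- list(genetic_term(T = grm$T_alpha, S = grm$A, blocks = grm$alpha_block))
  nms <- paste0(prefix, "_add")
  if (!is.null(grm$D)) {
    out <- c(out, list(genetic_term(T = grm$T_delta, S = grm$D,
                                    blocks = grm$delta_block)))
    nms <- c(nms, paste0(prefix, "_dom"))
  }
  setNames(out, nms)
}

normalize_terms <- function(terms, q) {
  if (inherits(terms, "genetic_term")) terms <- list(terms)
  terms <- purrr::map(terms, function(tm) {
    if (inherits(tm, "genetic_term")) return(tm)
    if (!is.matrix(tm)) abort("each term must be a matrix or a genetic_term()")
    if (nrow(tm) != q) abort("term matrices must have one row per individual")
    if (ncol(tm) == nrow(tm) && isTRUE(all.equal(tm, t(tm)))) {
      genetic_term(S = tm)
    } else {
      genetic_term(T = tm)
    }
  })
  if (is.null(names(terms)) || any(names(terms) == "")) {
    names(terms) <- paste0("term", seq_along(terms))
  }
  terms
}

as_design <- function(X, N, intercept = TRUE) {
  if (is.null(X)) {
    if (intercept) matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
    else matrix(0, N, 0)
  } else {
    X <- as.matrix(X)
    if (nrow(X) != N) abort("`X` must have one row per observation")
    X
  }
}

as_incidence <- function(Z, y, q) {
  if (is.null(Z)) {
    if (length(y) != q) abort("with `Z = NULL`, one observation per individual is assumed")
    return(NULL)  # identity sentinel
  }
  Z <- as.matrix(Z)
  if (nrow(Z) != length(y) || ncol(Z) != q) abort("`Z` must be N x q")
  if (any(rowSums(Z != 0) != 1L) || !all(Z %in% c(0, 1))) {
    abort("each row of `Z` must contain a single 1")
  }
  Z
}

Zmult <- function(Z, M) if (is.null(Z)) M else Z %*% M
Ztmult <- function(Z, v) if (is.null(Z)) v else crossprod(Z, v)

# ---- conditional-expectation (CE) route ------------------------------------

#' GBLUP via the conditional-expectation formulation
#'
#' Solves the mixed model through the phenotypic covariance
#' `V = Z (sum_i sigma2_i S_i) Z' + sigma2_e I`: fixed effects by generalized
#' least squares with a Moore-Penrose generalized inverse, then each genetic
#' value as `u_i = sigma2_i S_i Z' P y = S_i eps_i`, where `eps_i` are the
#' regressed phenotypic values. Singular relationship matrices are handled
#' without forming any relationship-matrix inverse. Efficient when
#' individuals are fewer than effects.
#'
#' @param y Phenotype vector (length N).
#' @param terms Named list of [genetic_term()] objects or matrices (square
#'   symmetric = `S`, otherwise `T`).
#' @param sigma2 Named (or positionally matched) vector of variance
#'   components, one per term.
#' @param sigma2_e Residual variance (> 0).
#' @param X Fixed-effect design matrix (default: intercept only).
#' @param Z N x q incidence matrix; `NULL` means one observation per
#'   individual.
#' @return A `gblup_fit` with BLUE `b_hat`, per-term predictions `u`,
#'   regressed phenotypes `epsilon`, and total genetic values `g_hat`.
#' @export
gblup_ce <- function(y, terms, sigma2, sigma2_e, X = NULL, Z = NULL) {
  y <- as.numeric(y); N <- length(y)
  q <- if (is.null(Z)) N else ncol(as.matrix(Z))
  terms <- normalize_terms(terms, q)
  sigma2 <- match_sigma2(sigma2, terms)
  Z <- as_incidence(Z, y, q)
  X <- as_design(X, N)
  if (sigma2_e <= 0) abort("`sigma2_e` must be positive for the CE route")

  G <- Reduce(`+`, purrr::map2(terms, sigma2, function(tm, s2) s2 * tm$S))
  V <- Zmult(Z, t(Zmult(Z, G))) + diag(sigma2_e, N)
  R <- tryCatch(chol(V), error = function(e) {
    abort("phenotypic covariance V is not positive definite")
  })
  Vinv_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  if (ncol(X) > 0L) {
    Vinv_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
    XtViX <- crossprod(X, Vinv_X)
    if (qr(XtViX)$rank < ncol(X)) {
      message("rank-deficient fixed-effect design; using a generalized inverse")
    }
    b_hat <- drop(ginv_sym(XtViX) %*% crossprod(X, Vinv_y))
    Py <- Vinv_y - Vinv_X %*% b_hat
  } else {
    b_hat <- numeric(0)
    Py <- Vinv_y
  }
  ZtPy <- Ztmult(Z, Py)
  eps <- purrr::map2(terms, sigma2, function(tm, s2) drop(s2 * ZtPy))
  u <- purrr::map2(terms, eps, function(tm, e) drop(tm$S %*% e))
  new_gblup_fit(method = "ce", b_hat = b_hat, u = u, epsilon = eps, tau = NULL,
                terms = terms, sigma2 = sigma2, sigma2_e = sigma2_e,
                samples = rownames(terms[[1]]$S))
}

# ---- mixed-model-equations (QM) route --------------------------------------

#' GBLUP via the mixed-model equations at the effect level
#'
#' Solves Henderson-style mixed-model equations for the fixed effects and
#' the effect vectors `tau_i`, with ridge blocks `lambda_i I`
#' (`lambda_i = sigma2_e / sigma2_i`), then maps effects to genetic values
#' as `u_i = T_i tau_i`. No relationship-matrix inverse is formed, so
#' rank-deficient coding is fine; every included term needs
#' `sigma2_i > 0` and a `T` matrix. Efficient when effects are fewer than
#' individuals.
#'
#' @inheritParams gblup_ce
#' @return A `gblup_fit` with effect-level solutions `tau` in addition to
#'   the quantities of [gblup_ce()].
#' @export
gblup_qm <- function(y, terms, sigma2, sigma2_e, X = NULL, Z = NULL) {
  y <- as.numeric(y); N <- length(y)
  q <- guess_q(terms, Z, N)
  terms <- normalize_terms(terms, q)
  sigma2 <- match_sigma2(sigma2, terms)
  if (any(sigma2 <= 0)) {
    abort("every term included in the QM route needs sigma2 > 0; drop null terms first")
  }
  if (any(purrr::map_lgl(terms, ~ is.null(.x$T)))) {
    abort("the QM route needs the coding matrix `T` of every term")
  }
  Z <- as_incidence(Z, y, q)
  X <- as_design(X, N)
  Zg <- do.call(cbind, purrr::map(terms, function(tm) Zmult(Z, tm$T)))
  t_i <- purrr::map_int(terms, ~ ncol(.x$T))
  lambda <- sigma2_e / sigma2
  lam_vec <- rep(lambda, times = t_i)

  C <- rbind(
    cbind(crossprod(X), crossprod(X, Zg)),
    cbind(crossprod(Zg, X), crossprod(Zg) + diag(lam_vec, nrow = length(lam_vec)))
  )
  rhs <- c(crossprod(X, y), crossprod(Zg, y))
  sol <- tryCatch(drop(chol2inv(chol(C)) %*% rhs), error = function(e) {
    message("singular mixed-model equations; using a generalized inverse")
    drop(ginv_sym(C) %*% rhs)
  })
  cX <- ncol(X)
  b_hat <- sol[seq_len(cX)]
  tau_all <- if (cX > 0L) sol[-seq_len(cX)] else sol
  idx <- split(seq_along(tau_all), rep(seq_along(terms), times = t_i))
  tau <- purrr::map(idx, ~ tau_all[.x])
  names(tau) <- names(terms)
  u <- purrr::map2(terms, tau, function(tm, tv) drop(tm$T %*% tv))
  new_gblup_fit(method = "qm", b_hat = b_hat, u = u, epsilon = NULL, tau = tau,
                terms = terms, sigma2 = sigma2, sigma2_e = sigma2_e,
                samples = rownames(terms[[1]]$T))
}

guess_q <- function(terms, Z, N) {
  if (!is.null(Z)) return(ncol(as.matrix(Z)))
  N
}

match_sigma2 <- function(sigma2, terms) {
  if (length(sigma2) != length(terms)) {
    abort("`sigma2` must supply one variance per term")
  }
  if (!is.null(names(sigma2)) && all(names(terms) %in% names(sigma2))) {
    sigma2 <- sigma2[names(terms)]
  }
  if (any(sigma2 < 0)) abort("variance components must be nonnegative")
  setNames(as.numeric(sigma2), names(terms))
}

new_gblup_fit <- function(method, b_hat, u, epsilon, tau, terms, sigma2,
                          sigma2_e, samples = NULL) {
  g_hat <- Reduce(`+`, u)
  structure(list(
    method = method, b_hat = b_hat, u = u, epsilon = epsilon, tau = tau,
    g_hat = g_hat, terms = terms, sigma2 = sigma2, sigma2_e = sigma2_e,
    samples = samples %||% paste0("ind", seq_along(g_hat))
  ), class = "gblup_fit")
}

#' Genomic BLUP of haplotype / SNP genetic values
#'
#' Front end selecting between the two equivalent solving routes: the
#' conditional-expectation (CE) route through the phenotypic covariance, and
#' the mixed-model-equations (QM) route at the effect level. Both give
#' identical predictions; `method = "auto"` picks CE when individuals are
#' fewer than fixed effects plus genetic effects, QM otherwise (falling back
#' to CE when a term lacks a coding matrix or has a zero variance).
#'
#' @inheritParams gblup_ce
#' @param method `"auto"`, `"ce"` or `"qm"`.
#' @examples
#' set.seed(1)
#' g <- simulate_haplotypes(40, list(list(alleles = c("00", "01", "11"),
#'                                        freq = c(0.5, 0.3, 0.2))), seed = 2)
#' grm <- genomic_relationship(
#'   haplotype_coding(g, enumerate_haplotypes(g, plan_blocks(g, n_snps = 2))))
#' y <- rnorm(40)
#' fit <- gblup(y, grm_terms(grm), sigma2 = c(1, 0.5), sigma2_e = 1)
#' tidy(fit)
#' @export
gblup <- function(y, terms, sigma2, sigma2_e, X = NULL, Z = NULL,
                  method = c("auto", "ce", "qm")) {
  method <- match.arg(method)
  if (method == "auto") {
    q <- if (is.null(Z)) length(y) else ncol(as.matrix(Z))
    tl <- normalize_terms(terms, q)
    have_T <- all(!purrr::map_lgl(tl, ~ is.null(.x$T)))
    n_eff <- sum(purrr::map_int(tl, ~ if (is.null(.x$T)) 0L else ncol(.x$T)))
    cX <- if (is.null(X)) 1L else ncol(as.matrix(X))
    method <- if (have_T && all(sigma2 > 0) && q >= cX + n_eff) "qm" else "ce"
  }
  switch(method,
         ce = gblup_ce(y, terms, sigma2, sigma2_e, X = X, Z = Z),
         qm = gblup_qm(y, terms, sigma2, sigma2_e, X = X, Z = Z))
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> route = %s, %d random term(s), %d individuals\n",
              toupper(x$method), length(x$u), length(x$g_hat)))
  invisible(x)
}

#' @rdname gblup
#' @param x,object A `gblup_fit`.
#' @param ... Unused.
#' @export
tidy.gblup_fit <- function(x, ...) {
  purrr::imap_dfr(x$u, function(u, nm) {
    tibble::tibble(sample = x$samples, term = nm, u = as.numeric(u))
  }) |>
    dplyr::bind_rows(tibble::tibble(sample = x$samples, term = "total",
                                    u = as.numeric(x$g_hat)))
}

#' @rdname gblup
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n_terms = length(x$u),
                 q = length(x$g_hat), sigma2_e = x$sigma2_e)
}

#' Predict genetic values of validation individuals
#'
#' Carries a fitted GBLUP to individuals without phenotypes. For a CE fit,
#' supply the training-validation relationship blocks `S01` (one q0 x q
#' matrix per term, from [cross_relationship()]); predictions are
#' `u_i0 = S01_i eps_i`. For a QM fit, supply the validation coding `T0`
#' (one q0 x t matrix per term, built against the training catalog,
#' frequencies and scale constants); predictions are `u_i0 = T0_i tau_i`.
#' The two routes give identical values.
#'
#' @param object A `gblup_fit`.
#' @param S01 Named list of cross-relationship matrices (CE route).
#' @param T0 Named list of validation coding matrices (QM route).
#' @param samples Optional validation sample identifiers.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `term`, `u` (includes the summed
#'   `"total"` genotypic value per individual).
#' @export
predict.gblup_fit <- function(object, S01 = NULL, T0 = NULL, samples = NULL, ...) {
  if (object$method == "ce") {
    if (is.null(S01)) abort("a CE fit predicts validation individuals from `S01`")
    S01 <- S01[names(object$u)]
    u0 <- purrr::map2(S01, object$epsilon, function(S, e) drop(S %*% e))
  } else {
    if (is.null(T0)) abort("a QM fit predicts validation individuals from `T0`")
    T0 <- T0[names(object$u)]
    u0 <- purrr::map2(T0, object$tau, function(Tm, tv) drop(Tm %*% tv))
  }
  q0 <- length(u0[[1]])
  samples <- samples %||% paste0("val", seq_len(q0))
  purrr::imap_dfr(u0, function(u, nm) {
    tibble::tibble(sample = samples, term = nm, u = as.numeric(u))
  }) |>
    dplyr::bind_rows(tibble::tibble(sample = samples, term = "total",
                                    u = as.numeric(Reduce(`+`, u0))))
}
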