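#' Control settings for EM-GREML
#'
#' @param tol Convergence tolerance: maximum relative change of any variance
#'   component between iterations.
#' @param max_iter Iteration cap; the EM algorithm is reliable but slow.
#' @param floor_frac Lower floor on every component as a fraction of the
#'   phenotypic variance, keeping `lambda_i` finite in the QM updates.
#' @param keep_history Record per-iteration estimates.
#' @return A list of control values.
#' @export
greml_control <- function(tol = 1e-8, max_iter = 10000L, floor_frac = 1e-12,
                          keep_history = TRUE) {
  list(tol = tol, max_iter = as.integer(max_iter), floor_frac = floor_frac,
       keep_history = keep_history)
}

default_start <- function(terms, y) {
  # equal split of the phenotypic variance across all components
  n_comp <- length(terms) + 1L
  rep(var(y), n_comp) / n_comp
}

#' EM-GREML via the conditional-expectation formulation
#'
#' Restricted maximum likelihood estimation of the variance components by
#' the EM-type multiplicative updates
#' `sigma2_i <- sigma2_i * (y' P Z S_i Z' P y) / tr(P Z S_i Z')` and
#' `sigma2_e <- sigma2_e * (y' P P y) / tr(P)`, whose fixed point solves the
#' REML score equations. Every update keeps the estimates nonnegative.
#' A spectral fast path (one genetic term, one observation per individual)
#' diagonalizes `S` once so each iteration costs O(q) instead of O(q^3).
#'
#' @inheritParams gblup_ce
#' @param start Optional positive starting values, ordered as
#'   `c(sigma2 terms, sigma2_e)`; defaults to an equal split of the
#'   phenotypic variance.
#' @param control A [greml_control()] list.
#' @return A `greml_fit`: named `sigma2`, `sigma2_e`, `converged`,
#'   `iterations`, per-iteration `history` tibble (with the monitored REML
#'   log-likelihood), and the inputs needed to refit GBLUP at the estimates.
#' @export
em_reml_ce <- function(y, terms, X = NULL, Z = NULL, start = NULL,
                       control = greml_control()) {
  y <- as.numeric(y); N <- length(y)
  q <- if (is.null(Z)) N else ncol(as.matrix(Z))
  terms <- normalize_terms(terms, q)
  Z <- as_incidence(Z, y, q)
  X <- as_design(X, N)
  start <- start %||% default_start(terms, y)
  if (length(start) != length(terms) + 1L || any(start <= 0)) {
    abort("`start` must give a positive value for every component and the residual")
  }
  floor_val <- control$floor_frac * var(y)

  if (length(terms) == 1L && is.null(Z)) {
    res <- em_ce_spectral(y, terms[[1]]$S, X, start, control, floor_val)
  } else {
    res <- em_ce_dense(y, terms, X, Z, start, control, floor_val)
  }
  new_greml_fit(res, terms, names(terms), "ce", y = y, X = X, Z = Z)
}

em_ce_dense <- function(y, terms, X, Z, start, control, floor_val) {
  N <- length(y)
  ZSZ <- purrr::map(terms, function(tm) Zmult(Z, t(Zmult(Z, tm$S))))
  s2 <- head(start, -1L); s2e <- start[length(start)]
  hist <- list(); conv <- FALSE; it <- 0L
  for (it in seq_len(control$max_iter)) {
    V <- Reduce(`+`, purrr::map2(ZSZ, s2, `*`)) + diag(s2e, N)
    R <- chol(V)
    Vinv <- chol2inv(R)
    if (ncol(X) > 0L) {
      VinvX <- Vinv %*% X
      XtViX <- crossprod(X, VinvX)
      P <- Vinv - VinvX %*% ginv_sym(XtViX) %*% t(VinvX)
      ldX <- sum(log(pmax(eigen(XtViX, symmetric = TRUE,
                                only.values = TRUE)$values, 1e-300)))
    } else {
      P <- Vinv; ldX <- 0
    }
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(R))) + ldX + sum(y * Py))
    new_s2 <- purrr::map2_dbl(ZSZ, s2, function(M, s) {
      s * drop(crossprod(Py, M %*% Py)) / sum(P * M)
    })
    new_s2e <- s2e * sum(Py^2) / sum(diag(P))
    new_s2 <- pmax(new_s2, floor_val); new_s2e <- max(new_s2e, floor_val)
    rel <- max(abs(c(new_s2, new_s2e) - c(s2, s2e)) /
                 pmax(abs(c(s2, s2e)), floor_val))
    if (control$keep_history) hist[[it]] <- c(new_s2, sigma2_e = new_s2e, loglik = ll)
    s2 <- new_s2; s2e <- new_s2e
    if (rel < control$tol) { conv <- TRUE; break }
  }
  list(sigma2 = s2, sigma2_e = s2e, converged = conv, iterations = it,
       history = hist)
}

em_ce_spectral <- function(y, S, X, start, control, floor_val) {
  q <- length(y)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  yt <- drop(crossprod(es$vectors, y))
  Xt <- crossprod(es$vectors, X)
  s2 <- start[1L]; s2e <- start[2L]
  hist <- list(); conv <- FALSE; it <- 0L
  for (it in seq_len(control$max_iter)) {
    d <- 1 / (s2 * lam + s2e)
    if (ncol(Xt) > 0L) {
      Xd <- Xt * d
      A <- crossprod(Xt, Xd)
      Ainv <- ginv_sym(A)
      b <- drop(Ainv %*% crossprod(Xd, yt))
      w <- d * (yt - drop(Xt %*% b))
      tr_PS <- sum(lam * d) - sum(Ainv * crossprod(Xd, Xt * (lam * d)))
      tr_P <- sum(d) - sum(Ainv * crossprod(Xd, Xd))
      ldX <- sum(log(pmax(eigen(A, symmetric = TRUE,
                                only.values = TRUE)$values, 1e-300)))
    } else {
      w <- d * yt
      tr_PS <- sum(lam * d); tr_P <- sum(d); ldX <- 0
    }
    ll <- -0.5 * (-sum(log(d)) + ldX + sum(yt * w))
    new_s2 <- max(s2 * sum(lam * w^2) / tr_PS, floor_val)
    new_s2e <- max(s2e * sum(w^2) / tr_P, floor_val)
    rel <- max(abs(c(new_s2, new_s2e) - c(s2, s2e)) /
                 pmax(abs(c(s2, s2e)), floor_val))
    if (control$keep_history) hist[[it]] <- c(new_s2, sigma2_e = new_s2e, loglik = ll)
    s2 <- new_s2; s2e <- new_s2e
    if (rel < control$tol) { conv <- TRUE; break }
  }
  list(sigma2 = s2, sigma2_e = s2e, converged = conv, iterations = it,
       history = hist)
}

#' EM-GREML via the mixed-model equations
#'
#' The effect-level EM updates
#' `sigma2_i <- tau_i' tau_i / (t_i - lambda_i tr(C^ii))` and
#' `sigma2_e <- e'e / (N - (r - sum_i tr(C^ii) lambda_i))`, with `C^ii` the
#' diagonal blocks of the inverse coefficient matrix after absorbing the
#' fixed effects and `r` the rank of the full mixed-model-equation
#' coefficient matrix. Iterates are identical to those of [em_reml_ce()] on
#' the same data; this route is preferred when effects are fewer than
#' individuals.
#'
#' @inheritParams em_reml_ce
#' @return A `greml_fit`, additionally carrying the final effect solutions
#'   `tau` for per-block heritability partitioning.
#' @export
em_reml_qm <- function(y, terms, X = NULL, Z = NULL, start = NULL,
                       control = greml_control()) {
  y <- as.numeric(y); N <- length(y)
  q <- guess_q(terms, Z, N)
  terms <- normalize_terms(terms, q)
  if (any(purrr::map_lgl(terms, ~ is.null(.x$T)))) {
    abort("the QM route needs the coding matrix `T` of every term")
  }
  Z <- as_incidence(Z, y, q)
  X <- as_design(X, N)
  start <- start %||% default_start(terms, y)
  if (length(start) != length(terms) + 1L || any(start <= 0)) {
    abort("`start` must give a positive value for every component and the residual")
  }
  floor_val <- control$floor_frac * var(y)

  Zg <- do.call(cbind, purrr::map(terms, function(tm) Zmult(Z, tm$T)))
  t_i <- purrr::map_int(terms, ~ ncol(.x$T))
  idx <- split(seq_len(sum(t_i)), rep(seq_along(terms), times = t_i))
  XtX <- crossprod(X)
  XtXinv <- ginv_sym(XtX)
  rank_X <- if (ncol(X) > 0L) qr(X)$rank else 0L
  r_mme <- rank_X + sum(t_i)   # lambda blocks keep the random part full rank
  if (ncol(X) > 0L) {
    MZg <- Zg - X %*% (XtXinv %*% crossprod(X, Zg))
  } else {
    MZg <- Zg
  }
  ZtMZ <- crossprod(Zg, MZg)
  ZtMy <- drop(crossprod(MZg, y))

  s2 <- head(start, -1L); s2e <- start[length(start)]
  hist <- list(); conv <- FALSE; it <- 0L; tau <- NULL
  for (it in seq_len(control$max_iter)) {
    lambda <- s2e / s2
    H <- ZtMZ + diag(rep(lambda, times = t_i), nrow = sum(t_i))
    Hinv <- chol2inv(chol(H))
    tau_all <- drop(Hinv %*% ZtMy)
    tau <- purrr::map(idx, ~ tau_all[.x])
    tr_Cii <- purrr::map_dbl(idx, ~ sum(diag(Hinv)[.x]))
    new_s2 <- purrr::pmap_dbl(list(tau, t_i, lambda, tr_Cii),
                              function(tv, t0, lam, trc) {
                                sum(tv^2) / (t0 - lam * trc)
                              })
    b <- drop(XtXinv %*% crossprod(X, y - Zg %*% tau_all))
    e <- y - drop(Zg %*% tau_all) - if (ncol(X) > 0L) drop(X %*% b) else 0
    new_s2e <- sum(e^2) / (N - (r_mme - sum(lambda * tr_Cii)))
    new_s2 <- pmax(new_s2, floor_val); new_s2e <- max(new_s2e, floor_val)
    rel <- max(abs(c(new_s2, new_s2e) - c(s2, s2e)) /
                 pmax(abs(c(s2, s2e)), floor_val))
    if (control$keep_history) hist[[it]] <- c(new_s2, sigma2_e = new_s2e, loglik = NA_real_)
    s2 <- new_s2; s2e <- new_s2e
    if (rel < control$tol) { conv <- TRUE; break }
  }
  res <- list(sigma2 = s2, sigma2_e = s2e, converged = conv, iterations = it,
              history = hist, tau = setNames(tau, names(terms)))
  new_greml_fit(res, terms, names(terms), "qm", y = y, X = X, Z = Z)
}

new_greml_fit <- function(res, terms, term_names, method, y, X, Z) {
  sigma2 <- setNames(as.numeric(res$sigma2), term_names)
  hist <- if (length(res$history)) {
    hm <- do.call(rbind, res$history)
    colnames(hm) <- c(term_names, "sigma2_e", "loglik")
    tibble::as_tibble(hm) |>
      dplyr::mutate(iteration = dplyr::row_number(), .before = 1L)
  } else {
    tibble::tibble()
  }
  structure(list(
    method = method, sigma2 = sigma2, sigma2_e = res$sigma2_e,
    converged = res$converged, iterations = res$iterations,
    history = hist, tau = res$tau, terms = terms
  ), class = "greml_fit")
}

#' EM-GREML variance-component estimation
#'
#' Front end to the two equivalent EM-GREML routes ([em_reml_ce()],
#' [em_reml_qm()]). `method = "auto"` uses the effect-level (QM) route when
#' every term carries a coding matrix with fewer total effects than
#' individuals, and the covariance-level (CE) route otherwise.
#'
#' @inheritParams em_reml_ce
#' @param method `"auto"`, `"ce"` or `"qm"`.
#' @examples
#' g <- simulate_haplotypes(120, replicate(5, list(
#'   alleles = c("00", "01", "10"), freq = c(0.5, 0.3, 0.2)), simplify = FALSE),
#'   seed = 7)
#' grm <- genomic_relationship(
#'   haplotype_coding(g, enumerate_haplotypes(g, plan_blocks(g, n_snps = 2))))
#' sim <- simulate_phenotypes(grm_terms(grm)["hap_add"], sigma2 = 2,
#'                            sigma2_e = 1, seed = 8)
#' fit <- greml(sim$y, grm_terms(grm)["hap_add"],
#'              control = greml_control(tol = 1e-6, max_iter = 500))
#' tidy(fit)
#' @export
greml <- function(y, terms, X = NULL, Z = NULL, start = NULL,
                  method = c("auto", "ce", "qm"), control = greml_control()) {
  method <- match.arg(method)
  if (method == "auto") {
    q <- if (is.null(Z)) length(y) else ncol(as.matrix(Z))
    tl <- normalize_terms(terms, q)
    have_T <- all(!purrr::map_lgl(tl, ~ is.null(.x$T)))
    n_eff <- sum(purrr::map_int(tl, ~ if (is.null(.x$T)) 0L else ncol(.x$T)))
    method <- if (have_T && q >= n_eff) "qm" else "ce"
  }
  switch(method,
         ce = em_reml_ce(y, terms, X = X, Z = Z, start = start, control = control),
         qm = em_reml_qm(y, terms, X = X, Z = Z, start = start, control = control))
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("<greml_fit> route = %s, %s after %d iteration(s)\n",
              toupper(x$method),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(tidy(x))
  invisible(x)
}

#' @rdname greml
#' @param x,object A `greml_fit`.
#' @param ... Unused.
#' @export
tidy.greml_fit <- function(x, ...) {
  s2y <- sum(x$sigma2) + x$sigma2_e
  tibble::tibble(
    term = c(names(x$sigma2), "residual"),
    sigma2 = c(unname(x$sigma2), x$sigma2_e),
    h2 = c(unname(x$sigma2) / s2y, NA_real_)
  )
}

#' @rdname greml
#' @export
glance.greml_fit <- function(x, ...) {
  s2y <- sum(x$sigma2) + x$sigma2_e
  tibble::tibble(
    sigma2_y = s2y, H2 = sum(x$sigma2) / s2y,
    converged = x$converged, iterations = x$iterations,
    method = x$method
  )
}

#' Convergence trace of an EM-GREML run
#'
#' @param object A `greml_fit` (run with `keep_history = TRUE`).
#' @param ... Unused.
#' @return A ggplot of component estimates against iteration.
#' @export
autoplot.greml_fit <- function(object, ...) {
  if (!nrow(object$history)) abort("no history was recorded for this fit")
  dat <- tidyr::pivot_longer(object$history,
                             cols = -c("iteration", "loglik"),
                             names_to = "component", values_to = "estimate")
  ggplot2::ggplot(dat, ggplot2::aes(.data$iteration, .data$estimate,
                                    colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EM iteration", y = "variance component", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heritability partition from a GREML fit
#'
#' Per-term heritabilities `h2_i = sigma2_i / sigma2_y` (phenotypic variance
#' `sigma2_y = sum_i sigma2_i + sigma2_e`), their total `H2`, and — when the
#' fit carries effect solutions and block assignments — the per-block
#' partition `h2_ij = (tau_ij' tau_ij / tau_i' tau_i) h2_i`, whose block
#' shares sum exactly to each term's heritability.
#'
#' @param fit A `greml_fit` (per-block partition needs the QM route, whose
#'   `tau` is retained) or, alternatively, a named `sigma2` vector plus
#'   `sigma2_e`.
#' @param sigma2_e Residual variance when `fit` is a plain vector.
#' @param tau Optional named list of effect vectors (overrides the fit's).
#' @param blocks Optional named list of per-effect block assignments
#'   (overrides the terms').
#' @return List with `terms` (tibble: term, sigma2, h2), `H2`, and `blocks`
#'   (tibble: term, block, share, h2; `NULL` when no effect-level
#'   information is available).
#' @export
heritabilities <- function(fit, sigma2_e = NULL, tau = NULL, blocks = NULL) {
  if (inherits(fit, "greml_fit")) {
    sigma2 <- fit$sigma2
    sigma2_e <- fit$sigma2_e
    tau <- tau %||% fit$tau
    blocks <- blocks %||% purrr::map(fit$terms, "blocks")
  } else {
    sigma2 <- fit
    if (is.null(sigma2_e)) abort("supply `sigma2_e` with a plain `sigma2` vector")
  }
  s2y <- sum(sigma2) + sigma2_e
  if (s2y <= 0) abort("phenotypic variance is zero; heritabilities undefined")
  terms_tbl <- tibble::tibble(
    term = names(sigma2) %||% paste0("term", seq_along(sigma2)),
    sigma2 = as.numeric(sigma2),
    h2 = as.numeric(sigma2) / s2y
  )
  block_tbl <- NULL
  if (!is.null(tau)) {
    block_tbl <- purrr::imap(tau, function(tv, nm) {
      bl <- blocks[[nm]]
      if (is.null(bl)) return(NULL)
      tot <- sum(tv^2)
      if (tot == 0) return(NULL)
      share <- tapply(tv^2, bl, sum) / tot
      tibble::tibble(term = nm, block = names(share),
                     share = as.numeric(share),
                     h2 = as.numeric(share) * terms_tbl$h2[terms_tbl$term == nm])
    }) |> purrr::compact()
    block_tbl <- if (length(block_tbl)) dplyr::bind_rows(block_tbl) else NULL
  }
  list(terms = terms_tbl, H2 = sum(terms_tbl$h2), blocks = block_tbl)
}
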