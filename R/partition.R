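#' Allelic means of a multi-allelic locus
#'
#' The allelic mean of allele `i` is the frequency-weighted average of the
#' genotypic values of all genotypes carrying `i`, which under HWE reduces to
#' `mu_i = sum_j p_j g_ij`.
#'
#' @param spec A [locus_spec()].
#' @return Named numeric vector of `h` allelic means.
#' @export
allelic_means <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  g <- spec$g
  for (i in seq_len(spec$h)) {
    miss <- which(is.na(g[i, ]))
    if (length(miss)) {
      abort(sprintf(
        "allelic mean of allele %s needs genotypic value for pair %s",
        spec$alleles[i], pair_label(i, miss[1L], spec$alleles)))
    }
  }
  setNames(as.numeric(g %*% spec$p), spec$alleles)
}

#' Population mean of genotypic values
#'
#' HWE mean of all genotypic values,
#' `mu = sum_i p_i^2 g_ii + 2 sum_{i<j} p_i p_j g_ij`, equivalently the
#' frequency-weighted mean of the allelic means.
#'
#' @inheritParams allelic_means
#' @return Scalar population mean.
#' @export
population_mean <- function(spec) {
  sum(spec$p * allelic_means(spec))
}

#' Additive effects (average effects of gene substitution)
#'
#' Returns the `h - 1` independent additive effects against the reference
#' allele: `alpha_1k = mu_1 - mu_k` for each non-reference allele `k`, where
#' allele 1 denotes the reference (most frequent) allele. Any other pairwise
#' substitution effect is the difference of two of these.
#'
#' @inheritParams allelic_means
#' @return Named numeric vector of length `h - 1` (empty for a monomorphic
#'   locus), named `"ref/k"` by allele labels.
#' @export
additive_effects <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  if (spec$h < 2L) return(setNames(numeric(0), character(0)))
  mu_i <- allelic_means(spec)
  r <- spec$ref_allele
  k <- setdiff(seq_len(spec$h), r)
  setNames(mu_i[r] - mu_i[k], paste0(spec$alleles[r], "/", spec$alleles[k]))
}

#' Dominance effects of heterozygous genotypes
#'
#' The dominance effect of heterozygote `(k, f)` is the deviation of its
#' genotypic value from the mean of the two corresponding homozygotes:
#' `delta_kf = g_kf - (g_kk + g_ff) / 2`. A homozygote has no dominance
#' effect, so only the h(h-1)/2 heterozygote pairs are returned. Pairs for
#' which any of the three required genotypic values is missing are flagged
#' `NA` (and are dropped from dominance coding downstream) rather than
#' raising an error.
#'
#' @inheritParams allelic_means
#' @return Tibble with columns `k`, `f` (allele indices, `k < f`), `pair`
#'   (label) and `delta` (possibly `NA`).
#' @export
dominance_effects <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  hp <- het_pairs(spec$h)
  g <- spec$g
  delta <- g[cbind(hp$k, hp$f)] - 0.5 * (diag(g)[hp$k] + diag(g)[hp$f])
  tibble::tibble(
    k = hp$k, f = hp$f,
    pair = pair_label(hp$k, hp$f, spec$alleles),
    delta = as.numeric(delta)
  )
}

#' Additive coding of a genotype for one additive effect
#'
#' Frequency-dependent regression weight linking the breeding value of
#' genotype `(i, j)` to the additive effect of non-reference allele `k`:
#' `2 p_k` when the genotype does not carry `k`; `-(1 - 2 p_k)` when it
#' carries one copy; `-2 (1 - p_k)` when homozygous for `k`.
#'
#' @param i,j Allele indices of the genotype (unordered; vectors recycle).
#' @param k Index of the effect (non-reference) allele.
#' @param p Allele frequency vector.
#' @param ref_allele Index of the reference allele; `k` must differ from it.
#' @return Numeric coding value(s).
#' @export
additive_coding <- function(i, j, k, p, ref_allele = which.max(p)) {
  if (any(k == ref_allele)) {
    abort("additive effects are defined against the reference allele; `k` must differ from it")
  }
  n <- max(length(i), length(j), length(k))
  i <- rep_len(i, n); j <- rep_len(j, n); k <- rep_len(k, n)
  copies <- (i == k) + (j == k)
  pk <- p[k]
  out <- 2 * pk                         # genotype and effect share no allele
  out[copies == 1L] <- -(1 - 2 * pk[copies == 1L])
  out[copies == 2L] <- -2 * (1 - pk[copies == 2L])
  out
}

#' Dominance coding of a genotype for one dominance effect
#'
#' Frequency-dependent regression weight linking the dominance deviation of
#' genotype `(i, j)` to the dominance effect of heterozygote pair `(k, f)`.
#' The five cases depend on how many alleles the genotype shares with the
#' effect pair: two shared (`{i,j} = {k,f}`); one shared with `i != j`; one
#' shared with `i = j`; or none.
#'
#' @param i,j Allele indices of the genotype (unordered; vectors recycle).
#' @param k,f Allele indices of the dominance-effect pair, `k != f`.
#' @param p Allele frequency vector.
#' @return Numeric coding value(s).
#' @export
dominance_coding <- function(i, j, k, f, p) {
  if (any(k == f)) abort("a dominance effect belongs to a heterozygote pair: `k` and `f` must differ")
  n <- max(length(i), length(j), length(k), length(f))
  i <- rep_len(i, n); j <- rep_len(j, n)
  k <- rep_len(k, n); f <- rep_len(f, n)
  i_in <- i == k | i == f
  j_in <- j == k | j == f
  # shared genotype allele (when exactly one is shared) and the effect pair's
  # non-shared member
  s <- ifelse(i_in, i, j)
  ns <- ifelse(s == k, f, k)
  out <- 2 * p[k] * p[f]                                  # no shared allele
  one <- xor(i_in, j_in) | (i == j & i_in)
  het1 <- one & i != j
  hom1 <- one & i == j
  out[het1] <- -p[ns[het1]] * (1 - 2 * p[s[het1]])        # one shared, het
  out[hom1] <- -2 * p[ns[hom1]] * (1 - p[s[hom1]])        # one shared, hom
  both <- i != j & i_in & j_in
  out[both] <- 1 - p[i[both]] * (1 - p[j[both]]) - p[j[both]] * (1 - p[i[both]])
  out
}

# Additive coding matrix: one row per genotype, one column per
# non-reference allele (in allele-index order).
locus_W_alpha <- function(spec, geno = genotype_pairs(spec$h)) {
  if (spec$h < 2L) {
    return(matrix(0, nrow(geno), 0,
                  dimnames = list(pair_label(geno$i, geno$j, spec$alleles), NULL)))
  }
  ks <- setdiff(seq_len(spec$h), spec$ref_allele)
  W <- vapply(ks, function(k) {
    additive_coding(geno$i, geno$j, k, spec$p, spec$ref_allele)
  }, numeric(nrow(geno)))
  W <- matrix(W, nrow = nrow(geno),
              dimnames = list(pair_label(geno$i, geno$j, spec$alleles),
                              paste0("alpha_", spec$alleles[spec$ref_allele],
                                     "/", spec$alleles[ks])))
  W
}

# Dominance coding matrix: one row per genotype, one column per heterozygote
# effect pair (canonical k < f order); `pairs` may restrict the columns.
locus_W_delta <- function(spec, geno = genotype_pairs(spec$h),
                          pairs = het_pairs(spec$h)) {
  if (nrow(pairs) == 0L) {
    return(matrix(0, nrow(geno), 0,
                  dimnames = list(pair_label(geno$i, geno$j, spec$alleles), NULL)))
  }
  W <- matrix(0, nrow(geno), nrow(pairs),
              dimnames = list(pair_label(geno$i, geno$j, spec$alleles),
                              paste0("delta_", pair_label(pairs$k, pairs$f,
                                                          spec$alleles))))
  for (c0 in seq_len(nrow(pairs))) {
    W[, c0] <- dominance_coding(geno$i, geno$j, pairs$k[c0], pairs$f[c0], spec$p)
  }
  W
}

#' Partition genotypic values into additive and dominance components
#'
#' Decomposes the genotypic values of a multi-allelic locus as
#' `g_ij = mu + a_ij + d_ij` under HWE: `mu` the population mean, `a_ij`
#' the breeding value (sum of the two allelic effects) and `d_ij` the
#' dominance deviation. Additive and dominance values are computed twice,
#' directly from the allelic means and as coding-matrix products
#' `W_alpha %*% alpha` and `W_delta %*% delta`; the two routes must agree,
#' which validates the factorization on every call. HWE variances
#' `var_g = var_a + var_d` are returned.
#'
#' @inheritParams allelic_means
#' @param tol Relative tolerance for the factorization cross-check.
#' @return Object of class `hap_partition`: list with `mu`, `allelic_means`,
#'   `alpha`, `delta` (tibble), `genotypes` (tibble with frequencies,
#'   `g`, `a`, `d`), `W_alpha`, `W_delta`, `var_g`, `var_a`, `var_d`, `spec`.
#' @examples
#' part <- partition_locus(example_locus())
#' part$mu
#' tidy(part)
#' @export
partition_locus <- function(spec, tol = 1e-9) {
  stopifnot(inherits(spec, "locus_spec"))
  h <- spec$h
  p <- spec$p
  mu_i <- allelic_means(spec)
  mu <- sum(p * mu_i)
  alpha <- additive_effects(spec)
  delta <- dominance_effects(spec)

  geno <- genotype_pairs(h)
  a_direct <- (mu_i[geno$i] - mu) + (mu_i[geno$j] - mu)
  g_vals <- spec$g[cbind(geno$i, geno$j)]
  d_direct <- g_vals - mu - a_direct

  W_alpha <- locus_W_alpha(spec, geno)
  W_delta <- locus_W_delta(spec, geno)
  if (h >= 2L) {
    a_fact <- as.numeric(W_alpha %*% alpha)
    scale_a <- max(abs(a_direct), 1)
    if (max(abs(a_fact - a_direct)) > tol * scale_a) {
      abort("internal error: additive factorization disagrees with direct partition")
    }
    ok <- !is.na(delta$delta)
    if (all(ok)) {
      d_fact <- as.numeric(W_delta %*% delta$delta)
      scale_d <- max(abs(d_direct), 1)
      if (max(abs(d_fact - d_direct)) > tol * scale_d) {
        abort("internal error: dominance factorization disagrees with direct partition")
      }
    }
  }

  freq <- ifelse(geno$i == geno$j, p[geno$i]^2, 2 * p[geno$i] * p[geno$j])
  # HWE second moments over ordered genotypes (off-diagonal pairs count twice)
  var_g <- sum(freq * g_vals^2, na.rm = TRUE) - mu^2
  var_a <- sum(freq * a_direct^2)
  var_d <- sum(freq * d_direct^2, na.rm = TRUE)

  structure(list(
    spec = spec,
    mu = mu,
    allelic_means = mu_i,
    alpha = alpha,
    delta = delta,
    genotypes = tibble::tibble(
      i = geno$i, j = geno$j,
      genotype = pair_label(geno$i, geno$j, spec$alleles),
      frequency = freq, g = g_vals,
      a = as.numeric(a_direct), d = as.numeric(d_direct)
    ),
    W_alpha = W_alpha,
    W_delta = W_delta,
    var_g = var_g, var_a = var_a, var_d = var_d
  ), class = "hap_partition")
}

#' @export
print.hap_partition <- function(x, ...) {
  cat(sprintf("<hap_partition> h = %d, mu = %.4f\n", x$spec$h, x$mu))
  cat(sprintf("variances: g %.4f = a %.4f + d %.4f\n", x$var_g, x$var_a, x$var_d))
  print(x$genotypes)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname partition_locus
#' @param x A `hap_partition` object.
#' @param ... Unused.
#' @export
tidy.hap_partition <- function(x, ...) x$genotypes

#' @rdname partition_locus
#' @export
glance.hap_partition <- function(x, ...) {
  tibble::tibble(
    h = x$spec$h, mu = x$mu,
    var_g = x$var_g, var_a = x$var_a, var_d = x$var_d
  )
}

#' Plot a locus partition
#'
#' Bar chart of the additive and dominance components of each genotypic
#' value, centered on the population mean.
#'
#' @param object A `hap_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_partition <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$genotypes, cols = c("a", "d"),
                             names_to = "component", values_to = "value")
  dat$component <- dplyr::recode(dat$component, a = "additive", d = "dominance")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$genotype, y = .data$value,
                                    fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "genotype", y = "deviation from population mean",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
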