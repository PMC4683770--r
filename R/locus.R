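#' Specify a multi-allelic locus
#'
#' A locus here is any genetic unit with `h` alleles: a single SNP (`h = 2`),
#' a multi-allelic marker, or a haplotype block in which each distinct
#' haplotype is treated as an allele. A locus specification couples the allele
#' frequencies with the genotypic values of the h(h+1)/2 unordered genotypes;
#' Hardy-Weinberg equilibrium is assumed whenever the frequencies are used to
#' weight genotypes.
#'
#' @param p Numeric vector of allele frequencies (nonnegative, summing to 1).
#' @param g Symmetric `h x h` matrix of genotypic values, `g[i, j]` the value
#'   of the unordered genotype carrying alleles `i` and `j`. Values may be
#'   `NA`; operations state individually how missing values are handled.
#'   A vector of length h(h+1)/2 in the order of [genotypes()] (homozygotes
#'   `1..h`, then heterozygotes `1/2, 1/3, ...`) is also accepted.
#' @param alleles Optional character labels for the alleles.
#' @param ref_allele Index of the reference allele ("allele 1" of the additive
#'   effects). Defaults to the most frequent allele; ties are broken by the
#'   allele whose label sorts first (by index when labels are absent).
#' @param tol Tolerance for the frequency simplex check.
#'
#' @return An object of class `locus_spec`: a list with elements `h`, `p`,
#'   `g`, `alleles`, `ref_allele`.
#' @examples
#' locus_spec(p = c(0.7, 0.3), g = matrix(c(1, 0.5, 0.5, -1), 2, 2))
#' @export
locus_spec <- function(p, g, alleles = NULL, ref_allele = NULL, tol = 1e-8) {
  p <- as.numeric(p)
  h <- length(p)
  if (h < 1L) abort("at least one allele is required")
  check_simplex(p, tol = tol, what = "allele frequencies")
  if (!is.matrix(g)) {
    gp <- genotype_pairs(h)
    if (length(g) != nrow(gp)) {
      abort(sprintf("`g` must be an %d x %d matrix or a vector of length %d",
                    h, h, nrow(gp)))
    }
    gm <- matrix(NA_real_, h, h)
    gm[cbind(gp$i, gp$j)] <- g
    gm[cbind(gp$j, gp$i)] <- g
    g <- gm
  }
  if (!all(dim(g) == c(h, h))) {
    abort(sprintf("`g` must be %d x %d to match %d allele frequencies", h, h, h))
  }
  if (!isTRUE(all.equal(g, t(g)))) abort("`g` must be symmetric (g_ij = g_ji)")
  g <- (g + t(g)) / 2
  if (is.null(alleles)) {
    alleles <- as.character(seq_len(h))
  } else if (length(alleles) != h) {
    abort("`alleles` must have one label per allele")
  }
  if (is.null(ref_allele)) {
    tied <- which(p >= max(p) - tol)
    ref_allele <- tied[order(alleles[tied])][1L]
  }
  ref_allele <- as.integer(ref_allele)
  if (ref_allele < 1L || ref_allele > h) abort("`ref_allele` out of range")
  structure(
    list(h = h, p = p, g = g, alleles = alleles, ref_allele = ref_allele),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> %d allele(s), reference allele %s\n",
              x$h, x$alleles[x$ref_allele]))
  cat("frequencies:", paste(format(x$p), collapse = " "), "\n")
  invisible(x)
}

#' Allele frequencies from genotype frequencies
#'
#' Recovers allele frequencies from a table of unordered-genotype frequencies:
#' each allele receives the full frequency of its homozygote plus half of each
#' heterozygote that carries it.
#'
#' @param P Symmetric `h x h` matrix; `P[i, j]` (with the two mirror entries
#'   holding the same number) is the frequency of the unordered genotype
#'   carrying alleles `i` and `j`. The diagonal plus the upper triangle must
#'   sum to 1.
#' @param tol Validation tolerance.
#' @return Numeric vector of `h` allele frequencies, summing to 1.
#' @examples
#' P <- matrix(c(0.25, 0.25, 0.25, 0.25), 2, 2)  # HWE at p = 0.5
#' allele_frequencies(P)
#' @export
allele_frequencies <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) abort("`P` must be a square matrix")
  if (!isTRUE(all.equal(P, t(P), tolerance = tol))) abort("`P` must be symmetric")
  if (any(P < -tol)) abort("genotype frequencies must be nonnegative")
  tot <- sum(diag(P)) + sum(P[upper.tri(P)])
  if (abs(tot - 1) > tol) {
    abort(sprintf("genotype frequencies must sum to 1 (got %.10g)", tot))
  }
  p <- diag(P) + 0.5 * (rowSums(P) - diag(P))
  as.numeric(p / sum(p))
}

#' HWE genotype frequencies from allele frequencies
#'
#' @param p Allele frequency vector.
#' @return Symmetric matrix with `p_i^2` on the diagonal and the full
#'   unordered-heterozygote frequency `2 p_i p_j` in both mirror entries.
#' @export
hwe_genotype_frequencies <- function(p) {
  check_simplex(p)
  P <- 2 * outer(p, p)
  diag(P) <- p^2
  P
}

#' The packaged four-haplotype example locus
#'
#' Loads the small worked example shipped with the package: a haplotype block
#' with four haplotypes at frequencies 0.4, 0.3, 0.2, 0.1 and ten assigned
#' genotypic values. Useful for illustrating the additive/dominance partition.
#'
#' @return A [locus_spec()].
#' @examples
#' partition_locus(example_locus())
#' @export
example_locus <- function() {
  freq <- readr::read_tsv(
    system.file("extdata", "example_block_frequencies.tsv", package = "haplopart"),
    show_col_types = FALSE
  )
  vals <- readr::read_tsv(
    system.file("extdata", "example_block_values.tsv", package = "haplopart"),
    show_col_types = FALSE
  )
  h <- nrow(freq)
  g <- matrix(NA_real_, h, h)
  ii <- match(vals$allele1, freq$haplotype)
  jj <- match(vals$allele2, freq$haplotype)
  g[cbind(ii, jj)] <- vals$value
  g[cbind(jj, ii)] <- vals$value
  locus_spec(p = freq$frequency, g = g, alleles = as.character(freq$haplotype))
}
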