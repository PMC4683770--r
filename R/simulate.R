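#' Simulate a Hardy-Weinberg haplotype population
#'
#' Each individual draws its two haplotypes per block independently from the
#' block's haplotype frequency spectrum, so genotype frequencies are HWE
#' products of haplotype frequencies by construction. Blocks are simulated
#' unlinked.
#'
#' @param q Number of individuals.
#' @param blocks List of block spectra, each a list with `alleles`
#'   (character haplotype strings over the block's SNPs, all the same
#'   length) and `freq` (simplex of the same length).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A [phased_genotypes()] object; the blocks occupy consecutive
#'   SNP positions in order.
#' @examples
#' g <- simulate_haplotypes(10, list(list(alleles = c("00", "01", "10", "11"),
#'                                        freq = c(0.4, 0.3, 0.2, 0.1))),
#'                          seed = 1)
#' @export
simulate_haplotypes <- function(q, blocks, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  set.seed(as.integer(seed))
  hap1_cols <- list(); hap2_cols <- list()
  for (bl in blocks) {
    alleles <- as.character(bl$alleles)
    check_simplex(bl$freq, what = "haplotype frequencies")
    if (length(alleles) != length(bl$freq)) {
      abort("each block needs one frequency per haplotype string")
    }
    L <- unique(nchar(alleles))
    if (length(L) != 1L) abort("haplotype strings within a block must have equal length")
    i1 <- sample.int(length(alleles), q, replace = TRUE, prob = bl$freq)
    i2 <- sample.int(length(alleles), q, replace = TRUE, prob = bl$freq)
    split_mat <- function(idx) {
      m <- matrix(as.integer(unlist(strsplit(alleles[idx], ""), use.names = FALSE)),
                  nrow = q, byrow = TRUE)
      m
    }
    hap1_cols[[length(hap1_cols) + 1L]] <- split_mat(i1)
    hap2_cols[[length(hap2_cols) + 1L]] <- split_mat(i2)
  }
  phased_genotypes(do.call(cbind, hap1_cols), do.call(cbind, hap2_cols))
}

#' Simulate a Mendelian pedigree at unlinked SNPs
#'
#' Founders draw haplotypes gamete-wise from per-SNP allele frequencies
#' (HWE); each offspring receives, independently at every SNP, one allele
#' drawn at random from each parent's two alleles (unlinked loci, no
#' recombination map needed). Pair labels are returned for averaging
#' genomic relationships by relationship class.
#'
#' @param n_families Number of independent families.
#' @param m Number of unlinked bi-allelic SNPs.
#' @param design `"nuclear"` (sire + dam + `n_offspring` full sibs; yields
#'   parent-offspring and full-sib pairs) or `"half_sib"` (one sire, two
#'   dams, one offspring each; yields half-sib pairs).
#' @param n_offspring Offspring per couple under the nuclear design.
#' @param p Per-SNP allele frequencies; defaults to uniform draws on
#'   `freq_range`.
#' @param freq_range Range of the uniform frequency draw.
#' @param n_unrelated_pairs Number of across-family pairs labelled
#'   `"unrelated"` (sampled without replacement among founders).
#' @param seed Integer seed (required).
#' @return List with `geno` (a [phased_genotypes()]), `pairs` (tibble
#'   `id1`, `id2`, `relationship`) and `roles` (tibble `sample`, `role`,
#'   `family`).
#' @export
simulate_pedigree <- function(n_families, m, design = c("nuclear", "half_sib"),
                              n_offspring = 1L, p = NULL,
                              freq_range = c(0.1, 0.9),
                              n_unrelated_pairs = n_families, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  design <- match.arg(design)
  set.seed(as.integer(seed))
  p <- p %||% runif(m, freq_range[1L], freq_range[2L])
  if (length(p) != m) abort("`p` must give a frequency per SNP")

  draw_founder <- function() {
    list(h1 = rbinom(m, 1L, p), h2 = rbinom(m, 1L, p))
  }
  mate <- function(par1, par2) {
    pick1 <- runif(m) < 0.5
    pick2 <- runif(m) < 0.5
    list(h1 = ifelse(pick1, par1$h1, par1$h2),
         h2 = ifelse(pick2, par2$h1, par2$h2))
  }

  inds <- list(); roles <- list(); pairs <- list()
  add_ind <- function(hap, name, role, fam) {
    inds[[name]] <<- hap
    roles[[length(roles) + 1L]] <<- tibble::tibble(sample = name, role = role,
                                                   family = fam)
  }
  for (fam in seq_len(n_families)) {
    if (design == "nuclear") {
      sire <- draw_founder(); dam <- draw_founder()
      sid <- sprintf("f%d_sire", fam); did <- sprintf("f%d_dam", fam)
      add_ind(sire, sid, "founder", fam); add_ind(dam, did, "founder", fam)
      kids <- character(n_offspring)
      for (o in seq_len(n_offspring)) {
        kid <- mate(sire, dam)
        kids[o] <- sprintf("f%d_o%d", fam, o)
        add_ind(kid, kids[o], "offspring", fam)
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          id1 = c(sid, did), id2 = kids[o], relationship = "parent_offspring")
      }
      if (n_offspring >= 2L) {
        cmb <- utils::combn(kids, 2L)
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          id1 = cmb[1L, ], id2 = cmb[2L, ], relationship = "full_sib")
      }
    } else {
      sire <- draw_founder(); dam1 <- draw_founder(); dam2 <- draw_founder()
      sid <- sprintf("f%d_sire", fam)
      add_ind(sire, sid, "founder", fam)
      add_ind(dam1, sprintf("f%d_dam1", fam), "founder", fam)
      add_ind(dam2, sprintf("f%d_dam2", fam), "founder", fam)
      k1 <- sprintf("f%d_o1", fam); k2 <- sprintf("f%d_o2", fam)
      add_ind(mate(sire, dam1), k1, "offspring", fam)
      add_ind(mate(sire, dam2), k2, "offspring", fam)
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        id1 = k1, id2 = k2, relationship = "half_sib")
    }
  }
  roles <- dplyr::bind_rows(roles)
  founders <- roles$sample[roles$role == "founder"]
  if (n_unrelated_pairs > 0L && length(unique(roles$family)) > 1L) {
    fam_of <- setNames(roles$family, roles$sample)
    for (u in seq_len(n_unrelated_pairs)) {
      cand <- sample(founders, 2L)
      while (fam_of[cand[1L]] == fam_of[cand[2L]]) cand <- sample(founders, 2L)
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        id1 = cand[1L], id2 = cand[2L], relationship = "unrelated")
    }
  }
  nm <- names(inds)
  hap1 <- do.call(rbind, purrr::map(inds, "h1"))
  hap2 <- do.call(rbind, purrr::map(inds, "h2"))
  list(
    geno = phased_genotypes(hap1, hap2, samples = nm),
    pairs = dplyr::bind_rows(pairs),
    roles = roles
  )
}

#' Average genomic relationship by relationship class
#'
#' @param S Relationship matrix with sample dimnames.
#' @param pairs Tibble with `id1`, `id2`, `relationship` (as from
#'   [simulate_pedigree()]).
#' @return Tibble with per-class mean, standard deviation, pair count and
#'   Monte-Carlo standard error of the mean.
#' @export
relationship_means <- function(S, pairs) {
  v <- S[cbind(match(pairs$id1, rownames(S)), match(pairs$id2, colnames(S)))]
  tibble::tibble(relationship = pairs$relationship, value = v) |>
    dplyr::group_by(.data$relationship) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), se = .data$sd / sqrt(.data$n),
                     .groups = "drop")
}

#' Simulate phenotypes under the haplotype mixed model
#'
#' Draws each effect vector `tau_i` iid Gaussian with variance `sigma2_i`,
#' forms genetic values `u_i = T_i tau_i`, and returns
#' `y = X b + Z sum_i u_i + e` with residual variance `sigma2_e`, along with
#' the true effects and genetic values for recovery scoring.
#'
#' @param terms Named list of [genetic_term()]s or `T` matrices.
#' @param sigma2 Named vector of true variances, one per term.
#' @param sigma2_e True residual variance.
#' @param X,b Optional fixed-effect design and coefficients.
#' @param Z Optional N x q incidence matrix (default one record each).
#' @param seed Integer seed (required).
#' @return List with `y`, `tau` (list), `u` (list), `g` (summed genetic
#'   values), `e`.
#' @export
simulate_phenotypes <- function(terms, sigma2, sigma2_e, X = NULL, b = NULL,
                                Z = NULL, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  set.seed(as.integer(seed))
  q <- if (is.null(Z)) NULL else ncol(as.matrix(Z))
  terms <- normalize_terms(terms, q %||% nrow(
    (terms[[1]]$T %||% terms[[1]]$S) %||% terms[[1]]))
  if (any(purrr::map_lgl(terms, ~ is.null(.x$T)))) {
    abort("phenotype simulation draws effect vectors and needs `T` for every term")
  }
  sigma2 <- match_sigma2(sigma2, terms)
  qn <- nrow(terms[[1]]$T)
  N <- if (is.null(Z)) qn else nrow(as.matrix(Z))
  tau <- purrr::map2(terms, sigma2, function(tm, s2) {
    rnorm(ncol(tm$T), sd = sqrt(s2))
  })
  u <- purrr::map2(terms, tau, function(tm, tv) drop(tm$T %*% tv))
  g <- Reduce(`+`, u)
  e <- rnorm(N, sd = sqrt(sigma2_e))
  fixed <- if (!is.null(X)) drop(as.matrix(X) %*% b) else 0
  y <- fixed + drop(Zmult(Z, g)) + e
  list(y = as.numeric(y), tau = tau, u = u, g = g, e = e)
}
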