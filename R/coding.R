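#' Enumerate haplotype alleles within blocks
#'
#' Treats each haplotype block as a multi-allelic locus: the distinct phased
#' allele strings observed within a block are its 'alleles'. Alleles are
#' indexed in lexicographic string order; frequencies default to sample
#' haplotype counts over the `2q` chromosomes; the reference allele of each
#' block is its most frequent allele (ties to the string that sorts first).
#'
#' @param geno A [phased_genotypes()] object (the training population when
#'   the catalog is reused for validation coding).
#' @param plan A [plan_blocks()] block plan.
#' @param freq Optional list of frequency vectors, one per block, overriding
#'   the sample estimates (must match each block's allele catalog length).
#' @return Object of class `hap_catalog`: per block, the haplotype strings,
#'   frequencies, reference allele, heterozygote effect pairs observed, and
#'   each individual's unordered allele pair.
#' @export
enumerate_haplotypes <- function(geno, plan, freq = NULL) {
  stopifnot(inherits(geno, "phased_geno"), inherits(plan, "block_plan"))
  q <- nrow(geno$hap1)
  blocks <- purrr::imap(plan, function(snps, nm) {
    s1 <- apply(geno$hap1[, snps, drop = FALSE], 1L, paste0, collapse = "")
    s2 <- apply(geno$hap2[, snps, drop = FALSE], 1L, paste0, collapse = "")
    alleles <- sort(unique(c(s1, s2)))
    h <- length(alleles)
    i1 <- match(s1, alleles)
    i2 <- match(s2, alleles)
    p <- as.numeric(tabulate(c(i1, i2), nbins = h) / (2L * q))
    list(snps = snps, alleles = alleles, h = h, freq = p,
         pair1 = pmin(i1, i2), pair2 = pmax(i1, i2))
  })
  if (!is.null(freq)) {
    if (length(freq) != length(blocks)) abort("`freq` must supply one vector per block")
    for (b in seq_along(blocks)) {
      if (length(freq[[b]]) != blocks[[b]]$h) {
        abort(sprintf("block %d: %d frequencies supplied for %d observed haplotypes",
                      b, length(freq[[b]]), blocks[[b]]$h))
      }
      check_simplex(freq[[b]], what = sprintf("block %d haplotype frequencies", b))
      blocks[[b]]$freq <- as.numeric(freq[[b]])
    }
  }
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    tied <- which(bl$freq >= max(bl$freq) - 1e-12)
    blocks[[b]]$ref <- tied[order(bl$alleles[tied])][1L]
    het <- unique(cbind(bl$pair1, bl$pair2)[bl$pair1 != bl$pair2, , drop = FALSE])
    het <- het[order(het[, 1L], het[, 2L]), , drop = FALSE]
    blocks[[b]]$het_pairs <- het
  }
  structure(list(blocks = blocks, samples = geno$samples),
            class = "hap_catalog")
}

#' @export
print.hap_catalog <- function(x, ...) {
  hs <- vapply(x$blocks, function(b) b$h, integer(1))
  cat(sprintf("<hap_catalog> %d block(s), %d-%d haplotypes per block\n",
              length(x$blocks), min(hs), max(hs)))
  invisible(x)
}

# Map a (possibly new) population onto an existing catalog. Haplotypes
# absent from the catalog carry no estimable effect and are coded as the
# block's reference allele, with a warning.
project_pairs <- function(geno, catalog) {
  q <- nrow(geno$hap1)
  unseen <- 0L
  blocks <- lapply(catalog$blocks, function(bl) {
    s1 <- apply(geno$hap1[, bl$snps, drop = FALSE], 1L, paste0, collapse = "")
    s2 <- apply(geno$hap2[, bl$snps, drop = FALSE], 1L, paste0, collapse = "")
    i1 <- match(s1, bl$alleles)
    i2 <- match(s2, bl$alleles)
    miss <- is.na(i1) | is.na(i2)
    if (any(miss)) {
      unseen <<- unseen + sum(is.na(i1)) + sum(is.na(i2))
      i1[is.na(i1)] <- bl$ref
      i2[is.na(i2)] <- bl$ref
    }
    bl$pair1 <- pmin(i1, i2)
    bl$pair2 <- pmax(i1, i2)
    bl
  })
  if (unseen > 0L) {
    warn(sprintf(
      "%d haplotype(s) not present in the training catalog were coded as the reference allele",
      unseen))
  }
  blocks
}

#' Haplotype additive and dominance coding matrices
#'
#' Builds the genome-wide coding matrices of the haplotype mixed model: for
#' each individual, the additive coding row over every non-reference
#' haplotype of every block and the dominance coding row over every
#' heterozygote pair observed in the catalog population. Frequencies are the
#' catalog's (training) frequencies, so validation individuals are coded
#' consistently against the training population.
#'
#' @param geno A [phased_genotypes()] object to code (training or
#'   validation individuals).
#' @param catalog A [enumerate_haplotypes()] catalog defining alleles,
#'   frequencies, reference alleles and dominance columns.
#' @return Object of class `hap_coding`: list with `W_alpha` (q x n_alpha),
#'   `W_delta` (q x n_delta), per-column block indices `alpha_block` and
#'   `delta_block`, and `samples`. Monomorphic blocks contribute no columns.
#' @export
haplotype_coding <- function(geno, catalog) {
  stopifnot(inherits(geno, "phased_geno"), inherits(catalog, "hap_catalog"))
  blocks <- project_pairs(geno, catalog)
  q <- nrow(geno$hap1)
  Wa_list <- list(); Wd_list <- list()
  a_block <- integer(0); d_block <- integer(0)
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    if (bl$h < 2L) next
    spec_b <- list(h = bl$h, p = bl$freq, ref_allele = bl$ref,
                   alleles = bl$alleles)
    geno_tbl <- tibble::tibble(i = bl$pair1, j = bl$pair2)
    ks <- setdiff(seq_len(bl$h), bl$ref)
    Wa <- vapply(ks, function(k) {
      additive_coding(geno_tbl$i, geno_tbl$j, k, bl$freq, bl$ref)
    }, numeric(q))
    Wa <- matrix(Wa, nrow = q)
    colnames(Wa) <- paste0("b", b, ".a.", bl$alleles[ks])
    Wa_list[[length(Wa_list) + 1L]] <- Wa
    a_block <- c(a_block, rep(b, ncol(Wa)))
    if (nrow(bl$het_pairs) > 0L) {
      Wd <- matrix(0, q, nrow(bl$het_pairs))
      for (c0 in seq_len(nrow(bl$het_pairs))) {
        Wd[, c0] <- dominance_coding(geno_tbl$i, geno_tbl$j,
                                     bl$het_pairs[c0, 1L], bl$het_pairs[c0, 2L],
                                     bl$freq)
      }
      colnames(Wd) <- paste0("b", b, ".d.", bl$het_pairs[, 1L], "_",
                             bl$het_pairs[, 2L])
      Wd_list[[length(Wd_list) + 1L]] <- Wd
      d_block <- c(d_block, rep(b, ncol(Wd)))
    }
  }
  W_alpha <- if (length(Wa_list)) do.call(cbind, Wa_list) else matrix(0, q, 0)
  W_delta <- if (length(Wd_list)) do.call(cbind, Wd_list) else matrix(0, q, 0)
  rownames(W_alpha) <- geno$samples
  rownames(W_delta) <- geno$samples
  structure(list(W_alpha = W_alpha, W_delta = W_delta,
                 alpha_block = a_block, delta_block = d_block,
                 samples = geno$samples),
            class = "hap_coding")
}

#' Per-SNP statistics for single-SNP coding
#'
#' Reference allele (the more frequent of the two codes, ties to code 0) and
#' effect-allele frequency per SNP, estimated from the sample. Reuse the
#' training statistics when coding a validation population.
#'
#' @param geno A [phased_genotypes()] object.
#' @return Tibble with columns `snp`, `ref_code`, `p_effect` (effect-allele
#'   frequency) and `monomorphic`.
#' @export
snp_stats <- function(geno) {
  stopifnot(inherits(geno, "phased_geno"))
  q <- nrow(geno$hap1)
  p1 <- (colSums(geno$hap1) + colSums(geno$hap2)) / (2 * q)  # freq of code 1
  ref_code <- ifelse(p1 > 0.5, 1L, 0L)
  p_effect <- ifelse(ref_code == 1L, 1 - p1, p1)
  tibble::tibble(
    snp = seq_len(ncol(geno$hap1)),
    ref_code = ref_code,
    p_effect = as.numeric(p_effect),
    monomorphic = p_effect <= 0 | p_effect >= 1
  )
}

#' Single-SNP additive and dominance coding matrices
#'
#' The bi-allelic (h = 2) special case of the multi-allelic coding: with
#' `c` copies of the effect (non-reference) allele at frequency `p`, the
#' additive codes are `2p`, `-(1 - 2p)`, `-2(1 - p)` for `c = 0, 1, 2`, and
#' the dominance codes are `-2p^2`... for the two homozygotes and `2p(1-p)`
#' for the heterozygote. Monomorphic SNPs contribute zero columns.
#'
#' @param geno A [phased_genotypes()] object.
#' @param stats Optional [snp_stats()] table (training statistics) used to
#'   code this population; defaults to statistics of `geno` itself.
#' @return Object of class `snp_coding`: list with `W_alpha`, `W_delta`
#'   (both q x m), per-column `block` index (the SNP index) and `samples`.
#' @export
snp_coding <- function(geno, stats = NULL) {
  stopifnot(inherits(geno, "phased_geno"))
  stats <- stats %||% snp_stats(geno)
  q <- nrow(geno$hap1); m <- ncol(geno$hap1)
  if (nrow(stats) != m) abort("`stats` must describe the same SNPs as `geno`")
  # copies of the effect allele
  eff1 <- sweep(geno$hap1, 2L, stats$ref_code, `!=`)
  eff2 <- sweep(geno$hap2, 2L, stats$ref_code, `!=`)
  copies <- eff1 + eff2
  p <- stats$p_effect
  Wa <- matrix(0, q, m)
  Wd <- matrix(0, q, m)
  for (s in seq_len(m)) {
    if (stats$monomorphic[s]) next
    ps <- p[s]; cs <- copies[, s]
    Wa[, s] <- c(2 * ps, -(1 - 2 * ps), -2 * (1 - ps))[cs + 1L]
    Wd[, s] <- c(-2 * ps^2, 2 * ps * (1 - ps), -2 * (1 - ps)^2)[cs + 1L]
  }
  colnames(Wa) <- paste0(geno$id, ".a")
  colnames(Wd) <- paste0(geno$id, ".d")
  rownames(Wa) <- rownames(Wd) <- geno$samples
  structure(list(W_alpha = Wa, W_delta = Wd,
                 alpha_block = seq_len(m), delta_block = seq_len(m),
                 stats = stats, samples = geno$samples),
            class = "snp_coding")
}
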