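# A random multi-allelic locus with full genotypic values.
random_locus <- function(h, seed) {
  set.seed(seed)
  p <- rgamma(h, shape = 2) + 0.05
  p <- p / sum(p)
  g <- matrix(rnorm(h * h, mean = 20, sd = 6), h, h)
  g <- (g + t(g)) / 2
  locus_spec(p, g)
}

# The four-haplotype example block as a 2-SNP phased population with one
# individual per genotype (homozygotes first, then heterozygotes), so the
# coding rows line up with the partition's genotype table.
example_block_population <- function() {
  strings <- c("00", "01", "10", "11")  # alleles 1..4 in catalog order
  gp <- rbind(cbind(1:4, 1:4),
              t(utils::combn(4, 2)))
  split_hap <- function(idx) {
    matrix(as.integer(unlist(strsplit(strings[idx], ""))), ncol = 2, byrow = TRUE)
  }
  phased_genotypes(split_hap(gp[, 1]), split_hap(gp[, 2]),
                   samples = paste0("g", gp[, 1], gp[, 2]))
}

# Small simulated dataset with haplotype (and optionally SNP) random terms.
small_dataset <- function(q, n_blocks = 3, seed = 1, n_terms = 2,
                          sigma2 = NULL, sigma2_e = 1) {
  blocks <- replicate(n_blocks, list(alleles = c("00", "01", "10", "11"),
                                     freq = c(0.4, 0.3, 0.2, 0.1)),
                      simplify = FALSE)
  geno <- simulate_haplotypes(q, blocks, seed = seed)
  cat0 <- enumerate_haplotypes(geno, plan_blocks(geno, n_snps = 2))
  grm_h <- genomic_relationship(haplotype_coding(geno, cat0))
  terms <- grm_terms(grm_h, prefix = "hap")
  if (n_terms == 4) {
    grm_s <- genomic_relationship(snp_coding(geno))
    terms <- c(terms, grm_terms(grm_s, prefix = "snp"))
  }
  terms <- terms[seq_len(n_terms)]
  sigma2 <- sigma2 %||% setNames(rep(1, n_terms), names(terms))
  set.seed(seed + 1000)
  X <- cbind(1, rnorm(q))
  sim <- simulate_phenotypes(terms, sigma2 = sigma2, sigma2_e = sigma2_e,
                             seed = seed + 2000)
  list(y = sim$y + drop(X %*% c(10, 0.5)), X = X, terms = terms,
       sigma2 = sigma2, sigma2_e = sigma2_e, geno = geno, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
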