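test_that("haplotype enumeration matches a manual tally", {
  hap1 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(0L, 0L))
  hap2 <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 0L), c(1L, 0L))
  g <- phased_genotypes(hap1, hap2)
  cat0 <- enumerate_haplotypes(g, plan_blocks(g, n_snps = 2))
  bl <- cat0$blocks[[1]]
  expect_equal(bl$alleles, c("00", "01", "10"))
  # manual tally of the 8 chromosomes: 00 x3, 01 x3, 10 x2
  expect_equal(bl$freq, c(3, 3, 2) / 8)
  expect_equal(sum(bl$freq), 1)
  expect_equal(bl$pair1, c(1L, 2L, 1L, 1L))
  expect_equal(bl$pair2, c(2L, 2L, 3L, 3L))

  # monomorphic block
  mono <- phased_genotypes(matrix(1L, 3, 2), matrix(1L, 3, 2))
  cm <- enumerate_haplotypes(mono, plan_blocks(mono, n_snps = 2))
  expect_equal(cm$blocks[[1]]$h, 1L)
  expect_equal(ncol(haplotype_coding(mono, cm)$W_alpha), 0L)
})

test_that("coding matrices equal the printed ten-genotype example matrices", {
  g <- example_block_population()
  plan <- plan_blocks(g, n_snps = 2)
  cat0 <- enumerate_haplotypes(g, plan, freq = list(c(0.4, 0.3, 0.2, 0.1)))
  cod <- haplotype_coding(g, cat0)
  W_alpha_printed <- rbind(
    c(0.6, 0.4, 0.2), c(-1.4, 0.4, 0.2), c(0.6, -1.6, 0.2), c(0.6, 0.4, -1.8),
    c(-0.4, 0.4, 0.2), c(0.6, -0.6, 0.2), c(0.6, 0.4, -0.8),
    c(-0.4, -0.6, 0.2), c(-0.4, 0.4, -0.8), c(0.6, -0.6, -0.8))
  W_delta_printed <- rbind(
    c(-0.36, -0.24, -0.12, 0.12, 0.06, 0.04),
    c(-0.56, 0.16, 0.08, -0.28, -0.14, 0.04),
    c(0.24, -0.64, 0.08, -0.48, 0.06, -0.16),
    c(0.24, 0.16, -0.72, 0.12, -0.54, -0.36),
    c(0.54, -0.04, -0.02, -0.08, -0.04, 0.04),
    c(-0.06, 0.56, -0.02, -0.18, 0.06, -0.06),
    c(-0.06, -0.04, 0.58, 0.12, -0.24, -0.16),
    c(-0.16, -0.24, 0.08, 0.62, -0.04, -0.06),
    c(-0.16, 0.16, -0.32, -0.08, 0.66, -0.16),
    c(0.24, -0.24, -0.32, -0.18, -0.24, 0.74))
  expect_equal(unname(cod$W_alpha), W_alpha_printed, tolerance = 1e-12)
  expect_equal(unname(cod$W_delta), W_delta_printed, tolerance = 1e-12)
})

test_that("scaling yields unit mean diagonal and matches a manual product", {
  set.seed(5)
  W <- matrix(rnorm(12), 3, 4)
  res <- genomic_relationship(W)
  expect_equal(mean(diag(res$S)), 1)
  k_manual <- mean(diag(W %*% t(W)))
  expect_equal(res$S, (W / sqrt(k_manual)) %*% t(W / sqrt(k_manual)))

  # duplicate individuals give identical rows and columns
  W2 <- rbind(W, W[2, ])
  S2 <- genomic_relationship(W2)$S
  expect_equal(S2[2, ], S2[4, ])
  expect_equal(S2[, 2], S2[, 4])

  expect_error(genomic_relationship(matrix(0, 3, 2)), "polymorphic")
})

test_that("relationship matrices are symmetric positive semi-definite", {
  ds <- small_dataset(q = 25, n_blocks = 4, seed = 21)
  for (tm in ds$terms) {
    S <- tm$S
    expect_equal(S, t(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(S)))
    expect_equal(mean(diag(S)), 1)
  }
})

test_that("single-SNP coding is the h = 2 special case of the block coding", {
  set.seed(31)
  g <- simulate_haplotypes(80, list(list(alleles = c("0", "1"),
                                         freq = c(0.7, 0.3))), seed = 31)
  # one-SNP blocks through the haplotype machinery
  cat0 <- enumerate_haplotypes(g, plan_blocks(g, n_snps = 1))
  hc <- haplotype_coding(g, cat0)
  sc <- snp_coding(g)
  expect_equal(unname(hc$W_alpha), unname(sc$W_alpha))
  expect_equal(unname(hc$W_delta), unname(sc$W_delta))
  A_h <- genomic_relationship(hc)$A
  A_s <- genomic_relationship(sc)$A
  expect_equal(A_h, A_s)

  # and the SNP column matches the two-allele locus partition coding
  st <- snp_stats(g)
  p2 <- st$p_effect[1]
  loc <- locus_spec(c(1 - p2, p2), matrix(c(0, 0, 0, 0), 2, 2))
  copies <- (g$hap1[, 1] != st$ref_code[1]) + (g$hap2[, 1] != st$ref_code[1])
  geno_tbl <- cbind(i = ifelse(copies == 2, 2L, 1L),
                    j = ifelse(copies >= 1, 2L, 1L))
  expect_equal(sc$W_alpha[, 1],
               additive_coding(geno_tbl[, "i"], geno_tbl[, "j"], 2, loc$p, 1),
               ignore_attr = TRUE)
})

test_that("cross-relationships extend the training matrix consistently", {
  ds <- small_dataset(q = 20, n_blocks = 3, seed = 41)
  geno <- ds$geno
  cat0 <- enumerate_haplotypes(geno, plan_blocks(geno, n_snps = 2))
  cod <- haplotype_coding(geno, cat0)
  grm <- genomic_relationship(cod)
  # validation = training reproduces the training matrix
  S01 <- cross_relationship(cod$W_alpha, cod$W_alpha, grm$k_alpha)
  expect_equal(S01, grm$A)
  # one validation individual duplicating training individual 7
  val <- subset_individuals(geno, 7)
  codv <- haplotype_coding(val, cat0)
  Sv <- cross_relationship(codv$W_alpha, cod$W_alpha, grm$k_alpha)
  expect_equal(drop(Sv), grm$A[7, ], ignore_attr = TRUE)
  # random split against a direct computation
  tr <- subset_individuals(geno, 1:15); va <- subset_individuals(geno, 16:20)
  cat_tr <- enumerate_haplotypes(tr, plan_blocks(tr, n_snps = 2))
  ctr <- haplotype_coding(tr, cat_tr); cva <- haplotype_coding(va, cat_tr)
  k <- mean(rowSums(ctr$W_alpha^2))
  expect_equal(cross_relationship(cva$W_alpha, ctr$W_alpha),
               (cva$W_alpha / sqrt(k)) %*% t(ctr$W_alpha / sqrt(k)))
})

test_that("validation haplotypes unseen in training are coded as reference", {
  tr <- phased_genotypes(rbind(c(0L, 0L), c(0L, 0L)), rbind(c(0L, 1L), c(0L, 0L)))
  va <- phased_genotypes(rbind(c(1L, 1L)), rbind(c(0L, 1L)))
  cat0 <- enumerate_haplotypes(tr, plan_blocks(tr, n_snps = 2))
  expect_warning(codv <- haplotype_coding(va, cat0), "reference allele")
  codt <- haplotype_coding(tr, cat0)
  expect_equal(ncol(codv$W_alpha), ncol(codt$W_alpha))
})

test_that("haplotype relationships shrink toward but never exceed SNP ones as blocks grow", {
  ped <- simulate_pedigree(60, 240, design = "nuclear", n_offspring = 1, seed = 71)
  po <- ped$pairs[ped$pairs$relationship == "parent_offspring", ]
  mean_po <- vapply(c(1, 4, 12), function(bs) {
    cat0 <- enumerate_haplotypes(ped$geno, plan_blocks(ped$geno, n_snps = bs))
    A <- genomic_relationship(haplotype_coding(ped$geno, cat0))$A
    mean(relationship_means(A, po)$mean)
  }, numeric(1))
  expect_true(all(diff(mean_po) < 0.02))  # monotone non-increase, small MC slack
  expect_lt(mean_po[3], mean_po[1])
})

test_that("relationship matrices round-trip through both text formats", {
  ds <- small_dataset(q = 8, n_blocks = 2, seed = 81)
  A <- ds$terms[[1]]$S
  rownames(A) <- colnames(A) <- paste0("s", 1:8)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_grm(A, f1, format = "square")
  write_grm(A, f2, format = "long")
  expect_equal(read_grm(f1, "square"), A)
  expect_equal(read_grm(f2, "long"), A)
})
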