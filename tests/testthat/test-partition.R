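test_that("allele frequencies recover from genotype frequency tables", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(allele_frequencies(hwe_genotype_frequencies(p)), p)

  P <- matrix(0, 4, 4); P[1, 1] <- 1
  expect_equal(allele_frequencies(P), c(1, 0, 0, 0))

  P <- matrix(0, 2, 2); P[1, 2] <- P[2, 1] <- 1  # one heterozygote class
  expect_equal(allele_frequencies(P), c(0.5, 0.5))

  expect_error(allele_frequencies(matrix(c(0.5, 0, 0, 0.4), 2, 2)), "sum to 1")
  expect_error(allele_frequencies(matrix(c(1.2, -0.1, -0.1, 0.1), 2, 2)),
               "nonnegative")
})

test_that("allelic means and population mean match direct weighted sums", {
  loc <- example_locus()
  mu_i <- allelic_means(loc)
  # independent oracle: direct weighted sums over the printed table
  expect_equal(unname(mu_i[1]), 0.4 * 25 + 0.3 * 18 + 0.2 * 15 + 0.1 * 10)  # 19.4
  expect_equal(unname(mu_i[2]), 0.4 * 18 + 0.3 * 30 + 0.2 * 33 + 0.1 * 40)  # 26.8
  expect_equal(population_mean(loc), 22.09)
  expect_equal(population_mean(loc), sum(loc$p * mu_i))

  flat <- locus_spec(c(0.5, 0.3, 0.2), matrix(7, 3, 3))
  expect_equal(unname(allelic_means(flat)), rep(7, 3))
  expect_equal(population_mean(flat), 7)

  sym <- locus_spec(c(0.5, 0.5), matrix(c(1, 0, 0, -1), 2, 2))
  expect_equal(population_mean(sym), 0)
})

test_that("additive and dominance effects reproduce the worked example", {
  loc <- example_locus()
  expect_equal(unname(additive_effects(loc)), c(-7.4, -1.1, -2.5))
  expect_equal(dominance_effects(loc)$delta, c(-9.5, -6, -20, 9.5, 7.5, -14))

  # any substitution effect is a difference of reference-based effects
  mu_i <- allelic_means(loc)
  a <- additive_effects(loc)
  expect_equal(unname(a[2] - a[1]), unname(mu_i[2] - mu_i[3]))  # alpha_23 = 6.3
  expect_equal(unname(a[2] - a[1]), 6.3)

  expect_length(additive_effects(locus_spec(1, matrix(5, 1, 1))), 0)
  flat <- locus_spec(c(0.6, 0.4), matrix(3, 2, 2))
  expect_equal(unname(additive_effects(flat)), 0)

  # purely additive genotypic values have no dominance
  v <- c(1, 4, -2)
  gadd <- outer(v, v, `+`)
  expect_equal(dominance_effects(locus_spec(c(0.2, 0.5, 0.3), gadd))$delta,
               rep(0, 3))
})

test_that("missing heterozygote values flag dominance effects, not others", {
  loc <- example_locus()
  g <- loc$g
  g[1, 2] <- g[2, 1] <- NA
  loc2 <- locus_spec(loc$p, g)
  d <- dominance_effects(loc2)
  expect_true(is.na(d$delta[d$pair == "1/2"]))
  full <- dominance_effects(loc)
  expect_equal(d$delta[-1], full$delta[-1])
  expect_error(allelic_means(loc2), "1/2")
})

test_that("coding values match the worked entries and contract checks fire", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(additive_coding(1, 1, 2, p, ref_allele = 1), 0.6)
  expect_equal(additive_coding(1, 2, 2, p, ref_allele = 1), -0.4)
  expect_equal(additive_coding(1, 2, 2, c(0.5, 0.5), ref_allele = 1), 0)
  expect_error(additive_coding(1, 1, 1, p, ref_allele = 1), "reference")

  expect_equal(dominance_coding(1, 2, 1, 2, p), 0.54)
  expect_equal(dominance_coding(1, 1, 2, 3, p), 0.12)
  expect_equal(dominance_coding(1, 1, 2, 3, c(0.5, 0, 0.5)), 0)
  expect_error(dominance_coding(1, 2, 2, 2, p), "must differ")
})

test_that("the full worked-example partition reproduces every printed value", {
  part <- partition_locus(example_locus())
  expect_equal(part$mu, 22.09)
  expect_equal(part$genotypes$a,
               c(-5.38, 9.42, -3.18, -0.38, 2.02, -4.28, -2.88, 3.12, 4.52, -1.78))
  expect_equal(part$genotypes$d,
               c(8.29, -1.51, -1.91, 13.29, -6.11, -2.81, -9.21, 7.79, 13.39, -8.31))
  expect_equal(part$var_g, 71.0419, tolerance = 1e-10)
  expect_equal(part$var_a, 20.1178, tolerance = 1e-10)
  expect_equal(part$var_d, 50.9241, tolerance = 1e-10)
  expect_equal(part$var_g, part$var_a + part$var_d)
  # reconstruction g = mu + a + d
  expect_equal(part$mu + part$genotypes$a + part$genotypes$d, part$genotypes$g)
})

test_that("partition invariants hold on randomized loci", {
  for (h in 2:8) {
    part <- partition_locus(random_locus(h, seed = 100 + h))
    w <- part$genotypes$frequency
    expect_lt(abs(sum(w * part$genotypes$a)), 1e-10)
    expect_lt(abs(sum(w * part$genotypes$d)), 1e-10)
    expect_equal(part$var_g, part$var_a + part$var_d,
                 tolerance = 1e-9)
    expect_equal(part$mu + part$genotypes$a + part$genotypes$d,
                 part$genotypes$g, tolerance = 1e-12)
  }
})

test_that("factorized values agree with the allelic-effect brute-force oracle", {
  # oracle: alpha from allelic effects, a_ij = a_i + a_j with
  # a_i = -(1 - p_i) alpha_ref,i + sum_{k != i} p_k alpha_ref,k; d_ij from the
  # double-sum form sum_{k != j} sum_{f != i} p_k p_f (d_ij - d_ik - d_jf + d_kf)
  for (h in c(2, 3, 5, 8)) {
    loc <- random_locus(h, seed = 300 + h)
    part <- partition_locus(loc)
    p <- loc$p
    mu_i <- allelic_means(loc)
    r <- loc$ref_allele
    alpha_full <- mu_i[r] - mu_i          # alpha_{ref,k}, zero at k = ref
    a_allelic <- vapply(seq_len(h), function(i) {
      -(1 - p[i]) * alpha_full[i] + sum(p[-i] * alpha_full[-i])
    }, numeric(1))
    delta_mat <- matrix(0, h, h)
    for (k in seq_len(h - 1)) for (f in (k + 1):h) {
      delta_mat[k, f] <- delta_mat[f, k] <- loc$g[k, f] - (loc$g[k, k] + loc$g[f, f]) / 2
    }
    for (row in seq_len(nrow(part$genotypes))) {
      i <- part$genotypes$i[row]; j <- part$genotypes$j[row]
      expect_equal(part$genotypes$a[row], a_allelic[i] + a_allelic[j],
                   tolerance = 1e-9)
      d_oracle <- 0
      for (k in setdiff(seq_len(h), j)) for (f in setdiff(seq_len(h), i)) {
        d_oracle <- d_oracle + p[k] * p[f] *
          (delta_mat[i, j] - delta_mat[i, k] - delta_mat[j, f] + delta_mat[k, f])
      }
      expect_equal(part$genotypes$d[row], d_oracle, tolerance = 1e-9)
    }
    # and the W-matrix route agrees element-wise
    expect_equal(as.numeric(part$W_alpha %*% part$alpha), part$genotypes$a,
                 tolerance = 1e-9)
    expect_equal(as.numeric(part$W_delta %*% part$delta$delta), part$genotypes$d,
                 tolerance = 1e-9)
  }
})

test_that("partition is invariant to relabeling non-reference alleles", {
  loc <- random_locus(5, seed = 42)
  r <- loc$ref_allele
  set.seed(99)
  perm <- seq_len(5)
  others <- setdiff(perm, r)
  perm[others] <- sample(others)  # relabel everything except the reference
  loc2 <- locus_spec(loc$p[perm], loc$g[perm, perm])
  p1 <- partition_locus(loc)
  p2 <- partition_locus(loc2)
  expect_equal(p1$mu, p2$mu)
  expect_equal(p1$var_a, p2$var_a)
  expect_equal(p1$var_d, p2$var_d)
  expect_equal(sort(unname(p1$alpha)), sort(unname(p2$alpha)))
})

test_that("h = 2 coding reduces to the classical bi-allelic codes", {
  p <- c(0.7, 0.3)
  expect_equal(additive_coding(1, 1, 2, p, 1), 2 * 0.3)
  expect_equal(additive_coding(1, 2, 2, p, 1), -(1 - 2 * 0.3))
  expect_equal(additive_coding(2, 2, 2, p, 1), -2 * (1 - 0.3))
  expect_equal(dominance_coding(1, 2, 1, 2, p), 2 * 0.7 * 0.3)
  expect_equal(dominance_coding(1, 1, 1, 2, p), -2 * 0.3^2)
  expect_equal(dominance_coding(2, 2, 1, 2, p), -2 * 0.7^2)
})

test_that("monomorphic loci are legal and contribute nothing", {
  part <- partition_locus(locus_spec(1, matrix(3, 1, 1)))
  expect_equal(part$mu, 3)
  expect_equal(ncol(part$W_alpha), 0L)
  expect_equal(part$var_a, 0)
  expect_equal(part$var_d, 0)
})

test_that("tidy and glance return the partition tables", {
  part <- partition_locus(example_locus())
  td <- tidy(part)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10)
  gl <- glance(part)
  expect_equal(gl$var_g, gl$var_a + gl$var_d)
})
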