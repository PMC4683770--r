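test_that("the two solving routes give identical BLUE and GBLUP", {
  for (seed in c(1, 2, 3)) {
    for (nt in c(2, 4)) {
      ds <- small_dataset(q = 30, n_blocks = 3, seed = seed, n_terms = nt,
                          sigma2 = setNames(c(2, 1, 1.5, 0.5)[seq_len(nt)],
                                            NULL))
      f_ce <- gblup_ce(ds$y, ds$terms, sigma2 = ds$sigma2, sigma2_e = 1, X = ds$X)
      f_qm <- gblup_qm(ds$y, ds$terms, sigma2 = ds$sigma2, sigma2_e = 1, X = ds$X)
      expect_equal(f_ce$b_hat, f_qm$b_hat, tolerance = 1e-8)
      for (nm in names(f_ce$u)) {
        expect_equal(f_ce$u[[nm]], f_qm$u[[nm]], tolerance = 1e-8)
      }
      expect_equal(f_ce$g_hat, f_qm$g_hat, tolerance = 1e-8)
    }
  }
})

test_that("zero genetic variance collapses GBLUP to ordinary least squares", {
  ds <- small_dataset(q = 25, seed = 7)
  f <- gblup_ce(ds$y, ds$terms, sigma2 = c(0, 0), sigma2_e = 2, X = ds$X)
  expect_equal(unname(unlist(f$u)), rep(0, 50))
  ols <- drop(solve(crossprod(ds$X), crossprod(ds$X, ds$y)))
  expect_equal(f$b_hat, ols, ignore_attr = TRUE)
})

test_that("identity relationship with intercept reduces to ridge shrinkage", {
  set.seed(11)
  q <- 20
  y <- rnorm(q, mean = 3)
  f <- gblup_ce(y, list(id = genetic_term(S = diag(q))), sigma2 = 1.5,
                sigma2_e = 0.5, X = matrix(1, q, 1))
  # closed-form ridge oracle on centered y: u = s2/(s2 + s2e) * (y - ybar)
  # (V has compound symmetry; P centers then scales)
  expect_equal(f$u$id, 1.5 / (1.5 + 0.5) * (y - mean(y)), tolerance = 1e-10)

  # QM with orthonormal T and no fixed effects is textbook ridge
  Tm <- qr.Q(qr(matrix(rnorm(q * 5), q, 5)))
  lam <- 0.5 / 1.5
  f2 <- gblup_qm(y, list(g = genetic_term(T = Tm)), sigma2 = 1.5,
                 sigma2_e = 0.5, X = matrix(0, q, 0))
  tau_oracle <- solve(crossprod(Tm) + lam * diag(5), crossprod(Tm, y))
  expect_equal(f2$tau$g, drop(tau_oracle), tolerance = 1e-10)
})

test_that("effect estimates vanish under infinite shrinkage and shrink monotonically", {
  ds <- small_dataset(q = 25, seed = 13)
  norms <- vapply(c(5, 1, 0.1, 1e-4), function(s2) {
    f <- gblup_qm(ds$y, ds$terms["hap_add"], sigma2 = s2, sigma2_e = 1, X = ds$X)
    sqrt(sum(f$tau$hap_add^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))      # larger lambda, smaller effects
  expect_lt(norms[4], 1e-2 * norms[1])   # infinite-shrinkage limit
})

test_that("the CE route tolerates singular relationship matrices", {
  set.seed(17)
  q <- 12
  Tm <- matrix(rnorm(q * 2), q, 2)   # rank-2 coding, singular q x q S
  S <- tcrossprod(Tm)
  y <- rnorm(q)
  f <- gblup_ce(y, list(g = genetic_term(S = S)), sigma2 = 1, sigma2_e = 1)
  expect_true(all(is.finite(f$u$g)))
  f2 <- gblup_qm(y, list(g = genetic_term(T = Tm)), sigma2 = 1, sigma2_e = 1)
  expect_equal(f$u$g, f2$u$g, tolerance = 1e-8)
})

test_that("validation predictions agree across routes and edge cases", {
  ds <- small_dataset(q = 30, n_blocks = 3, seed = 19)
  geno <- ds$geno
  tr_idx <- 1:22; va_idx <- 23:30
  tr <- subset_individuals(geno, tr_idx); va <- subset_individuals(geno, va_idx)
  cat0 <- enumerate_haplotypes(tr, plan_blocks(tr, n_snps = 2))
  ctr <- haplotype_coding(tr, cat0)
  grm <- genomic_relationship(ctr)
  terms <- grm_terms(grm)
  y <- ds$y[tr_idx]
  s2 <- c(hap_add = 2, hap_dom = 1)
  f_ce <- gblup_ce(y, terms, sigma2 = s2, sigma2_e = 1, X = ds$X[tr_idx, ])
  f_qm <- gblup_qm(y, terms, sigma2 = s2, sigma2_e = 1, X = ds$X[tr_idx, ])

  cva <- haplotype_coding(va, cat0)
  S01 <- list(hap_add = cross_relationship(cva$W_alpha, ctr$W_alpha, grm$k_alpha),
              hap_dom = cross_relationship(cva$W_delta, ctr$W_delta, grm$k_delta))
  T0 <- list(hap_add = cva$W_alpha / sqrt(grm$k_alpha),
             hap_dom = cva$W_delta / sqrt(grm$k_delta))
  p_ce <- predict(f_ce, S01 = S01)
  p_qm <- predict(f_qm, T0 = T0)
  expect_equal(p_ce$u, p_qm$u, tolerance = 1e-8)

  # validation = training reproduces the training GBLUP
  S11 <- list(hap_add = grm$A, hap_dom = grm$D)
  p_self <- predict(f_ce, S01 = S11)
  expect_equal(p_self$u[p_self$term == "hap_add"], f_ce$u$hap_add,
               tolerance = 1e-10, ignore_attr = TRUE)

  # a validation individual identical to a training one predicts identically
  twin <- subset_individuals(tr, 5)
  ctw <- haplotype_coding(twin, cat0)
  ptw <- predict(f_qm, T0 = list(hap_add = ctw$W_alpha / sqrt(grm$k_alpha),
                                 hap_dom = ctw$W_delta / sqrt(grm$k_delta)))
  expect_equal(ptw$u[ptw$term == "total"], f_qm$g_hat[5],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("method auto-selection follows the matrix-size comparison", {
  ds <- small_dataset(q = 10, n_blocks = 4, seed = 23)  # many effects, few ind.
  f <- gblup(ds$y, ds$terms, sigma2 = c(1, 1), sigma2_e = 1, X = ds$X)
  expect_equal(f$method, "ce")
  ds2 <- small_dataset(q = 60, n_blocks = 1, seed = 23) # few effects
  f2 <- gblup(ds2$y, ds2$terms, sigma2 = c(1, 1), sigma2_e = 1, X = ds2$X)
  expect_equal(f2$method, "qm")
})

test_that("predictions have zero mean structure over repeated simulation", {
  means <- vapply(1:100, function(r) {
    ds <- small_dataset(q = 15, n_blocks = 2, seed = 4000 + r, n_terms = 1)
    f <- gblup_ce(ds$y, ds$terms, sigma2 = 1, sigma2_e = 1, X = ds$X)
    mean(f$u$hap_add)
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
})
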