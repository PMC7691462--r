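test_that("call-rate and MAF filters remove exactly the planted loci", {
  set.seed(101)
  n <- 500
  ## locus 1: fine; locus 2: 60% call rate; locus 3: MAF 0.049;
  ## locus 4: MAF 0.051 (boundary pair); locus 5: fine but duplicated group
  G <- matrix(1L, n, 5)
  G[, 1] <- rbinom(n, 2, 0.3)
  G[, 2] <- rbinom(n, 2, 0.3); G[sample(n, 0.4 * n), 2] <- NA
  G[, 3] <- 0L; G[sample(n, 49), 3] <- 1L            # 49/1000 alleles
  G[, 4] <- 0L; G[sample(n, 51), 4] <- 1L            # 51/1000 alleles
  G[, 5] <- rbinom(n, 2, 0.4)
  gt <- genotypes(G, rep(c("P1", "P2"), each = n / 2),
                  locus_groups = c("r1", "r2", "r3", "r4", "r1"))
  res <- filter_snps(gt, min_ind_frac = 0.70, min_pop_frac = 0.70,
                     min_maf = 0.05, one_per_locus = TRUE)
  rep <- res$report
  expect_equal(rep$n_removed_missingness, 1)
  expect_equal(rep$removed$missingness, "L2")
  expect_equal(rep$removed$maf, "L3")        # 0.049 out, 0.051 stays
  expect_equal(rep$n_removed_duplicate, 1)   # one SNP of group r1 dropped
  expect_setequal(rep$retained, c("L1", "L4"))
  expect_equal(rep$n_input_loci,
               rep$n_removed_missingness + rep$n_removed_maf +
                 rep$n_removed_duplicate + rep$n_retained)
})

test_that("the per-population presence rule uses the population fraction", {
  ## locus genotyped well in 1 of 3 pops only -> removed at min_pop_frac 0.7
  set.seed(5)
  G <- matrix(rbinom(30 * 2, 2, 0.5), 30, 2)
  G[11:30, 2] <- NA                      # pops 2 and 3 empty at locus 2
  gt <- genotypes(G, rep(c("P1", "P2", "P3"), each = 10))
  res <- filter_snps(gt, min_maf = 0, one_per_locus = FALSE)
  expect_equal(res$report$removed$missingness, "L2")
  expect_equal(res$report$retained, "L1")
})

test_that("expected heterozygosity matches the unbiased hand formula", {
  ## monomorphic site
  gt0 <- genotypes(matrix(0L, 4, 3), rep("A", 4))
  expect_equal(unname(expected_heterozygosity(gt0)), 0)
  ## one locus, p = 0.5, n = 10: 2 * 0.25 * 20/19
  gt1 <- genotypes(cbind(rep(c(0L, 2L), 5)), rep("A", 10))
  expect_equal(unname(expected_heterozygosity(gt1)), 0.5 * 20 / 19,
               tolerance = 1e-12)
})

test_that("H_E matches the Balding-Nichols analytic expectation and falls with divergence", {
  set.seed(42)
  n_loci <- 2000; n <- 20; F <- 0.2
  p0 <- runif(n_loci, 0.1, 0.9)
  psite <- rbeta(n_loci, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  gt <- sample_genotypes(list(S = psite), list(S = n))
  he <- expected_heterozygosity(gt)
  ## E[2p(1-p)] under p0 ~ U(0.1, 0.9) times (1 - F)
  expected <- 2 * (0.5 - (0.25 + (0.8^2) / 12)) * (1 - F)
  se <- sd(2 * psite * (1 - psite)) / sqrt(n_loci)
  expect_lt(abs(he - expected), 3 * se + 0.01)

  ## monotone decrease with F (Monte-Carlo regression slope < 0)
  hes <- sapply(c(0.05, 0.2, 0.4), function(f) {
    ps <- rbeta(n_loci, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    unname(expected_heterozygosity(sample_genotypes(list(S = ps),
                                                    list(S = n))))
  })
  expect_lt(coef(lm(hes ~ c(0.05, 0.2, 0.4)))[2], 0)
})

test_that("pairwise theta matches the textbook variance-components oracle", {
  set.seed(7)
  ## small hand-sized dataset, including missing genotypes
  G <- matrix(sample(c(0L, 1L, 2L, NA), 10 * 3, TRUE,
                     prob = c(.3, .3, .3, .1)), 10, 3)
  pops <- rep(c("A", "B"), each = 5)
  th <- pairwise_fst_wc(genotypes(G, pops))$fst[1, 2]
  expect_equal(th, oracle_wc_theta(G, pops), tolerance = 1e-12)

  ## several random multi-pop datasets against the oracle (global theta)
  for (s in 1:5) {
    set.seed(s)
    G2 <- matrix(rbinom(60 * 8, 2, rep(runif(8, .1, .9), each = 60)), 60, 8)
    pops2 <- rep(c("A", "B", "C"), each = 20)
    expect_equal(pairwise_fst_wc(genotypes(G2, pops2))$global,
                 oracle_wc_theta(G2, pops2), tolerance = 1e-12)
  }
})

test_that("theta is 1 at fixed differences, ~0 under panmixia, and label-swap invariant", {
  gt_fix <- genotypes(cbind(rep(c(0L, 2L), each = 10)),
                      rep(c("A", "B"), each = 10))
  expect_equal(pairwise_fst_wc(gt_fix)$fst[1, 2], 1)

  set.seed(8)
  G <- matrix(rbinom(80 * 150, 2, rep(runif(150, .2, .8), each = 80)), 80, 150)
  gt <- genotypes(G, rep(c("A", "B"), each = 40))
  pw <- pairwise_fst_wc(gt, n_perm = 99, seed = 1)
  expect_lt(abs(pw$fst[1, 2]), 0.02)
  expect_gt(pw$p_values[1, 2], 0.05)

  ## swapping reference/alternate alleles at every locus leaves theta alone
  gt_sw <- genotypes(2L - G, rep(c("A", "B"), each = 40))
  expect_equal(pairwise_fst_wc(gt_sw)$fst[1, 2], pw$fst[1, 2],
               tolerance = 1e-12)
})

test_that("negative theta values are reported, not truncated", {
  ## identical allele counts in both samples push the estimate below zero
  G <- rbind(matrix(c(0L, 1L, 2L), 6, 9), matrix(c(0L, 1L, 2L), 6, 9))
  gt <- genotypes(G, rep(c("A", "B"), each = 6))
  expect_lt(pairwise_fst_wc(gt)$fst[1, 2], 0)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(31)
  ps <- replicate(120, {
    G <- matrix(rbinom(20 * 40, 2, rep(runif(40, .2, .8), each = 20)), 20, 40)
    gt <- genotypes(G, rep(c("A", "B"), each = 10))
    pairwise_fst_wc(gt, n_perm = 99, seed = sample.int(1e6, 1))$p_values[1, 2]
  })
  ## p-values are discrete (99 permutations), so ties are expected; the KS
  ## statistic itself is still a fair uniformity check
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("population-specific beta ranks diverged sites and averages to theta", {
  set.seed(12)
  n_loci <- 800
  p0 <- runif(n_loci, 0.2, 0.8)
  make_bn <- function(f) rbeta(n_loci, p0 * (1 - f) / f,
                               (1 - p0) * (1 - f) / f)
  freqs <- list(A = make_bn(0.02), B = make_bn(0.02), C = make_bn(0.3))
  gt <- sample_genotypes(freqs, list(A = 15, B = 15, C = 15))
  beta <- popspecific_fst_wh(gt)
  expect_equal(names(which.max(beta)), "C")

  ## panmictic pool: all beta approximately zero
  gp <- sample_genotypes(list(A = p0, B = p0, C = p0),
                         list(A = 15, B = 15, C = 15))
  expect_true(all(abs(popspecific_fst_wh(gp)) < 0.05))

  ## balanced design: mean beta tracks the global theta
  expect_lt(abs(mean(beta) - pairwise_fst_wc(gt)$global), 0.02)
})

test_that("HWE screening removes gross departures and honours the strict majority rule", {
  ## all-heterozygote locus in every pop is removed; HWE loci are kept
  set.seed(3)
  n <- 30
  G <- cbind(rep(1L, 3 * n),
             rbinom(3 * n, 2, 0.5),
             rbinom(3 * n, 2, 0.3))
  gt <- genotypes(G, rep(c("A", "B", "C"), each = n))
  hw <- hwe_screen(gt, fdr = 0.10)
  expect_identical(hw$removed, "L1")
  expect_setequal(colnames(hw$genotypes$G), c("L2", "L3"))

  ## flagged in exactly half of the pops: retained (strictly more required)
  G2 <- cbind(c(rep(1L, n), rbinom(n, 2, 0.5)), rbinom(2 * n, 2, 0.5))
  gt2 <- genotypes(G2, rep(c("A", "B"), each = n))
  hw2 <- hwe_screen(gt2, fdr = 0.10)
  expect_identical(hw2$removed, character(0))
})

test_that("the exact HWE mid-p matches direct enumeration", {
  ## n = 5 individuals, 4 copies of the rare allele
  pr <- oracle_hwe_probs(5, 4)
  for (h in c(0, 2, 4)) {
    p_obs <- pr[as.character(h)]
    expected <- sum(pr[pr <= p_obs + 1e-12]) - 0.5 * p_obs
    expect_equal(riverscape:::hwe_exact_midp(h, 5L, 4L), unname(expected),
                 tolerance = 1e-12)
  }
  ## monomorphic locus is never significant
  expect_equal(riverscape:::hwe_exact_midp(0L, 10L, 0L), 1)
})
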