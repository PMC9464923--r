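# Grid-cell oracle checks use configurations where p-values sit exactly on
# grid points, so the conditional-ECDF arithmetic can be enumerated by hand.

test_that("grid cells reproduce hand-enumerated conditional ECDF ratios", {
  # stratum at threshold -log10 p2 = 1.4 (p2 <= 0.04 for all three SNPs)
  # with primary p {0.01, 0.02, 0.9}: condFDR at p1 = 0.01 is
  # 0.01 / (1/3) = 0.03
  pair <- toy_pair(paste0("s", 1:3), p_a = c(0.01, 0.02, 0.9),
                   p_b = rep(0.04, 3), z_a = 1, z_b = 1)
  grid <- build_fdr_grid(pair, singleton_ld(pair$SNP), primary = "a",
                         iterations = 1, seed = 1)
  i <- which(abs(grid$grid - 2.0) < 1e-9)   # p1 = 1e-2
  j <- which(abs(grid$grid - 1.3) < 1e-9)   # p2 <= 10^-1.3 ~ 0.0501
  expect_equal(grid$value[i, j], 0.03, tolerance = 1e-12)
  # p1 = 1 -> condFDR = 1 (ECDF is 1 at the largest p)
  expect_equal(grid$value[1, 1], 1)
})

test_that("the rank-1 cell equals n times the smallest p-value", {
  # unconditional column (threshold 0): the smallest of n pruned p-values
  # has ECDF rank 1/n, so condFDR = n * p1
  n <- 5
  pair <- toy_pair(paste0("s", 1:n), p_a = c(0.001, 0.2, 0.4, 0.6, 0.8),
                   p_b = rep(1, n), z_a = 1, z_b = 1)
  grid <- build_fdr_grid(pair, singleton_ld(pair$SNP), primary = "a",
                         iterations = 1, seed = 1)
  i <- which(abs(grid$grid - 3.0) < 1e-9)
  expect_equal(grid$value[i, 1], n * 0.001, tolerance = 1e-12)
})

test_that("grids are monotone along the primary axis and in (0, 1]", {
  sim <- simulate_gwas(sim_config(m = 20000, seed = 71))
  grid <- build_fdr_grid(sim$pair, sim$ld, primary = "a",
                         iterations = 5, seed = 72)
  expect_true(all(grid$value > 0 & grid$value <= 1))
  # non-decreasing with increasing p1 = non-increasing with the grid index
  expect_true(all(apply(grid$value, 2, function(v) all(diff(v) <= 1e-12))))
})

test_that("condFDR is invariant to duplicating the SNP set", {
  set.seed(80)
  m <- 5000
  pair <- toy_pair(paste0("s", 1:m), z_a = rnorm(m, sd = 1.2),
                   z_b = rnorm(m, sd = 1.1))
  dup <- rbind(as.data.frame(pair),
               transform(as.data.frame(pair), SNP = paste0(SNP, "_d")))
  class(dup) <- class(pair)
  g1 <- build_fdr_grid(pair, singleton_ld(pair$SNP), primary = "a",
                       iterations = 1, seed = 1)
  g2 <- build_fdr_grid(dup, singleton_ld(dup$SNP), primary = "a",
                       iterations = 1, seed = 1)
  # ECDF ratios are unchanged on every conditioning column that meets the
  # minimum stratum size in the smaller set (tighter columns differ by
  # design: they inherit in one grid but stand in the doubled one)
  x2 <- -log10(pair$P_B)
  cols <- vapply(g1$grid, function(s) sum(x2 >= s) >= g1$min_stratum,
                 logical(1))
  expect_lt(max(abs(g1$value[, cols] - g2$value[, cols])), 1e-9)
})

test_that("the conjunctional FDR is exactly the max of the reciprocals", {
  sim <- simulate_gwas(sim_config(m = 10000, seed = 90))
  asg <- condfdr(sim$pair, sim$ld, iterations = 5, seed = 91)
  expect_identical(asg$CONJFDR, pmax(asg$CONDFDR_AB, asg$CONDFDR_BA))
  expect_true(all(asg$CONJFDR >= asg$CONDFDR_AB))
  expect_true(all(asg$CONJFDR >= asg$CONDFDR_BA))
  expect_true(all(asg$CONDFDR_AB > 0 & asg$CONDFDR_AB <= 1))
  # nesting: a tighter threshold never enlarges the significant set
  tight <- assign_fdr(sim$pair, attr(asg, "grid_ab"), attr(asg, "grid_ba"),
                      threshold = 0.01)
  expect_true(all(which(tight$SIG_CONJ) %in% which(asg$SIG_CONJ)))
})

test_that("interpolated values respect grid clamping and equality cases", {
  pair <- toy_pair(paste0("s", 1:3), p_a = c(0.01, 0.02, 0.9),
                   p_b = rep(0.04, 3), z_a = 1, z_b = 1)
  ga <- build_fdr_grid(pair, singleton_ld(pair$SNP), primary = "a",
                       iterations = 1, seed = 1)
  gb <- build_fdr_grid(pair, singleton_ld(pair$SNP), primary = "b",
                       iterations = 1, seed = 1)
  # a SNP far beyond the grid is clamped to the boundary cell
  far <- toy_pair("sX", p_a = 1e-15, p_b = 1e-15, z_a = 9, z_b = 9)
  asg <- assign_fdr(far, ga, gb)
  expect_equal(asg$CONDFDR_AB, ga$value[length(ga$grid), length(ga$grid)])
  # equal conditional FDRs give that same conjunctional value
  asg2 <- data.frame(CONDFDR_AB = 0.2, CONDFDR_BA = 0.2)
  expect_equal(pmax(asg2$CONDFDR_AB, asg2$CONDFDR_BA), 0.2)
})

test_that("an independent conditioning trait leaves condFDR unconditional", {
  sim <- simulate_gwas(sim_config(m = 50000, block_sizes = 1L,
                                  pi1s = 0.01, pi2s = 0.01, pi12 = 0,
                                  sigma_b1_sq = 40 / 272000,
                                  sigma_b2_sq = 40 / 17900, seed = 95))
  grid <- build_fdr_grid(sim$pair, sim$ld, primary = "a",
                         iterations = 1, seed = 96)
  # compare the t=1 column with the p2 <= 0.1 column over the well-populated
  # range: agreement within Monte-Carlo tolerance on the log scale
  rows <- grid$grid <= 2.5
  j <- which(abs(grid$grid - 1.0) < 1e-9)
  d <- abs(log10(grid$value[rows, 1]) - log10(grid$value[rows, j]))
  expect_lt(max(d), 0.2)
})
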