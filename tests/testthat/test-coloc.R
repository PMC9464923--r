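# Brute-force oracle: enumerate every causal configuration (none, one SNP
# for one trait, pairs for H3, shared for H4) with prior weights and
# normalize in plain arithmetic. Independent of the log-sum-exp path.
brute_coloc <- function(la, lb, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  a <- exp(la); b <- exp(lb)
  n <- length(a)
  h0 <- 1
  h1 <- p1 * sum(a)
  h2 <- p2 * sum(b)
  h3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) h3 <- h3 + p1 * p2 * a[i] * b[j]
  }
  h4 <- p12 * sum(a * b)
  w <- c(h0, h1, h2, h3, h4)
  w / sum(w)
}

region_df <- function(z_trait, z_qtl, v = 0.01) {
  data.frame(SNP = paste0("s", seq_along(z_trait)),
             Z_TRAIT = z_trait, V_TRAIT = v, Z_QTL = z_qtl, V_QTL = v,
             stringsAsFactors = FALSE)
}

test_that("log ABF matches the two-density ratio and its limits", {
  z <- 5; v <- 0.01; w <- 0.0225
  beta_hat <- z * sqrt(v)
  direct <- dnorm(beta_hat, 0, sqrt(v + w), log = TRUE) -
    dnorm(beta_hat, 0, sqrt(v), log = TRUE)
  expect_equal(log_abf(z, v, w), direct, tolerance = 1e-12)
  # null signal: negative evidence
  expect_lt(log_abf(0, 0.01, 0.04), 0)
  # vanishing prior variance: no evidence either way
  expect_equal(log_abf(3, 0.01, 1e-12), 0, tolerance = 1e-9)
  expect_error(log_abf(1, -1, 1), "positive")
  expect_error(log_abf(1, 1, 0), "positive")
})

test_that("posteriors equal brute-force enumeration to 1e-10 up to 6 SNPs", {
  zg <- c(0, 1.5, 4, 8)
  # exhaustive z-grids for 2-SNP regions (both traits)
  for (za1 in zg) for (za2 in zg) for (zb1 in zg) for (zb2 in zg) {
    reg <- region_df(c(za1, za2), c(zb1, zb2))
    res <- colocalize(reg)
    la <- log_abf(reg$Z_TRAIT, reg$V_TRAIT, 0.15^2)
    lb <- log_abf(reg$Z_QTL, reg$V_QTL, 0.20^2)
    expect_lt(max(abs(unname(res$pp) - brute_coloc(la, lb))), 1e-10)
  }
  # random regions of 3..6 SNPs
  set.seed(321)
  for (n in 3:6) {
    for (rep in 1:20) {
      reg <- region_df(sample(zg, n, TRUE) + rnorm(n, 0, 0.3),
                       sample(zg, n, TRUE) + rnorm(n, 0, 0.3),
                       v = runif(1, 0.005, 0.05))
      res <- colocalize(reg)
      la <- log_abf(reg$Z_TRAIT, reg$V_TRAIT, 0.15^2)
      lb <- log_abf(reg$Z_QTL, reg$V_QTL, 0.20^2)
      expect_lt(max(abs(unname(res$pp) - brute_coloc(la, lb))), 1e-10)
      expect_equal(sum(res$pp), 1, tolerance = 1e-9)
    }
  }
})

test_that("posteriors are permutation invariant and sum to one", {
  set.seed(5)
  reg <- region_df(rnorm(20, 0, 2), rnorm(20, 0, 2))
  res <- colocalize(reg)
  perm <- reg[sample(nrow(reg)), ]
  expect_equal(colocalize(perm)$pp, res$pp, tolerance = 1e-12)
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)
})

test_that("a sharp shared signal yields PP4 > 0.8, stable under p12 priors", {
  reg <- region_df(c(8, rep(0, 9)), c(8, rep(0, 9)))
  res <- colocalize(reg)
  expect_gt(res$pp["PP4"], 0.8)
  expect_equal(res$decision, "H4")
  sens <- coloc_sensitivity(reg, p12 = c(1e-5, 5e-6))
  expect_true(sens$stable)
  expect_gt(sens$results[["5e-06"]]$pp["PP4"], 0.8)
})

test_that("two distinct sharp signals keep PP3 >= 0.8 under both priors", {
  reg <- region_df(c(8, rep(0, 9)), c(rep(0, 9), 8))
  sens <- coloc_sensitivity(reg, p12 = c(1e-5, 5e-6))
  for (r in sens$results) {
    expect_gt(r$pp["PP3"], 0.8)
    expect_equal(r$decision, "H3")
  }
  expect_true(sens$stable)
})

test_that("no signal anywhere gives PP0 > 0.99 with 100 SNPs", {
  # variances of a realistically powered study (n = 1000, v = 2/n)
  reg <- region_df(rep(0, 100), rep(0, 100), v = 0.002)
  res <- colocalize(reg)
  expect_gt(res$pp["PP0"], 0.99)
})

test_that("decreasing p12 never increases PP4", {
  set.seed(17)
  for (rep in 1:5) {
    reg <- region_df(rnorm(15, 0, 3), rnorm(15, 0, 3))
    p12s <- c(1e-4, 1e-5, 5e-6, 1e-6)
    pp4 <- vapply(p12s, function(p) {
      colocalize(reg, priors = suppressWarnings(
        coloc_priors(p12 = p)))$pp[["PP4"]]
    }, numeric(1))
    expect_true(all(diff(pp4) <= 1e-12))
  }
})

test_that("region assembly windows, aligns and approximates variances", {
  trait <- sumstats(paste0("s", 1:6), chr = 1,
                    bp = c(1e6, 1.1e6, 1.2e6, 1.3e6, 1.6e6, 2e6),
                    a1 = "G", a2 = "A", z = c(1, 8, 0, 1, 2, 3), n = 1e4)
  qtl <- sumstats(paste0("s", c(1:4, 6)), chr = 1,
                  bp = c(1e6, 1.1e6, 1.2e6, 1.3e6, 2e6),
                  a1 = "G", a2 = "A", z = c(0, 7.5, 1, 0, 2), n = 5e3)
  reg <- coloc_region(trait, qtl, lead_snp = "s2", window = 250000)
  # s5 at 1.6e6 is outside the 250-kb window; s6 is outside too
  expect_setequal(reg$SNP, c("s1", "s2", "s3", "s4"))
  expect_equal(unique(reg$V_TRAIT), 1 / (2 * 1e4 * 0.25))
  expect_equal(unique(reg$V_QTL), 1 / (2 * 5e3 * 0.25))
  res <- colocalize(reg)
  expect_gt(res$pp["PP4"], 0.5)
  expect_error(coloc_region(trait, qtl, "missing"), "not found")
})

test_that("scaling both prior variances keeps H3 vs H4 ranking stable", {
  shared <- region_df(c(8, rep(0, 5)), c(8, rep(0, 5)))
  distinct <- region_df(c(8, rep(0, 5)), c(rep(0, 5), 8))
  for (sc in c(0.5, 1, 2)) {
    r_shared <- colocalize(shared, w_trait_sq = sc * 0.15^2,
                           w_qtl_sq = sc * 0.20^2)
    r_distinct <- colocalize(distinct, w_trait_sq = sc * 0.15^2,
                             w_qtl_sq = sc * 0.20^2)
    expect_gt(r_shared$pp["PP4"], r_shared$pp["PP3"])
    expect_gt(r_distinct$pp["PP3"], r_distinct$pp["PP4"])
  }
})
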