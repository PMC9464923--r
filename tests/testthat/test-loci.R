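make_assignment <- function(pair, stat_ba, stat_ab = NULL, conj = NULL) {
  if (is.null(stat_ab)) stat_ab <- stat_ba
  if (is.null(conj)) conj <- pmax(stat_ab, stat_ba)
  out <- data.frame(SNP = pair$SNP, CHR = pair$CHR, BP = pair$BP,
                    P_A = pair$P_A, P_B = pair$P_B,
                    CONDFDR_AB = stat_ab, CONDFDR_BA = stat_ba,
                    CONJFDR = conj,
                    SIG_COND_AB = stat_ab < 0.05,
                    SIG_COND_BA = stat_ba < 0.05,
                    SIG_CONJ = conj < 0.05, stringsAsFactors = FALSE)
  attr(out, "threshold") <- 0.05
  class(out) <- c("fdr_assignment", "data.frame")
  out
}

test_that("five-SNP toy clumping merges into one locus led by the best SNP", {
  snp <- paste0("s", 1:5)
  pair <- toy_pair(snp, bp = 1:5 * 1e5, z_a = 1, z_b = 1)
  stat <- c(0.01, 0.02, 0.2, 0.03, 0.04)
  ld <- ld_reference(pairs = data.frame(
    SNP_A = c("s1", "s4"), SNP_B = c("s2", "s5"), R2 = c(0.7, 0.05)))
  loci <- clump_loci(make_assignment(pair, stat), pair, ld,
                     statistic = "condfdr_ba")
  # s3 is not significant; s2 is absorbed as candidate of s1; gaps between
  # candidate borders (200, 400, 500 kb positions) are under 250 kb
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$SNP, "s1")
  expect_equal(loci$START, 1e5)
  expect_equal(loci$END, 5e5)
  expect_true(all(c("s1", "s2") %in% strsplit(loci$CANDIDATES, ",")[[1]]))
})

test_that("a lone significant SNP forms a singleton locus", {
  pair <- toy_pair("s1", bp = 123456, z_a = 2, z_b = -3)
  loci <- clump_loci(make_assignment(pair, 0.01), pair, singleton_ld("s1"),
                     statistic = "condfdr_ba")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$SNP, "s1")
  expect_equal(loci$START, 123456)
  expect_equal(loci$END, 123456)
  expect_equal(loci$CANDIDATES, "s1")
  expect_equal(loci$DIRECTION, "discordant")
})

test_that("no significant SNP yields an empty locus table, not an error", {
  pair <- toy_pair(paste0("s", 1:3), z_a = 1, z_b = 1)
  loci <- clump_loci(make_assignment(pair, rep(0.5, 3)), pair,
                     singleton_ld(pair$SNP), statistic = "condfdr_ba")
  expect_s3_class(loci, "locus_table")
  expect_equal(nrow(loci), 0L)
})

test_that("published worked example: 11 condFDR and 6 conjFDR loci", {
  ex <- pcos_t2d_example()
  cond_loci <- clump_loci(ex$assignment, ex$pair, ex$ld,
                          statistic = "condfdr_ba")
  conj_loci <- clump_loci(ex$assignment, ex$pair, ex$ld,
                          statistic = "conjfdr")
  expect_equal(nrow(cond_loci), 11L)
  expect_equal(nrow(conj_loci), 6L)
  expect_true(all(conj_loci$SNP %in% cond_loci$SNP))
})

test_that("direction classification matches the printed z-score signs", {
  leads <- pcos_t2d_leads()
  dirs <- classify_direction(leads$Z_T2D, leads$Z_PCOS)
  expect_equal(unname(dirs[leads$SNP == "rs1509096"]), "concordant")
  expect_equal(unname(dirs[leads$SNP == "rs4234212"]), "discordant")
  expect_equal(sum(dirs == "concordant"), 6L)
  expect_equal(sum(dirs == "discordant"), 5L)
  expect_equal(classify_direction(0, 1), "undetermined")
})

test_that("novelty needs sub-threshold GWAS p and catalog independence", {
  ex <- pcos_t2d_example()
  loci <- clump_loci(ex$assignment, ex$pair, ex$ld, statistic = "condfdr_ba")
  catalog <- known_pcos_snps()
  out <- classify_novel(loci, loci$P_B, catalog, ex$ld)
  # the two catalog members match themselves (distance 0) -> not novel
  expect_false(any(out$NOVEL[out$SNP %in% catalog$SNP]))
  expect_equal(sum(out$NOVEL), 9L)
  expect_true(out$NOVEL[out$SNP == "rs13061415"])
  # genome-wide-significant original p blocks novelty regardless of catalog
  out2 <- classify_novel(loci, rep(1e-9, nrow(loci)), catalog, ex$ld)
  expect_false(any(out2$NOVEL))
})

test_that("clumping invariants hold on simulated data with LD blocks", {
  sim <- simulate_gwas(sim_config(m = 20000, block_sizes = 5L,
                                  r2_within = 0.8, pi1s = 0.004,
                                  pi2s = 0.004, pi12 = 0.004,
                                  sigma_b1_sq = 60 / 272000,
                                  sigma_b2_sq = 60 / 17900,
                                  rho12 = 0.9, seed = 101))
  asg <- condfdr(sim$pair, sim$ld, iterations = 10, seed = 102)
  loci <- clump_loci(asg, sim$pair, sim$ld, statistic = "conjfdr")
  expect_gt(nrow(loci), 0)
  # lead SNPs pairwise r2 < 0.1
  if (nrow(loci) > 1) {
    for (i in seq_len(nrow(loci) - 1)) {
      r2 <- ld_r2(sim$ld, loci$SNP[i], loci$SNP[-seq_len(i)])
      expect_true(all(r2 < 0.1))
    }
  }
  # every candidate is in r2 >= 0.6 with some lead of its (merged) locus
  for (k in seq_len(nrow(loci))) {
    cand <- strsplit(loci$CANDIDATES[k], ",")[[1]]
    leads_k <- strsplit(loci$LEADS[k], ",")[[1]]
    hit <- Reduce(`|`, lapply(leads_k, function(l)
      ld_r2(sim$ld, l, cand) >= 0.6 | cand == l))
    expect_true(all(hit))
    expect_equal(loci$START[k], min(sim$pair$BP[sim$pair$SNP %in% cand]))
    expect_equal(loci$END[k], max(sim$pair$BP[sim$pair$SNP %in% cand]))
  }
  # order independence: permuting the input rows yields identical loci
  perm <- sample(nrow(sim$pair))
  pair2 <- sim$pair[perm, ]
  class(pair2) <- class(sim$pair)
  asg2 <- asg[perm, ]
  class(asg2) <- class(asg)
  attr(asg2, "threshold") <- attr(asg, "threshold")
  loci2 <- clump_loci(asg2, pair2, sim$ld, statistic = "conjfdr")
  expect_equal(loci2[order(loci2$CHR, loci2$START), -1],
               loci[order(loci$CHR, loci$START), -1],
               ignore_attr = TRUE)
})
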