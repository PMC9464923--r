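test_that("reading the packaged lead-SNP table yields 11 validated records", {
  leads <- pcos_t2d_leads()
  f <- write_tsv(data.frame(SNP = leads$SNP, CHR = leads$CHR, BP = leads$BP,
                            A1 = leads$A1, A2 = leads$A2,
                            Z = leads$Z_T2D, P = leads$P_T2D, N = 272000))
  ss <- read_sumstats(f)
  expect_s3_class(ss, "sumstats")
  expect_equal(nrow(ss), 11L)
  i <- match("rs13061415", ss$SNP)
  expect_equal(ss$P[i], 6.6e-9)
  expect_equal(ss$Z[i], 5.80)
})

test_that("degenerate inputs error cleanly", {
  f <- tempfile()
  writeLines("SNP\tCHR\tBP\tA1\tA2\tZ\tP\tN", f)
  expect_error(read_sumstats(f), "no data rows|no valid")
  f2 <- write_tsv(data.frame(SNP = "rs1", CHR = 1, BP = 100, A1 = "G"))
  expect_error(read_sumstats(f2), "missing mandatory")
  expect_error(read_sumstats(tempfile()), "not found")
})

test_that("z is derived from beta/se and p from z when absent", {
  f <- write_tsv(data.frame(SNP = c("rs1", "rs2"), CHR = 1, BP = c(1e5, 2e5),
                            A1 = "G", A2 = "A", BETA = c(0.1, -0.2),
                            SE = c(0.05, 0.04), N = 1000))
  ss <- read_sumstats(f)
  expect_equal(ss$Z, c(2, -5))
  expect_equal(ss$P, 2 * pnorm(-c(2, 5)))
})

test_that("validation drops inconsistent, invalid and duplicate rows", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs1", "rs4"),
                   CHR = c(1, 1, 23, 1, 1), BP = 1:5 * 1e5,
                   A1 = c("G", "G", "G", "G", "G"),
                   A2 = c("A", "G", "A", "A", "A"),
                   Z = c(2, 2, 2, 2, 10),
                   P = c(2 * pnorm(-2), 2 * pnorm(-2), 2 * pnorm(-2),
                         2 * pnorm(-2), 0.5),
                   N = 1000)
  f <- write_tsv(df)
  # rs2: identical alleles; rs3: CHR 23; rs1 duplicate; rs4: z/p mismatch
  ss <- suppressMessages(read_sumstats(f))
  expect_equal(ss$SNP, "rs1")
  expect_equal(attr(ss, "n_dropped"), 4L)
})

test_that("write/read round trip reproduces records exactly", {
  ss <- sumstats(snp = c("rs1", "rs2"), chr = c(1, 2), bp = c(12345, 6789),
                 a1 = c("G", "C"), a2 = c("A", "T"),
                 z = c(1.234567890123, -0.1), n = c(1000, 2000))
  f <- tempfile(fileext = ".tsv")
  write_sumstats(ss, f)
  back <- read_sumstats(f)
  expect_identical(as.data.frame(back)[names(back)],
                   as.data.frame(ss)[names(ss)])
})

test_that("harmonize negates z on allele swap and drops ambiguous SNPs", {
  a <- sumstats(snp = c("rs1", "rs2", "rs3", "rs4"), chr = 1,
                bp = 1:4 * 1e5,
                a1 = c("G", "G", "A", "G"), a2 = c("A", "A", "T", "A"),
                z = c(2.0, 1.0, 1.0, 1.0))
  b <- sumstats(snp = c("rs1", "rs2", "rs3", "rs4"), chr = 1,
                bp = 1:4 * 1e5,
                a1 = c("A", "G", "A", "C"), a2 = c("G", "A", "T", "T"),
                z = c(1.5, 0.7, 0.5, 0.9))
  h <- suppressMessages(harmonize(a, b))
  # rs1 swapped -> -1.5; rs2 same; rs3 ambiguous (A/T); rs4 mismatched
  expect_equal(h$SNP, c("rs1", "rs2"))
  expect_equal(h$Z_B, c(-1.5, 0.7))
  expect_equal(attr(h, "n_ambiguous"), 1L)
  expect_equal(attr(h, "n_mismatch"), 1L)
})

test_that("harmonization inverts random allele permutations exactly", {
  set.seed(42)
  n <- 1000
  z_true <- rnorm(n)
  snp <- paste0("rs", seq_len(n))
  a <- sumstats(snp = snp, chr = 1, bp = seq_len(n) * 1e4,
                a1 = "G", a2 = "A", z = rnorm(n))
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  b <- sumstats(snp = snp, chr = 1, bp = seq_len(n) * 1e4,
                a1 = ifelse(flip, "A", "G"), a2 = ifelse(flip, "G", "A"),
                z = ifelse(flip, -z_true, z_true))
  h <- harmonize(a, b)
  expect_equal(h$Z_B, z_true)
  # sign flipped exactly for swapped-allele SNPs
  expect_equal(sign(h$Z_B) * sign(ifelse(flip, -z_true, z_true)),
               ifelse(flip, -1, 1))
  # idempotence: a harmonized pair re-harmonized changes nothing
  a2 <- sumstats(snp = h$SNP, chr = h$CHR, bp = h$BP, a1 = h$A1, a2 = h$A2,
                 z = h$Z_A)
  b2 <- sumstats(snp = h$SNP, chr = h$CHR, bp = h$BP, a1 = h$A1, a2 = h$A2,
                 z = h$Z_B)
  h2 <- harmonize(a2, b2)
  expect_equal(h2$Z_B, h$Z_B)
  expect_equal(h2$Z_A, h$Z_A)
})

test_that("harmonize errors on empty intersection", {
  a <- sumstats("rs1", 1, 100, "G", "A", 1)
  b <- sumstats("rs2", 1, 100, "G", "A", 1)
  expect_error(harmonize(a, b), "no shared")
})

test_that("LD blocks are connected components of the r2 > 0.1 graph", {
  pairs <- data.frame(SNP_A = c("s1", "s2", "s4"),
                      SNP_B = c("s2", "s3", "s5"),
                      R2 = c(0.7, 0.2, 0.05))
  ld <- ld_reference(pairs = pairs)
  blk <- ld_block_of(ld, c("s1", "s2", "s3", "s4", "s5"))
  expect_equal(blk[1], blk[2])          # r2 = 0.7 links s1-s2
  expect_equal(blk[2], blk[3])          # r2 = 0.2 > 0.1 links s2-s3
  expect_false(blk[4] == blk[5])        # r2 = 0.05 does not link
  expect_equal(ld_r2(ld, "s1", "s2"), 0.7)
  expect_equal(ld_r2(ld, "s1", "s5"), 0)  # absent pair -> 0
  expect_equal(ld_r2(ld, "s1", "s1"), 1)
})

test_that("block-file round trip preserves the reference", {
  ld <- ld_reference(blocks = c(a = 1, b = 1, c = 2), r2_within = 0.8)
  f <- tempfile(fileext = ".tsv")
  write_ld_blocks(ld, f)
  back <- read_ld(f, r2_within = 0.8)
  expect_equal(ld_block_of(back, c("a", "b", "c")),
               ld_block_of(ld, c("a", "b", "c")))
  expect_equal(ld_r2(back, "a", "b"), 0.8)
  expect_equal(ld_r2(back, "a", "c"), 0)
})
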