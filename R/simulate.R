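#' Configuration for the two-trait causal-mixture GWAS generator
#'
#' Defines the generating model: every SNP belongs to one of four components
#' (null / trait-1-specific / trait-2-specific / shared) drawn with
#' probabilities `(1 - pi1s - pi2s - pi12, pi1s, pi2s, pi12)`. Causal
#' effects are Gaussian on the standardized-genotype scale with per-trait
#' discoverabilities `sigma_b1_sq`, `sigma_b2_sq`; inside the shared
#' component the two effects are correlated with coefficient `rho12`.
#' LD is modeled as disjoint equicorrelated blocks with a single
#' within-block r-squared.
#'
#' The defaults emulate a well-powered case-control GWAS (trait 1, effective
#' sample size 272,000) paired with a modestly powered one (trait 2,
#' effective sample size 17,900), polygenicities of a few parts in ten
#' thousand, and a strongly correlated shared component — the regime of the
#' type-2-diabetes / polycystic-ovary-syndrome pairing that motivates the
#' package.
#'
#' @param m Number of SNPs.
#' @param block_sizes Fixed LD-block size (scalar) or a vector of sizes to
#'   sample from; 1 gives independent SNPs.
#' @param r2_within Within-block r-squared (single value in \[0, 1\]).
#' @param pi1s,pi2s,pi12 Component probabilities (trait-1-specific,
#'   trait-2-specific, shared); their sum must be at most 1.
#' @param sigma_b1_sq,sigma_b2_sq Discoverabilities: variance of causal
#'   effect sizes per trait.
#' @param rho12 Effect-size correlation inside the shared component.
#' @param n1,n2 Per-trait (effective) sample sizes.
#' @param sigma01,sigma02 Null-score standard deviations (1 = no inflation;
#'   values above 1 model uniform inflation).
#' @param seed RNG seed; every draw is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(m = 100000L, block_sizes = 5L, r2_within = 0.8,
                       pi1s = 5e-4, pi2s = 1.6e-4, pi12 = 2e-4,
                       sigma_b1_sq = 1.1e-4, sigma_b2_sq = 1.7e-3,
                       rho12 = 0.9, n1 = 272000, n2 = 17900,
                       sigma01 = 1, sigma02 = 1, seed) {
  cfg <- list(m = as.integer(m), block_sizes = as.integer(block_sizes),
              r2_within = r2_within, pi1s = pi1s, pi2s = pi2s, pi12 = pi12,
              sigma_b1_sq = sigma_b1_sq, sigma_b2_sq = sigma_b2_sq,
              rho12 = rho12, n1 = n1, n2 = n2,
              sigma01 = sigma01, sigma02 = sigma02, seed = as.integer(seed))
  with(cfg, {
    if (m < 1) stop("m must be positive", call. = FALSE)
    if (any(block_sizes < 1)) stop("block sizes must be >= 1", call. = FALSE)
    if (is.na(r2_within) || r2_within < 0 || r2_within > 1) {
      stop("r2_within must lie in [0, 1]", call. = FALSE)
    }
    if (min(pi1s, pi2s, pi12) < 0 || pi1s + pi2s + pi12 > 1) {
      stop("component probabilities must be >= 0 and sum to <= 1",
           call. = FALSE)
    }
    if (min(sigma_b1_sq, sigma_b2_sq) < 0) {
      stop("discoverabilities must be >= 0", call. = FALSE)
    }
    if (abs(rho12) > 1) stop("|rho12| must be <= 1", call. = FALSE)
    if (min(sigma01, sigma02) < 1) {
      stop("null-score standard deviations must be >= 1", call. = FALSE)
    }
    if (min(n1, n2) <= 0) stop("sample sizes must be positive", call. = FALSE)
  })
  if (is.na(cfg$seed)) stop("a seed is required", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate two-trait GWAS summary statistics with known causal truth
#'
#' Draws each SNP's component from the four-component multinomial, its
#' causal effects from the component's (possibly correlated) Gaussian, and
#' produces per-trait z-scores
#' `z_t = sqrt(n_t) * signal_t + noise_t`, where the signal of a SNP in an
#' LD block is its own effect plus `sqrt(r2_within)` times the summed
#' effects of its block partners, and the noise is block-equicorrelated
#' (correlation `r2_within`, variance `sigma0t^2`). P-values are two-sided
#' normal. Alleles are assigned consistently (`A1 = "G"`, `A2 = "A"`).
#'
#' SNPs are laid out on chromosomes 1-22 in contiguous blocks at 10-kb
#' spacing, so positional operations (region exclusion, locus merging)
#' behave as on real data.
#'
#' @param config A [sim_config()].
#' @return A `gwas_sim` list with elements `a`, `b` (two `sumstats`),
#'   `ld` (`ld_ref` built from the true block labels), `truth` (data frame
#'   `SNP, COMPONENT, BETA1, BETA2, BLOCK`), `pair` (the already-aligned
#'   `harmonized_pair`), and `config`.
#' @examples
#' sim <- simulate_gwas(sim_config(m = 1000, seed = 1))
#' table(sim$truth$COMPONENT)
#' @export
simulate_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m

  # LD blocks
  if (length(config$block_sizes) == 1L) {
    nb <- ceiling(m / config$block_sizes)
    block <- rep(seq_len(nb), each = config$block_sizes)[seq_len(m)]
  } else {
    sizes <- sample(config$block_sizes,
                    size = ceiling(m / min(config$block_sizes)) + 1L,
                    replace = TRUE)
    while (sum(sizes) < m) sizes <- c(sizes, sample(config$block_sizes, 10L,
                                                    replace = TRUE))
    block <- rep(seq_along(sizes), times = sizes)[seq_len(m)]
  }
  nb <- max(block)

  # genome layout: blocks contiguous, split over 22 chromosomes
  blocks_per_chrom <- ceiling(nb / 22)
  chrom <- 1L + (block - 1L) %/% blocks_per_chrom
  pos <- numeric(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- 1e6 + (seq_along(idx) - 1) * 1e4
  }

  # causal components
  u <- stats::runif(m)
  comp <- integer(m)                       # 0 null, 1 c1, 2 c2, 3 both
  comp[u < config$pi1s] <- 1L
  comp[u >= config$pi1s & u < config$pi1s + config$pi2s] <- 2L
  comp[u >= config$pi1s + config$pi2s &
         u < config$pi1s + config$pi2s + config$pi12] <- 3L

  beta1 <- numeric(m); beta2 <- numeric(m)
  s1 <- sqrt(config$sigma_b1_sq); s2 <- sqrt(config$sigma_b2_sq)
  i1 <- comp == 1L; i2 <- comp == 2L; ib <- comp == 3L
  beta1[i1] <- stats::rnorm(sum(i1), 0, s1)
  beta2[i2] <- stats::rnorm(sum(i2), 0, s2)
  if (any(ib)) {
    e1 <- stats::rnorm(sum(ib)); e2 <- stats::rnorm(sum(ib))
    beta1[ib] <- s1 * e1
    beta2[ib] <- s2 * (config$rho12 * e1 +
                         sqrt(1 - config$rho12^2) * e2)
  }

  # LD convolution inside equicorrelated blocks: tag SNPs carry
  # sqrt(r2) of their partners' causal signal
  sq_r <- sqrt(config$r2_within)
  bs1 <- rowsum(beta1, block); bs2 <- rowsum(beta2, block)
  sig1 <- beta1 + sq_r * (bs1[block] - beta1)
  sig2 <- beta2 + sq_r * (bs2[block] - beta2)

  # block-equicorrelated noise, independent across traits
  rho_n <- config$r2_within
  ub1 <- stats::rnorm(nb); ub2 <- stats::rnorm(nb)
  eps1 <- config$sigma01 * (sqrt(rho_n) * ub1[block] +
                              sqrt(1 - rho_n) * stats::rnorm(m))
  eps2 <- config$sigma02 * (sqrt(rho_n) * ub2[block] +
                              sqrt(1 - rho_n) * stats::rnorm(m))

  z1 <- sqrt(config$n1) * sig1 + eps1
  z2 <- sqrt(config$n2) * sig2 + eps2
  p1 <- pmax(2 * stats::pnorm(-abs(z1)), .Machine$double.xmin)
  p2 <- pmax(2 * stats::pnorm(-abs(z2)), .Machine$double.xmin)

  snp <- paste0("snp", seq_len(m))
  mk <- function(z, p, n) {
    ss <- data.frame(SNP = snp, CHR = chrom, BP = pos,
                     A1 = "G", A2 = "A", Z = z, P = p, N = n,
                     stringsAsFactors = FALSE)
    class(ss) <- c("sumstats", "data.frame")
    ss
  }
  pair <- data.frame(SNP = snp, CHR = chrom, BP = pos, A1 = "G", A2 = "A",
                     Z_A = z1, P_A = p1, N_A = config$n1,
                     Z_B = z2, P_B = p2, N_B = config$n2,
                     stringsAsFactors = FALSE)
  class(pair) <- c("harmonized_pair", "data.frame")

  truth <- data.frame(
    SNP = snp,
    COMPONENT = c("null", "c1", "c2", "both")[comp + 1L],
    BETA1 = beta1, BETA2 = beta2, BLOCK = block,
    stringsAsFactors = FALSE
  )
  structure(list(
    a = mk(z1, p1, config$n1), b = mk(z2, p2, config$n2),
    ld = ld_reference(blocks = stats::setNames(block, snp),
                      r2_within = config$r2_within),
    truth = truth, pair = pair, config = config
  ), class = "gwas_sim")
}

#' @export
print.gwas_sim <- function(x, ...) {
  tab <- table(factor(x$truth$COMPONENT,
                      levels = c("null", "c1", "c2", "both")))
  cat("Synthetic two-trait GWAS: ", x$config$m, " SNPs, ",
      length(unique(x$truth$BLOCK)), " LD blocks (seed ", x$config$seed,
      ")\n", sep = "")
  cat("  components: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the two summary-statistic TSVs, the LD block file, and the truth
#' table (`SNP, COMPONENT, BETA1, BETA2, BLOCK`).
#'
#' @param sim A `gwas_sim`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    trait_a = file.path(dir, paste0(prefix, "_trait_a.tsv")),
    trait_b = file.path(dir, paste0(prefix, "_trait_b.tsv")),
    ld = file.path(dir, paste0(prefix, "_ld_blocks.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_sumstats(sim$a, paths["trait_a"])
  write_sumstats(sim$b, paths["trait_b"])
  write_ld_blocks(sim$ld, paths["ld"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
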