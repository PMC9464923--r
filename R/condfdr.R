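#' Build a conditional-FDR lookup grid
#'
#' Estimates condFDR(primary | conditioning) on a two-dimensional grid of
#' `-log10 p` values. For each random-pruning iteration and each cumulative
#' conditioning threshold `s` (secondary `-log10 p >= s`), the conditional
#' FDR at primary level `p1` is the conservative empirical estimate
#' `min(1, p1 / Fhat(p1 | s))`, where `Fhat` is the empirical CDF of the
#' primary p-values among pruned SNPs in the stratum (with the null
#' proportion set to 1 and the exceedance count floored at one SNP so the
#' rank-1 value equals `n * p1`). Grids are averaged over iterations and
#' then monotonized along the primary axis by a running maximum from the
#' smallest to the largest p-value.
#'
#' A conditional ECDF cannot be estimated from a handful of SNPs: a SNP
#' sitting alone in an extreme conditioning stratum would act as its own
#' reference distribution and receive `condFDR = p1` regardless of
#' multiplicity. Conditioning columns whose stratum held fewer than
#' `min_stratum` pruned SNPs (in an iteration) therefore inherit the
#' nearest looser column's values; the loosest (all-SNPs) column always
#' stands.
#'
#' @param pair A post-QC `harmonized_pair`.
#' @param ld An `ld_ref` for random pruning.
#' @param primary `"a"` or `"b"`: the trait whose FDR is estimated,
#'   conditioned on the other.
#' @param iterations,seed Pruning settings (default 100 iterations).
#' @param x_max,dx Grid range and spacing on the `-log10 p` scale
#'   (defaults 10 and 0.1; values beyond `x_max` are clamped).
#' @param min_stratum Minimum pruned-SNP count for a conditioning stratum
#'   to define its own column (default 100).
#' @return An `fdr_grid` object: `grid` (vector of `-log10 p` grid points),
#'   `value` (matrix, rows = primary grid, columns = conditioning
#'   thresholds), `primary`, `iterations`.
#' @export
build_fdr_grid <- function(pair, ld, primary = c("a", "b"),
                           iterations = 100L, seed, x_max = 10, dx = 0.1,
                           min_stratum = 100L) {
  primary <- match.arg(primary)
  stopifnot(iterations >= 1L)
  p1 <- if (primary == "a") pair$P_A else pair$P_B
  p2 <- if (primary == "a") pair$P_B else pair$P_A
  g <- seq(0, x_max, by = dx)
  ng <- length(g)
  x1 <- pmin(-log10(p1), x_max)
  x2 <- pmin(-log10(p2), x_max)
  b1 <- findInterval(x1, g)            # in 1..ng
  b2 <- findInterval(x2, g)

  subsets <- random_prune(pair, ld, iterations = iterations, seed = seed)
  acc <- matrix(0, ng, ng)
  ndef <- numeric(ng)                  # iterations with a non-empty column
  p1_grid <- 10^(-g)
  for (idx in subsets) {
    h <- matrix(0, ng, ng)
    tab <- tabulate((b2[idx] - 1L) * ng + b1[idx], nbins = ng * ng)
    h[] <- tab
    # joint exceedance S[i, j] = #{x1 >= g[i], x2 >= g[j]}
    S <- apply(h, 2L, function(cl) rev(cumsum(rev(cl))))
    S <- t(apply(S, 1L, function(rw) rev(cumsum(rev(rw)))))
    ntot <- S[1L, ]                    # stratum sizes per threshold
    def <- ntot >= min_stratum
    def[1L] <- ntot[1L] > 0            # the all-SNPs column always stands
    if (!any(def)) next
    # beyond the observed range of primary p the ECDF continues at its last
    # (rank-1) value: carry the smallest nonzero exceedance count forward,
    # which keeps ECDF ratios invariant under duplication of the SNP set
    Sd <- S[, def, drop = FALSE]
    Sd <- apply(Sd, 2L, function(cl) pmax(cl, min(cl[cl > 0])))
    Fhat <- Sd / rep(ntot[def], each = ng)
    cond <- pmin(1, p1_grid / Fhat)
    acc[, def] <- acc[, def] + cond
    ndef[def] <- ndef[def] + 1
  }
  if (all(ndef == 0)) stop("no non-empty conditioning stratum", call. = FALSE)
  val <- matrix(NA_real_, ng, ng)
  def <- ndef > 0
  val[, def] <- acc[, def, drop = FALSE] / rep(ndef[def], each = ng)
  # undefined tighter columns inherit the nearest looser threshold
  for (j in seq_len(ng)[-1L]) if (!def[j]) val[, j] <- val[, j - 1L]
  # monotone non-decreasing along increasing primary p (decreasing grid)
  for (j in seq_len(ng)) {
    val[, j] <- rev(cummax(rev(val[, j])))
  }
  structure(list(grid = g, value = val, primary = primary,
                 iterations = iterations, dx = dx, x_max = x_max,
                 min_stratum = min_stratum),
            class = "fdr_grid")
}

#' @export
print.fdr_grid <- function(x, ...) {
  cat("condFDR lookup grid (primary trait ", x$primary, "): ",
      length(x$grid), " x ", length(x$grid), " cells, ",
      x$iterations, " pruning iterations\n", sep = "")
  invisible(x)
}

#' @keywords internal
interp_fdr_grid <- function(grid, x1, x2) {
  g <- grid$grid
  ng <- length(g)
  dx <- grid$dx
  cl <- function(x) pmin(pmax(x, 0), grid$x_max)
  x1 <- cl(x1); x2 <- cl(x2)
  i <- pmin(1L + as.integer(floor(x1 / dx)), ng - 1L)
  j <- pmin(1L + as.integer(floor(x2 / dx)), ng - 1L)
  tx <- (x1 - g[i]) / dx
  ty <- (x2 - g[j]) / dx
  v <- grid$value
  v00 <- v[cbind(i, j)];       v10 <- v[cbind(i + 1L, j)]
  v01 <- v[cbind(i, j + 1L)];  v11 <- v[cbind(i + 1L, j + 1L)]
  out <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  pmin(pmax(out, .Machine$double.xmin), 1)
}

#' Assign per-SNP condFDR and conjFDR values
#'
#' Every SNP of the pair (pruned or not) receives its two reciprocal
#' conditional FDR values by bilinear interpolation on the lookup grids,
#' and the conjunctional FDR as their maximum, which upper-bounds the
#' posterior probability that the SNP is null for either trait.
#' SNPs outside the grid range are clamped to the boundary.
#'
#' @param pair The `harmonized_pair` the grids were built from.
#' @param grid_ab `fdr_grid` with primary trait `a` (condFDR of A given B).
#' @param grid_ba `fdr_grid` with primary trait `b`.
#' @param threshold Significance threshold for the flags (default 0.05).
#' @return An `fdr_assignment` data frame: `SNP, CHR, BP, P_A, P_B,
#'   CONDFDR_AB, CONDFDR_BA, CONJFDR, SIG_COND_AB, SIG_COND_BA, SIG_CONJ`.
#' @export
assign_fdr <- function(pair, grid_ab, grid_ba, threshold = 0.05) {
  stopifnot(grid_ab$primary == "a", grid_ba$primary == "b")
  x_a <- -log10(pair$P_A)
  x_b <- -log10(pair$P_B)
  cond_ab <- interp_fdr_grid(grid_ab, x_a, x_b)
  cond_ba <- interp_fdr_grid(grid_ba, x_b, x_a)
  conj <- pmax(cond_ab, cond_ba)
  out <- data.frame(
    SNP = pair$SNP, CHR = pair$CHR, BP = pair$BP,
    P_A = pair$P_A, P_B = pair$P_B,
    CONDFDR_AB = cond_ab, CONDFDR_BA = cond_ba, CONJFDR = conj,
    SIG_COND_AB = cond_ab < threshold,
    SIG_COND_BA = cond_ba < threshold,
    SIG_CONJ = conj < threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("fdr_assignment", "data.frame")
  out
}

#' @export
print.fdr_assignment <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat("condFDR/conjFDR assignment: ", nrow(x), " SNPs\n", sep = "")
  cat(sprintf("  condFDR(A|B) < %g: %d   condFDR(B|A) < %g: %d   conjFDR < %g: %d\n",
              thr, sum(x$SIG_COND_AB), thr, sum(x$SIG_COND_BA),
              thr, sum(x$SIG_CONJ)))
  invisible(x)
}

#' One-call condFDR/conjFDR computation
#'
#' Builds both reciprocal lookup grids and assigns per-SNP values.
#'
#' @inheritParams build_fdr_grid
#' @param threshold Significance threshold for the flags.
#' @param ... Passed to [build_fdr_grid()] (grid spacing, `min_stratum`).
#' @return An `fdr_assignment`, with the two grids attached as attributes
#'   `grid_ab` and `grid_ba`.
#' @export
condfdr <- function(pair, ld, iterations = 100L, seed, threshold = 0.05,
                    ...) {
  grid_ab <- build_fdr_grid(pair, ld, primary = "a",
                            iterations = iterations, seed = seed, ...)
  grid_ba <- build_fdr_grid(pair, ld, primary = "b",
                            iterations = iterations, seed = seed + 1L, ...)
  out <- assign_fdr(pair, grid_ab, grid_ba, threshold = threshold)
  attr(out, "grid_ab") <- grid_ab
  attr(out, "grid_ba") <- grid_ba
  out
}

#' Manhattan-style plot of condFDR or conjFDR values
#'
#' Plots `-log10` of the chosen FDR statistic along the genome.
#'
#' @param x An `fdr_assignment`.
#' @param statistic Column to plot.
#' @param threshold Horizontal reference line (default 0.05).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fdr_assignment <- function(x, statistic = c("CONJFDR", "CONDFDR_AB",
                                                 "CONDFDR_BA"),
                                threshold = 0.05, ...) {
  statistic <- match.arg(statistic)
  ord <- order(x$CHR, x$BP)
  v <- -log10(x[[statistic]][ord])
  chr <- x$CHR[ord]
  pos <- cumsum(c(0, diff(x$BP[ord]) > 0) * 0 + 1)  # index along genome
  graphics::plot(pos, v, pch = 16, cex = 0.3,
                 col = c("grey30", "grey60")[1 + chr %% 2],
                 xlab = "SNP (genome order)",
                 ylab = paste0("-log10 ", statistic), ...)
  graphics::abline(h = -log10(threshold), col = "red", lty = 2)
  invisible(x)
}
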