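#' Random LD pruning
#'
#' Draws, for each iteration, one uniformly chosen SNP per LD block
#' (blocks are the `r2 > 0.1` connected components of the reference;
#' SNPs absent from the reference count as singleton blocks). Averaging
#' empirical distributions over such draws removes the over-counting of
#' correlated SNPs without fixing an arbitrary representative.
#'
#' @param pair A `harmonized_pair`.
#' @param ld An `ld_ref`.
#' @param iterations Number of pruning draws (default 100).
#' @param seed RNG seed; subsets are reproducible from it.
#' @return List of `iterations` integer vectors of row indices into `pair`.
#' @export
random_prune <- function(pair, ld, iterations = 100L, seed) {
  stopifnot(iterations >= 1L)
  block <- ld_block_of(ld, pair$SNP)
  m <- nrow(pair)
  set.seed(seed)
  lapply(seq_len(iterations), function(i) {
    ord <- sample.int(m)
    sort(ord[!duplicated(block[ord])])
  })
}

#' Stratified conditional Q-Q curves
#'
#' For each conditioning stratum (secondary-trait p-value below a
#' threshold `t`), computes the averaged empirical exceedance of the
#' primary trait's p-values over random-pruning iterations: at each nominal
#' grid point `g`, the fraction of stratum SNPs with `-log10 p >= g`,
#' averaged across iterations, reported as `y = -log10(fraction)`.
#' Plotted in the conventional orientation (nominal on the vertical axis
#' against the empirical quantile), increasing leftward deflection of
#' tighter strata is the pleiotropic-enrichment readout.
#'
#' SNPs beyond genome-wide significance in the primary trait
#' (`-log10 p >= 7.3`, i.e. `p < 5e-8`) are excluded so the curves describe
#' sub-threshold polygenic signal.
#'
#' @param pair A `harmonized_pair` (post-QC).
#' @param ld An `ld_ref`.
#' @param primary `"a"` or `"b"`: the trait whose p-values form the curve;
#'   the other trait conditions.
#' @param strata Descending conditioning p-value thresholds in (0, 1].
#' @param iterations,seed Pruning settings, see [random_prune()].
#' @param grid Nominal `-log10 p` grid on which iteration-level empirical
#'   fractions are averaged.
#' @return A `cond_qq` object: list with `curves` (one data frame
#'   `x` = nominal grid, `y` = -log10 averaged exceedance per stratum),
#'   `counts` (mean stratum sizes), `strata`, `primary`, `iterations`.
#' @export
conditional_qq <- function(pair, ld, primary = c("a", "b"),
                           strata = c(1, 0.1, 0.01, 0.001),
                           iterations = 100L, seed,
                           grid = seq(0, 7.3, by = 0.01)) {
  primary <- match.arg(primary)
  stopifnot(all(diff(strata) < 0), all(strata > 0), all(strata <= 1))
  p1 <- if (primary == "a") pair$P_A else pair$P_B
  p2 <- if (primary == "a") pair$P_B else pair$P_A
  x1 <- -log10(p1)
  x2 <- -log10(p2)
  sub <- x1 < 7.3                       # focus below genome-wide significance

  subsets <- random_prune(pair, ld, iterations = iterations, seed = seed)
  ng <- length(grid)
  acc <- matrix(0, nrow = ng, ncol = length(strata))
  cnt <- numeric(length(strata))
  n_used <- numeric(length(strata))
  for (idx in subsets) {
    idx <- idx[sub[idx]]
    for (k in seq_along(strata)) {
      sel <- idx[p2[idx] < strata[k]]
      ns <- length(sel)
      if (ns == 0L) next
      # exceedance count at each grid point via a reversed cumulative sum
      bins <- findInterval(x1[sel], grid)     # 0 never occurs (x1 >= 0)
      h <- tabulate(bins, nbins = ng)
      exceed <- rev(cumsum(rev(h)))           # #{x1 >= grid[i]}
      acc[, k] <- acc[, k] + exceed / ns
      cnt[k] <- cnt[k] + ns
      n_used[k] <- n_used[k] + 1
    }
  }
  dropped <- n_used == 0
  if (any(dropped)) {
    warning("stratum with zero SNPs dropped: t = ",
            paste(strata[dropped], collapse = ", "))
  }
  curves <- list()
  for (k in which(!dropped)) {
    frac <- acc[, k] / n_used[k]
    # zero exceedance gives an infinite empirical quantile (curve ends)
    curves[[paste0("t", strata[k])]] <- data.frame(x = grid, y = -log10(frac))
  }
  structure(list(curves = curves,
                 counts = stats::setNames(cnt / pmax(n_used, 1), strata)[!dropped],
                 strata = strata[!dropped], primary = primary,
                 iterations = iterations),
            class = "cond_qq")
}

#' Nominal significance attained at a given empirical quantile
#'
#' Reads a conditional Q-Q curve in the conventional orientation: returns
#' the nominal `-log10 p` at which the averaged empirical exceedance
#' fraction of a stratum falls to `10^-q`. Larger values for tighter
#' conditioning strata quantify pleiotropic enrichment.
#'
#' @param qq A `cond_qq` object.
#' @param q Empirical `-log10` quantile (default 2, i.e. the top 1%).
#' @return Named numeric vector, one value per stratum.
#' @export
qq_enrichment <- function(qq, q = 2) {
  vapply(qq$curves, function(cv) {
    i <- which(cv$y >= q)
    if (!length(i)) return(max(cv$x))
    cv$x[min(i)]
  }, numeric(1))
}

#' @export
print.cond_qq <- function(x, ...) {
  cat("Stratified conditional Q-Q (primary trait ", x$primary, ", ",
      x$iterations, " pruning iterations)\n", sep = "")
  cat("  mean stratum sizes: ",
      paste(sprintf("p<%s: %.0f", names(x$counts), x$counts),
            collapse = ", "), "\n", sep = "")
  enr <- qq_enrichment(x)
  cat("  nominal -log10 p at empirical quantile 2: ",
      paste(sprintf("%.2f", enr), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot stratified conditional Q-Q curves
#'
#' Conventional orientation: empirical `-log10` quantile on the horizontal
#' axis, nominal `-log10 p` on the vertical; the dotted line is the global
#' null.
#'
#' @param x A `cond_qq` object.
#' @param cols Curve colors, one per stratum.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cond_qq <- function(x, cols = c("blue", "orange", "green3", "purple"),
                         ...) {
  xmax <- max(vapply(x$curves, function(cv) max(cv$y[is.finite(cv$y)]),
                     numeric(1)))
  graphics::plot(NA, xlim = c(0, min(xmax, 10)), ylim = c(0, 7.3),
                 xlab = expression(Empirical ~ -log[10] ~ q),
                 ylab = expression(Nominal ~ -log[10] ~ p), ...)
  graphics::abline(0, 1, lty = 3)
  for (k in seq_along(x$curves)) {
    cv <- x$curves[[k]]
    graphics::lines(cv$y, cv$x, col = cols[(k - 1) %% length(cols) + 1])
  }
  graphics::legend("bottomright", legend = paste0("p < ", x$strata),
                   col = cols[seq_along(x$curves)], lty = 1, bty = "n")
  invisible(x)
}
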