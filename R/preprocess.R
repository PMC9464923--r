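#' Default long-range LD exclusion regions (hg19)
#'
#' The extended MHC region (chr6:25,119,106-33,854,733) and the 8p23.1
#' inversion polymorphism (chr8:7,200,000-12,500,000). Both regions carry
#' unusually long-range LD that biases FDR lookup tables built from pruned
#' SNPs, so they are removed before any conditional-FDR computation.
#' Boundaries are 1-based and inclusive on both ends.
#'
#' @return Data frame with columns `CHR`, `START`, `END`, `LABEL`.
#' @export
default_exclusion_regions <- function() {
  data.frame(
    CHR = c(6L, 8L),
    START = c(25119106, 7200000),
    END = c(33854733, 12500000),
    LABEL = c("MHC", "8p23.1"),
    stringsAsFactors = FALSE
  )
}

#' Remove SNPs inside exclusion regions
#'
#' Drops every SNP whose position falls inside any of the given regions
#' (`START <= BP <= END` on the matching chromosome). No record is modified;
#' the output is a subset of the input.
#'
#' @param pair A `harmonized_pair`.
#' @param regions Data frame with columns `CHR`, `START`, `END`; defaults to
#'   [default_exclusion_regions()]. An empty region set returns the input
#'   unchanged.
#' @return The filtered `harmonized_pair`, with attribute `n_excluded`.
#' @export
exclude_regions <- function(pair, regions = default_exclusion_regions()) {
  if (is.null(regions) || nrow(regions) == 0L) return(pair)
  stopifnot(all(regions$START <= regions$END))
  hit <- rep(FALSE, nrow(pair))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (pair$CHR == regions$CHR[i] &
                    pair$BP >= regions$START[i] & pair$BP <= regions$END[i])
  }
  if (any(hit)) message("exclude_regions: removed ", sum(hit), " SNP(s)")
  out <- pair[!hit, , drop = FALSE]
  if (nrow(out) == 0L) warning("all SNPs fell inside exclusion regions")
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(hit)
  class(out) <- c("harmonized_pair", "data.frame")
  out
}

# median of the 1-df chi-square distribution
CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)

#' Genomic-control correction for one trait
#'
#' Estimates the genomic inflation factor as the median observed chi-square
#' statistic divided by the null 1-df chi-square median (0.4549364...),
#' floors it at 1 so deflated statistics are never inflated, and corrects
#' the p-values via `p = P(chi2_1 > z^2 / lambda)`. The correction preserves
#' the rank order of p-values, and applying it a second time gives
#' lambda = 1 (after flooring).
#'
#' @param pair A `harmonized_pair`.
#' @param trait `"a"` or `"b"`: which trait's z-scores to use.
#' @return A `gc_result` list: `lambda_gc` (floored), `lambda_raw`
#'   (pre-floor), and `p_corrected`.
#' @export
genomic_control <- function(pair, trait = c("a", "b")) {
  trait <- match.arg(trait)
  z <- if (trait == "a") pair$Z_A else pair$Z_B
  if (length(z) < 100) {
    warning("genomic control estimated from fewer than 100 SNPs")
  }
  if (all(z == 0)) stop("all z-scores are zero; lambda undefined",
                        call. = FALSE)
  lambda_raw <- stats::median(z^2) / CHISQ1_MEDIAN
  lambda <- max(1, lambda_raw)
  p_corrected <- stats::pchisq(z^2 / lambda, df = 1, lower.tail = FALSE)
  # survival function returns 0-probability only at infinite chi2; clamp
  p_corrected <- pmin(pmax(p_corrected, .Machine$double.xmin), 1)
  structure(list(lambda_gc = lambda, lambda_raw = lambda_raw,
                 p_corrected = p_corrected, trait = trait),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("Genomic control (trait %s): lambda = %.4f (raw %.4f)\n",
              x$trait, x$lambda_gc, x$lambda_raw))
  invisible(x)
}

#' Apply genomic control to both traits of a pair
#'
#' Convenience wrapper replacing `P_A` and `P_B` with their
#' genomic-control-corrected values; z-scores are left untouched.
#'
#' @param pair A `harmonized_pair`.
#' @return The corrected pair with attribute `lambda_gc`
#'   (named vector, floored values).
#' @export
apply_genomic_control <- function(pair) {
  ga <- genomic_control(pair, "a")
  gb <- genomic_control(pair, "b")
  pair$P_A <- ga$p_corrected
  pair$P_B <- gb$p_corrected
  attr(pair, "lambda_gc") <- c(a = ga$lambda_gc, b = gb$lambda_gc)
  pair
}
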