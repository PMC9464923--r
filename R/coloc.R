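# Approximate-Bayes-factor colocalization of a trait signal with a
# molecular-QTL signal in a region, under the five-hypothesis single-causal
# configuration model (H0 no signal / H1 trait only / H2 QTL only /
# H3 two distinct causal SNPs / H4 one shared causal SNP).

#' Wakefield log approximate Bayes factor
#'
#' For an estimate with variance `v` and z-score `z`, under a Gaussian
#' effect prior of variance `w`: with `r = w / (v + w)`,
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)` — the log ratio of the marginal
#' density of the estimate under the alternative to the null.
#'
#' @param z Z-score(s).
#' @param v Variance(s) of the effect estimate (`SE^2`), positive.
#' @param w Prior effect variance, positive.
#' @return Log Bayes factor(s), same length as `z`.
#' @export
log_abf <- function(z, v, w) {
  if (any(v <= 0) || any(w <= 0)) {
    stop("v and w must be positive", call. = FALSE)
  }
  r <- w / (v + w)
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization priors
#'
#' Per-SNP prior probabilities of being causal for the trait only (`p1`),
#' the molecular phenotype only (`p2`), or both (`p12`). Defaults are the
#' conventional 1e-4 / 1e-4 / 1e-5.
#'
#' @param p1,p2,p12 Priors in (0, 1); a warning is issued when
#'   `p12 > min(p1, p2)`.
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  if (p12 > min(p1, p2)) {
    warning("p12 larger than min(p1, p2); priors are usually ordered")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Assemble region data for colocalization
#'
#' Collects, for the SNPs shared between a trait and a QTL dataset within
#' a window around a lead SNP, the z-scores and effect-estimate variances.
#' Variances come from `SE^2` when effect/SE columns are present; otherwise
#' the standardized-trait approximation `v = 1 / (2 * n * 0.25)` is used
#' and noted.
#'
#' @param trait,qtl `sumstats` objects (the QTL set is typically one gene's
#'   cis associations).
#' @param lead_snp Lead SNP id; the region is `lead +/- window`.
#' @param window Half-width in base pairs (default 250,000, i.e. a 500-kb
#'   region).
#' @param w_trait,w_qtl Prior effect SDs squared are `w^2`; defaults 0.15
#'   (case-control log-odds scale) and 0.20 (quantitative scale).
#' @return A `coloc_region` data frame: `SNP, Z_TRAIT, V_TRAIT, Z_QTL,
#'   V_QTL`, with prior variances as attributes.
#' @export
coloc_region <- function(trait, qtl, lead_snp, window = 250000,
                         w_trait = 0.15, w_qtl = 0.20) {
  i <- match(lead_snp, trait$SNP)
  if (is.na(i)) stop("lead SNP not found in trait data", call. = FALSE)
  reg <- trait$CHR == trait$CHR[i] & abs(trait$BP - trait$BP[i]) <= window
  tr <- trait[reg, , drop = FALSE]
  m <- match(tr$SNP, qtl$SNP)
  keep <- !is.na(m)
  tr <- tr[keep, , drop = FALSE]
  ql <- qtl[m[keep], , drop = FALSE]
  if (nrow(tr) < 2) stop("fewer than 2 shared SNPs in the region",
                         call. = FALSE)
  v_of <- function(ss) {
    if (all(is.finite(ss$N))) 1 / (2 * ss$N * 0.25)
    else stop("sample sizes needed to approximate estimate variances",
              call. = FALSE)
  }
  out <- data.frame(SNP = tr$SNP, Z_TRAIT = tr$Z, V_TRAIT = v_of(tr),
                    Z_QTL = ql$Z, V_QTL = v_of(ql),
                    stringsAsFactors = FALSE)
  attr(out, "w_trait_sq") <- w_trait^2
  attr(out, "w_qtl_sq") <- w_qtl^2
  class(out) <- c("coloc_region", "data.frame")
  out
}

#' @keywords internal
logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Colocalize two association signals in a region
#'
#' Computes per-SNP log approximate Bayes factors for the trait and the
#' QTL, combines them under the five single-causal-variant hypotheses with
#' the given priors (all sums in log space), and returns normalized
#' posterior probabilities PP0-PP4. The hypothesis reaching a posterior of
#' at least `decision_threshold` (default 0.80), if any, is the reported
#' decision.
#'
#' @param region A `coloc_region`, or a data frame with columns
#'   `SNP, Z_TRAIT, V_TRAIT, Z_QTL, V_QTL` (at least 2 SNPs).
#' @param priors A [coloc_priors()].
#' @param w_trait_sq,w_qtl_sq Prior effect variances; default to the
#'   region's attributes, falling back to `0.15^2` and `0.20^2`.
#' @param decision_threshold Posterior needed to call a hypothesis.
#' @return A `coloc_result` list: `pp` (named numeric, PP0-PP4),
#'   `decision` (`"H0"`..`"H4"` or `NA`), `lbf_trait`, `lbf_qtl`,
#'   `n_snps`, `priors`.
#' @export
colocalize <- function(region, priors = coloc_priors(),
                       w_trait_sq = NULL, w_qtl_sq = NULL,
                       decision_threshold = 0.80) {
  need <- c("SNP", "Z_TRAIT", "V_TRAIT", "Z_QTL", "V_QTL")
  if (!all(need %in% names(region))) {
    stop("region must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(region$SNP)) stop("duplicated SNPs in region",
                                      call. = FALSE)
  if (nrow(region) < 2) stop("need at least 2 SNPs", call. = FALSE)
  if (is.null(w_trait_sq)) {
    w_trait_sq <- attr(region, "w_trait_sq")
    if (is.null(w_trait_sq)) w_trait_sq <- 0.15^2
  }
  if (is.null(w_qtl_sq)) {
    w_qtl_sq <- attr(region, "w_qtl_sq")
    if (is.null(w_qtl_sq)) w_qtl_sq <- 0.20^2
  }
  la <- log_abf(region$Z_TRAIT, region$V_TRAIT, w_trait_sq)
  lb <- log_abf(region$Z_QTL, region$V_QTL, w_qtl_sq)

  l1 <- logsumexp(la)
  l2 <- logsumexp(lb)
  l4 <- logsumexp(la + lb)
  # sum over i != j equals (sum_i)(sum_j) minus the diagonal, in log space
  ldiff <- l4 - (l1 + l2)
  l3 <- if (ldiff >= 0) -Inf else l1 + l2 + log1p(-exp(ldiff))

  lh <- c(H0 = 0,
          H1 = log(priors$p1) + l1,
          H2 = log(priors$p2) + l2,
          H3 = log(priors$p1) + log(priors$p2) + l3,
          H4 = log(priors$p12) + l4)
  lz <- logsumexp(lh)
  pp <- exp(lh - lz)
  names(pp) <- paste0("PP", 0:4)
  decision <- if (any(pp >= decision_threshold)) {
    paste0("H", which.max(pp) - 1L)
  } else NA_character_
  structure(list(pp = pp, decision = decision,
                 lbf_trait = la, lbf_qtl = lb,
                 n_snps = nrow(region), priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization (", x$n_snps, " SNPs, p12 = ",
      format(x$priors$p12), ")\n", sep = "")
  cat("  ", paste(sprintf("%s = %.3f", names(x$pp), x$pp),
                  collapse = "  "), "\n", sep = "")
  cat("  decision: ",
      if (is.na(x$decision)) "none (no posterior >= 0.80)" else x$decision,
      "\n", sep = "")
  invisible(x)
}

#' Prior-sensitivity analysis for colocalization
#'
#' Repeats the analysis under alternative shared-causal priors `p12` and
#' flags the result stable when the called hypothesis (posterior >= 0.80)
#' is identical under all of them.
#'
#' @param region A `coloc_region` (or compatible data frame).
#' @param p12 Vector of `p12` priors to compare (default `1e-5` and
#'   `5e-6`).
#' @param priors Base priors supplying `p1` and `p2`.
#' @param ... Passed to [colocalize()].
#' @return A `coloc_sensitivity` list: `results` (one `coloc_result` per
#'   prior, named by `p12`) and `stable` (logical).
#' @export
coloc_sensitivity <- function(region, p12 = c(1e-5, 5e-6),
                              priors = coloc_priors(), ...) {
  results <- lapply(p12, function(pp12) {
    colocalize(region,
               priors = coloc_priors(p1 = priors$p1, p2 = priors$p2,
                                     p12 = pp12), ...)
  })
  names(results) <- format(p12)
  decisions <- vapply(results, `[[`, character(1), "decision")
  stable <- length(unique(decisions)) == 1L && !any(is.na(decisions))
  structure(list(results = results, stable = stable),
            class = "coloc_sensitivity")
}

#' @export
print.coloc_sensitivity <- function(x, ...) {
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("p12 = %s: PP4 = %.3f, decision %s\n", nm, r$pp["PP4"],
                ifelse(is.na(r$decision), "none", r$decision)))
  }
  cat("stable under priors:", x$stable, "\n")
  invisible(x)
}
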