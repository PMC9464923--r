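#' Lead SNPs of the PCOS / type-2-diabetes worked example
#'
#' The 11 lead SNPs found associated with polycystic ovary syndrome (PCOS)
#' conditional on type 2 diabetes (T2D) in a published cross-trait condFDR
#' analysis of the DIAGRAM T2D and PCOS consortium meta-analyses, with
#' their conditional FDR (PCOS given T2D), conjunctional FDR, original GWAS
#' p-values and z-scores. `CONDFDR` and `CONJFDR` are the statistics the
#' locus counts and direction classification operate on. Positions are
#' hg19; `A1` is the alternative (effect) allele.
#'
#' The z-score columns are stored in their statistically consistent
#' pairing with the p-value columns (`2 * pnorm(-|Z_T2D|)` reproduces
#' `P_T2D` on every row), which is how the package validates them.
#'
#' @return Data frame with one row per lead SNP.
#' @examples
#' leads <- pcos_t2d_leads()
#' table(classify_direction(leads$Z_T2D, leads$Z_PCOS))
#' @export
pcos_t2d_leads <- function() {
  utils::read.delim(
    system.file("extdata", "pcos_t2d_leads.tsv", package = "pleioverlap"),
    stringsAsFactors = FALSE)
}

#' Synthetic catalog of previously reported PCOS SNPs
#'
#' A stand-in for a literature catalog of previously reported PCOS
#' association signals, containing the two worked-example lead SNPs that
#' fall in previously reported loci (the real catalog is an external
#' literature resource and is not redistributed). Used to demonstrate
#' [classify_novel()].
#'
#' @return Data frame with columns `SNP`, `CHR`, `BP`.
#' @export
known_pcos_snps <- function() {
  utils::read.delim(
    system.file("extdata", "known_pcos_snps_synthetic.tsv",
                package = "pleioverlap"),
    stringsAsFactors = FALSE)
}

#' Worked-example lead SNPs as a harmonized pair and FDR assignment
#'
#' Recasts [pcos_t2d_leads()] into the package's native containers so the
#' locus machinery can run on them: trait A is T2D, trait B is PCOS, and
#' the per-SNP FDR values are the published conditional (PCOS given T2D)
#' and conjunctional FDRs. The leads are already LD-pruned, so an empty
#' pairwise LD reference accompanies them.
#'
#' @return List with elements `pair` (`harmonized_pair`),
#'   `assignment` (`fdr_assignment`), and `ld` (`ld_ref` with every lead
#'   its own block).
#' @export
pcos_t2d_example <- function() {
  leads <- pcos_t2d_leads()
  pair <- data.frame(
    SNP = leads$SNP, CHR = leads$CHR, BP = leads$BP,
    A1 = leads$A1, A2 = leads$A2,
    Z_A = leads$Z_T2D, P_A = leads$P_T2D, N_A = NA_real_,
    Z_B = leads$Z_PCOS, P_B = leads$P_PCOS, N_B = NA_real_,
    stringsAsFactors = FALSE)
  class(pair) <- c("harmonized_pair", "data.frame")
  # conjFDR = max of the two conditional FDRs; the published table carries
  # condFDR(PCOS|T2D) and the conjFDR, so condFDR(T2D|PCOS) is only known
  # to be <= conjFDR -- setting it to the conjFDR preserves the max rule.
  assignment <- data.frame(
    SNP = leads$SNP, CHR = leads$CHR, BP = leads$BP,
    P_A = leads$P_T2D, P_B = leads$P_PCOS,
    CONDFDR_AB = leads$CONJFDR, CONDFDR_BA = leads$CONDFDR,
    CONJFDR = leads$CONJFDR,
    SIG_COND_AB = leads$CONJFDR < 0.05,
    SIG_COND_BA = leads$CONDFDR < 0.05,
    SIG_CONJ = leads$CONJFDR < 0.05,
    stringsAsFactors = FALSE)
  attr(assignment, "threshold") <- 0.05
  class(assignment) <- c("fdr_assignment", "data.frame")
  ld <- ld_reference(blocks = stats::setNames(seq_len(nrow(leads)),
                                              leads$SNP))
  list(pair = pair, assignment = assignment, ld = ld)
}
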