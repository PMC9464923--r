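#' Clump significant SNPs into genomic loci
#'
#' Implements the FUMA-style locus definition. (1) SNPs with the chosen FDR
#' statistic below the threshold are significant; (2) independent
#' significant SNPs are chosen greedily by ascending statistic (ties broken
#' by chromosome, position, id), removing SNPs with `r2 >= 0.6` to an
#' already-chosen one; (3) lead SNPs are the subset mutually independent at
#' `r2 < 0.1`, same greedy order; (4) candidate SNPs are all SNPs of the
#' pair (regardless of their own FDR value) with `r2 >= 0.6` to a lead;
#' (5) loci on one chromosome whose candidate-SNP borders lie within the
#' merge distance are merged, keeping the best-statistic lead.
#'
#' @param assignment An `fdr_assignment` covering all SNPs of `pair`.
#' @param pair The matching `harmonized_pair`.
#' @param ld An `ld_ref`.
#' @param statistic `"condfdr_ab"`, `"condfdr_ba"`, or `"conjfdr"`.
#' @param threshold Significance threshold (default 0.05, strict `<`).
#' @param r2_candidate,r2_lead Clumping thresholds (defaults 0.6 and 0.1).
#' @param merge_kb Locus-merge distance between candidate borders in base
#'   pairs (default 250,000).
#' @return A `locus_table` data frame with one row per locus: `LOCUS, CHR,
#'   START, END, SNP` (best lead), `BP`, the lead's FDR statistics,
#'   p-values and z-scores, `N_CANDIDATES`, `LEADS` (all lead SNPs of a
#'   merged locus) and `CANDIDATES` (comma-separated ids), `DIRECTION`.
#'   Empty (0-row) when nothing is significant.
#' @export
clump_loci <- function(assignment, pair, ld,
                       statistic = c("conjfdr", "condfdr_ab", "condfdr_ba"),
                       threshold = 0.05, r2_candidate = 0.6, r2_lead = 0.1,
                       merge_kb = 250000) {
  statistic <- match.arg(statistic)
  stat_col <- c(conjfdr = "CONJFDR", condfdr_ab = "CONDFDR_AB",
                condfdr_ba = "CONDFDR_BA")[[statistic]]
  stopifnot(all(pair$SNP %in% assignment$SNP))
  stat <- assignment[[stat_col]][match(pair$SNP, assignment$SNP)]

  empty <- function() {
    out <- data.frame(LOCUS = integer(), CHR = integer(), START = numeric(),
                      END = numeric(), SNP = character(), BP = numeric(),
                      STAT = numeric(), CONDFDR_AB = numeric(),
                      CONDFDR_BA = numeric(), CONJFDR = numeric(),
                      P_A = numeric(), P_B = numeric(), Z_A = numeric(),
                      Z_B = numeric(), N_CANDIDATES = integer(),
                      LEADS = character(),
                      CANDIDATES = character(), DIRECTION = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("locus_table", "data.frame")
    out
  }
  sig <- which(stat < threshold)
  if (!length(sig)) return(empty())

  ord <- sig[order(stat[sig], pair$CHR[sig], pair$BP[sig], pair$SNP[sig])]
  # greedy selection at r2 < r2_candidate => independent significant SNPs
  indep <- integer(0)
  for (i in ord) {
    cand <- indep[pair$CHR[indep] == pair$CHR[i]]
    if (!length(cand) ||
        all(ld_r2(ld, pair$SNP[i], pair$SNP[cand]) < r2_candidate)) {
      indep <- c(indep, i)
    }
  }
  # lead SNPs: mutually independent at r2 < r2_lead, same order
  leads <- integer(0)
  for (i in indep) {
    cand <- leads[pair$CHR[leads] == pair$CHR[i]]
    if (!length(cand) ||
        all(ld_r2(ld, pair$SNP[i], pair$SNP[cand]) < r2_lead)) {
      leads <- c(leads, i)
    }
  }

  # candidate SNPs per lead: any SNP of the pair with r2 >= r2_candidate
  block <- ld_block_of(ld, pair$SNP)
  loci <- lapply(leads, function(i) {
    same_chr <- which(pair$CHR == pair$CHR[i] & block == block[i])
    r2 <- ld_r2(ld, pair$SNP[i], pair$SNP[same_chr])
    cand <- same_chr[r2 >= r2_candidate | same_chr == i]
    list(lead = i, leads = i, cand = cand,
         chr = pair$CHR[i],
         start = min(pair$BP[cand]), end = max(pair$BP[cand]))
  })

  # merge loci whose candidate borders are within merge_kb
  key <- order(vapply(loci, `[[`, numeric(1), "chr"),
               vapply(loci, `[[`, numeric(1), "start"))
  loci <- loci[key]
  merged <- list()
  for (lc in loci) {
    n <- length(merged)
    if (n > 0 && merged[[n]]$chr == lc$chr &&
        lc$start - merged[[n]]$end <= merge_kb) {
      cur <- merged[[n]]
      cur$cand <- union(cur$cand, lc$cand)
      cur$leads <- union(cur$leads, lc$leads)
      cur$start <- min(cur$start, lc$start)
      cur$end <- max(cur$end, lc$end)
      if (stat[lc$lead] < stat[cur$lead] ||
          (stat[lc$lead] == stat[cur$lead] &&
             pair$BP[lc$lead] < pair$BP[cur$lead])) {
        cur$lead <- lc$lead
      }
      merged[[n]] <- cur
    } else {
      merged[[n + 1L]] <- lc
    }
  }

  rows <- lapply(seq_along(merged), function(k) {
    lc <- merged[[k]]
    i <- lc$lead
    a <- assignment[match(pair$SNP[i], assignment$SNP), ]
    data.frame(
      LOCUS = k, CHR = lc$chr, START = lc$start, END = lc$end,
      SNP = pair$SNP[i], BP = pair$BP[i],
      STAT = stat[i],
      CONDFDR_AB = a$CONDFDR_AB, CONDFDR_BA = a$CONDFDR_BA,
      CONJFDR = a$CONJFDR,
      P_A = pair$P_A[i], P_B = pair$P_B[i],
      Z_A = pair$Z_A[i], Z_B = pair$Z_B[i],
      N_CANDIDATES = length(lc$cand),
      LEADS = paste(sort(pair$SNP[lc$leads]), collapse = ","),
      CANDIDATES = paste(sort(pair$SNP[lc$cand]), collapse = ","),
      DIRECTION = classify_direction(pair$Z_A[i], pair$Z_B[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "statistic") <- statistic
  attr(out, "threshold") <- threshold
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Effect-direction concordance of a lead SNP
#'
#' Compares the signs of the two traits' z-scores: `"concordant"` when the
#' allelic effects point the same way, `"discordant"` when they oppose,
#' `"undetermined"` when either z-score is zero.
#'
#' @param z_a,z_b Lead z-scores (vectorized).
#' @return Character vector.
#' @export
classify_direction <- function(z_a, z_b) {
  s <- sign(z_a) * sign(z_b)
  ifelse(s > 0, "concordant", ifelse(s < 0, "discordant", "undetermined"))
}

#' Novelty classification of lead SNPs against a catalog
#'
#' A lead SNP is novel when (1) its FDR statistic is below the threshold,
#' (2) its p-value in the original primary GWAS exceeds the genome-wide
#' threshold (so it was not discoverable unconditionally), (3) it is in low
#' LD (`r2 < 0.6`) with every previously reported SNP, and (4) it lies more
#' than the merge distance (250 kb) from every reported SNP.
#'
#' @param loci A `locus_table`.
#' @param original_p Numeric vector: the lead SNPs' p-values in the original
#'   primary GWAS (same order as `loci`).
#' @param catalog Data frame of previously reported SNPs with columns
#'   `SNP`, `CHR`, `BP`.
#' @param ld An `ld_ref`.
#' @param gwas_threshold Genome-wide significance threshold (default 5e-8).
#' @param distance_bp Minimum separation from reported SNPs (default
#'   250,000).
#' @return The `locus_table` with a logical `NOVEL` column added.
#' @export
classify_novel <- function(loci, original_p, catalog, ld,
                           gwas_threshold = 5e-8, distance_bp = 250000) {
  stopifnot(length(original_p) == nrow(loci),
            all(c("SNP", "CHR", "BP") %in% names(catalog)))
  thr <- attr(loci, "threshold")
  if (is.null(thr)) thr <- 0.05
  novel <- logical(nrow(loci))
  for (k in seq_len(nrow(loci))) {
    if (!(loci$STAT[k] < thr) || original_p[k] <= gwas_threshold) next
    near <- catalog$CHR == loci$CHR[k] &
      abs(catalog$BP - loci$BP[k]) <= distance_bp
    in_ld <- FALSE
    if (nrow(catalog)) {
      in_ld <- any(ld_r2(ld, loci$SNP[k], catalog$SNP) >= 0.6)
    }
    novel[k] <- !any(near) && !in_ld
  }
  loci$NOVEL <- novel
  loci
}

#' @export
print.locus_table <- function(x, ...) {
  cat("Genomic loci (", attr(x, "statistic"), " < ", attr(x, "threshold"),
      "): ", nrow(x), " locus/loci\n", sep = "")
  if (nrow(x)) {
    show <- x[, intersect(c("LOCUS", "CHR", "BP", "SNP", "STAT",
                            "N_CANDIDATES", "DIRECTION", "NOVEL"),
                          names(x))]
    print.data.frame(show, digits = 3)
  }
  invisible(x)
}

#' Write a locus table
#'
#' @param loci A `locus_table`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  utils::write.table(as.data.frame(loci), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
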