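#' Read and validate GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistic table with header columns
#' `SNP, CHR, BP, A1, A2, Z, P, N` (or `BETA` and `SE` in place of `Z`),
#' validates every row, and returns a `sumstats` object. `A1` is the effect
#' allele and `Z` is the signed association z-score of the `A1` dosage.
#'
#' Rows failing any invariant are dropped with a message: p outside (0, 1],
#' identical or non-ACGT alleles, invalid chromosome/position, or a z-score
#' inconsistent with the stated two-sided normal p-value
#' (`|2 * pnorm(-|z|) - p| > 0.1 * p`). Duplicated SNP ids keep the first
#' occurrence. If `Z` is absent but `BETA`/`SE` are present, `z = beta / se`;
#' if `P` is absent it is filled in as `2 * pnorm(-|z|)`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param col_map Optional named character vector mapping the canonical
#'   column names (`SNP`, `CHR`, `BP`, `A1`, `A2`, `Z`, `BETA`, `SE`, `P`,
#'   `N`) to the names actually used in the file, e.g.
#'   `c(SNP = "rsid", P = "pval")`.
#' @return A `sumstats` object: a data frame with columns
#'   `SNP, CHR, BP, A1, A2, Z, P, N` and an attribute `n_dropped`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(SNP = c("rs1", "rs2"), CHR = 1L, BP = c(100L, 200L),
#'              A1 = "G", A2 = "A", Z = c(1.5, -0.3),
#'              P = 2 * pnorm(-abs(c(1.5, -0.3))), N = 10000L),
#'   f, sep = "\t", quote = FALSE, row.names = FALSE)
#' ss <- read_sumstats(f)
#' @export
read_sumstats <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistic file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      hit <- match(col_map[[canon]], names(raw))
      if (!is.na(hit)) names(raw)[hit] <- canon
    }
  }
  needed <- c("SNP", "CHR", "BP", "A1", "A2")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_z <- "Z" %in% names(raw)
  has_beta <- all(c("BETA", "SE") %in% names(raw))
  if (!has_z && !has_beta) {
    stop("need either a Z column or BETA and SE columns", call. = FALSE)
  }
  z <- if (has_z) as.numeric(raw$Z) else as.numeric(raw$BETA) / as.numeric(raw$SE)
  p_given <- "P" %in% names(raw)
  p <- if (p_given) as.numeric(raw$P) else 2 * stats::pnorm(-abs(z))
  n <- if ("N" %in% names(raw)) as.numeric(raw$N) else NA_real_

  ss <- data.frame(
    SNP = as.character(raw$SNP),
    CHR = suppressWarnings(as.integer(raw$CHR)),
    BP = suppressWarnings(as.double(raw$BP)),
    A1 = toupper(as.character(raw$A1)),
    A2 = toupper(as.character(raw$A2)),
    Z = z, P = p, N = n,
    stringsAsFactors = FALSE
  )
  if (nrow(ss) == 0L) stop("no data rows in ", path, call. = FALSE)
  validate_sumstats(ss, check_zp = p_given && (has_z || has_beta))
}

#' @keywords internal
validate_sumstats <- function(ss, check_zp = TRUE) {
  ok <- !is.na(ss$SNP) & nzchar(ss$SNP) &
    !is.na(ss$CHR) & ss$CHR >= 1L & ss$CHR <= 22L &
    !is.na(ss$BP) & ss$BP >= 1 &
    ss$A1 %in% c("A", "C", "G", "T") & ss$A2 %in% c("A", "C", "G", "T") &
    ss$A1 != ss$A2 &
    !is.na(ss$Z) & is.finite(ss$Z) &
    !is.na(ss$P) & ss$P > 0 & ss$P <= 1
  if (check_zp) {
    p_from_z <- 2 * stats::pnorm(-abs(ss$Z))
    ok <- ok & (abs(p_from_z - ss$P) <= 0.1 * ss$P)
  }
  ok[is.na(ok)] <- FALSE
  dup <- duplicated(ss$SNP)
  keep <- ok & !dup
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("read_sumstats: dropped ", n_dropped, " row(s) (",
            sum(!ok), " invalid, ", sum(dup & ok), " duplicate id)")
  }
  out <- ss[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no valid summary-statistic rows after validation", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Construct a sumstats object from vectors
#'
#' In-memory constructor applying the same validation as [read_sumstats()].
#'
#' @param snp,chr,bp,a1,a2,z,p,n Per-SNP fields; `p` defaults to
#'   `2 * pnorm(-abs(z))` and `n` to `NA`.
#' @return A `sumstats` object.
#' @export
sumstats <- function(snp, chr, bp, a1, a2, z, p = NULL, n = NA_real_) {
  check_zp <- !is.null(p)
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(z))
  ss <- data.frame(SNP = as.character(snp), CHR = as.integer(chr),
                   BP = as.double(bp), A1 = toupper(a1), A2 = toupper(a2),
                   Z = as.numeric(z), P = as.numeric(p),
                   N = as.numeric(n), stringsAsFactors = FALSE)
  validate_sumstats(ss, check_zp = check_zp)
}

#' Write summary statistics to a tab-delimited file
#'
#' Writes the canonical `SNP, CHR, BP, A1, A2, Z, P, N` dialect read by
#' [read_sumstats()]; a write/read round trip reproduces the records exactly.
#'
#' @param ss A `sumstats` object (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  cols <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "P", "N")
  out <- as.data.frame(ss)[, cols]
  # 17 significant digits round-trip IEEE doubles exactly
  for (nm in c("BP", "Z", "P", "N")) {
    out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                        sprintf("%.17g", out[[nm]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", nrow(x), " SNPs, chromosomes ",
      min(x$CHR), "-", max(x$CHR), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("... ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}

# ---- LD reference ----------------------------------------------------------

#' Build an LD reference from pairwise r-squared values or block labels
#'
#' An LD reference stores (i) the pairwise r-squared lookup used for
#' clumping and candidate-SNP definition and (ii) a partition of SNPs into
#' LD blocks used for random pruning. Blocks are the connected components of
#' the graph with an edge wherever r-squared exceeds `block_r2` (0.1 by
#' default); an absent pair is treated as r-squared 0.
#'
#' When the reference is built from block labels only (e.g. the generator's
#' truth), the pairwise lookup returns `r2_within` for two SNPs in the same
#' block and 0 otherwise.
#'
#' @param pairs Data frame with columns `SNP_A`, `SNP_B`, `R2`, or `NULL`.
#' @param blocks Named vector (names = SNP ids) of block labels, or `NULL`.
#' @param r2_within Within-block r-squared assumed when only `blocks` are
#'   given.
#' @param block_r2 Threshold defining blocks from `pairs` (default 0.1).
#' @return An `ld_ref` object.
#' @export
ld_reference <- function(pairs = NULL, blocks = NULL, r2_within = NA_real_,
                         block_r2 = 0.1) {
  if (is.null(pairs) && is.null(blocks)) {
    stop("supply pairwise r2 values and/or block labels", call. = FALSE)
  }
  pair_env <- NULL
  if (!is.null(pairs)) {
    stopifnot(all(c("SNP_A", "SNP_B", "R2") %in% names(pairs)))
    r2 <- as.numeric(pairs$R2)
    if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
      stop("r2 values must lie in [0, 1]", call. = FALSE)
    }
    a <- as.character(pairs$SNP_A); b <- as.character(pairs$SNP_B)
    key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
    pair_env <- new.env(parent = emptyenv(), size = length(key))
    for (i in seq_along(key)) assign(key[i], r2[i], envir = pair_env)
    if (is.null(blocks)) {
      # connected components of the r2 > block_r2 graph
      edge <- r2 > block_r2
      ids <- unique(c(a, b))
      if (any(edge)) {
        g <- igraph::graph_from_data_frame(
          data.frame(a[edge], b[edge]), directed = FALSE,
          vertices = data.frame(ids))
        comp <- igraph::components(g)$membership
        blocks <- comp[ids]
        names(blocks) <- ids
      } else {
        blocks <- stats::setNames(seq_along(ids), ids)
      }
    }
  }
  structure(list(block_of = blocks, pairs = pair_env,
                 r2_within = r2_within, block_r2 = block_r2),
            class = "ld_ref")
}

#' Read an LD reference from file
#'
#' Accepts either a pairwise file (`SNP_A, SNP_B, R2`) or a block-assignment
#' file (`SNP, BLOCK`), both tab-delimited with a header.
#'
#' @param path File path.
#' @param r2_within Assumed within-block r-squared when reading a block file.
#' @return An `ld_ref` object.
#' @export
read_ld <- function(path, r2_within = NA_real_) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (all(c("SNP_A", "SNP_B", "R2") %in% names(tab))) {
    ld_reference(pairs = tab)
  } else if (all(c("SNP", "BLOCK") %in% names(tab))) {
    ld_reference(blocks = stats::setNames(tab$BLOCK, tab$SNP),
                 r2_within = r2_within)
  } else {
    stop("LD file must have columns SNP_A/SNP_B/R2 or SNP/BLOCK",
         call. = FALSE)
  }
}

#' Write LD block assignments
#'
#' @param ld An `ld_ref` object with block labels.
#' @param path Output path (tab-delimited `SNP`, `BLOCK`).
#' @return `path`, invisibly.
#' @export
write_ld_blocks <- function(ld, path) {
  utils::write.table(
    data.frame(SNP = names(ld$block_of), BLOCK = as.character(ld$block_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise r-squared lookup
#'
#' @param ld An `ld_ref` object.
#' @param a,b SNP id vectors (recycled); an unknown pair has r-squared 0.
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- numeric(n)
  same <- a == b
  out[same] <- 1
  if (!is.null(ld$pairs)) {
    key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
    for (i in which(!same)) {
      v <- get0(key[i], envir = ld$pairs, ifnotfound = NA_real_)
      if (!is.na(v)) out[i] <- v
    }
    if (!is.na(ld$r2_within)) {
      miss <- !same & out == 0
      if (any(miss)) {
        ba <- ld$block_of[a[miss]]; bb <- ld$block_of[b[miss]]
        hit <- !is.na(ba) & !is.na(bb) & ba == bb
        out[miss][hit] <- ld$r2_within
      }
    }
  } else if (!is.na(ld$r2_within)) {
    ba <- ld$block_of[a]; bb <- ld$block_of[b]
    hit <- !same & !is.na(ba) & !is.na(bb) & ba == bb
    out[hit] <- ld$r2_within
  }
  out
}

#' Block label per SNP
#'
#' SNPs absent from the reference are treated as singleton blocks.
#'
#' @param ld An `ld_ref` object.
#' @param snp Character vector of SNP ids.
#' @return Character vector of block labels, one per SNP.
#' @export
ld_block_of <- function(ld, snp) {
  snp <- as.character(snp)
  lab <- as.character(ld$block_of[snp])
  miss <- is.na(lab)
  # unseen SNPs get unique singleton labels that cannot clash
  lab[miss] <- paste0(".singleton.", snp[miss])
  lab
}

#' @export
print.ld_ref <- function(x, ...) {
  cat("LD reference: ", length(x$block_of), " SNPs in ",
      length(unique(x$block_of)), " blocks", sep = "")
  if (!is.na(x$r2_within)) cat(" (within-block r2 = ", x$r2_within, ")",
                               sep = "")
  cat("\n")
  invisible(x)
}

# ---- Harmonization ---------------------------------------------------------

#' Align two traits on shared SNPs with consistent allele orientation
#'
#' Intersects two summary-statistic sets on SNP id and re-signs the second
#' trait's z-scores so both refer to the same effect allele. When trait B
#' lists the alleles in swapped order (`A1_b == A2_a`, `A2_b == A1_a`),
#' `z_b` is negated. Strand-ambiguous SNPs (A/T or C/G) and SNPs whose
#' allele pairs do not match either way are dropped and counted.
#'
#' @param a,b `sumstats` objects.
#' @return A `harmonized_pair` object: data frame with columns
#'   `SNP, CHR, BP, A1, A2, Z_A, P_A, N_A, Z_B, P_B, N_B` (alleles and
#'   positions taken from `a`), plus attributes `n_flipped`,
#'   `n_ambiguous`, `n_mismatch`.
#' @export
harmonize <- function(a, b) {
  m <- match(a$SNP, b$SNP)
  keep <- !is.na(m)
  if (!any(keep)) stop("no shared SNPs between the two traits", call. = FALSE)
  a2 <- a[keep, , drop = FALSE]
  b2 <- b[m[keep], , drop = FALSE]

  ambiguous <- (a2$A1 == "A" & a2$A2 == "T") | (a2$A1 == "T" & a2$A2 == "A") |
    (a2$A1 == "C" & a2$A2 == "G") | (a2$A1 == "G" & a2$A2 == "C")
  same <- b2$A1 == a2$A1 & b2$A2 == a2$A2
  swapped <- b2$A1 == a2$A2 & b2$A2 == a2$A1
  usable <- !ambiguous & (same | swapped)
  n_ambiguous <- sum(ambiguous)
  n_mismatch <- sum(!ambiguous & !(same | swapped))
  if (n_ambiguous + n_mismatch > 0) {
    message("harmonize: dropped ", n_ambiguous, " strand-ambiguous and ",
            n_mismatch, " allele-mismatched SNP(s)")
  }
  z_b <- ifelse(swapped, -b2$Z, b2$Z)

  out <- data.frame(
    SNP = a2$SNP, CHR = a2$CHR, BP = a2$BP, A1 = a2$A1, A2 = a2$A2,
    Z_A = a2$Z, P_A = a2$P, N_A = a2$N,
    Z_B = z_b, P_B = b2$P, N_B = b2$N,
    stringsAsFactors = FALSE
  )[usable, , drop = FALSE]
  if (nrow(out) == 0L) stop("no usable shared SNPs after allele matching",
                            call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_flipped") <- sum(swapped & usable)
  attr(out, "n_ambiguous") <- n_ambiguous
  attr(out, "n_mismatch") <- n_mismatch
  class(out) <- c("harmonized_pair", "data.frame")
  out
}

#' @keywords internal
as_harmonized_pair <- function(df) {
  stopifnot(all(c("SNP", "CHR", "BP", "Z_A", "P_A", "Z_B", "P_B") %in%
                  names(df)))
  rownames(df) <- NULL
  class(df) <- c("harmonized_pair", "data.frame")
  df
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("Harmonized trait pair: ", nrow(x), " shared SNPs\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("... ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}
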