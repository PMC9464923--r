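# Shared fixtures built in code.

# a small harmonized pair with hand-set values
toy_pair <- function(snp, chr = 1L, bp = NULL, z_a = 0, p_a = NULL,
                     z_b = 0, p_b = NULL, n_a = 1e4, n_b = 1e4) {
  n <- length(snp)
  if (is.null(bp)) bp <- seq_len(n) * 1e5
  if (is.null(p_a)) p_a <- 2 * pnorm(-abs(z_a))
  if (is.null(p_b)) p_b <- 2 * pnorm(-abs(z_b))
  df <- data.frame(SNP = snp, CHR = chr, BP = bp, A1 = "G", A2 = "A",
                   Z_A = z_a, P_A = p_a, N_A = n_a,
                   Z_B = z_b, P_B = p_b, N_B = n_b,
                   stringsAsFactors = FALSE)
  class(df) <- c("harmonized_pair", "data.frame")
  df
}

# singleton-block LD reference over the given SNPs
singleton_ld <- function(snp) {
  ld_reference(blocks = setNames(seq_along(snp), snp))
}

# write a sumstats data frame to a temp TSV
write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
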