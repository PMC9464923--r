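#' Parse a "chrom:start-end" region string
#'
#' @param x Character vector like `"6:25119106-33854733"`.
#' @return Data frame with columns `CHR`, `START`, `END`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+):([0-9,]+)-([0-9,]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed region string: ", x[bad][1], call. = FALSE)
  num <- function(s) as.numeric(gsub(",", "", s))
  data.frame(CHR = as.integer(vapply(m, `[`, character(1), 2L)),
             START = num(vapply(m, `[`, character(1), 3L)),
             END = num(vapply(m, `[`, character(1), 4L)))
}

#' Deterministic per-stage seed
#'
#' Derives a stage seed from the global seed and the stage name so stages
#' can be re-run in isolation with identical draws.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Pipeline run configuration
#'
#' Bundles every stage's inputs and parameters. Either a simulation config
#' or three input paths (two summary-statistic TSVs and an LD file) must be
#' given.
#'
#' @param outdir Output directory.
#' @param seed Global seed (mandatory; per-stage seeds derive from it).
#' @param simulation A [sim_config()], or `NULL` to read files.
#' @param trait_a,trait_b,ld_file Input paths when not simulating.
#' @param exclusion_regions Data frame `CHR/START/END` or character vector
#'   of `"chrom:start-end"` strings; defaults to the MHC and 8p23.1
#'   regions.
#' @param iterations Random-pruning iterations (default 100).
#' @param fdr_threshold Significance threshold (default 0.05).
#' @param r2_candidate,r2_lead Clumping thresholds (0.6, 0.1).
#' @param merge_bp Locus merge distance (250,000 bp).
#' @param novelty_threshold Genome-wide threshold for novelty (5e-8).
#' @param catalog Optional known-SNP catalog (path or data frame
#'   `SNP/CHR/BP`).
#' @param do_qq,do_mixture Stage switches.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed, simulation = NULL,
                       trait_a = NULL, trait_b = NULL, ld_file = NULL,
                       exclusion_regions = default_exclusion_regions(),
                       iterations = 100L, fdr_threshold = 0.05,
                       r2_candidate = 0.6, r2_lead = 0.1,
                       merge_bp = 250000, novelty_threshold = 5e-8,
                       catalog = NULL, do_qq = TRUE, do_mixture = TRUE) {
  if (is.null(simulation) &&
      (is.null(trait_a) || is.null(trait_b) || is.null(ld_file))) {
    stop("either a simulation config or trait_a/trait_b/ld_file paths ",
         "are required", call. = FALSE)
  }
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.character(exclusion_regions)) {
    exclusion_regions <- parse_region(exclusion_regions)
  }
  stopifnot(fdr_threshold >= 0, fdr_threshold <= 1,
            r2_candidate > 0, r2_candidate <= 1,
            r2_lead > 0, r2_lead <= r2_candidate,
            merge_bp >= 0, iterations >= 1)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulation = simulation, trait_a = trait_a,
                 trait_b = trait_b, ld_file = ld_file,
                 exclusion_regions = exclusion_regions,
                 iterations = as.integer(iterations),
                 fdr_threshold = fdr_threshold,
                 r2_candidate = r2_candidate, r2_lead = r2_lead,
                 merge_bp = merge_bp,
                 novelty_threshold = novelty_threshold,
                 catalog = catalog, do_qq = do_qq, do_mixture = do_mixture),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulation`
#' mapping holds [sim_config()] fields.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(sim_config, y$simulation)
  }
  do.call(run_config, y)
}

#' Run the full cross-trait pleiotropy analysis
#'
#' Executes simulate/ingest, harmonization, QC (region exclusion and
#' genomic control), conditional Q-Q curves, condFDR/conjFDR, locus
#' definition, and the causal-mixture overlap model, writing every
#' intermediate artifact plus a manifest (stage parameters, seeds, file
#' MD5 hashes) to the output directory. Re-running with the same
#' configuration reproduces all outputs bit-identically.
#'
#' @param config A [run_config()].
#' @return A `pleio_run` list with the manifest, stage counts, and the key
#'   in-memory results (`pair`, `assignment`, `loci_condfdr`,
#'   `loci_conjfdr`, `overlap`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  counts <- list()
  out_path <- function(name) file.path(config$outdir, name)
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      seed = stage_seed(config$seed, stage),
      params = params,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files))))
  }

  # --- ingest / simulate
  if (!is.null(config$simulation)) {
    sim <- simulate_gwas(config$simulation)
    files <- write_sim(sim, config$outdir)
    a <- sim$a; b <- sim$b; ld <- sim$ld; truth <- sim$truth
    note("ingest", list(mode = "simulate", m = config$simulation$m),
         unname(files))
  } else {
    a <- read_sumstats(config$trait_a)
    b <- read_sumstats(config$trait_b)
    ld <- read_ld(config$ld_file)
    truth <- NULL
    note("ingest", list(mode = "files", trait_a = config$trait_a,
                        trait_b = config$trait_b), character(0))
  }
  counts$snps_a <- nrow(a); counts$snps_b <- nrow(b)

  # --- harmonize + QC
  pair <- harmonize(a, b)
  counts$shared <- nrow(pair)
  pair <- exclude_regions(pair, config$exclusion_regions)
  counts$after_exclusion <- nrow(pair)
  lam <- c(genomic_control(pair, "a")$lambda_gc,
           genomic_control(pair, "b")$lambda_gc)
  pair <- apply_genomic_control(pair)
  pair_file <- out_path("harmonized_qc.tsv")
  utils::write.table(as.data.frame(pair), pair_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("preprocess", list(lambda_a = lam[1], lambda_b = lam[2]), pair_file)

  # --- conditional Q-Q
  qq <- NULL
  if (config$do_qq) {
    qq <- conditional_qq(pair, ld, primary = "b",
                         iterations = config$iterations,
                         seed = stage_seed(config$seed, "qq"))
    qq_file <- out_path("conditional_qq.tsv")
    qq_tab <- do.call(rbind, lapply(names(qq$curves), function(nm) {
      data.frame(STRATUM = nm, qq$curves[[nm]])
    }))
    utils::write.table(qq_tab, qq_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("qq", list(iterations = config$iterations), qq_file)
  }

  # --- condFDR / conjFDR
  assignment <- condfdr(pair, ld, iterations = config$iterations,
                        seed = stage_seed(config$seed, "condfdr"),
                        threshold = config$fdr_threshold)
  fdr_file <- out_path("fdr_assignment.tsv")
  utils::write.table(as.data.frame(assignment), fdr_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$sig_condfdr_ba <- sum(assignment$SIG_COND_BA)
  counts$sig_conj <- sum(assignment$SIG_CONJ)
  note("condfdr", list(iterations = config$iterations,
                       threshold = config$fdr_threshold), fdr_file)

  # --- loci (trait B conditioned on A, and conjunctional)
  loci_cond <- clump_loci(assignment, pair, ld, statistic = "condfdr_ba",
                          threshold = config$fdr_threshold,
                          r2_candidate = config$r2_candidate,
                          r2_lead = config$r2_lead,
                          merge_kb = config$merge_bp)
  loci_conj <- clump_loci(assignment, pair, ld, statistic = "conjfdr",
                          threshold = config$fdr_threshold,
                          r2_candidate = config$r2_candidate,
                          r2_lead = config$r2_lead,
                          merge_kb = config$merge_bp)
  if (!is.null(config$catalog) && nrow(loci_cond)) {
    catalog <- config$catalog
    if (is.character(catalog)) {
      catalog <- utils::read.delim(catalog, stringsAsFactors = FALSE)
    }
    loci_cond <- classify_novel(
      loci_cond, loci_cond$P_B, catalog, ld,
      gwas_threshold = config$novelty_threshold,
      distance_bp = config$merge_bp)
  }
  f1 <- out_path("loci_condfdr.tsv"); f2 <- out_path("loci_conjfdr.tsv")
  write_loci(loci_cond, f1); write_loci(loci_conj, f2)
  counts$loci_condfdr <- nrow(loci_cond)
  counts$loci_conjfdr <- nrow(loci_conj)
  note("loci", list(threshold = config$fdr_threshold,
                    merge_bp = config$merge_bp), c(f1, f2))

  # --- causal-mixture overlap model
  overlap <- NULL
  if (config$do_mixture) {
    sub <- random_prune(pair, ld, iterations = 1L,
                        seed = stage_seed(config$seed, "mixture"))[[1]]
    pp <- pair[sub, , drop = FALSE]
    class(pp) <- class(pair)
    fa <- fit_univariate(pp, trait = "a")
    fb <- fit_univariate(pp, trait = "b")
    full <- fit_bivariate(pp, fa, fb)
    nullfit <- fit_bivariate(pp, fa, fb, pi12_fixed = 0)
    overlap <- summarize_overlap(full,
                                 aic_delta = compare_models_aic(full, nullfit))
    mix_file <- out_path("overlap_summary.yaml")
    yaml::write_yaml(list(
      params = overlap$params,
      shared = overlap$shared, specific1 = overlap$specific1,
      specific2 = overlap$specific2, dice = overlap$dice, rg = overlap$rg,
      n90_1 = overlap$n90_1, n90_2 = overlap$n90_2,
      aic_delta = overlap$aic_delta), mix_file)
    note("mixture", list(pruned_snps = nrow(pp)), mix_file)
  }

  manifest$counts <- counts
  manifest_file <- out_path("manifest.yaml")
  yaml::write_yaml(manifest, manifest_file)
  structure(list(manifest = manifest, manifest_file = manifest_file,
                 pair = pair, qq = qq, assignment = assignment,
                 loci_condfdr = loci_cond, loci_conjfdr = loci_conj,
                 overlap = overlap, truth = truth, config = config),
            class = "pleio_run")
}

#' @export
print.pleio_run <- function(x, ...) {
  cat("Pleiotropy pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  for (nm in names(x$manifest$counts)) {
    cat(sprintf("  %-18s %s\n", nm, x$manifest$counts[[nm]]))
  }
  invisible(x)
}
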