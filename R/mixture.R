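# Gaussian causal-mixture models for z-scores.
#
# Univariate: z ~ (1 - pi) N(0, s0^2) + pi N(0, s0^2 + n * sb^2).
# Bivariate: four components (null / specific-1 / specific-2 / shared) with
# the shared component's effects correlated (rho12). The likelihood omits
# the LD-and-heterozygosity convolution of the full genome-wide model and
# is meant for pruned (approximately independent) z-scores.
#
# Likelihoods are evaluated on binned z-scores (counts at bin midpoints):
# with bin widths well below the null SD the approximation error per
# observation is O(width^2) and immaterial next to sampling error, while
# evaluation cost drops from the number of SNPs to the number of occupied
# bins.

# bin a z vector: midpoints and counts (width 0.05)
bin_z <- function(z, width = 0.05) {
  i <- round(z / width)
  tab <- table(i)
  list(mid = as.numeric(names(tab)) * width, w = as.vector(tab))
}

# jointly bin two z vectors on a width-0.1 lattice
bin_z2 <- function(z1, z2, width = 0.1) {
  i1 <- round(z1 / width); i2 <- round(z2 / width)
  key <- paste(i1, i2)
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  list(mid1 = as.numeric(ij[, 1]) * width,
       mid2 = as.numeric(ij[, 2]) * width,
       w = as.vector(tab))
}

#' Fit the univariate causal-mixture model
#'
#' Maximum-likelihood fit of polygenicity `pi`, discoverability
#' `sigma_b_sq` (per-causal effect variance) and null-score SD `sigma0`
#' to pruned, post-QC z-scores, under
#' `z ~ (1 - pi) N(0, sigma0^2) + pi N(0, sigma0^2 + n * sigma_b_sq)`.
#' Optimization is bounded quasi-Newton (L-BFGS-B) in transformed
#' coordinates (logit for `pi`, log for variances) from a fixed set of
#' starting points; the best converged start wins.
#'
#' @param stats A `sumstats` object, a `harmonized_pair` (with `trait`), or
#'   a plain numeric z-score vector.
#' @param n Per-SNP sample size; defaults to the median `N` of `stats`.
#' @param trait For a `harmonized_pair`: `"a"` or `"b"`.
#' @return A `uvmix` object with elements `pi`, `sigma_b_sq`, `sigma0`,
#'   `n`, `m`, `loglik`, `convergence`; methods: `print`, `coef`, `logLik`.
#' @export
fit_univariate <- function(stats, n = NULL, trait = c("a", "b")) {
  trait <- match.arg(trait)
  if (is.numeric(stats)) {
    z <- stats
    if (is.null(n)) stop("supply n when passing a raw z vector",
                         call. = FALSE)
  } else if (inherits(stats, "harmonized_pair")) {
    z <- if (trait == "a") stats$Z_A else stats$Z_B
    if (is.null(n)) n <- stats::median(if (trait == "a") stats$N_A
                                       else stats$N_B)
  } else {
    z <- stats$Z
    if (is.null(n)) n <- stats::median(stats$N)
  }
  if (is.na(n) || n <= 0) stop("sample size n unavailable", call. = FALSE)
  m <- length(z)
  zb <- bin_z(z)

  nll <- function(par) {
    pi1 <- stats::plogis(par[1])
    s2 <- exp(par[2])                   # n * sigma_b_sq on the z scale
    s0 <- exp(par[3])
    d <- (1 - pi1) * stats::dnorm(zb$mid, 0, s0) +
      pi1 * stats::dnorm(zb$mid, 0, sqrt(s0^2 + s2))
    -sum(zb$w * log(pmax(d, 1e-320)))
  }
  starts <- expand.grid(pi = c(1e-4, 1e-3, 1e-2),
                        s2 = c(5, 30), s0 = 1)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- c(stats::qlogis(starts$pi[k]), log(starts$s2[k]),
              log(starts$s0[k]))
    fit <- tryCatch(
      stats::optim(par0, nll, method = "L-BFGS-B",
                   lower = c(stats::qlogis(1e-8), log(1e-4), log(0.5)),
                   upper = c(stats::qlogis(0.5), log(1e4), log(3)),
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("univariate mixture fit failed from all starts",
                          call. = FALSE)
  out <- list(pi = stats::plogis(best$par[1]),
              sigma_b_sq = exp(best$par[2]) / n,
              sigma0 = exp(best$par[3]),
              n = n, m = m, loglik = -best$value,
              convergence = best$convergence)
  class(out) <- "uvmix"
  out
}

#' @export
print.uvmix <- function(x, ...) {
  cat("Univariate causal mixture fit (", x$m, " SNPs)\n", sep = "")
  cat(sprintf("  polygenicity pi      = %.3g\n", x$pi))
  cat(sprintf("  discoverability sb^2 = %.3g  (n * sb^2 = %.3g)\n",
              x$sigma_b_sq, x$n * x$sigma_b_sq))
  cat(sprintf("  null score SD sigma0 = %.4f\n", x$sigma0))
  cat(sprintf("  log-likelihood       = %.2f\n", x$loglik))
  invisible(x)
}

#' @export
coef.uvmix <- function(object, ...) {
  c(pi = object$pi, sigma_b_sq = object$sigma_b_sq, sigma0 = object$sigma0)
}

#' @export
logLik.uvmix <- function(object, ...) {
  structure(object$loglik, df = 3, nobs = object$m, class = "logLik")
}

#' @keywords internal
bvmix_nll <- function(z1, z2, pi1s, pi2s, pi12, s2_1, s2_2, rho12,
                      s0_1, s0_2, w = 1) {
  # component variances on the z scale
  v1n <- s0_1^2; v1c <- s0_1^2 + s2_1
  v2n <- s0_2^2; v2c <- s0_2^2 + s2_2
  dn <- function(z, v) stats::dnorm(z, 0, sqrt(v))
  # shared component: correlation of z-scores induced by correlated effects
  cov12 <- rho12 * sqrt(s2_1 * s2_2)
  r <- cov12 / sqrt(v1c * v2c)
  det <- v1c * v2c - cov12^2
  dboth <- exp(-(v2c * z1^2 - 2 * cov12 * z1 * z2 + v1c * z2^2) /
                 (2 * det)) / (2 * pi * sqrt(det))
  pi0 <- 1 - pi1s - pi2s - pi12
  d <- pi0 * dn(z1, v1n) * dn(z2, v2n) +
    pi1s * dn(z1, v1c) * dn(z2, v2n) +
    pi2s * dn(z1, v1n) * dn(z2, v2c) +
    pi12 * dboth
  -sum(w * log(pmax(d, 1e-320)))
}

#' Fit the bivariate causal-mixture model
#'
#' Estimates the shared-component probability `pi12` and the
#' shared-effect correlation `rho12` by maximum likelihood over the
#' four-component bivariate Gaussian mixture of the two traits' z-scores,
#' with the margins constrained to the univariate fits
#' (`pi1s + pi12 = pi_1`, `pi2s + pi12 = pi_2`, discoverabilities and
#' null SDs fixed). Optional SNP-resampling bootstrap gives standard
#' errors.
#'
#' @param pair A pruned, post-QC `harmonized_pair`.
#' @param fit_a,fit_b Univariate [fit_univariate()] results for the two
#'   traits.
#' @param pi12_fixed Fix `pi12` at this value instead of estimating it
#'   (use 0 for the no-overlap null model of the AIC comparison).
#' @param n_boot Bootstrap resamples for standard errors (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return A `bvmix` object: `params` (pi1s, pi2s, pi12, sigma_b1_sq,
#'   sigma_b2_sq, rho12, sigma01, sigma02), `loglik`, `df` (free
#'   parameters), `m`, `n1`, `n2`, and `boot` (resampled pi12/rho12) when
#'   bootstrapped.
#' @export
fit_bivariate <- function(pair, fit_a, fit_b, pi12_fixed = NULL,
                          n_boot = 0L, seed = 1L) {
  z1 <- pair$Z_A; z2 <- pair$Z_B
  m <- length(z1)
  pi1 <- fit_a$pi; pi2 <- fit_b$pi
  s2_1 <- fit_a$n * fit_a$sigma_b_sq
  s2_2 <- fit_b$n * fit_b$sigma_b_sq
  s0_1 <- fit_a$sigma0; s0_2 <- fit_b$sigma0
  pi12_max <- min(pi1, pi2)
  lo <- max(0, pi1 + pi2 - 1)
  if (lo > pi12_max) stop("margins infeasible: pi1 + pi2 - 1 > min(pi1, pi2)",
                          call. = FALSE)

  fit_once <- function(z1, z2) {
    zb <- bin_z2(z1, z2)
    if (!is.null(pi12_fixed)) {
      pi12 <- pi12_fixed
      if (pi12 > pi12_max + 1e-12) stop("pi12_fixed exceeds min margin",
                                        call. = FALSE)
      if (pi12 == 0) {
        ll <- -bvmix_nll(zb$mid1, zb$mid2, pi1, pi2, 0, s2_1, s2_2, 0,
                         s0_1, s0_2, w = zb$w)
        return(list(pi12 = 0, rho12 = NA_real_, loglik = ll, df = 0L))
      }
      nll1 <- function(v) bvmix_nll(zb$mid1, zb$mid2, pi1 - pi12,
                                    pi2 - pi12, pi12, s2_1, s2_2, tanh(v),
                                    s0_1, s0_2, w = zb$w)
      best <- NULL
      for (v0 in atanh(c(-0.5, 0, 0.5))) {
        f <- tryCatch(stats::optim(v0, nll1, method = "Brent",
                                   lower = atanh(-0.999),
                                   upper = atanh(0.999)),
                      error = function(e) NULL)
        if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
      }
      return(list(pi12 = pi12, rho12 = tanh(best$par),
                  loglik = -best$value, df = 1L))
    }
    nll2 <- function(par) {
      pi12 <- lo + (pi12_max - lo) * stats::plogis(par[1])
      bvmix_nll(zb$mid1, zb$mid2, pi1 - pi12, pi2 - pi12, pi12,
                s2_1, s2_2, tanh(par[2]), s0_1, s0_2, w = zb$w)
    }
    starts <- data.frame(f = stats::qlogis(c(0.1, 0.5, 0.9, 0.5, 0.5)),
                         r = atanh(c(0, 0, 0, -0.5, 0.5)))
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      f <- tryCatch(
        stats::optim(c(starts$f[k], starts$r[k]), nll2, method = "L-BFGS-B",
                     lower = c(stats::qlogis(1e-6), atanh(-0.999)),
                     upper = c(stats::qlogis(1 - 1e-6), atanh(0.999)),
                     control = list(maxit = 300)),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    if (is.null(best)) stop("bivariate mixture fit failed from all starts",
                            call. = FALSE)
    list(pi12 = lo + (pi12_max - lo) * stats::plogis(best$par[1]),
         rho12 = tanh(best$par[2]), loglik = -best$value, df = 2L)
  }

  fit <- fit_once(z1, z2)
  boot <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    boot <- t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(m, m, replace = TRUE)
      fb <- fit_once(z1[idx], z2[idx])
      c(pi12 = fb$pi12, rho12 = fb$rho12)
    }, numeric(2)))
  }
  out <- list(
    params = list(pi1s = pi1 - fit$pi12, pi2s = pi2 - fit$pi12,
                  pi12 = fit$pi12,
                  sigma_b1_sq = fit_a$sigma_b_sq,
                  sigma_b2_sq = fit_b$sigma_b_sq,
                  rho12 = fit$rho12, sigma01 = s0_1, sigma02 = s0_2),
    loglik = fit$loglik, df = fit$df, m = m,
    n1 = fit_a$n, n2 = fit_b$n, boot = boot
  )
  class(out) <- "bvmix"
  out
}

#' @export
print.bvmix <- function(x, ...) {
  p <- x$params
  cat("Bivariate causal mixture fit (", x$m, " SNPs)\n", sep = "")
  cat(sprintf("  pi1s = %.3g   pi2s = %.3g   pi12 = %.3g\n",
              p$pi1s, p$pi2s, p$pi12))
  cat(sprintf("  rho12 = %.3f   log-likelihood = %.2f (df = %d)\n",
              if (is.na(p$rho12)) NA else p$rho12, x$loglik, x$df))
  if (!is.null(x$boot)) {
    se <- apply(x$boot, 2, stats::sd, na.rm = TRUE)
    cat(sprintf("  bootstrap SE: pi12 %.2g, rho12 %.2g (%d resamples)\n",
                se[1], se[2], nrow(x$boot)))
  }
  invisible(x)
}

#' @export
coef.bvmix <- function(object, ...) unlist(object$params)

#' @export
logLik.bvmix <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$m,
            class = "logLik")
}

#' AIC comparison of the overlap model against a constrained fit
#'
#' `aic_delta = AIC(constrained) - AIC(full)`; a positive value favors the
#' model with polygenic overlap. Comparing a model with itself gives 0
#' exactly.
#'
#' @param full,constrained `bvmix` fits on identical data (the constrained
#'   fit typically has `pi12_fixed = 0`).
#' @return Numeric `aic_delta`.
#' @export
compare_models_aic <- function(full, constrained) {
  stopifnot(inherits(full, "bvmix"), inherits(constrained, "bvmix"),
            full$m == constrained$m)
  aic <- function(f) 2 * f$df - 2 * f$loglik
  aic(constrained) - aic(full)
}

#' Fraction of causal SNPs explaining a given share of heritability
#'
#' For i.i.d. Gaussian effects, squared effects are chi-square(1) scaled;
#' the smallest fraction `q` of causal SNPs (taken from the largest effects
#' down) whose expected summed squared effects reach a share `share` of the
#' total solves `E[X 1(X > x_q)] / E[X] = share` with
#' `q = P(chi2_1 > x_q)`. Solved numerically by bisection on `x_q`.
#'
#' @param share Heritability share (default 0.9).
#' @return The fraction `q` in (0, 1).
#' @export
causal_fraction_for_share <- function(share = 0.9) {
  stopifnot(share > 0, share < 1)
  # E[X 1(X > x)] for chi2_1 equals P(chi2_3 > x) (E[X] = 1)
  f <- function(x) stats::pchisq(x, df = 3, lower.tail = FALSE) - share
  x_q <- stats::uniroot(f, c(0, 50), tol = 1e-12)$root
  stats::pchisq(x_q, df = 1, lower.tail = FALSE)
}

#' Summarize polygenic overlap
#'
#' Converts fitted mixture parameters into the standard overlap report:
#' causal-variant counts, the Dice coefficient
#' `2 * shared / ((specific1 + shared) + (specific2 + shared))`, the
#' model-implied genetic correlation
#' `rg = rho12 * pi12 / sqrt(pi_1 * pi_2)`, and the number of causal
#' variants explaining 90% of each trait's SNP heritability
#' (`n90 = pi_t * m * q90`, with `q90` from
#' [causal_fraction_for_share()]).
#'
#' @param fit A `bvmix` object (or a list with the same `params`).
#' @param m Number of SNPs the probabilities refer to; defaults to the
#'   fit's.
#' @param aic_delta Optional AIC difference from [compare_models_aic()].
#' @return An `overlap_summary` list: counts (`shared`, `specific1`,
#'   `specific2`), `dice`, `rg`, `n90_1`, `n90_2`, `aic_delta`, bootstrap
#'   SEs when available.
#' @export
summarize_overlap <- function(fit, m = NULL, aic_delta = NA_real_) {
  p <- fit$params
  if (is.null(m)) m <- fit$m
  pi_1 <- p$pi1s + p$pi12
  pi_2 <- p$pi2s + p$pi12
  dice <- if (pi_1 + pi_2 > 0) 2 * p$pi12 / (pi_1 + pi_2) else 0
  rg <- if (pi_1 > 0 && pi_2 > 0 && p$pi12 > 0) {
    p$rho12 * p$pi12 / sqrt(pi_1 * pi_2)
  } else if (p$pi12 == 0) 0 else NA_real_
  q90 <- causal_fraction_for_share(0.9)
  se <- NULL
  if (!is.null(fit$boot)) {
    pi12_b <- fit$boot[, "pi12"]
    se <- c(shared = stats::sd(pi12_b * m),
            dice = stats::sd(2 * pi12_b / (pi_1 + pi_2)))
  }
  structure(list(
    shared = p$pi12 * m, specific1 = p$pi1s * m, specific2 = p$pi2s * m,
    dice = dice, rg = rg,
    n90_1 = pi_1 * m * q90, n90_2 = pi_2 * m * q90, q90 = q90,
    aic_delta = aic_delta, se = se, m = m, params = p
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  k <- function(v) sprintf("%.1fK", v / 1000)
  cat("Polygenic overlap summary\n")
  cat(sprintf("  causal variants: %s shared, %s + %s trait-specific\n",
              k(x$shared), k(x$specific1), k(x$specific2)))
  cat(sprintf("  n90 (90%% heritability): %s and %s\n",
              k(x$n90_1), k(x$n90_2)))
  cat(sprintf("  Dice coefficient = %.1f%%   rg = %s\n", 100 * x$dice,
              ifelse(is.na(x$rg), "undefined", sprintf("%.2f", x$rg))))
  if (!is.na(x$aic_delta)) {
    cat(sprintf("  AIC(no overlap) - AIC(overlap) = %.2f%s\n", x$aic_delta,
                if (x$aic_delta > 0) "  (overlap model favored)" else ""))
  }
  if (!is.null(x$se)) {
    cat(sprintf("  bootstrap SE: shared %s, Dice %.3f\n",
                k(x$se["shared"]), x$se["dice"]))
  }
  invisible(x)
}

#' Venn-style plot of shared and trait-specific causal variants
#'
#' Two overlapping circles with areas proportional to the per-trait causal
#' counts and the labelled intersection.
#'
#' @param x An `overlap_summary`.
#' @param labels Trait labels.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.overlap_summary <- function(x, labels = c("trait 1", "trait 2"), ...) {
  n1 <- x$specific1 + x$shared; n2 <- x$specific2 + x$shared
  r1 <- sqrt(n1); r2 <- sqrt(n2)
  sc <- 1 / max(r1, r2)
  r1 <- r1 * sc; r2 <- r2 * sc
  d <- (r1 + r2) * (1 - x$dice)        # heuristic center separation
  graphics::plot(NA, xlim = c(-1.6, 1.6 + d), ylim = c(-1.6, 1.6),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::polygon(r1 * cos(th), r1 * sin(th),
                    col = grDevices::adjustcolor("red", 0.3))
  graphics::polygon(d + r2 * cos(th), r2 * sin(th),
                    col = grDevices::adjustcolor("blue", 0.3))
  graphics::text(-r1 / 2, 0, sprintf("%s\n%.1fK", labels[1],
                                     x$specific1 / 1000))
  graphics::text(d + r2 / 2, 0, sprintf("%s\n%.1fK", labels[2],
                                        x$specific2 / 1000))
  graphics::text(d / 2, 0, sprintf("%.1fK", x$shared / 1000))
  graphics::title(sprintf("Dice = %.1f%%", 100 * x$dice))
  invisible(x)
}
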