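#' Filter and decision settings for the differential-expression stage
#'
#' @param median_threshold genes must have median log2 normalized expression
#'   strictly greater than this to be tested (default 3.71).
#' @param fdr Benjamini-Hochberg FDR level; genes with `q <= fdr` are called
#'   (inclusive bound).
#' @param lfc_cutoff absolute log2 fold-change bound for the additionally
#'   filtered tally; strictly greater than (`|log2fc| = lfc_cutoff` is
#'   excluded).
#' @return object of class `de_filter_spec`.
#' @export
de_filter_spec <- function(median_threshold = 3.71, fdr = 0.01,
                           lfc_cutoff = 1.0) {
  if (fdr <= 0 || fdr >= 1) stop("de_filter_spec: fdr must lie in (0, 1)")
  if (!is.finite(median_threshold) || !is.finite(lfc_cutoff)) {
    stop("de_filter_spec: thresholds must be finite")
  }
  structure(list(median_threshold = median_threshold, fdr = fdr,
                 lfc_cutoff = lfc_cutoff), class = "de_filter_spec")
}

#' Genes eligible for differential-expression testing
#'
#' Keeps a gene iff it is called active in at least one sample type and its
#' median log2 normalized expression across all samples is strictly greater
#' than the threshold.
#'
#' @param lcpm gene x sample log2-CPM matrix (see [logcpm()]).
#' @param calls an [call_activity()] result over the same genes.
#' @param spec a [de_filter_spec()].
#' @return character vector of retained gene ids (row order of `lcpm`).
#' @export
filter_expressed <- function(lcpm, calls, spec = de_filter_spec()) {
  gene_ids <- rownames(lcpm)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(nrow(lcpm)))
  if (!setequal(gene_ids, unique(calls$gene_id))) {
    stop("filter_expressed: gene universes of lcpm and calls differ")
  }
  any_active <- tapply(calls$active, calls$gene_id, any)
  med <- apply(lcpm, 1, stats::median)
  keep <- as.logical(any_active[gene_ids]) & med > spec$median_threshold
  gene_ids[keep]
}

de_design_matrix <- function(design, contrast_type = NULL) {
  st <- as.character(design$sample_type)
  types <- unique(st)
  if (length(types) != 2) {
    stop("differential expression requires exactly two sample types")
  }
  if (is.null(contrast_type)) contrast_type <- types[1]
  ref <- setdiff(types, contrast_type)
  treat <- factor(st, levels = c(ref, contrast_type))
  if ("replicate" %in% names(design)) {
    block <- factor(design$replicate)
    X <- stats::model.matrix(~ treat + block)
  } else {
    X <- stats::model.matrix(~ treat)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  attr(X, "coef_name") <- paste0("treat", contrast_type)
  X
}

#' Log2-CPM with precision weights from the mean-variance trend
#'
#' Transforms counts to log2-CPM, fits an unweighted linear model per gene,
#' smooths the square root of the residual standard deviation against mean
#' log2 count with lowess, and converts the trend into per-observation
#' inverse-variance precision weights (`trend^-4` evaluated at each
#' observation's predicted log2 count, linear interpolation with constant
#' extrapolation at the ends).
#'
#' @param counts gene x sample count matrix.
#' @param norm a [tmm_factors()] result (or NULL for library sizes only).
#' @param design sample metadata data.frame (`sample_id`, `sample_type`,
#'   optional `replicate` used as a block).
#' @param span lowess span of the mean-variance trend.
#' @param contrast_type sample type whose coefficient is reported (default:
#'   first type present; the contrast is this type minus the other).
#' @return list of class `voom_data`: `E` (log2-CPM), `weights`, `trend`
#'   (list with `x`, `y`), `design` (model matrix).
#' @export
voom_transform <- function(counts, norm = NULL, design, span = 0.5,
                           contrast_type = NULL) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  if (is.null(norm)) {
    eff <- colSums(counts)
  } else {
    stopifnot(inherits(norm, "norm_factors"))
    eff <- norm$library_size * norm$tmm_factor
  }
  X <- de_design_matrix(design, contrast_type)
  if (n < ncol(X)) {
    stop("voom_transform: fewer samples than design columns")
  }
  dfres <- n - ncol(X)
  if (dfres < 2) {
    stop("voom_transform: need >= 2 residual degrees of freedom")
  }
  E <- t(log2(t(counts + 0.5) / (eff + 1) * 1e6))

  fit <- stats::lm.fit(X, t(E))
  res <- t(as.matrix(fit$residuals))
  sigma <- sqrt(rowSums(res^2) / dfres)
  sx <- rowMeans(E) + mean(log2(eff + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy)
  lo <- stats::lowess(sx[ok], sy[ok], f = span)
  trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)

  fitted_lcpm <- t(as.matrix(fit$fitted.values))
  fitted_lcount <- fitted_lcpm +
    matrix(rep(log2(eff + 1) - log2(1e6), each = nrow(E)), nrow(E), n)
  w <- trend_fun(fitted_lcount)^-4
  w[!is.finite(w) | w <= 0] <- min(w[is.finite(w) & w > 0])
  w <- matrix(w, nrow(E), n, dimnames = dimnames(E))

  structure(list(E = E, weights = w,
                 trend = list(x = lo$x, y = lo$y),
                 design = X),
            class = "voom_data")
}

#' Per-gene weighted linear model fits
#'
#' Weighted least squares of each gene's log2 expression on the design
#' (treatment plus optional replicate block); reports the treatment
#' coefficient (log2 fold change of the contrast type over the reference),
#' its unscaled standard error, the residual variance and degrees of freedom.
#'
#' @param voom a [voom_transform()] result (or a list with `E`, `weights`,
#'   `design`).
#' @return data.frame of class `gene_fits` with columns `gene_id`, `coef`,
#'   `stdev_unscaled`, `sigma2`, `df`.
#' @export
fit_models <- function(voom) {
  E <- voom$E; W <- voom$weights; X <- voom$design
  G <- nrow(E); n <- ncol(E); p <- ncol(X)
  cn <- attr(X, "coef_name")
  ci <- if (!is.null(cn)) match(cn, colnames(X)) else 2L
  dfres <- n - p
  coefs <- numeric(G); seu <- numeric(G); s2 <- numeric(G)
  for (g in seq_len(G)) {
    sw <- sqrt(W[g, ])
    Xw <- X * sw
    yw <- E[g, ] * sw
    qrx <- qr(Xw)
    beta <- qr.coef(qrx, yw)
    r <- yw - Xw %*% beta
    XtX_inv <- chol2inv(qr.R(qrx)[seq_len(p), seq_len(p), drop = FALSE])
    coefs[g] <- beta[ci]
    seu[g] <- sqrt(XtX_inv[ci, ci])
    s2[g] <- sum(r^2) / dfres
  }
  gene_ids <- rownames(E)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(G))
  out <- data.frame(gene_id = gene_ids, coef = coefs, stdev_unscaled = seu,
                    sigma2 = s2, df = dfres, stringsAsFactors = FALSE)
  class(out) <- c("gene_fits", "data.frame")
  out
}

# inverse of the trigamma function (Newton on 1/trigamma, which is almost
# linear), used when moment-matching the prior degrees of freedom
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated statistics
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` by
#' moment-matching the distribution of log residual variances
#' (digamma/trigamma inversion), shrinks each gene's residual variance to
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and tests the treatment
#' coefficient with a t-statistic on `d0 + d` degrees of freedom. P-values
#' are two-sided; q-values are Benjamini-Hochberg.
#'
#' @param fits a [fit_models()] result (>= 10 genes).
#' @param d0_override force the no-moderation (`0`) or full-shrinkage
#'   (`Inf`) limit; mainly for validation.
#' @return data.frame of class `moderated_result` with columns `gene_id`,
#'   `log2fc`, `mod_t`, `p`, `q`, `df_residual`, `df_prior`, `s2_prior`,
#'   `s2_post`. When every variance is identical the degenerate `d0 = Inf`
#'   branch is taken and flagged in `attr(, "degenerate")`.
#' @export
moderate <- function(fits, d0_override = NULL) {
  stopifnot(is.data.frame(fits),
            all(c("coef", "stdev_unscaled", "sigma2", "df") %in% names(fits)))
  if (nrow(fits) < 10) stop("moderate: need >= 10 genes")
  s2 <- fits$sigma2
  d <- fits$df
  if (any(d < 1)) stop("moderate: non-positive residual df")

  degenerate <- FALSE
  ok <- s2 > 0
  if (is.null(d0_override)) {
    z <- log(s2[ok])
    e <- z - digamma(d[ok] / 2) + log(d[ok] / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(d[ok] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- mean(s2[ok])
      degenerate <- TRUE
    }
  } else {
    d0 <- d0_override
    z <- log(s2[ok])
    e <- z - digamma(d[ok] / 2) + log(d[ok] / 2)
    s02 <- if (is.finite(d0) && d0 > 0) {
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      mean(s2[ok])
    }
  }

  if (is.infinite(d0)) {
    s2post <- rep(s02, length(s2))
    df_total <- rep(Inf, length(d))
  } else if (d0 == 0) {
    s2post <- s2
    df_total <- d
  } else {
    s2post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  tstat <- fits$coef / (fits$stdev_unscaled * sqrt(s2post))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(
    gene_id = fits$gene_id, log2fc = fits$coef, mod_t = tstat,
    p = p, q = bh_adjust(p),
    df_residual = d, df_prior = d0, s2_prior = s02, s2_post = s2post,
    stringsAsFactors = FALSE
  )
  attr(out, "degenerate") <- degenerate
  class(out) <- c("moderated_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort p ascending, `q_(i) = min_{j >= i}
#' p_(j) * n / j`, capped at 1, mapped back to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`; NA or NaN is an error.
#' @return vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("bh_adjust: NA/NaN in p-values")
  if (any(p < 0 | p > 1)) stop("bh_adjust: p-values outside [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Summary counts of differential expression
#'
#' Tallies significant genes per direction at `q <= fdr` (inclusive), the
#' subset additionally passing `|log2fc| > lfc_cutoff` (strict), and the
#' per-direction average linear-scale fold change, `mean(2^|log2fc|)` over
#' that direction's significant genes.
#'
#' @param results a [moderate()] result.
#' @param spec a [de_filter_spec()].
#' @return list of class `de_summary`.
#' @export
de_summary <- function(results, spec = de_filter_spec()) {
  sig <- results$q <= spec$fdr
  up <- sig & results$log2fc > 0
  down <- sig & results$log2fc < 0
  big <- abs(results$log2fc) > spec$lfc_cutoff
  out <- list(
    n_tested = nrow(results),
    n_up = sum(up), n_down = sum(down),
    n_up_lfc = sum(up & big), n_down_lfc = sum(down & big),
    avg_fc_up = if (any(up)) mean(2^abs(results$log2fc[up])) else NA_real_,
    avg_fc_down = if (any(down)) mean(2^abs(results$log2fc[down]))
                  else NA_real_,
    fdr = spec$fdr, lfc_cutoff = spec$lfc_cutoff
  )
  class(out) <- "de_summary"
  out
}

#' @export
print.de_summary <- function(x, ...) {
  cat("differential expression at FDR <=", x$fdr * 100, "% (",
      x$n_tested, "genes tested )\n")
  cat(sprintf("  up:   %d (|log2FC| > %g: %d), average Fc = %s\n",
              x$n_up, x$lfc_cutoff, x$n_up_lfc,
              if (is.na(x$avg_fc_up)) "-" else sprintf("%.2f", x$avg_fc_up)))
  cat(sprintf("  down: %d (|log2FC| > %g: %d), average Fc = %s\n",
              x$n_down, x$lfc_cutoff, x$n_down_lfc,
              if (is.na(x$avg_fc_down)) "-"
              else sprintf("%.2f", x$avg_fc_down)))
  invisible(x)
}
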