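#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes one scaling factor per sample relative to a reference sample,
#' from the weighted mean of trimmed log expression ratios (M-values), then
#' rescales all factors to geometric mean 1. Genes with a zero count in
#' either the sample or the reference are excluded from the M/A vectors;
#' 30% of M-values and 5% of A-values are trimmed from each tail; weights
#' are inverse asymptotic binomial variances. The reference defaults to the
#' sample whose 75th-percentile CPM is closest to the mean of those
#' percentiles.
#'
#' @param counts non-negative integer gene x sample matrix (>= 2 samples).
#' @param ref_sample optional reference sample name or index.
#' @param trim_m,trim_a tail trim fractions for M- and A-values.
#' @return data.frame of class `norm_factors` with columns `sample_id`,
#'   `library_size`, `tmm_factor`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        trim_m = 0.3, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("tmm_factors: need at least two samples")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("tmm_factors: counts must be finite and non-negative")
  }
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero)) {
    stop("tmm_factors: all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sample_ids <- colnames(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(counts)))

  if (is.null(ref_sample)) {
    f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, sample_ids)
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1 || ref > ncol(counts)) {
      stop("tmm_factors: unknown reference sample")
    }
  }

  f <- vapply(seq_len(ncol(counts)), function(i) {
    tmm_pair(counts[, i], counts[, ref], lib[i], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  out <- data.frame(sample_id = sample_ids, library_size = lib,
                    tmm_factor = f, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ref_sample") <- sample_ids[ref]
  class(out) <- c("norm_factors", "data.frame")
  out
}

# single-pair TMM factor (sample vs reference), 2^(weighted trimmed mean M)
tmm_pair <- function(y, yr, N, Nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (length(y) == 0) return(1)
  M <- log2((y / N) / (yr / Nr))
  A <- 0.5 * log2((y / N) * (yr / Nr))
  v <- (N - y) / (N * y) + (Nr - yr) / (Nr * yr)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("norm_factors (reference:", attr(x, "ref_sample"), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Log2 counts per million with a prior count
#'
#' `log2((count + prior) / (library_size * tmm_factor + 2 * prior) * 1e6)`,
#' the depth-normalized log2 expression used for the median filter, the QC
#' views and the smooth gene-level normalization.
#'
#' @param counts gene x sample count matrix.
#' @param norm a [tmm_factors()] result (or NULL for factors of 1).
#' @param prior_count positive prior count.
#' @return gene x sample numeric matrix.
#' @export
logcpm <- function(counts, norm = NULL, prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (prior_count <= 0) stop("logcpm: prior_count must be positive")
  if (is.null(norm)) {
    lib <- colSums(counts)
    f <- rep(1, ncol(counts))
  } else {
    stopifnot(inherits(norm, "norm_factors"))
    lib <- norm$library_size
    f <- norm$tmm_factor
  }
  if (any(lib == 0)) stop("logcpm: zero library size")
  eff <- lib * f + 2 * prior_count
  log2(sweep(counts + prior_count, 2, eff, "/") * 1e6)
}

#' Gene-level offsets from a smooth function of length and GC content
#'
#' Fits an additive local-linear (loess, degree 1) surface of mean log-CPM on
#' the z-scores of log gene length and of GC fraction, by two rounds of
#' backfitting, and returns the centered fitted values as per-gene additive
#' offsets on the natural-log scale. Genes with systematically higher capture
#' (longer, or GC-favoured) receive a positive offset, which the activity
#' model then absorbs so that fixed effects are comparable across genes.
#'
#' @param counts gene x sample count matrix.
#' @param features data.frame with columns `gene_id`, `length`, `gc` covering
#'   every gene in `counts`.
#' @param span loess span for both smoothers.
#' @param norm optional [tmm_factors()] result used for the CPM denominator.
#' @return named numeric vector of centered per-gene offsets (natural log).
#' @export
length_gc_offsets <- function(counts, features, span = 0.5, norm = NULL) {
  counts <- as.matrix(counts)
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(nrow(counts)))
  idx <- match(gene_ids, features$gene_id)
  if (anyNA(idx)) {
    miss <- gene_ids[is.na(idx)]
    stop("length_gc_offsets: features missing for gene(s): ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) " ..." else "")
  }
  len <- features$length[idx]
  gc <- features$gc[idx]
  if (any(len < 1) || any(gc < 0 | gc > 1)) {
    stop("length_gc_offsets: invalid length or gc values")
  }
  y <- rowMeans(logcpm(counts, norm = norm)) * log(2)   # natural-log scale
  zl <- zscore_or_zero(log(len))
  zg <- zscore_or_zero(gc)

  f1 <- rep(0, length(y)); f2 <- rep(0, length(y))
  for (round in 1:2) {
    f1 <- smooth_1d(zl, y - f2, span)
    f2 <- smooth_1d(zg, y - f1, span)
  }
  off <- f1 + f2
  off <- off - mean(off)
  names(off) <- gene_ids
  off
}

zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

smooth_1d <- function(x, y, span) {
  if (diff(range(x)) < 1e-12) return(rep(mean(y), length(y)))
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}

#' Assemble the full gene-by-sample offset matrix
#'
#' Combines the sample-level part, `log(library_size * tmm_factor)`, with the
#' centered per-gene length/GC offsets, on the natural-log scale of the
#' activity model's linear predictor.
#'
#' @param counts gene x sample count matrix.
#' @param norm a [tmm_factors()] result.
#' @param gene_offsets per-gene offsets from [length_gc_offsets()] (or NULL).
#' @return gene x sample numeric matrix of offsets.
#' @export
build_offsets <- function(counts, norm, gene_offsets = NULL) {
  counts <- as.matrix(counts)
  stopifnot(inherits(norm, "norm_factors"))
  if (ncol(counts) != nrow(norm)) {
    stop("build_offsets: counts and norm factors do not conform")
  }
  eff <- log(norm$library_size * norm$tmm_factor)
  off <- matrix(rep(eff, each = nrow(counts)), nrow(counts), ncol(counts))
  if (!is.null(gene_offsets)) {
    if (length(gene_offsets) != nrow(counts)) {
      stop("build_offsets: gene_offsets length mismatch")
    }
    off <- off + gene_offsets
  }
  dimnames(off) <- dimnames(counts)
  off
}
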