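#' Specification of the gene-activity decision rule
#'
#' @param threshold_T log-scale activity threshold on the sample-type fixed
#'   effect. `NULL` (default) selects the threshold automatically at fit
#'   time: the log expected count corresponding to 1 CPM at the median
#'   effective library size (see [auto_threshold()]).
#' @param call_cutoff posterior-probability cutoff; a gene is called active
#'   in a sample type iff `P(beta_gs > T | data)` is strictly greater than
#'   this value (ties are inactive).
#' @param max_iterations,tolerance control of the per-gene mode finding and
#'   of the empirical-Bayes coordinate ascent.
#' @return object of class `activity_model_spec`.
#' @export
activity_model_spec <- function(threshold_T = NULL, call_cutoff = 0.5,
                                max_iterations = 50, tolerance = 1e-6) {
  if (call_cutoff <= 0 || call_cutoff >= 1) {
    stop("activity_model_spec: call_cutoff must lie in (0, 1)")
  }
  if (tolerance <= 0) stop("activity_model_spec: tolerance must be positive")
  if (!is.null(threshold_T) && !is.finite(threshold_T)) {
    stop("activity_model_spec: threshold_T must be finite or NULL")
  }
  structure(list(threshold_T = threshold_T, call_cutoff = call_cutoff,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "activity_model_spec")
}

#' Automatic activity threshold
#'
#' The activity threshold defaults to the fixed-effect value at which a gene's
#' expected count equals 1 CPM in the median-depth sample:
#' `T = log(1e-6 * median(column sums)) - median(column means of offsets)`.
#' The second term places `T` on the same scale as the fitted fixed effects,
#' whatever convention the offset matrix uses for its sample-level part.
#'
#' @param counts gene x sample count matrix.
#' @param offsets conforming offset matrix (natural log).
#' @return scalar threshold on the fixed-effect scale.
#' @export
auto_threshold <- function(counts, offsets) {
  log(1e-6 * stats::median(colSums(as.matrix(counts)))) -
    stats::median(colMeans(as.matrix(offsets)))
}

check_activity_inputs <- function(counts, offsets, design) {
  counts <- as.matrix(counts)
  offsets <- as.matrix(offsets)
  if (!all(dim(counts) == dim(offsets))) {
    stop("offsets must conform to counts")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers")
  }
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  if (!all(c("sample_id", "sample_type") %in% names(design))) {
    stop("design must have columns sample_id and sample_type")
  }
  if (nrow(design) != ncol(counts)) {
    stop("design rows must match count columns")
  }
  tab <- table(design$sample_type)
  if (any(tab < 2)) {
    stop("need >= 2 replicates per sample type; offending type(s): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  list(counts = counts, offsets = offsets,
       sample_types = unique(as.character(design$sample_type)),
       type_of = match(as.character(design$sample_type),
                       unique(as.character(design$sample_type))))
}

# One full coordinate-ascent pass over all genes simultaneously (vectorized
# Newton updates for the fixed effects, replicate random effects, random-
# effect precision and log-dispersion of every gene).
#
# state: B (G x S), U (G x n), lam (G), lphi (G)
# hyper: m, v (length S), a, b, mphi, vphi
ca_sweep <- function(Y, O, type_of, state, hyper, step_cap = 3) {
  G <- nrow(Y); S <- length(hyper$m)
  B <- state$B; U <- state$U; lam <- state$lam; lphi <- state$lphi
  delta <- rep(0, G)

  nb_sw <- function(eta, k) {
    mu <- exp(pmin(pmax(eta, -700), 30 + log(max(1, max(Y)))))
    list(mu = mu,
         s = Y - (Y + k) * mu / (mu + k),
         w = (Y + k) * k * mu / (mu + k)^2)
  }
  K <- matrix(exp(-lphi), G, ncol(Y))

  # fixed effects (each sample type is conditionally independent)
  eta <- B[, type_of, drop = FALSE] + U + O
  sw <- nb_sw(eta, K)
  for (s in seq_len(S)) {
    cols <- which(type_of == s)
    num <- rowSums(sw$s[, cols, drop = FALSE]) - (B[, s] - hyper$m[s]) / hyper$v[s]
    den <- rowSums(sw$w[, cols, drop = FALSE]) + 1 / hyper$v[s]
    step <- pmin(pmax(num / den, -step_cap), step_cap)
    B[, s] <- B[, s] + step
    delta <- pmax(delta, abs(step))
  }

  # replicate random effects
  eta <- B[, type_of, drop = FALSE] + U + O
  sw <- nb_sw(eta, K)
  stepU <- (sw$s - U * lam) / (sw$w + lam)
  stepU <- pmin(pmax(stepU, -step_cap), step_cap)
  U <- U + stepU
  delta <- pmax(delta, apply(abs(stepU), 1, max))

  # random-effect precision: conditional mode of Gamma(a + q/2, b + SSU/2)
  q <- ncol(Y)
  sh <- hyper$a + q / 2
  lam_new <- pmax(sh - 1, 1e-3) / (hyper$b + rowSums(U^2) / 2)
  lam <- pmin(pmax(lam_new, 1e-8), 1e8)

  # log-dispersion: damped Newton with analytic gradient
  eta <- B[, type_of, drop = FALSE] + U + O
  gfun <- function(lp) {
    k <- exp(-lp)
    Km <- matrix(k, G, ncol(Y))
    mu <- exp(pmin(pmax(eta, -700), 30 + log(max(1, max(Y)))))
    dldk <- digamma(Y + Km) - digamma(Km) + log(Km) + 1 -
      log(mu + Km) - (Y + Km) / (mu + Km)
    -k * rowSums(dldk) - (lp - hyper$mphi) / hyper$vphi
  }
  h <- 0.05
  g0 <- gfun(lphi)
  hess <- (gfun(lphi + h) - gfun(lphi - h)) / (2 * h)
  step <- ifelse(hess < -1e-8, -g0 / hess, 0.2 * sign(g0))
  step <- pmin(pmax(step, -1), 1)
  lphi <- pmin(pmax(lphi + step, -8), 4)
  delta <- pmax(delta, abs(step))

  list(B = B, U = U, lam = lam, lphi = lphi, delta = delta,
       hess_lphi = hess)
}

# posterior curvatures at the joint mode: profile (Schur-complement) SD of
# each fixed effect, conditional variances of the replicate random effects,
# and the Laplace variance of the log-dispersion
posterior_curvatures <- function(Y, O, type_of, state, hyper) {
  G <- nrow(Y); S <- length(hyper$m)
  K <- matrix(exp(-state$lphi), G, ncol(Y))
  eta <- state$B[, type_of, drop = FALSE] + state$U + O
  mu <- exp(pmin(pmax(eta, -700), 700))
  w <- (Y + K) * K * mu / (mu + K)^2
  sd <- matrix(NA_real_, G, S)
  for (s in seq_len(S)) {
    cols <- which(type_of == s)
    ws <- w[, cols, drop = FALSE]
    hbb <- rowSums(ws) + 1 / hyper$v[s]
    schur <- hbb - rowSums(ws^2 / (ws + state$lam))
    sd[, s] <- 1 / sqrt(pmax(schur, 1e-12))
  }
  gfun <- function(lp) {
    k <- exp(-lp)
    Km <- matrix(k, G, ncol(Y))
    dldk <- digamma(Y + Km) - digamma(Km) + log(Km) + 1 -
      log(mu + Km) - (Y + Km) / (mu + Km)
    -k * rowSums(dldk) - (lp - hyper$mphi) / hyper$vphi
  }
  h <- 0.05
  hess <- (gfun(state$lphi + h) - gfun(state$lphi - h)) / (2 * h)
  list(sdB = sd,
       u_var = 1 / (w + state$lam),
       lphi_var = 1 / pmax(-hess, 1e-8))
}

posterior_sd <- function(Y, O, type_of, state, hyper) {
  posterior_curvatures(Y, O, type_of, state, hyper)$sdB
}

fit_modes <- function(Y, O, type_of, hyper, state = NULL,
                      max_iterations = 50, tolerance = 1e-6) {
  G <- nrow(Y); S <- max(type_of)
  if (is.null(state)) {
    B <- matrix(0, G, S)
    for (s in seq_len(S)) {
      cols <- which(type_of == s)
      B[, s] <- log((rowSums(Y[, cols, drop = FALSE]) + 0.5) /
                      rowSums(exp(O[, cols, drop = FALSE])))
    }
    state <- list(B = B, U = matrix(0, G, ncol(Y)),
                  lam = rep(hyper$a / hyper$b, G),
                  lphi = rep(hyper$mphi, G))
  }
  delta <- rep(Inf, G)
  for (it in seq_len(max_iterations)) {
    sw <- ca_sweep(Y, O, type_of, state, hyper)
    state <- sw[c("B", "U", "lam", "lphi")]
    delta <- sw$delta
    if (max(delta) < tolerance) break
  }
  state$delta <- delta
  state$failed <- delta > max(100 * tolerance, 1e-4)
  state$iterations <- it
  state
}

#' Empirical-Bayes estimation of the model hyperpriors
#'
#' Estimates, by pooling information across all genes, the hyperparameters of
#' the hierarchical negative-binomial model: the normal prior (mean and
#' diagonal variance, one entry per sample type) of the fixed effects, the
#' gamma prior (shape, rate) of the replicate random-effect precision, and
#' the normal prior of the log NB dispersion. Method-of-moments estimates
#' initialize a coordinate ascent in which gene-level Laplace posterior
#' summaries and hyperparameter updates alternate (an EM on the
#' Laplace-approximated marginal likelihood), run for at most
#' `max_iterations` rounds or until the largest hyperparameter change drops
#' below `tolerance`.
#'
#' @param counts gene x sample integer count matrix.
#' @param offsets conforming natural-log offset matrix (see
#'   [build_offsets()]).
#' @param design data.frame with columns `sample_id`, `sample_type` (and
#'   optionally `replicate`); >= 2 replicates per sample type.
#' @param max_iterations,tolerance outer-loop control.
#' @return object of class `hyperparameters`: list with
#'   `fixed_effect_mean`, `fixed_effect_var` (named per sample type),
#'   `ranef_shape`, `ranef_rate`, `log_disp_mean`, `log_disp_var`,
#'   `iterations`, `converged`.
#' @export
fit_hyperpriors <- function(counts, offsets, design,
                            max_iterations = 50, tolerance = 1e-6) {
  ci <- check_activity_inputs(counts, offsets, design)
  Y <- ci$counts; O <- ci$offsets; type_of <- ci$type_of
  S <- length(ci$sample_types); G <- nrow(Y)
  if (G < 10) stop("fit_hyperpriors: need >= 10 genes")

  # --- method-of-moments initialization ---
  m <- numeric(S); v <- numeric(S)
  bhat <- matrix(0, G, S)
  for (s in seq_len(S)) {
    cols <- which(type_of == s)
    bhat[, s] <- log((rowSums(Y[, cols, drop = FALSE]) + 0.5) /
                       rowSums(exp(O[, cols, drop = FALSE])))
    m[s] <- mean(bhat[, s])
    samp_var <- mean(1 / (rowSums(Y[, cols, drop = FALSE]) + 1))
    v[s] <- max(stats::var(bhat[, s]) - samp_var, 1e-2)
  }
  lphi_hat <- rep(NA_real_, G)
  E <- exp(O)
  resc <- Y / E
  num <- 0; den <- 0
  phi_pool <- c()
  for (s in seq_len(S)) {
    cols <- which(type_of == s)
    mb <- rowMeans(resc[, cols, drop = FALSE])
    vr <- apply(resc[, cols, drop = FALSE], 1, stats::var)
    shot <- mb * rowMeans(1 / E[, cols, drop = FALSE])
    est <- (vr - shot) / mb^2
    ok <- is.finite(est) & mb > 1 & est > 1e-4 & est < 10
    phi_pool <- c(phi_pool, est[ok])
  }
  if (length(phi_pool) >= 10) {
    mphi <- mean(log(phi_pool))
    vphi <- max(stats::var(log(phi_pool)) / 2, 1e-2)  # MOM log-phi is noisy
  } else {
    mphi <- log(0.1); vphi <- 0.25
  }
  a <- 2; b <- 0.04
  hyper <- list(m = m, v = v, a = a, b = b, mphi = mphi, vphi = vphi)

  # --- coordinate ascent (EM with Laplace posterior summaries) ---
  state <- NULL
  converged <- FALSE
  q <- ncol(Y)
  for (round in seq_len(max_iterations)) {
    state <- fit_modes(Y, O, type_of, hyper, state,
                       max_iterations = if (round == 1) 40 else 15,
                       tolerance = tolerance)
    cv <- posterior_curvatures(Y, O, type_of, state, hyper)
    sdB <- cv$sdB
    old <- unlist(hyper[c("m", "v", "mphi", "vphi")])
    old <- c(old, log(hyper$a), log(hyper$b))

    for (s in seq_len(S)) {
      hyper$m[s] <- mean(state$B[, s])
      hyper$v[s] <- max(mean((state$B[, s] - hyper$m[s])^2) +
                          mean(sdB[, s]^2), 1e-3)
    }
    hyper$mphi <- mean(state$lphi)
    hyper$vphi <- max(mean((state$lphi - hyper$mphi)^2) +
                        mean(cv$lphi_var), 1e-3)

    # E-step sum of squares includes the conditional posterior variances of
    # the random effects; without them the precision estimate diverges
    ssu <- rowSums(state$U^2 + cv$u_var)
    Elam <- (hyper$a + q / 2) / (hyper$b + ssu / 2)
    Eloglam <- digamma(hyper$a + q / 2) - log(hyper$b + ssu / 2)
    gm <- gamma_mle(mean(Elam), mean(Eloglam))
    hyper$a <- gm$shape; hyper$b <- gm$rate

    new <- c(unlist(hyper[c("m", "v", "mphi", "vphi")]),
             log(hyper$a), log(hyper$b))
    if (max(abs(new - old)) < max(tolerance, 1e-5)) {
      converged <- TRUE
      break
    }
  }

  structure(list(
    fixed_effect_mean = stats::setNames(hyper$m, ci$sample_types),
    fixed_effect_var = stats::setNames(hyper$v, ci$sample_types),
    ranef_shape = hyper$a, ranef_rate = hyper$b,
    log_disp_mean = hyper$mphi, log_disp_var = hyper$vphi,
    sample_types = ci$sample_types,
    iterations = round, converged = converged
  ), class = "hyperparameters")
}

# gamma MLE from the mean and mean-log of (pseudo-)observations;
# solves log(shape) - digamma(shape) = log(mean) - meanlog by Newton
gamma_mle <- function(mean_x, meanlog_x) {
  s <- log(mean_x) - meanlog_x
  if (!is.finite(s) || s <= 0) return(list(shape = 1e4, rate = 1e4 / mean_x))
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:25) {
    f <- log(shape) - digamma(shape) - s
    fp <- 1 / shape - trigamma(shape)
    step <- f / fp
    shape <- shape - step
    if (!is.finite(shape) || shape <= 0) { shape <- 0.01; break }
    if (abs(step) < 1e-10) break
  }
  shape <- min(max(shape, 0.01), 1e4)
  list(shape = shape, rate = shape / mean_x)
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat("hyperparameters (", if (x$converged) "converged" else "not converged",
      " after ", x$iterations, " rounds)\n", sep = "")
  cat("  fixed-effect prior mean:",
      paste(sprintf("%s=%.3f", names(x$fixed_effect_mean),
                    x$fixed_effect_mean), collapse = ", "), "\n")
  cat("  fixed-effect prior var :",
      paste(sprintf("%s=%.3f", names(x$fixed_effect_var),
                    x$fixed_effect_var), collapse = ", "), "\n")
  cat(sprintf("  ranef precision ~ Gamma(shape=%.3g, rate=%.3g)\n",
              x$ranef_shape, x$ranef_rate))
  cat(sprintf("  log-dispersion ~ Normal(%.3f, var %.3f)\n",
              x$log_disp_mean, x$log_disp_var))
  invisible(x)
}

hyper_internal <- function(hyper) {
  list(m = as.numeric(hyper$fixed_effect_mean),
       v = as.numeric(hyper$fixed_effect_var),
       a = hyper$ranef_shape, b = hyper$ranef_rate,
       mphi = hyper$log_disp_mean, vphi = hyper$log_disp_var)
}

#' Posterior summaries and activity probabilities for all genes
#'
#' For each gene, finds the joint posterior mode of the sample-type fixed
#' effects, replicate random effects and log NB dispersion under the fitted
#' hyperpriors, takes a Laplace (Gaussian) approximation with the random
#' effects and dispersion profiled at their modes, and reports
#' `p_active = P(beta_gs > T) = 1 - pnorm((T - mean) / sd)` per gene and
#' sample type.
#'
#' @param counts,offsets,design as in [fit_hyperpriors()].
#' @param hyper a [fit_hyperpriors()] result.
#' @param spec an [activity_model_spec()].
#' @return data.frame of class `gene_posterior` with columns `gene_id`,
#'   `sample_type`, `post_mean`, `post_sd`, `p_active`, `failed`; the
#'   threshold used is stored in `attr(, "threshold_T")`.
#' @export
activity_posteriors <- function(counts, offsets, design, hyper,
                                spec = activity_model_spec()) {
  ci <- check_activity_inputs(counts, offsets, design)
  stopifnot(inherits(hyper, "hyperparameters"))
  hy <- hyper_internal(hyper)
  Tthr <- spec$threshold_T
  if (is.null(Tthr)) Tthr <- auto_threshold(ci$counts, ci$offsets)

  state <- fit_modes(ci$counts, ci$offsets, ci$type_of, hy,
                     max_iterations = spec$max_iterations,
                     tolerance = spec$tolerance)
  sdB <- posterior_sd(ci$counts, ci$offsets, ci$type_of, state, hy)
  G <- nrow(ci$counts); S <- length(ci$sample_types)
  gene_ids <- rownames(ci$counts)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(G))

  out <- data.frame(
    gene_id = rep(gene_ids, times = S),
    sample_type = rep(ci$sample_types, each = G),
    post_mean = as.numeric(state$B),
    post_sd = as.numeric(sdB),
    stringsAsFactors = FALSE
  )
  out$p_active <- stats::pnorm((out$post_mean - Tthr) / out$post_sd)
  out$failed <- rep(state$failed, times = S)
  attr(out, "threshold_T") <- Tthr
  attr(out, "state") <- state
  class(out) <- c("gene_posterior", "data.frame")
  out
}

#' Posterior for a single gene
#'
#' Convenience wrapper around [activity_posteriors()] for one gene's counts.
#'
#' @param gene_counts integer vector of per-sample counts for one gene.
#' @param offsets_row numeric vector of that gene's offsets.
#' @param design sample metadata as in [fit_hyperpriors()].
#' @param hyper fitted [fit_hyperpriors()] object.
#' @param spec an [activity_model_spec()].
#' @return one row per sample type (`gene_posterior` data.frame).
#' @export
gene_posterior <- function(gene_counts, offsets_row, design, hyper,
                           spec = activity_model_spec()) {
  Y <- matrix(as.numeric(gene_counts), nrow = 1)
  O <- matrix(as.numeric(offsets_row), nrow = 1)
  rownames(Y) <- rownames(O) <- "gene"
  if (is.null(spec$threshold_T)) {
    stop("gene_posterior: supply an explicit threshold_T in the spec ",
         "(the automatic threshold needs the full count matrix)")
  }
  activity_posteriors(Y, O, design, hyper, spec)
}

#' Activity calls from posterior probabilities
#'
#' A gene is called active in a sample type iff `p_active` strictly exceeds
#' the cutoff (default 0.5); a posterior probability of exactly 0.5 is
#' inactive. Genes flagged as non-converged are reported inactive with
#' `failed = TRUE`.
#'
#' @param post a [activity_posteriors()] result.
#' @param spec an [activity_model_spec()].
#' @return data.frame of class `activity_call` with columns `gene_id`,
#'   `sample_type`, `p_active`, `active`, `failed`.
#' @export
call_activity <- function(post, spec = activity_model_spec()) {
  stopifnot(is.data.frame(post),
            all(c("gene_id", "sample_type", "p_active") %in% names(post)))
  failed <- if ("failed" %in% names(post)) post$failed else FALSE
  out <- data.frame(
    gene_id = post$gene_id, sample_type = post$sample_type,
    p_active = post$p_active,
    active = post$p_active > spec$call_cutoff & !failed,
    failed = failed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("activity_call", "data.frame")
  out
}

#' Two-way activity Venn partition
#'
#' Set algebra on the activity calls of two sample types over a common gene
#' universe: counts of genes exclusively active in each type, active in both,
#' and the union total.
#'
#' @param calls an [call_activity()] result covering exactly two sample
#'   types, or a list of two named logical vectors over the same genes.
#' @param types optional length-2 character giving which two sample types to
#'   contrast (defaults to the first two present).
#' @return list of class `venn_partition`: `exclusive_a`, `exclusive_b`,
#'   `shared`, `union_total`, plus the type labels.
#' @export
venn_partition <- function(calls, types = NULL) {
  if (is.data.frame(calls)) {
    tt <- unique(calls$sample_type)
    if (is.null(types)) types <- tt[1:2]
    if (length(types) != 2 || !all(types %in% tt)) {
      stop("venn_partition: need two sample types present in calls")
    }
    a <- calls[calls$sample_type == types[1], ]
    b <- calls[calls$sample_type == types[2], ]
    if (!setequal(a$gene_id, b$gene_id) || nrow(a) != nrow(b)) {
      stop("venn_partition: mismatched gene universes between sample types")
    }
    b <- b[match(a$gene_id, b$gene_id), ]
    va <- a$active; vb <- b$active
  } else if (is.list(calls) && length(calls) == 2) {
    va <- calls[[1]]; vb <- calls[[2]]
    if (length(va) != length(vb)) {
      stop("venn_partition: mismatched gene universes")
    }
    if (!is.null(names(va)) && !is.null(names(vb))) {
      if (!setequal(names(va), names(vb))) {
        stop("venn_partition: mismatched gene universes")
      }
      vb <- vb[names(va)]
    }
    types <- if (is.null(types)) c("A", "B") else types
  } else {
    stop("venn_partition: unsupported input")
  }
  out <- list(exclusive_a = sum(va & !vb),
              exclusive_b = sum(!va & vb),
              shared = sum(va & vb),
              union_total = sum(va | vb),
              types = types)
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  pct <- function(k) if (x$union_total > 0) {
    sprintf(" (%d%%)", round(100 * k / x$union_total))
  } else ""
  cat("active gene partition (", x$types[1], " vs ", x$types[2], ")\n",
      sep = "")
  cat("  only ", x$types[1], ": ", x$exclusive_a, pct(x$exclusive_a), "\n",
      sep = "")
  cat("  only ", x$types[2], ": ", x$exclusive_b, pct(x$exclusive_b), "\n",
      sep = "")
  cat("  both: ", x$shared, pct(x$shared), "\n", sep = "")
  cat("  union total: ", x$union_total, "\n", sep = "")
  invisible(x)
}
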