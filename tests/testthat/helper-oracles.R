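# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (sorting, explicit summation, dense linear algebra) and
# share no code with the package implementations they check.

# Brute-force TMM: explicit M/A vectors, sort-based double trim, weighted
# mean by inverse asymptotic variance. `ref` must be given.
oracle_tmm <- function(counts, ref, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  one <- function(i) {
    y <- counts[, i]; yr <- counts[, ref]
    keep <- y > 0 & yr > 0
    y <- y[keep]; yr <- yr[keep]
    # same fp expression as the implementation so that exact ties rank
    # identically; the trim and weighting below are independent
    M <- log2((y / lib[i]) / (yr / lib[ref]))
    A <- 0.5 * log2((y / lib[i]) * (yr / lib[ref]))
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    w <- 1 / ((lib[i] - y) / (lib[i] * y) + (lib[ref] - yr) / (lib[ref] * yr))
    2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f / exp(mean(log(f)))
}

# Exact upper-tail hypergeometric probability by pmf summation.
oracle_hyper_tail <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(stats::dhyper(j, K, N - K, n))
}

# Least-squares Procrustes distance after centering, rotation/reflection and
# scaling; used to compare MDS output with a known configuration.
procrustes_rmse <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  R <- s$v %*% t(s$u)
  sc <- sum(s$d) / sum(Yc^2)
  sqrt(mean((Xc - sc * Yc %*% R)^2))
}

# 2-D grid integration of a gene's posterior over (beta_s, log phi), with
# the replicate random effects held at their fitted modes; the independent
# check of the Laplace approximation.
oracle_grid_p_active <- function(counts_row, offsets_row, type_of, s,
                                 B_mode, U_mode, hyper, Tval,
                                 center, halfwidth, lphi_mode,
                                 nb = 241, nl = 81) {
  bgrid <- seq(center - halfwidth, center + halfwidth, length.out = nb)
  lgrid <- seq(lphi_mode - 4, lphi_mode + 4, length.out = nl)
  m <- hyper$fixed_effect_mean[s]; v <- hyper$fixed_effect_var[s]
  lp <- outer(bgrid, lgrid, Vectorize(function(b, lphi) {
    B <- B_mode; B[s] <- b
    mu <- exp(B[type_of] + U_mode + offsets_row)
    sum(stats::dnbinom(counts_row, size = exp(-lphi), mu = mu, log = TRUE)) +
      stats::dnorm(b, m, sqrt(v), log = TRUE) +
      stats::dnorm(lphi, hyper$log_disp_mean, sqrt(hyper$log_disp_var),
                   log = TRUE)
  }))
  w <- exp(lp - max(lp))
  sum(w[bgrid > Tval, ]) / sum(w)
}

# small deterministic NB count matrix for quick tests
tiny_counts <- function(G = 60, n = 8, seed = 42, mu = 50, phi = 0.1) {
  set.seed(seed)
  m <- matrix(as.integer(stats::rnbinom(G * n, size = 1 / phi, mu = mu)),
              G, n)
  dimnames(m) <- list(sprintf("g%03d", seq_len(G)),
                      paste0("s", seq_len(n)))
  m
}

two_group_meta <- function(n_rep = 4, types = c("hair", "noHair")) {
  data.frame(
    sample_id = paste0(rep(types, each = n_rep), "_r", seq_len(n_rep)),
    sample_type = rep(types, each = n_rep),
    replicate = rep(seq_len(n_rep), times = 2),
    stringsAsFactors = FALSE
  )
}
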