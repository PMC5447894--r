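make_calls <- function(gene_ids, active_a, active_b) {
  data.frame(
    gene_id = rep(gene_ids, 2),
    sample_type = rep(c("a", "b"), each = length(gene_ids)),
    p_active = 1, active = c(active_a, active_b), failed = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("expression filter applies the strict median rule", {
  lcpm <- matrix(c(rep(3.71, 4), rep(3.72, 4), rep(10, 4)), 3, 4,
                 byrow = TRUE, dimnames = list(c("g1", "g2", "g3"), NULL))
  calls <- make_calls(c("g1", "g2", "g3"), c(TRUE, TRUE, FALSE),
                      c(FALSE, FALSE, FALSE))
  keep <- filter_expressed(lcpm, calls, de_filter_spec())
  expect_identical(keep, "g2")   # g1 at exactly 3.71 excluded, g3 inactive

  calls0 <- make_calls(c("g1", "g2", "g3"), rep(FALSE, 3), rep(FALSE, 3))
  expect_identical(filter_expressed(lcpm, calls0), character(0))

  expect_error(filter_expressed(lcpm[1:2, ], calls), "universes")
})

test_that("voom weights are flat for homoskedastic data, positive always", {
  set.seed(4)
  G <- 400; n <- 8
  base <- runif(G, 3, 9)
  m <- matrix(as.integer(round(exp(base + rnorm(G * n, 0, 0.1)))), G, n)
  dimnames(m) <- list(sprintf("g%03d", 1:G), paste0("s", 1:n))
  meta <- two_group_meta()
  vm <- voom_transform(m, NULL, meta)
  expect_true(all(is.finite(vm$weights) & vm$weights > 0))
  expect_lt(sd(vm$weights) / mean(vm$weights), 0.2)
})

test_that("voom traces a decreasing mean-variance trend on NB counts", {
  sim <- simulate_counts(sim_config(n_genes = 1200, frac_de = 0,
                                    frac_inactive = 0, disp_meanlog = log(0.3),
                                    disp_sdlog = 0, baseline_mean = 2,
                                    baseline_sd = 2, seed = 44))
  vm <- voom_transform(sim$counts, tmm_factors(sim$counts), sim$meta)
  expect_gt(cor(rowMeans(vm$E), rowMeans(vm$weights), method = "spearman"), 0)
  expect_true(all(vm$weights > 0))
})

test_that("voom validates the design", {
  m <- tiny_counts(40, 4, seed = 6)
  meta <- two_group_meta(n_rep = 2)
  # treatment + block on 4 samples leaves 1 residual df
  expect_error(voom_transform(m, NULL, meta), "residual degrees")
  meta3 <- data.frame(sample_id = paste0("s", 1:4),
                      sample_type = c("a", "a", "b", "c"))
  expect_error(voom_transform(m, NULL, meta3), "two sample types")
})

test_that("unweighted two-group fit equals the difference of group means", {
  m <- tiny_counts(50, 8, seed = 9)
  meta <- two_group_meta()
  meta$replicate <- NULL
  vm <- voom_transform(m, NULL, meta)
  vm$weights[] <- 1
  fits <- fit_models(vm)
  grp <- meta$sample_type == "hair"
  manual <- rowMeans(vm$E[, grp]) - rowMeans(vm$E[, !grp])
  expect_equal(fits$coef, unname(manual), tolerance = 1e-10)

  # duplicated rows give identical fits
  vm2 <- vm
  vm2$E <- rbind(vm$E, dup = vm$E[3, ])
  vm2$weights <- rbind(vm$weights, vm$weights[3, ])
  f2 <- fit_models(vm2)
  expect_equal(unlist(f2[nrow(f2), -1]), unlist(f2[3, -1]),
               tolerance = 1e-12)
})

test_that("weighted fits match a brute-force normal-equations solver", {
  set.seed(12)
  meta <- two_group_meta()
  for (i in 1:5) {
    G <- 20
    E <- matrix(rnorm(G * 8, 5), G, 8,
                dimnames = list(sprintf("g%02d", 1:G), meta$sample_id))
    W <- matrix(runif(G * 8, 0.2, 5), G, 8)
    X <- stats::model.matrix(
      ~ factor(meta$sample_type, levels = c("noHair", "hair")) +
        factor(meta$replicate))
    vm <- list(E = E, weights = W, design = structure(
      X, coef_name = colnames(X)[2]))
    fits <- fit_models(vm)
    for (g in 1:G) {
      A <- t(X) %*% diag(W[g, ]) %*% X
      beta <- solve(A, t(X) %*% diag(W[g, ]) %*% E[g, ])
      expect_equal(fits$coef[g], as.numeric(beta[2, 1]), tolerance = 1e-9)
      r <- E[g, ] - X %*% beta
      s2 <- sum(W[g, ] * r^2) / (8 - ncol(X))
      expect_equal(fits$sigma2[g], s2, tolerance = 1e-9)
      expect_equal(fits$stdev_unscaled[g], sqrt(solve(A)[2, 2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("moderated t reduces to ordinary t as d0 -> 0 and to full
           shrinkage as d0 -> Inf", {
  set.seed(14)
  fits <- data.frame(
    gene_id = sprintf("g%02d", 1:40),
    coef = rnorm(40), stdev_unscaled = runif(40, 0.2, 1),
    sigma2 = rchisq(40, 5) / 5, df = 5
  )
  r0 <- moderate(fits, d0_override = 0)
  t_ord <- fits$coef / (fits$stdev_unscaled * sqrt(fits$sigma2))
  expect_equal(r0$mod_t, t_ord, tolerance = 1e-9)
  expect_equal(r0$p, 2 * pt(-abs(t_ord), 5), tolerance = 1e-12)

  rI <- moderate(fits, d0_override = Inf)
  expect_equal(rI$s2_post, rep(rI$s2_prior[1], 40))

  # s2_post always between min and max of (s2, s0^2)
  rm <- moderate(fits)
  lo <- pmin(fits$sigma2, rm$s2_prior)
  hi <- pmax(fits$sigma2, rm$s2_prior)
  expect_true(all(rm$s2_post >= lo - 1e-12 & rm$s2_post <= hi + 1e-12))
})

test_that("degenerate identical variances take the flagged d0=Inf branch", {
  fits <- data.frame(
    gene_id = sprintf("g%02d", 1:20), coef = rnorm(20),
    stdev_unscaled = 0.5, sigma2 = 1, df = 4
  )
  r <- moderate(fits)
  expect_true(attr(r, "degenerate"))
  expect_true(all(is.infinite(r$df_prior)))
})

test_that("type-I error is controlled on a simulated null", {
  sim <- simulate_counts(sim_config(n_genes = 2000, frac_de = 0,
                                    frac_inactive = 0, seed = 77))
  vm <- voom_transform(sim$counts, tmm_factors(sim$counts), sim$meta)
  res <- moderate(fit_models(vm))
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")

  set.seed(15)
  for (i in 1:10) {
    p <- runif(100)^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(100)
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-15)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("de_summary applies inclusive FDR and strict LFC bounds", {
  res <- data.frame(
    gene_id = paste0("g", 1:5),
    log2fc = c(2, 1.0, -3, 0.5, -1.5),
    mod_t = 0, p = 0,
    q = c(0.01, 0.01, 0.005, 0.02, 0.01),
    df_residual = 4, df_prior = 2, s2_prior = 1, s2_post = 1
  )
  s <- de_summary(res, de_filter_spec(fdr = 0.01, lfc_cutoff = 1))
  expect_identical(s$n_up, 2L)          # g1 (q=0.01 inclusive), g2
  expect_identical(s$n_down, 2L)        # g3, g5
  expect_identical(s$n_up_lfc, 1L)      # g2 at |lfc|=1 exactly excluded
  expect_identical(s$n_down_lfc, 2L)
  expect_equal(s$avg_fc_up, mean(2^c(2, 1)))
  expect_equal(s$avg_fc_down, mean(2^c(3, 1.5)))

  empty <- res[0, ]
  s0 <- de_summary(empty, de_filter_spec())
  expect_identical(s0$n_up + s0$n_down + s0$n_up_lfc + s0$n_down_lfc, 0L)
  expect_true(is.na(s0$avg_fc_up))
})

test_that("the DE stage is deterministic end to end", {
  sim <- simulate_counts(sim_config(n_genes = 500, seed = 50))
  run <- function() {
    nf <- tmm_factors(sim$counts)
    moderate(fit_models(voom_transform(sim$counts, nf, sim$meta)))
  }
  expect_identical(run(), run())
})

test_that("voom weights and moderated t agree with the limma reference", {
  library(limma)
  sim <- simulate_counts(sim_config(n_genes = 800, frac_de = 0.1,
                                    frac_inactive = 0, seed = 88))
  meta <- sim$meta
  X <- stats::model.matrix(
    ~ factor(meta$sample_type, levels = c("noHair", "hair")) +
      factor(meta$replicate))
  colnames(X) <- c("(Intercept)", "treathair", "block2", "block3", "block4")
  nf <- tmm_factors(sim$counts)

  vm <- voom_transform(sim$counts, nf, meta)
  lv <- limma::voom(sim$counts, design = X,
                    lib.size = nf$library_size * nf$tmm_factor)
  expect_equal(unname(vm$E), unname(lv$E), tolerance = 1e-10)
  # same trend construction; small differences only from lowess details
  expect_gt(cor(as.numeric(vm$weights), as.numeric(lv$weights)), 0.99)

  fits <- fit_models(vm)
  res <- moderate(fits)
  lf <- limma::eBayes(limma::lmFit(lv))
  expect_equal(res$df_prior, rep(lf$df.prior, nrow(res)), tolerance = 0.05)
  expect_equal(res$s2_prior, rep(lf$s2.prior, nrow(res)), tolerance = 0.01)
  expect_gt(cor(res$mod_t, lf$t[, "treathair"]), 0.999)
})
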