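# shared small fixture: one simulated dataset + fitted hyperpriors
sim_fix <- simulate_counts(sim_config(n_genes = 300, seed = 19,
                                      frac_inactive = 0.2, frac_de = 0.1,
                                      baseline_mean = log(60),
                                      baseline_sd = 1.2))
hyper_fix <- fit_hyperpriors(sim_fix$counts, sim_fix$offsets, sim_fix$meta,
                             max_iterations = 25)
T_fix <- auto_threshold(sim_fix$counts, sim_fix$offsets)
spec_fix <- activity_model_spec(threshold_T = T_fix)
post_fix <- activity_posteriors(sim_fix$counts, sim_fix$offsets,
                                sim_fix$meta, hyper_fix, spec_fix)

test_that("hyperprior estimation is exchangeable and validates input", {
  p <- sample(nrow(sim_fix$counts))
  hp <- fit_hyperpriors(sim_fix$counts[p, ], sim_fix$offsets[p, ],
                        sim_fix$meta, max_iterations = 25)
  expect_equal(hp$fixed_effect_mean, hyper_fix$fixed_effect_mean,
               tolerance = 1e-9)
  expect_equal(hp$fixed_effect_var, hyper_fix$fixed_effect_var,
               tolerance = 1e-9)
  expect_equal(hp$log_disp_mean, hyper_fix$log_disp_mean, tolerance = 1e-9)
  expect_gt(hyper_fix$log_disp_var, 0)

  meta_bad <- sim_fix$meta
  meta_bad$sample_type[2:8] <- "noHair"
  expect_error(fit_hyperpriors(sim_fix$counts, sim_fix$offsets, meta_bad),
               "2 replicates")
  cbad <- sim_fix$counts; cbad[1, 1] <- 1.5
  expect_error(fit_hyperpriors(cbad, sim_fix$offsets, sim_fix$meta),
               "integers")
})

test_that("hyperprior fixed-effect means are recovered on simulated data", {
  sim <- simulate_counts(sim_config(n_genes = 1500, frac_de = 0,
                                    frac_inactive = 0, baseline_mean = 2,
                                    baseline_sd = 1.5, seed = 101))
  hy <- fit_hyperpriors(sim$counts, sim$offsets, sim$meta)
  expect_lt(max(abs(hy$fixed_effect_mean - 2)), 0.2)
})

test_that("single-gene posterior behaves at the zero and large-count limits", {
  # all-zero counts in one sample type, T above the prior mean
  Tval <- max(hyper_fix$fixed_effect_mean) + 1
  sp <- activity_model_spec(threshold_T = Tval)
  o_row <- sim_fix$offsets[1, ]
  zero_gene <- rep(0L, 8)
  gp <- gene_posterior(zero_gene, o_row, sim_fix$meta, hyper_fix, sp)
  expect_true(all(gp$p_active < 0.5))

  # counts around exp(T + 3) on the offset scale: large-signal limit
  big_gene <- as.integer(round(exp(Tval + 3 + o_row)))
  gp2 <- gene_posterior(big_gene, o_row, sim_fix$meta, hyper_fix, sp)
  expect_true(all(gp2$p_active > 0.99))
})

test_that("posterior means shrink from the MLE toward the prior mean", {
  types <- unique(sim_fix$meta$sample_type)
  set.seed(1)
  for (g in sample(nrow(sim_fix$counts), 12)) {
    for (s in 1:2) {
      cols <- sim_fix$meta$sample_type == types[s]
      mle <- log((sum(sim_fix$counts[g, cols]) + 0.5) /
                   sum(exp(sim_fix$offsets[g, cols])))
      pm <- post_fix$post_mean[
        post_fix$gene_id == rownames(sim_fix$counts)[g] &
          post_fix$sample_type == types[s]]
      prior_m <- hyper_fix$fixed_effect_mean[s]
      lo <- min(mle, prior_m) - 0.15
      hi <- max(mle, prior_m) + 0.15
      expect_gt(pm, lo)
      expect_lt(pm, hi)
    }
  }
})

test_that("activity call rule is strict at the cutoff", {
  post <- data.frame(
    gene_id = c("a", "b", "c", "d"), sample_type = "t",
    p_active = c(0.5, 0.51, 0.4999, 1), failed = FALSE,
    stringsAsFactors = FALSE
  )
  calls <- call_activity(post, activity_model_spec())
  expect_identical(calls$active, c(FALSE, TRUE, FALSE, TRUE))

  set.seed(2)
  p <- runif(200)
  post2 <- data.frame(gene_id = as.character(1:200), sample_type = "t",
                      p_active = p, failed = FALSE)
  expect_identical(call_activity(post2)$active, p > 0.5)
})

test_that("adding counts never decreases p_active; p_active decreases in T", {
  set.seed(8)
  genes <- sample(nrow(sim_fix$counts), 25)
  counts2 <- sim_fix$counts
  cols <- sim_fix$meta$sample_type == "hair"
  counts2[genes, cols] <- counts2[genes, cols] + 5L
  post2 <- activity_posteriors(counts2, sim_fix$offsets, sim_fix$meta,
                               hyper_fix, spec_fix)
  sel <- post_fix$sample_type == "hair" &
    post_fix$gene_id %in% rownames(sim_fix$counts)[genes]
  expect_true(all(post2$p_active[sel] >= post_fix$p_active[sel] - 1e-8))

  spec_hi <- activity_model_spec(threshold_T = T_fix + 0.5)
  post_hi <- activity_posteriors(sim_fix$counts, sim_fix$offsets,
                                 sim_fix$meta, hyper_fix, spec_hi)
  expect_true(all(post_hi$p_active <= post_fix$p_active + 1e-10))
})

test_that("venn partition does set algebra and validates universes", {
  va <- setNames(c(TRUE, TRUE, FALSE, FALSE), paste0("g", 1:4))
  vb <- setNames(c(TRUE, FALSE, TRUE, FALSE), paste0("g", 1:4))
  v <- venn_partition(list(va, vb))
  expect_identical(unlist(v[1:4], use.names = FALSE), c(1L, 1L, 1L, 3L))

  v0 <- venn_partition(list(rep(FALSE, 5), rep(FALSE, 5)))
  expect_identical(unlist(v0[1:4], use.names = FALSE), c(0L, 0L, 0L, 0L))

  set.seed(3)
  for (i in 1:10) {
    a <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    v <- venn_partition(list(a, b))
    expect_identical(v$exclusive_a, sum(a & !b))
    expect_identical(v$exclusive_b, sum(b & !a))
    expect_identical(v$shared, sum(a & b))
    expect_identical(v$union_total, sum(a | b))
  }
  expect_error(venn_partition(list(a, b[-1])), "mismatched")
})

test_that("calls integrate with venn partition over the fixture", {
  calls <- call_activity(post_fix, spec_fix)
  v <- venn_partition(calls)
  expect_identical(v$exclusive_a + v$exclusive_b + v$shared, v$union_total)
  expect_lte(v$union_total, nrow(sim_fix$counts))
})
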