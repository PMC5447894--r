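#' End-to-end analysis: normalize, call activity, test, enrich, report
#'
#' Runs the full pipeline on a count matrix: TMM factors and length/GC
#' offsets, hierarchical-NB activity calling, the activity + median
#' inclusion filter, precision-weighted moderated differential expression
#' with BH control, optional enrichment of the significant genes against the
#' expressed background, and the QC views.
#'
#' @param counts gene x sample integer count matrix.
#' @param features data.frame `gene_id`, `length`, `gc`.
#' @param meta data.frame `sample_id`, `sample_type`, optional `replicate`.
#' @param annotation optional term/gene annotation data.frame for enrichment.
#' @param activity_spec an [activity_model_spec()].
#' @param de_spec a [de_filter_spec()].
#' @param n_top_genes genes used for the sample-distance views.
#' @return list of class `trichoseq_result` with elements `norm`,
#'   `gene_offsets`, `offsets`, `lcpm`, `hyper`, `posteriors`, `calls`,
#'   `venn`, `expressed`, `voom`, `fits`, `results`, `summary`,
#'   `enrichment` (or NULL), `mds`, `clustering`.
#' @export
run_pipeline <- function(counts, features, meta, annotation = NULL,
                         activity_spec = activity_model_spec(),
                         de_spec = de_filter_spec(),
                         n_top_genes = 500) {
  counts <- as.matrix(counts)
  norm <- tmm_factors(counts)
  gene_off <- length_gc_offsets(counts, features, norm = norm)
  offsets <- build_offsets(counts, norm, gene_off)
  lcpm <- logcpm(counts, norm)

  hyper <- fit_hyperpriors(counts, offsets, meta)
  post <- activity_posteriors(counts, offsets, meta, hyper, activity_spec)
  calls <- call_activity(post, activity_spec)
  venn <- venn_partition(calls)

  expressed <- filter_expressed(lcpm, calls, de_spec)
  results <- NULL; summary <- NULL; vm <- NULL; fits <- NULL
  enr <- NULL
  if (length(expressed) >= 10) {
    vm <- voom_transform(counts[expressed, , drop = FALSE], norm, meta)
    fits <- fit_models(vm)
    results <- moderate(fits)
    summary <- de_summary(results, de_spec)
    if (!is.null(annotation)) {
      fg <- results$gene_id[results$q <= de_spec$fdr]
      if (length(fg) > 0) {
        enr <- sea(fg, background = expressed, annotation = annotation)
      }
    }
  }

  d <- sample_distances(lcpm, min(n_top_genes, nrow(lcpm)))
  mds <- classical_mds(d, k = 2)
  hc <- hierarchical_clustering(d, "average")

  structure(list(
    norm = norm, gene_offsets = gene_off, offsets = offsets, lcpm = lcpm,
    hyper = hyper, posteriors = post, calls = calls, venn = venn,
    expressed = expressed, voom = vm, fits = fits, results = results,
    summary = summary, enrichment = enr,
    distances = d, mds = mds, clustering = hc
  ), class = "trichoseq_result")
}

#' @export
print.trichoseq_result <- function(x, ...) {
  cat("trichoseq pipeline result\n")
  print(x$venn)
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$enrichment)) {
    cat("enriched terms at q <= 0.05:", sum(x$enrichment$q <= 0.05), "\n")
  }
  invisible(x)
}
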