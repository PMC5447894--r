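#' Singular enrichment analysis against an expressed-gene background
#'
#' For each annotation term with at least `min_term_size` genes in the
#' background, builds the 2x2 membership table of a foreground gene list
#' against the background, computes the one-sided hypergeometric upper-tail
#' p-value for over-representation, an odds ratio (with a 0.5 continuity
#' correction when any cell is zero), and Benjamini-Hochberg q-values across
#' the tested terms. Terms with no background genes after intersection are
#' dropped. The annotation is taken as flat term-to-gene sets; no ontology
#' graph propagation is performed.
#'
#' @param foreground character vector of genes of interest (non-empty,
#'   subset of `background`).
#' @param background character vector: the expressed-gene reference set.
#' @param annotation data.frame with columns `term_id`, `gene_id` (a third
#'   column, if present, is carried through as the term name).
#' @param min_term_size smallest background term size tested.
#' @return data.frame of class `enrichment_result`, one row per tested term:
#'   `term_id`, `k` (foreground hits), `n` (foreground size), `K`
#'   (background hits), `N` (background size), `odds_ratio`, `p`, `q`,
#'   sorted by p.
#' @export
sea <- function(foreground, background, annotation, min_term_size = 5) {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (length(foreground) == 0) stop("sea: empty foreground")
  if (length(background) == 0) stop("sea: empty background")
  stray <- setdiff(foreground, background)
  if (length(stray)) {
    stop("sea: foreground genes missing from background: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) " ..." else "")
  }
  if (!all(c("term_id", "gene_id") %in% names(annotation))) {
    stop("sea: annotation needs columns term_id and gene_id")
  }
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  if (nrow(ann) == 0) {
    out <- data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  sets <- split(ann$gene_id, ann$term_id)
  sets <- lapply(sets, unique)
  Kv <- lengths(sets)
  sets <- sets[Kv >= min_term_size]
  if (length(sets) == 0) {
    out <- data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  N <- length(background)
  n <- length(foreground)
  k <- vapply(sets, function(g) sum(g %in% foreground), integer(1))
  K <- lengths(sets)
  p <- hyper_enrich_p(k, K, N, n)
  a <- k; b <- K - k; cc <- n - k; dd <- N - K - n + k
  corr <- (a == 0 | b == 0 | cc == 0 | dd == 0) * 0.5
  odds <- ((a + corr) * (dd + corr)) / ((b + corr) * (cc + corr))
  out <- data.frame(term_id = names(sets), k = as.integer(k),
                    n = n, K = as.integer(K), N = N,
                    odds_ratio = odds, p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE)
  if (ncol(annotation) >= 3) {
    nm_col <- names(annotation)[3]
    nms <- tapply(as.character(annotation[[nm_col]]), annotation$term_id,
                  function(x) x[1])
    out$term_name <- as.character(nms[out$term_id])
  }
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of at least `k` annotated genes in a foreground of size `n`
#' drawn from a background of size `N` containing `K` annotated genes. This
#' is the p-value kernel used by [sea()]; vectorized over all arguments.
#'
#' @param k foreground hits.
#' @param K background hits.
#' @param N background size.
#' @param n foreground size.
#' @return numeric vector of p-values.
#' @export
hyper_enrich_p <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
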