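#' Configuration for the synthetic count generator
#'
#' Builds a validated configuration object describing a two-condition RNA-seq
#' experiment: a single-cell-type sample (e.g. root hairs) against a
#' multi-cell-type reference (roots with hairs removed), with a configurable
#' number of biological replicates per sample type.
#'
#' Counts are negative-binomial with a per-gene dispersion drawn from a
#' log-normal law, per-sample replicate random effects on the log scale, a
#' log-linear capture bias in gene length and GC content, and per-sample
#' library sizes. A configurable fraction of genes is transcriptionally
#' inactive in exactly one sample type (simulated with a small positive leak
#' mean rather than structural zeros), and a fraction of the fully active
#' genes carries a true log2 fold change of fixed magnitude and random sign.
#'
#' @param n_genes number of genes.
#' @param sample_types character vector of sample-type labels (>= 2).
#' @param n_replicates biological replicates per sample type (>= 2).
#' @param frac_inactive fraction of genes inactive in exactly one sample type,
#'   in `[0, 1)`.
#' @param frac_de fraction of fully active genes that are truly differentially
#'   expressed between the first two sample types, in `[0, 1)`.
#' @param lfc_magnitude absolute log2 fold change of DE genes.
#' @param disp_meanlog,disp_sdlog mean and SD of `log(phi)` for the per-gene
#'   NB dispersion `phi` (variance = mu + phi * mu^2).
#' @param replicate_sd SD of the per-sample replicate random effect (natural
#'   log scale).
#' @param lib_size_range length-2 numeric, expected library size bounds.
#' @param length_range length-2 integer, gene length bounds in bp (sampled
#'   log-uniformly).
#' @param gc_range length-2 numeric in `[0, 1]`, GC-fraction bounds (uniform).
#' @param bias_strength length-2 numeric: coefficients coupling the log mean
#'   to the z-scores of log length and of GC fraction.
#' @param baseline_mean,baseline_sd normal law for the active-gene baseline
#'   log mean (natural log of expected counts at the reference library scale).
#' @param baseline_min lower truncation for the active baseline log mean
#'   (default none); use e.g. `log(50)` for a well-separated simulation.
#' @param leak_mean expected count (reference library scale) of a gene in a
#'   sample type where it is inactive.
#' @param seed integer seed; identical configurations give bit-identical
#'   output, and enlarging `n_genes` leaves earlier genes' draws unchanged.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_counts()]
#' @export
sim_config <- function(n_genes = 5000,
                       sample_types = c("hair", "noHair"),
                       n_replicates = 4,
                       frac_inactive = 0.1,
                       frac_de = 0.1,
                       lfc_magnitude = 2,
                       disp_meanlog = log(0.1),
                       disp_sdlog = 0.4,
                       replicate_sd = 0.1,
                       lib_size_range = c(8e5, 1.2e6),
                       length_range = c(300L, 8000L),
                       gc_range = c(0.3, 0.7),
                       bias_strength = c(0.4, 0.25),
                       baseline_mean = 4,
                       baseline_sd = 1.5,
                       baseline_min = -Inf,
                       leak_mean = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), sample_types = as.character(sample_types),
    n_replicates = as.integer(n_replicates),
    frac_inactive = frac_inactive, frac_de = frac_de,
    lfc_magnitude = lfc_magnitude,
    disp_meanlog = disp_meanlog, disp_sdlog = disp_sdlog,
    replicate_sd = replicate_sd,
    lib_size_range = as.numeric(lib_size_range),
    length_range = as.numeric(length_range), gc_range = as.numeric(gc_range),
    bias_strength = as.numeric(bias_strength),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    baseline_min = baseline_min, leak_mean = leak_mean,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  num_fields <- c("frac_inactive", "frac_de", "lfc_magnitude", "disp_meanlog",
                  "disp_sdlog", "replicate_sd", "baseline_mean", "baseline_sd",
                  "leak_mean")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]]) ||
        !is.finite(cfg[[f]])) {
      stop("sim_config: field '", f, "' must be a finite number")
    }
  }
  if (cfg$n_genes < 1) stop("sim_config: n_genes must be positive")
  if (length(cfg$sample_types) < 2) {
    stop("sim_config: need at least two sample types")
  }
  if (anyDuplicated(cfg$sample_types)) {
    stop("sim_config: sample_types must be unique")
  }
  if (cfg$n_replicates < 2) {
    stop("sim_config: n_replicates must be >= 2 ",
         "(replicate random effects are inestimable otherwise)")
  }
  if (cfg$frac_inactive < 0 || cfg$frac_inactive >= 1) {
    stop("sim_config: frac_inactive must lie in [0, 1)")
  }
  if (cfg$frac_de < 0 || cfg$frac_de >= 1) {
    stop("sim_config: frac_de must lie in [0, 1)")
  }
  if (cfg$replicate_sd < 0 || cfg$disp_sdlog < 0 || cfg$baseline_sd < 0) {
    stop("sim_config: SD parameters must be non-negative")
  }
  rng <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0) {
      stop("sim_config: ", what, " must be positive [min, max] with min <= max")
    }
  }
  rng(cfg$lib_size_range, "lib_size_range")
  rng(cfg$length_range, "length_range")
  if (length(cfg$gc_range) != 2 || cfg$gc_range[1] < 0 ||
      cfg$gc_range[2] > 1 || cfg$gc_range[1] > cfg$gc_range[2]) {
    stop("sim_config: gc_range must be [min, max] within [0, 1]")
  }
  if (length(cfg$bias_strength) != 2 || any(!is.finite(cfg$bias_strength))) {
    stop("sim_config: bias_strength must be two finite coefficients")
  }
  if (cfg$leak_mean <= 0) stop("sim_config: leak_mean must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      length(x$sample_types), "sample types x", x$n_replicates,
      "replicates\n")
  cat("  frac_inactive =", x$frac_inactive, " frac_de =", x$frac_de,
      " |log2FC| =", x$lfc_magnitude, "\n")
  cat("  dispersion: lognormal(", signif(x$disp_meanlog, 3), ",",
      signif(x$disp_sdlog, 3), ")  replicate_sd =", x$replicate_sd, "\n")
  invisible(x)
}

# Per-gene substream seed: a fixed integer hash of (seed, gene, phase) so that
# adding genes never reshuffles draws for existing genes.
gene_seed <- function(seed, gene, phase = 0) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(gene) * 7919 +
                as.numeric(phase) * 104729) %% 2147483647)
}

#' Simulate a gene-by-sample count matrix with known ground truth
#'
#' Draws a negative-binomial count matrix matching the generative model the
#' downstream activity and differential-expression stages assume: for gene g
#' in sample i of type s,
#' `log mu_gi = beta_gs + u_gi + o_gi`, where `beta_gs` is the sample-type
#' fixed effect, `u_gi` a replicate random effect (SD `replicate_sd`), and
#' `o_gi` the true offset: the length/GC capture bias plus the log ratio of
#' the sample's library size to its composition total. Per-sample relative
#' abundances are normalized so that the expected column sum equals the
#' configured library size exactly.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_data` with elements
#'   `counts` (integer gene x sample matrix), `features` (data.frame:
#'   gene_id, length, gc), `meta` (data.frame: sample_id, sample_type,
#'   replicate), `truth` (data.frame: gene_id, one `active_<type>` column per
#'   sample type, is_de, true_log2fc, dispersion, baseline_log_mean),
#'   `offsets` (true log-scale offset matrix, gene x sample), and
#'   `mu` (expected count matrix).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  cfg <- config
  G <- cfg$n_genes
  S <- length(cfg$sample_types)
  R <- cfg$n_replicates
  n <- S * R

  meta <- data.frame(
    sample_id = paste0(rep(cfg$sample_types, each = R), "_r", seq_len(R)),
    sample_type = rep(cfg$sample_types, each = R),
    replicate = rep(seq_len(R), times = S),
    stringsAsFactors = FALSE
  )

  # sample-level stream (phase 0, gene 0): library sizes
  set.seed(gene_seed(cfg$seed, 0L, 0L))
  lib <- stats::runif(n, cfg$lib_size_range[1], cfg$lib_size_range[2])

  gene_ids <- sprintf("g%05d", seq_len(G))
  llr <- log(cfg$length_range)

  length_bp <- numeric(G); gc <- numeric(G)
  beta <- matrix(0, G, S)           # natural-log fixed effects
  active <- matrix(TRUE, G, S)
  is_de <- logical(G)
  lfc <- numeric(G)                 # log2
  phi <- numeric(G)
  base <- numeric(G)
  u <- matrix(0, G, n)              # replicate random effects

  ln2 <- log(2)
  for (g in seq_len(G)) {
    set.seed(gene_seed(cfg$seed, g, 1L))
    length_bp[g] <- round(exp(stats::runif(1, llr[1], llr[2])))
    gc[g] <- stats::runif(1, cfg$gc_range[1], cfg$gc_range[2])
    b <- cfg$baseline_mean + cfg$baseline_sd * stats::rnorm(1)
    base[g] <- max(b, cfg$baseline_min)
    phi[g] <- exp(cfg$disp_meanlog + cfg$disp_sdlog * stats::rnorm(1))
    r_class <- stats::runif(1)
    r_which <- stats::runif(1)
    r_de <- stats::runif(1)
    r_sign <- stats::runif(1)
    u[g, ] <- cfg$replicate_sd * stats::rnorm(n)

    beta[g, ] <- base[g]
    if (r_class < cfg$frac_inactive) {
      s_off <- 1L + as.integer(floor(r_which * S))
      s_off <- min(s_off, S)
      active[g, s_off] <- FALSE
      beta[g, s_off] <- log(cfg$leak_mean)
    } else if (r_de < cfg$frac_de) {
      is_de[g] <- TRUE
      lfc[g] <- cfg$lfc_magnitude * if (r_sign < 0.5) 1 else -1
      # symmetric split of the effect between the first two sample types
      beta[g, 1] <- base[g] + lfc[g] * ln2 / 2
      beta[g, 2] <- base[g] - lfc[g] * ln2 / 2
    }
  }

  # capture bias: log-linear in theoretical z-scores of log length and GC,
  # so standardization does not depend on which genes were drawn
  zlen <- (log(length_bp) - mean(llr)) / (diff(llr) / sqrt(12))
  zgc_den <- diff(cfg$gc_range) / sqrt(12)
  zgc <- if (zgc_den > 0) (gc - mean(cfg$gc_range)) / zgc_den else rep(0, G)
  bias <- cfg$bias_strength[1] * zlen + cfg$bias_strength[2] * zgc

  type_of <- match(meta$sample_type, cfg$sample_types)
  w <- exp(beta[, type_of, drop = FALSE] + u + bias)   # relative abundances
  Stot <- colSums(w)
  # true offsets map beta + u to log mu; gene part is the bias, sample part
  # scales composition to the configured library size
  offs <- matrix(rep(log(lib / Stot), each = G), G, n) + bias
  mu <- w * rep(lib / Stot, each = G)

  counts <- matrix(0L, G, n)
  for (g in seq_len(G)) {
    set.seed(gene_seed(cfg$seed, g, 2L))
    counts[g, ] <- as.integer(stats::rnbinom(n, size = 1 / phi[g],
                                             mu = mu[g, ]))
  }

  dimnames(counts) <- list(gene_ids, meta$sample_id)
  dimnames(offs) <- dimnames(mu) <- dimnames(counts)
  dimnames(u) <- dimnames(counts)

  truth <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (s in seq_len(S)) {
    truth[[paste0("active_", cfg$sample_types[s])]] <- active[, s]
  }
  truth$is_de <- is_de
  truth$true_log2fc <- lfc
  truth$dispersion <- phi
  truth$baseline_log_mean <- base

  out <- list(
    counts = counts,
    features = data.frame(gene_id = gene_ids, length = length_bp, gc = gc,
                          stringsAsFactors = FALSE),
    meta = meta,
    truth = truth,
    offsets = offs,
    mu = mu,
    ranef = u,
    lib_sizes = stats::setNames(lib, meta$sample_id),
    config = cfg
  )
  class(out) <- "sim_data"
  out
}

#' @export
print.sim_data <- function(x, ...) {
  cat("sim_data:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      paste(unique(x$meta$sample_type), collapse = " vs "), ")\n")
  cat("  truly DE:", sum(x$truth$is_de),
      " inactive somewhere:", sum(!apply(
        as.matrix(x$truth[grep("^active_", names(x$truth))]), 1, all)), "\n")
  invisible(x)
}

#' Simulate a flat term-to-gene annotation
#'
#' Produces a two-column term/gene annotation for exercising the enrichment
#' stage. Designated enriched terms are built from a supplied gene subset
#' (typically a true DE set) padded with a small number of random background
#' genes; remaining terms are random draws from `gene_ids`.
#'
#' @param n_terms number of terms (0 gives an empty annotation).
#' @param gene_ids character vector of gene identifiers (non-empty).
#' @param enriched_terms named list mapping term ids to gene-id subsets of
#'   `gene_ids`.
#' @param seed integer seed.
#' @param term_size_range size range for the random (non-enriched) terms.
#' @return data.frame with columns `term_id`, `gene_id`.
#' @export
simulate_go_annotation <- function(n_terms, gene_ids,
                                   enriched_terms = list(),
                                   seed = 1L,
                                   term_size_range = c(5L, 50L)) {
  if (length(gene_ids) == 0) stop("simulate_go_annotation: empty gene_ids")
  n_terms <- as.integer(n_terms)
  if (n_terms < 0) stop("simulate_go_annotation: n_terms must be >= 0")
  for (nm in names(enriched_terms)) {
    extra <- setdiff(enriched_terms[[nm]], gene_ids)
    if (length(extra)) {
      stop("simulate_go_annotation: enriched term '", nm,
           "' contains genes outside gene_ids: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
    if (length(enriched_terms[[nm]]) == 0) {
      stop("simulate_go_annotation: enriched term '", nm, "' is empty")
    }
  }
  set.seed(as.integer(seed))
  pieces <- list()
  n_enr <- length(enriched_terms)
  if (n_enr > 0) {
    for (i in seq_len(n_enr)) {
      core <- unique(enriched_terms[[i]])
      pad <- max(1L, ceiling(0.2 * length(core)))
      pool <- setdiff(gene_ids, core)
      padding <- if (length(pool)) {
        sample(pool, min(pad, length(pool)))
      } else character()
      pieces[[names(enriched_terms)[i]]] <- c(core, padding)
    }
  }
  n_rand <- max(0L, n_terms - n_enr)
  if (n_rand > 0) {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_rand,
                    replace = TRUE)
    sizes <- pmin(sizes, length(gene_ids))
    for (i in seq_len(n_rand)) {
      pieces[[sprintf("TERM:%04d", i)]] <- sample(gene_ids, sizes[i])
    }
  }
  if (length(pieces) == 0) {
    return(data.frame(term_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    term_id = rep(names(pieces), lengths(pieces)),
    gene_id = unlist(pieces, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
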