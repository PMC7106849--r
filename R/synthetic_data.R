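#' Simulation configuration
#'
#' Parameters of the multi-platform expression simulator. Defaults emulate
#' the structure of a targeted cancer-isoform nCounter panel: 155
#' multi-isoform genes in a 79:37:18:21 mix of 2/3/4/5-isoform categories
#' (the ">4 isoforms" category is represented by 5-isoform genes), 10
#' single-isoform housekeeping genes, 14 spike-in probes, six tissue types,
#' 46 samples, and two technical replicates per sample.
#'
#' @param n_genes Number of multi-isoform panel genes.
#' @param category_weights Weights of the 2-, 3-, 4- and 5-isoform gene
#'   categories (need not sum to 1).
#' @param allocation `"proportional"` (deterministic largest-remainder
#'   allocation of genes to categories) or `"multinomial"` (sampled).
#' @param n_samples Number of biological samples (cell lines).
#' @param n_replicates Technical replicates measured per sample.
#' @param tissues Tissue type names, assigned to samples round-robin.
#' @param meanlog,sdlog Log-normal location/scale of per-isoform baseline
#'   expression (natural-log scale; defaults give median ~150 counts with a
#'   wide dynamic range).
#' @param bio_sd Per-sample, per-isoform biological variation (sd of a
#'   log-normal factor).
#' @param de_fraction Fraction of panel genes carrying a tissue-specific
#'   expression shift.
#' @param de_effect Multiplicative effect size of the shift.
#' @param noise_sd Multiplicative measurement noise sd (log scale) shared by
#'   the replicates of a sample.
#' @param replicate_sd Additional per-replicate multiplicative noise sd.
#' @param background Additive background floor on probe counts.
#' @param hk_level Housekeeping gene expression level (constant across
#'   samples up to measurement noise).
#' @param spike_level Spike-in probe expected count.
#' @param depth Sequencing depth of the count-like platform view.
#' @param ambiguity Within-gene read-ambiguity mixing rate of the count-like
#'   view (fraction of each gene's reads assigned uniformly among its
#'   isoforms instead of to their transcript of origin).
#' @param array_floor Additive background floor of the array-like view
#'   (cross-hybridization signal that compresses the low-expression range).
#' @param array_sd,count_sd Extra multiplicative noise of the array-like /
#'   count-like views.
#' @param ct_offset,ct_sd Intercept and noise sd of simulated qPCR Ct values
#'   (Ct = ct_offset - log2(expression) + noise).
#' @param seed Random seed; a fixed seed makes every simulator output
#'   reproducible.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 155,
                              category_weights = c(79, 37, 18, 21),
                              allocation = c("proportional", "multinomial"),
                              n_samples = 46,
                              n_replicates = 2,
                              tissues = c("ovary", "lung", "colon", "breast",
                                          "pancreas", "prostate"),
                              meanlog = 5, sdlog = 1.5,
                              bio_sd = 0.5,
                              de_fraction = 0.2, de_effect = 4,
                              noise_sd = 0.2, replicate_sd = 0.1,
                              background = 0,
                              hk_level = 500, spike_level = 100,
                              depth = 2e5, ambiguity = 0.2,
                              array_floor = 50, array_sd = 0.2,
                              count_sd = 0.1,
                              ct_offset = 30, ct_sd = 0.2,
                              seed = 1L) {
  allocation <- match.arg(allocation)
  stopifnot(n_genes >= 1, length(category_weights) == 4,
            all(category_weights >= 0), sum(category_weights) > 0,
            n_samples >= 1, n_replicates >= 1,
            noise_sd >= 0, replicate_sd >= 0, bio_sd >= 0, background >= 0,
            ambiguity >= 0, ambiguity <= 1)
  cfg <- list(n_genes = n_genes, category_weights = category_weights,
              allocation = allocation, n_samples = n_samples,
              n_replicates = n_replicates, tissues = tissues,
              meanlog = meanlog, sdlog = sdlog, bio_sd = bio_sd,
              de_fraction = de_fraction, de_effect = de_effect,
              noise_sd = noise_sd, replicate_sd = replicate_sd,
              background = background, hk_level = hk_level,
              spike_level = spike_level, depth = depth,
              ambiguity = ambiguity, array_floor = array_floor,
              array_sd = array_sd, count_sd = count_sd,
              ct_offset = ct_offset, ct_sd = ct_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic largest-remainder apportionment of n items to weights.
largest_remainder <- function(n, weights) {
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a probe panel
#'
#' Draws multi-isoform gene models from the configured 2/3/4/5-isoform
#' category mix (deterministically proportional by default, so e.g. 155
#' genes with the default weights yield exactly 79/37/18/21 genes per
#' category), designs a max-probe set for each via
#' [design_max_probe_panel()], and appends the 10 housekeeping
#' single-isoform genes (one probe each) and 14 spike-in control probes.
#'
#' @param cfg A [simulation_config()].
#' @return A [probe_panel()]. The multi-isoform genes are named `G001`,
#'   `G002`, ... with isoforms `G001.1`, `G001.2`, ...
#' @export
simulate_panel <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- 2:5
  if (cfg$allocation == "proportional") {
    counts <- largest_remainder(cfg$n_genes, cfg$category_weights)
  } else {
    withr_seed <- cfg$seed
    set.seed(withr_seed)
    counts <- as.vector(stats::rmultinom(1, cfg$n_genes,
                                         cfg$category_weights /
                                           sum(cfg$category_weights)))
  }
  n_iso_per_gene <- rep(sizes, counts)
  genes <- list(); probes <- list()
  for (i in seq_along(n_iso_per_gene)) {
    gid <- sprintf("G%03d", i)
    g <- gene_model(gid, paste0(gid, ".", seq_len(n_iso_per_gene[i])))
    genes[[gid]] <- g
    probes <- c(probes, design_max_probe_panel(g))
  }
  for (hk in housekeeping_genes) {
    g <- gene_model(hk, paste0(hk, ".1"))
    genes[[hk]] <- g
    probes <- c(probes, list(probe(paste0(hk, "_hk"), hk, g$isoform_ids,
                                   "housekeeping")))
  }
  for (k in seq_len(14))
    probes <- c(probes, list(probe(sprintf("SPIKE%02d", k), "SPIKE",
                                   character(), "spike_in")))
  probe_panel(genes, probes)
}

#' Simulate ground-truth expressions and tissue labels
#'
#' Per-isoform baselines are log-normal; each sample multiplies them by an
#' independent log-normal biological factor. Housekeeping genes are held
#' constant across samples (their variation downstream comes only from
#' measurement noise). A configured fraction of multi-isoform genes is
#' differentially expressed: all isoforms of such a gene are shifted by the
#' effect size in one randomly assigned tissue.
#'
#' @param panel A [probe_panel()] from [simulate_panel()].
#' @param cfg A [simulation_config()].
#' @return A `ground_truth` list: `expression` (isoform-level raw
#'   [expr_matrix()], samples `S01`...), `labels` (`sample_id`, `tissue`),
#'   `de_genes` (`gene_id`, `tissue` of the shift), `panel`, `config`.
#' @export
simulate_truth <- function(panel, cfg = simulation_config()) {
  stopifnot(inherits(panel, "probe_panel"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  tissue <- rep(cfg$tissues, length.out = cfg$n_samples)
  labels <- data.frame(sample_id = samples, tissue = tissue)
  iso <- unlist(lapply(panel$genes, `[[`, "isoform_ids"), use.names = FALSE)
  gene_of <- rep(names(panel$genes),
                 vapply(panel$genes, function(g) length(g$isoform_ids),
                        integer(1)))
  is_hk <- gene_of %in% housekeeping_genes
  baseline <- stats::rlnorm(length(iso), cfg$meanlog, cfg$sdlog)
  baseline[is_hk] <- cfg$hk_level
  X <- matrix(baseline, nrow = length(iso), ncol = cfg$n_samples,
              dimnames = list(iso, samples))
  if (cfg$bio_sd > 0) {
    fac <- matrix(stats::rlnorm(length(X), 0, cfg$bio_sd), nrow = nrow(X))
    fac[is_hk, ] <- 1
    X <- X * fac
  }
  panel_genes <- setdiff(names(panel$genes), housekeeping_genes)
  n_de <- round(cfg$de_fraction * length(panel_genes))
  de_genes <- data.frame(gene_id = character(), tissue = character())
  if (n_de > 0) {
    chosen <- sample(panel_genes, n_de)
    de_tissue <- sample(cfg$tissues, n_de, replace = TRUE)
    for (i in seq_len(n_de)) {
      rows <- gene_of == chosen[i]
      cols <- tissue == de_tissue[i]
      X[rows, cols] <- X[rows, cols] * cfg$de_effect
    }
    de_genes <- data.frame(gene_id = chosen, tissue = de_tissue)
  }
  structure(list(expression = expr_matrix(X, "isoform", "raw"),
                 labels = labels, de_genes = de_genes,
                 panel = panel, config = cfg),
            class = "ground_truth")
}

#' Annotation table of a ground truth / panel
#' @param x A `ground_truth` or [probe_panel()].
#' @return Data frame `isoform_id`, `gene_id`.
#' @export
panel_annotation <- function(x) {
  if (inherits(x, "ground_truth")) x <- x$panel
  stopifnot(inherits(x, "probe_panel"))
  data.frame(
    isoform_id = unlist(lapply(x$genes, `[[`, "isoform_ids"),
                        use.names = FALSE),
    gene_id = rep(names(x$genes),
                  vapply(x$genes, function(g) length(g$isoform_ids),
                         integer(1))))
}

#' Simulate raw probe counts from a ground truth
#'
#' The forward model of the probe-capture platform: per gene and sample,
#' expected probe intensities are y = A x_true; each sample draws one shared
#' multiplicative log-normal noise factor per probe (`noise_sd`) and each
#' technical replicate an additional independent factor (`replicate_sd`);
#' an additive background floor is applied last. Housekeeping probes
#' measure their gene's (constant) expression; spike-in probes fluctuate
#' around a fixed expected count.
#'
#' @param truth A `ground_truth` from [simulate_truth()].
#' @param cfg Optional config override (defaults to `truth$config`).
#' @return A raw [probe_counts()] matrix with `n_replicates` columns per
#'   sample, named `<sample>_rep<k>`.
#' @export
simulate_probe_counts <- function(truth, cfg = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(cfg)) cfg <- truth$config
  panel <- truth$panel
  set.seed(cfg$seed + 1L)
  X <- truth$expression$values
  samples <- colnames(X)
  reps <- as.vector(outer(paste0("_rep", seq_len(cfg$n_replicates)),
                          samples, function(r, s) paste0(s, r)))
  probe_ids <- names(panel$probes)
  Y <- matrix(0, nrow = length(probe_ids), ncol = length(reps),
              dimnames = list(probe_ids, reps))
  expected <- matrix(0, nrow = length(probe_ids), ncol = length(samples),
                     dimnames = list(probe_ids, samples))
  for (p in panel$probes) {
    if (p$probe_class == "spike_in") {
      expected[p$probe_id, ] <- cfg$spike_level
    } else {
      expected[p$probe_id, ] <- colSums(X[p$targets, , drop = FALSE])
    }
  }
  sample_noise <- matrix(
    if (cfg$noise_sd > 0) stats::rlnorm(length(expected), 0, cfg$noise_sd)
    else 1, nrow = nrow(expected), ncol = ncol(expected))
  for (r in seq_len(cfg$n_replicates)) {
    rep_noise <- matrix(
      if (cfg$replicate_sd > 0)
        stats::rlnorm(length(expected), 0, cfg$replicate_sd)
      else 1, nrow = nrow(expected), ncol = ncol(expected))
    cols <- paste0(samples, "_rep", r)
    Y[, cols] <- expected * sample_noise * rep_noise + cfg$background
  }
  probe_counts(Y, normalized = FALSE)
}

#' Simulate platform-specific views of the same ground truth
#'
#' Emulates the measurement characteristics of three platform families on
#' one shared truth:
#' \describe{
#'   \item{probe_capture}{the full probe pipeline: [simulate_probe_counts()],
#'     replicate collapse, housekeeping normalization, NNLS deconvolution
#'     ([quantify_panel()]).}
#'   \item{count}{a sequencing-like view: within each gene a fraction
#'     `ambiguity` of the expression mass is reassigned uniformly among the
#'     gene's isoforms (shared-exon read ambiguity), then Poisson counts at
#'     the configured depth are drawn and rescaled to expression units, with
#'     extra multiplicative noise `count_sd`.}
#'   \item{array}{a hybridization-array view: truth plus an additive
#'     cross-hybridization background floor `array_floor` (which compresses
#'     the low-expression range) and multiplicative noise `array_sd`.}
#' }
#'
#' @param truth A `ground_truth`.
#' @param cfg Optional config override.
#' @param views Which views to generate.
#' @return Named list of isoform-level raw [expr_matrix()] objects (the
#'   probe-capture element carries the `quantify_panel()` identifiability
#'   reports in attribute `"identifiability"`).
#' @export
simulate_platform_views <- function(truth, cfg = NULL,
                                    views = c("probe_capture", "count",
                                              "array")) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(cfg)) cfg <- truth$config
  views <- match.arg(views, several.ok = TRUE)
  X <- truth$expression$values
  ann <- panel_annotation(truth)
  gene_of <- ann$gene_id[match(rownames(X), ann$isoform_id)]
  out <- list()
  if ("probe_capture" %in% views) {
    counts <- simulate_probe_counts(truth, cfg)
    norm <- housekeeping_normalize(collapse_replicates(counts), truth$panel)
    q <- quantify_panel(norm, truth$panel)
    M <- q$isoform
    attr(M, "identifiability") <- q$identifiability
    out$probe_capture <- M
  }
  if ("count" %in% views) {
    set.seed(cfg$seed + 2L)
    mixed <- X
    for (g in unique(gene_of)) {
      rows <- which(gene_of == g)
      if (length(rows) > 1) {
        tot <- colSums(X[rows, , drop = FALSE])
        mixed[rows, ] <- (1 - cfg$ambiguity) * X[rows, , drop = FALSE] +
          cfg$ambiguity * matrix(tot / length(rows), nrow = length(rows),
                                 ncol = ncol(X), byrow = TRUE)
      }
    }
    S <- colSums(mixed)
    lambda <- sweep(mixed, 2, cfg$depth / S, `*`)
    cts <- matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda),
                  dimnames = dimnames(X))
    expr <- sweep(cts, 2, S / cfg$depth, `*`)
    if (cfg$count_sd > 0)
      expr <- expr * stats::rlnorm(length(expr), 0, cfg$count_sd)
    out$count <- expr_matrix(expr, "isoform", "raw")
  }
  if ("array" %in% views) {
    set.seed(cfg$seed + 3L)
    sig <- X + cfg$array_floor
    if (cfg$array_sd > 0)
      sig <- sig * stats::rlnorm(length(sig), 0, cfg$array_sd)
    out$array <- expr_matrix(sig, "isoform", "raw")
  }
  out
}

#' Simulate qPCR Ct values for selected genes
#'
#' Ct_j = ct_offset - log2(x_true_j) + N(0, ct_sd): one cycle threshold per
#' isoform per sample, with zero-expression isoforms reported as missing
#' (NA). On noiseless output, [ct_table_to_proportions()] recovers the true
#' isoform proportions exactly, and any per-sample offset (total-RNA
#' normalization) cancels.
#'
#' @param truth A `ground_truth`.
#' @param genes Gene ids to assay (default: the first 4 multi-isoform
#'   genes, mirroring a small qPCR validation panel).
#' @param cfg Optional config override.
#' @return Long data frame `gene_id`, `isoform_id`, `sample_id`, `ct`.
#' @export
simulate_ct <- function(truth, genes = NULL, cfg = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(cfg)) cfg <- truth$config
  ann <- panel_annotation(truth)
  panel_genes <- setdiff(names(truth$panel$genes), housekeeping_genes)
  if (is.null(genes)) genes <- utils::head(panel_genes, 4)
  set.seed(cfg$seed + 4L)
  ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  X <- truth$expression$values[ann$isoform_id, , drop = FALSE]
  rows <- lapply(colnames(X), function(s) {
    x <- X[, s]
    ct <- ifelse(x > 0,
                 cfg$ct_offset - log2(x) +
                   stats::rnorm(length(x), 0, cfg$ct_sd),
                 NA_real_)
    data.frame(gene_id = ann$gene_id, isoform_id = ann$isoform_id,
               sample_id = s, ct = ct, row.names = NULL)
  })
  do.call(rbind, rows)
}
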