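shared_pair <- function(M_a, M_b) {
  feats <- intersect(rownames(M_a$values), rownames(M_b$values))
  samples <- intersect(colnames(M_a$values), colnames(M_b$values))
  if (length(feats) < 3)
    stop("fewer than 3 shared features between the two matrices",
         call. = FALSE)
  if (length(samples) < 1)
    stop("no shared sample between the two matrices", call. = FALSE)
  list(a = M_a$values[feats, samples, drop = FALSE],
       b = M_b$values[feats, samples, drop = FALSE])
}

#' Per-sample Spearman correlation between two platforms
#'
#' For every sample shared by the two expression matrices, the Spearman rank
#' correlation of the shared features' expressions (average ranks for ties).
#' Being rank-based, the result is invariant to any strictly monotone
#' transform of either platform, so raw and log(x+1) inputs give identical
#' coefficients. A sample in which either platform is constant (or has < 3
#' complete feature pairs) has no defined coefficient and is reported NA
#' with a warning.
#'
#' @param M_a,M_b [expr_matrix()] objects at the same feature level.
#' @return A `sample_correlations` data frame: `sample_id`, `rho`; feature
#'   level and number of shared features in attributes `"level"`, `"n_features"`.
#' @export
spearman_per_sample <- function(M_a, M_b) {
  stopifnot(inherits(M_a, "expr_matrix"), inherits(M_b, "expr_matrix"))
  if (M_a$level != M_b$level)
    stop("feature levels differ: ", M_a$level, " vs ", M_b$level,
         call. = FALSE)
  sp <- shared_pair(M_a, M_b)
  rho <- vapply(seq_len(ncol(sp$a)), function(s) {
    x <- sp$a[, s]; y <- sp$b[, s]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || length(unique(x[ok])) == 1L ||
        length(unique(y[ok])) == 1L) {
      warning("sample ", colnames(sp$a)[s],
              ": constant or insufficient data; correlation undefined",
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok], method = "spearman")
  }, numeric(1))
  out <- data.frame(sample_id = colnames(sp$a), rho = rho)
  attr(out, "level") <- M_a$level
  attr(out, "n_features") <- nrow(sp$a)
  class(out) <- c("sample_correlations", "data.frame")
  out
}

#' Pooled Spearman correlation over all features and samples
#'
#' One Spearman coefficient over all (feature, sample) pairs pooled into a
#' single pair of vectors — the "overall correlation" of a scatter plot in
#' which each dot is one feature in one sample. Pooling is not an average of
#' per-sample coefficients: sample-specific offsets can drive it below (or
#' above) the per-sample mean.
#'
#' @param M_a,M_b [expr_matrix()] objects at the same feature level.
#' @return Single correlation coefficient.
#' @export
pooled_correlation <- function(M_a, M_b) {
  stopifnot(inherits(M_a, "expr_matrix"), inherits(M_b, "expr_matrix"))
  sp <- shared_pair(M_a, M_b)
  x <- as.vector(sp$a); y <- as.vector(sp$b)
  ok <- !is.na(x) & !is.na(y)
  if (length(unique(x[ok])) == 1L || length(unique(y[ok])) == 1L) {
    warning("constant pooled vector; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Features lowly expressed on both platforms
#'
#' Ranks features by mean expression across samples within each platform,
#' takes the bottom floor(N/3) of each, and returns the intersection — the
#' set on which platform sensitivity to low-abundance transcripts is
#' compared. Monotone rescaling of either platform leaves the result
#' unchanged.
#'
#' @param M_a,M_b [expr_matrix()] objects sharing >= 3 features.
#' @return Character vector of feature ids (possibly empty).
#' @export
low_expression_subset <- function(M_a, M_b) {
  stopifnot(inherits(M_a, "expr_matrix"), inherits(M_b, "expr_matrix"))
  sp <- shared_pair(M_a, M_b)
  k <- floor(nrow(sp$a) / 3)
  bottom <- function(V) {
    mu <- rowMeans(V, na.rm = TRUE)
    names(sort(mu))[seq_len(k)]
  }
  intersect(bottom(sp$a), bottom(sp$b))
}

#' Per-gene fold changes of a target tissue versus all other samples
#'
#' For every (target-tissue sample, other sample) pair and every gene, the
#' difference of log(x + 1) expressions — the log fold-change. With
#' `ratio = TRUE` the raw expression ratio (x_t + 1)/(x_o + 1) is returned
#' instead.
#'
#' @param M A gene-level log1p [expr_matrix()] (raw accepted when
#'   `ratio = TRUE`).
#' @param labels Data frame with columns `sample_id`, `tissue`.
#' @param target_tissue Tissue whose samples are compared against all others.
#' @param ratio Return raw ratios instead of log differences.
#' @return Long data frame: `gene_id`, `target_sample`, `other_sample`,
#'   `fold_change`; exactly one row per gene per sample pair.
#' @export
fold_change_pairs <- function(M, labels, target_tissue, ratio = FALSE) {
  stopifnot(inherits(M, "expr_matrix"))
  if (!ratio && M$transform != "log1p")
    stop("log fold-changes require a log1p matrix (see log_transform())",
         call. = FALSE)
  labels <- as.data.frame(labels)
  stopifnot(all(c("sample_id", "tissue") %in% names(labels)))
  samples <- colnames(M$values)
  tis <- labels$tissue[match(samples, labels$sample_id)]
  if (anyNA(tis))
    stop("missing tissue label for sample(s): ",
         paste(samples[is.na(tis)], collapse = ", "), call. = FALSE)
  tgt <- samples[tis == target_tissue]
  oth <- samples[tis != target_tissue]
  if (length(tgt) == 0L) stop("no sample in tissue ", target_tissue,
                              call. = FALSE)
  if (length(oth) == 0L) stop("no sample outside tissue ", target_tissue,
                              call. = FALSE)
  grid <- expand.grid(target_sample = tgt, other_sample = oth,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    t <- M$values[, grid$target_sample[i]]
    o <- M$values[, grid$other_sample[i]]
    fc <- if (ratio) {
      if (M$transform == "log1p") stop("ratio needs raw scale", call. = FALSE)
      (t + 1) / (o + 1)
    } else t - o
    data.frame(gene_id = rownames(M$values),
               target_sample = grid$target_sample[i],
               other_sample = grid$other_sample[i],
               fold_change = unname(fc), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA differential expression across tissue types
#'
#' Per gene, a one-way fixed-effects F test of equal mean expression across
#' tissue groups. Tissues with fewer than two samples cannot contribute a
#' within-group variance estimate and are dropped with a warning. Genes are
#' ranked by ascending p-value with lexicographic gene-id tie-break. Raw
#' p-values are the primary output; a Benjamini-Hochberg adjusted column
#' (`padj`) is attached as supplementary information.
#'
#' @param M A gene-level [expr_matrix()] (log1p recommended).
#' @param labels Data frame with columns `sample_id`, `tissue`.
#' @param k_top How many top genes to return in `$top`.
#' @return A `de_result`: list with `table` (gene_id, F, p_value, padj,
#'   rank — full ranked table), `top` (head of the ranking), `groups`
#'   (tissues used).
#' @export
anova_de <- function(M, labels, k_top = 10) {
  stopifnot(inherits(M, "expr_matrix"))
  labels <- as.data.frame(labels)
  stopifnot(all(c("sample_id", "tissue") %in% names(labels)))
  samples <- colnames(M$values)
  tis <- labels$tissue[match(samples, labels$sample_id)]
  if (anyNA(tis))
    stop("missing tissue label for sample(s): ",
         paste(samples[is.na(tis)], collapse = ", "), call. = FALSE)
  counts <- table(tis)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping tissue group(s) with a single sample: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- tis %in% names(counts)[counts >= 2]
    samples <- samples[keep]; tis <- tis[keep]
  }
  if (length(unique(tis)) < 2)
    stop("fewer than 2 usable tissue groups", call. = FALSE)
  grp <- factor(tis)
  res <- t(apply(M$values[, samples, drop = FALSE], 1, function(x) {
    fit <- stats::aov(x ~ grp)
    s <- summary(fit)[[1]]
    c(F = s$`F value`[1], p = s$`Pr(>F)`[1])
  }))
  tab <- data.frame(gene_id = rownames(M$values),
                    F = res[, 1], p_value = res[, 2], row.names = NULL)
  # a gene constant across all samples has no variance to partition: F = 0
  tab$F[is.na(tab$F)] <- 0
  tab$p_value[is.na(tab$p_value)] <- 1
  tab$padj <- stats::p.adjust(tab$p_value, method = "BH")
  ord <- order(tab$p_value, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 top = utils::head(tab, k_top),
                 groups = levels(grp)),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", nrow(x$table), " genes across groups: ",
      paste(x$groups, collapse = ", "), "\n", sep = "")
  print(x$top)
  invisible(x)
}

#' Full cross-platform concordance report
#'
#' Runs the whole comparison battery on a named set of platform expression
#' matrices sharing samples: per-sample and pooled Spearman correlations at
#' isoform and gene level for every platform pair, per-sample isoform
#' proportion differences (d), low-expression feature subsets with the
#' correlation restricted to them, and (given tissue labels) per-platform
#' ANOVA differential-expression rankings and target-tissue fold changes.
#'
#' @param platforms Named list of isoform-level raw [expr_matrix()] objects,
#'   one per platform.
#' @param annotation Data frame `isoform_id`, `gene_id` covering all
#'   features.
#' @param labels Optional data frame `sample_id`, `tissue`.
#' @param target_tissue Optional tissue for fold-change analysis (defaults
#'   to the most frequent label).
#' @param k_top Top-list length for the DE tables.
#' @return A `concordance_report`: list with `pairs` (per platform pair:
#'   `spearman_isoform`, `spearman_gene` (per-sample tables), `pooled_isoform`,
#'   `pooled_gene`, `mean_per_sample_isoform`, `mean_per_sample_gene`,
#'   `proportion_diff`, `low_expression` (feature ids + correlations on and
#'   off the subset)), `de` (per platform), `fold_changes` (per platform),
#'   and `platforms`/`samples` metadata. Serialize with
#'   [write_concordance_report()].
#' @export
platform_agreement_report <- function(platforms, annotation, labels = NULL,
                                      target_tissue = NULL, k_top = 10) {
  stopifnot(is.list(platforms), length(platforms) >= 2,
            !is.null(names(platforms)))
  stopifnot(all(vapply(platforms, inherits, logical(1), "expr_matrix")))
  gene_level <- lapply(platforms, function(M) {
    aggregate_to_genes(M, annotation)
  })
  pair_names <- utils::combn(names(platforms), 2, paste, collapse = "_vs_")
  pair_idx <- utils::combn(names(platforms), 2, identity, simplify = FALSE)
  pairs <- stats::setNames(lapply(pair_idx, function(pr) {
    Ma <- platforms[[pr[1]]]; Mb <- platforms[[pr[2]]]
    Ga <- gene_level[[pr[1]]]; Gb <- gene_level[[pr[2]]]
    sp_iso <- spearman_per_sample(Ma, Mb)
    sp_gene <- spearman_per_sample(Ga, Gb)
    d <- proportion_difference(isoform_proportions(Ma, annotation),
                               isoform_proportions(Mb, annotation))
    low <- low_expression_subset(Ga, Gb)
    low_cor <- if (length(low) >= 3) {
      sub <- function(M) expr_matrix(M$values[low, , drop = FALSE],
                                     level = M$level, transform = M$transform)
      pooled_correlation(sub(Ga), sub(Gb))
    } else NA_real_
    list(spearman_isoform = sp_iso,
         spearman_gene = sp_gene,
         pooled_isoform = pooled_correlation(Ma, Mb),
         pooled_gene = pooled_correlation(Ga, Gb),
         mean_per_sample_isoform = mean(sp_iso$rho, na.rm = TRUE),
         mean_per_sample_gene = mean(sp_gene$rho, na.rm = TRUE),
         proportion_diff = d,
         low_expression = list(features = low,
                               pooled_on_subset = low_cor,
                               pooled_full = pooled_correlation(Ga, Gb)))
  }), pair_names)
  de <- NULL; fc <- NULL
  if (!is.null(labels)) {
    if (is.null(target_tissue))
      target_tissue <- names(sort(table(labels$tissue), decreasing = TRUE))[1]
    de <- lapply(gene_level, function(G)
      anova_de(log_transform(G), labels, k_top))
    fc <- lapply(gene_level, function(G)
      fold_change_pairs(log_transform(G), labels, target_tissue))
  }
  structure(list(pairs = pairs, de = de, fold_changes = fc,
                 platforms = names(platforms),
                 samples = Reduce(intersect,
                                  lapply(platforms,
                                         function(M) colnames(M$values))),
                 target_tissue = if (!is.null(labels)) target_tissue),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> platforms: ",
      paste(x$platforms, collapse = ", "), "; ",
      length(x$samples), " shared samples\n", sep = "")
  for (nm in names(x$pairs)) {
    p <- x$pairs[[nm]]
    cat(sprintf("  %s: median isoform R_s %.3f | median gene R_s %.3f | median d %.3f\n",
                nm, stats::median(p$spearman_isoform$rho, na.rm = TRUE),
                stats::median(p$spearman_gene$rho, na.rm = TRUE),
                stats::median(p$proportion_diff$d)))
  }
  invisible(x)
}

#' Aggregate an isoform expression matrix to gene level
#'
#' Gene expression is the sum of the gene's isoform expressions (raw scale;
#' NA isoforms are ignored in the sum when at least one isoform of the gene
#' is estimable).
#'
#' @param M An isoform-level raw [expr_matrix()].
#' @param annotation Data frame `isoform_id`, `gene_id`.
#' @return A gene-level raw `expr_matrix`.
#' @export
aggregate_to_genes <- function(M, annotation) {
  stopifnot(inherits(M, "expr_matrix"), M$level == "isoform",
            M$transform == "raw")
  annotation <- as.data.frame(annotation)
  idx <- match(rownames(M$values), annotation$isoform_id)
  if (anyNA(idx))
    stop("isoform(s) without gene annotation: ",
         paste(utils::head(rownames(M$values)[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  gene_of <- annotation$gene_id[idx]
  out <- rowsum(ifelse(is.na(M$values), 0, M$values), gene_of)
  all_na <- rowsum((!is.na(M$values)) * 1, gene_of) == 0
  out[all_na] <- NA_real_
  expr_matrix(out[order(rownames(out)), , drop = FALSE], level = "gene",
              transform = "raw")
}
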