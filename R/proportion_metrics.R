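#' Within-gene isoform proportions
#'
#' Converts a raw-scale isoform expression matrix into per-gene, per-sample
#' isoform proportions p_ij = x_ij / sum_j x_ij. Gene/sample combinations
#' with zero total expression carry no proportion information and are
#' excluded (and recorded), never imputed as uniform. Isoforms with NA
#' expression (not estimable under the probe design) are likewise excluded.
#'
#' @param M An isoform-level raw [expr_matrix()].
#' @param annotation Data frame with columns `isoform_id`, `gene_id` mapping
#'   every feature of `M` to its gene (see [read_annotation()]).
#' @return A `proportion_table`: data frame with columns `gene_id`,
#'   `isoform_id`, `sample_id`, `proportion` (summing to 1 within each gene
#'   and sample), with the excluded zero-total gene/sample pairs in
#'   attribute `"excluded"`.
#' @examples
#' M <- expr_matrix(matrix(c(2, 3, 1, 4), 4, 1,
#'                  dimnames = list(paste0("iso", 1:4), "s1")), "isoform")
#' ann <- data.frame(isoform_id = paste0("iso", 1:4), gene_id = "G1")
#' isoform_proportions(M, ann)  # 0.2, 0.3, 0.1, 0.4
#' @export
isoform_proportions <- function(M, annotation) {
  stopifnot(inherits(M, "expr_matrix"), M$level == "isoform")
  if (M$transform != "raw")
    stop("proportions require raw-scale (pre-log) expressions", call. = FALSE)
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("isoform_id", "gene_id") %in% names(annotation)))
  iso <- rownames(M$values)
  idx <- match(iso, annotation$isoform_id)
  if (anyNA(idx))
    stop("isoform(s) without gene annotation: ",
         paste(utils::head(iso[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  gene_of <- annotation$gene_id[idx]
  samples <- colnames(M$values)
  rows <- vector("list", length(unique(gene_of)))
  excluded <- list()
  k <- 0L
  for (g in unique(gene_of)) {
    sel <- which(gene_of == g)
    X <- M$values[sel, , drop = FALSE]
    for (s in samples) {
      x <- stats::setNames(X[, s], rownames(X))
      x <- x[!is.na(x)]
      tot <- sum(x)
      if (length(x) == 0L || tot <= 0) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(gene_id = g, sample_id = s)
        next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = g, isoform_id = names(x),
                              sample_id = s, proportion = x / tot,
                              row.names = NULL)
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)])
         else data.frame(gene_id = character(), isoform_id = character(),
                         sample_id = character(), proportion = numeric())
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else data.frame(gene_id = character(),
                                           sample_id = character())
  class(out) <- c("proportion_table", "data.frame")
  out
}

#' Proportion difference between two platforms
#'
#' For each sample shared by the two proportion tables, computes
#' d = (1/n) * sum_i [ (1/m_i) * sum_j |p^a_ij - p^b_ij| ]
#' over the n genes represented with identical isoform sets on both
#' platforms in that sample. d lies in [0, 1], is symmetric in the two
#' platforms, equals 0 iff the tables agree, and reaches 1 only when every
#' gene's expression mass sits on disjoint isoforms in the two platforms.
#' Genes present on only one platform (or with differing isoform sets, e.g.
#' after a one-sided group collapse) are excluded and recorded.
#'
#' @param P_a,P_b `proportion_table` objects (see [isoform_proportions()]).
#' @return A `proportion_difference`: data frame with one row per shared
#'   sample (`sample_id`, `d`, `n_genes`), with excluded gene/sample pairs
#'   in attribute `"excluded"`.
#' @export
proportion_difference <- function(P_a, P_b) {
  P_a <- as.data.frame(P_a); P_b <- as.data.frame(P_b)
  samples <- intersect(unique(P_a$sample_id), unique(P_b$sample_id))
  if (length(samples) == 0L)
    stop("the two proportion tables share no sample", call. = FALSE)
  out <- data.frame(sample_id = character(), d = numeric(),
                    n_genes = integer())
  excluded <- list()
  for (s in samples) {
    a <- P_a[P_a$sample_id == s, ]
    b <- P_b[P_b$sample_id == s, ]
    genes <- intersect(unique(a$gene_id), unique(b$gene_id))
    terms <- numeric(0)
    for (g in genes) {
      ag <- a[a$gene_id == g, ]
      bg <- b[b$gene_id == g, ]
      if (length(ag$isoform_id) != length(bg$isoform_id) ||
          !setequal(ag$isoform_id, bg$isoform_id)) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(gene_id = g, sample_id = s,
                     reason = "isoform sets differ")
        next
      }
      pb <- bg$proportion[match(ag$isoform_id, bg$isoform_id)]
      terms[g] <- mean(abs(ag$proportion - pb))
    }
    if (length(terms) == 0L)
      stop("no gene is shared by both platforms in sample ", s,
           call. = FALSE)
    out <- rbind(out, data.frame(sample_id = s, d = mean(terms),
                                 n_genes = length(terms)))
  }
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else data.frame(gene_id = character(),
                                           sample_id = character(),
                                           reason = character())
  class(out) <- c("proportion_difference", "data.frame")
  out
}

#' Comparative-Ct conversion of qPCR cycle thresholds to proportions
#'
#' Treats each cycle-threshold unit as an `efficiency`-fold abundance
#' difference: relative quantity q_j = efficiency^(-Ct_j), proportion
#' p_j = q_j / sum(q). Adding a constant to all Ct values of a gene (e.g.
#' normalization to total RNA input) leaves the proportions unchanged.
#'
#' @param ct Named numeric vector of Ct values, one per isoform of one gene
#'   in one sample. NA (undetermined) isoforms are dropped with a warning.
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @return Named proportion vector over the detected isoforms, summing to 1.
#' @examples
#' ct_to_proportions(c(a = 20, b = 21, c = 22))  # 4/7, 2/7, 1/7
#' @export
ct_to_proportions <- function(ct, efficiency = 2) {
  ct <- unlist(ct)
  stopifnot(is.numeric(ct), efficiency > 1)
  drop <- !is.finite(ct)
  if (all(drop))
    stop("all Ct values are missing/undetermined", call. = FALSE)
  if (any(drop)) {
    warning("dropping isoform(s) with undetermined Ct: ",
            paste(names(ct)[drop], collapse = ", "), call. = FALSE)
    ct <- ct[!drop]
  }
  # subtract min before exponentiating for numerical stability (proportions
  # are invariant to a common Ct shift)
  q <- efficiency^(-(ct - min(ct)))
  q / sum(q)
}

#' Proportion table from a long Ct table
#'
#' Applies [ct_to_proportions()] within every gene/sample combination of a
#' long-format Ct table.
#'
#' @param ct_table Data frame with columns `gene_id`, `isoform_id`,
#'   `sample_id`, `ct`.
#' @param efficiency Amplification efficiency per cycle.
#' @return A `proportion_table` (see [isoform_proportions()]).
#' @export
ct_table_to_proportions <- function(ct_table, efficiency = 2) {
  ct_table <- as.data.frame(ct_table)
  stopifnot(all(c("gene_id", "isoform_id", "sample_id", "ct") %in%
                  names(ct_table)))
  parts <- split(ct_table,
                 list(ct_table$gene_id, ct_table$sample_id), drop = TRUE)
  rows <- lapply(parts, function(gs) {
    ct <- stats::setNames(gs$ct, gs$isoform_id)
    if (all(!is.finite(ct))) return(NULL)
    p <- ct_to_proportions(ct, efficiency)
    data.frame(gene_id = gs$gene_id[1], isoform_id = names(p),
               sample_id = gs$sample_id[1], proportion = unname(p))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "excluded") <- data.frame(gene_id = character(),
                                      sample_id = character())
  class(out) <- c("proportion_table", "data.frame")
  out
}

#' Wilcoxon rank-sum comparison of two sets of agreement statistics
#'
#' Two-sided rank-sum (Mann-Whitney) test, used e.g. to ask whether one
#' platform pair's per-sample proportion differences are systematically
#' larger than another's. The exact null distribution is used for small
#' tie-free samples (combined n <= 20); otherwise the normal approximation
#' with tie correction.
#'
#' @param d_values_a,d_values_b Numeric vectors (>= 3 values each).
#' @return Two-sided p-value.
#' @export
rank_sum_compare <- function(d_values_a, d_values_b) {
  a <- as.numeric(d_values_a); b <- as.numeric(d_values_b)
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 values per group", call. = FALSE)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied; rank-sum test is uninformative (p = 1)",
            call. = FALSE)
    return(1)
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !has_ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = !exact)$p.value)
  unname(p)
}
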