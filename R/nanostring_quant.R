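#' Default housekeeping gene set
#'
#' The ten housekeeping genes used for geometric-mean normalization of
#' nCounter-style panels: TAF5L, HPS6, DNTTIP2, GNRHR, ZNF407, KCNK7,
#' KIAA1539, RBM12, DGCR14, KHDRBS1.
#' @export
housekeeping_genes <- c("TAF5L", "HPS6", "DNTTIP2", "GNRHR", "ZNF407",
                        "KCNK7", "KIAA1539", "RBM12", "DGCR14", "KHDRBS1")

#' Probe count matrix
#'
#' Raw or normalized hybridization counts, probes in rows and samples (or
#' sample replicates) in columns.
#'
#' @param counts Numeric matrix, non-negative, rownames = probe ids,
#'   colnames = sample ids.
#' @param normalized Has housekeeping normalization been applied?
#' @return An object of class `probe_counts`.
#' @export
probe_counts <- function(counts, normalized = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicated probe ids", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE))
    stop("probe counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, normalized = isTRUE(normalized)),
            class = "probe_counts")
}

#' @export
print.probe_counts <- function(x, ...) {
  cat("<probe_counts> ", nrow(x$counts), " probes x ", ncol(x$counts),
      " samples; ", if (x$normalized) "normalized" else "raw", "\n", sep = "")
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Housekeeping geometric-mean normalization
#'
#' Scales each sample so that the geometric mean of its housekeeping probe
#' counts equals the cohort-wide geometric mean of those per-sample
#' geometric means. The per-sample scale factor is
#' reference / geomean(housekeeping counts in that sample), where the
#' reference is the geometric mean of the per-sample geomeans; the
#' across-sample geometric mean of housekeeping signal is therefore left
#' invariant, and overall signal scale is preserved.
#'
#' @param raw A raw [probe_counts()] matrix.
#' @param panel The [probe_panel()] mapping probes to genes.
#' @param housekeeping_gene_ids Genes whose probes anchor the normalization;
#'   defaults to the genes measured by the panel's housekeeping-class probes
#'   (the canonical ten-gene set is exported as [housekeeping_genes]).
#' @return A normalized `probe_counts` object, with the per-sample scale
#'   factors in attribute `"scale_factors"`.
#' @export
housekeeping_normalize <- function(raw, panel, housekeeping_gene_ids = NULL) {
  stopifnot(inherits(raw, "probe_counts"), inherits(panel, "probe_panel"))
  if (raw$normalized)
    stop("counts are already normalized; refusing to normalize twice",
         call. = FALSE)
  probe_gene <- vapply(panel$probes, `[[`, character(1), "gene_id")
  if (is.null(housekeeping_gene_ids)) {
    cls <- vapply(panel$probes, `[[`, character(1), "probe_class")
    housekeeping_gene_ids <- unique(probe_gene[cls == "housekeeping"])
    if (length(housekeeping_gene_ids) == 0L)
      stop("panel has no housekeeping-class probes and no explicit ",
           "housekeeping gene list was given", call. = FALSE)
  }
  hk_probes <- names(probe_gene)[probe_gene %in% housekeeping_gene_ids]
  hk_probes <- intersect(hk_probes, rownames(raw$counts))
  covered <- unique(probe_gene[hk_probes])
  missing <- setdiff(housekeeping_gene_ids, covered)
  if (length(missing))
    stop("housekeeping gene(s) without probes in the count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  hk <- raw$counts[hk_probes, , drop = FALSE]
  bad <- which(hk <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive housekeeping count: gene ",
         probe_gene[hk_probes[bad[1, 1]]], ", sample ",
         colnames(hk)[bad[1, 2]], call. = FALSE)
  g <- apply(hk, 2, geometric_mean)
  ref <- geometric_mean(g)
  factors <- ref / g
  out <- probe_counts(sweep(raw$counts, 2, factors, `*`), normalized = TRUE)
  attr(out, "scale_factors") <- factors
  out
}

#' Collapse technical replicates
#'
#' Averages replicate columns (arithmetic mean of normalized counts) into one
#' column per sample.
#'
#' @param x A [probe_counts()] object.
#' @param sample_of Character vector mapping each column to its sample;
#'   defaults to stripping a trailing `_rep<k>` suffix from column names.
#' @return `probe_counts` with one column per sample.
#' @export
collapse_replicates <- function(x, sample_of = NULL) {
  stopifnot(inherits(x, "probe_counts"))
  if (is.null(sample_of))
    sample_of <- sub("_rep[0-9]+$", "", colnames(x$counts))
  stopifnot(length(sample_of) == ncol(x$counts))
  samples <- unique(sample_of)
  out <- vapply(samples,
                function(s) rowMeans(x$counts[, sample_of == s, drop = FALSE]),
                numeric(nrow(x$counts)))
  colnames(out) <- samples
  probe_counts(out, normalized = x$normalized)
}

#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Minimizes ||y - A x||^2 subject to x >= 0. Deterministic (starts from the
#' all-zero, all-passive state) and convergent for any A; used to allocate
#' probe signal among a gene's isoforms.
#'
#' @param A Numeric design matrix (m x n).
#' @param y Numeric response vector (length m).
#' @param tol Dual-feasibility tolerance on the negative gradient
#'   w = t(A)(y - Ax); default `1e-10 * max(1, ||t(A) y||_inf)`.
#' @return List with `x` (the minimizer), `objective` (||y - Ax||^2) and
#'   `passive` (indices of the unconstrained coordinates).
#' @export
nnls_fit <- function(A, y, tol = NULL) {
  A <- as.matrix(A); storage.mode(A) <- "double"
  y <- as.numeric(y)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(y) == m)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(crossprod(A, y))))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, y))
  it <- 0L; itmax <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && it < itmax) {
    it <- it + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), y)
      z[P][is.na(z[P])] <- 0  # rank-deficient passive set: minimum-norm fill
      if (all(z[P] > 0)) { x <- z; break }
      neg <- P[z[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, y - A %*% x))
  }
  r <- y - drop(A %*% x)
  list(x = x, objective = sum(r^2), passive = which(passive))
}

#' Deconvolve one gene's probe intensities into isoform expressions
#'
#' Solves min ||y - A x||^2 s.t. x >= 0, where y holds the (normalized)
#' intensities of the gene's probes and A is the probe-isoform incidence
#' matrix. With a full-rank design and exactly consistent intensities the
#' true expressions are recovered exactly; under a max-probe design the last
#' isoform's value equals the max-probe signal minus the isoform-specific
#' signals. For rank-deficient designs a minimizer is still returned but the
#' split within each indistinguishable isoform group is arbitrary; only the
#' group sums are data-constrained (see `$identifiability`).
#'
#' @param y Numeric vector of probe intensities, one per row of A, >= 0.
#' @param A An [incidence_matrix()] (or 0/1 matrix).
#' @param tol Solver tolerance passed to [nnls_fit()].
#' @return Object of class `isoform_expression`: list with `values` (named
#'   non-negative vector), `isoform_ids`, `objective`, `identifiable`, and
#'   `identifiability` (the full [check_identifiability()] report).
#' @examples
#' A <- rbind(max = c(1, 1, 1, 1), p1 = c(1, 0, 0, 0),
#'            p2 = c(0, 1, 0, 0), p3 = c(0, 0, 1, 0))
#' colnames(A) <- paste0("iso", 1:4)
#' deconvolve_gene(c(10, 2, 3, 1), A)$values  # iso4 = 10 - (2 + 3 + 1)
#' @export
deconvolve_gene <- function(y, A, tol = NULL) {
  if (inherits(A, "incidence_matrix")) {
    report <- check_identifiability(A)
    iso <- A$isoform_ids
    A <- A$A
  } else {
    A <- as.matrix(A)
    report <- check_identifiability(A)
    iso <- colnames(A)
    if (is.null(iso)) iso <- paste0("iso", seq_len(ncol(A)))
  }
  y <- as.numeric(y)
  if (length(y) != nrow(A))
    stop("length(y) = ", length(y), " but A has ", nrow(A), " rows",
         call. = FALSE)
  if (any(y < 0)) stop("probe intensities must be non-negative", call. = FALSE)
  fit <- nnls_fit(A, y, tol)
  values <- pmax(fit$x, 0)
  names(values) <- iso
  structure(list(values = values, isoform_ids = iso,
                 objective = fit$objective,
                 identifiable = report$identifiable,
                 identifiability = report),
            class = "isoform_expression")
}

#' Total gene expression from isoform expressions
#'
#' Gene-level expression is the sum of the gene's isoform expressions.
#'
#' @param x An `isoform_expression` or non-negative numeric vector.
#' @return Single non-negative number.
#' @export
gene_expression_from_isoforms <- function(x) {
  if (inherits(x, "isoform_expression")) x <- x$values
  sum(as.numeric(x))
}

#' Expression matrix with level and transform metadata
#'
#' @param values Numeric matrix, features x samples, with dimnames.
#' @param level `"isoform"` or `"gene"`.
#' @param transform `"raw"` (non-negative linear scale) or `"log1p"`
#'   (log(x + 1) scale).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, level = c("isoform", "gene"),
                        transform = c("raw", "log1p")) {
  level <- match.arg(level); transform <- match.arg(transform)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("expression matrix needs feature ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  structure(list(values = values, level = level, transform = transform),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " ", x$level, "s x ",
      ncol(x$values), " samples [", x$transform, "]\n", sep = "")
  invisible(x)
}

#' log(x + 1) transform of an expression matrix
#'
#' Applies log(x + 1) entrywise (base 2 by default). Rank-based downstream
#' statistics are invariant to the base.
#'
#' @param M A raw-scale [expr_matrix()].
#' @param base Logarithm base.
#' @return `expr_matrix` with `transform = "log1p"`.
#' @export
log_transform <- function(M, base = 2) {
  stopifnot(inherits(M, "expr_matrix"))
  if (M$transform != "raw")
    stop("matrix is already log-transformed", call. = FALSE)
  if (any(M$values < 0, na.rm = TRUE))
    stop("negative values cannot be log(x+1)-transformed", call. = FALSE)
  expr_matrix(log(M$values + 1, base = base), level = M$level,
              transform = "log1p")
}

#' Quantify a whole panel: probe counts to isoform and gene expression
#'
#' Runs the per-gene deconvolution over every endogenous panel gene and
#' every sample. Housekeeping genes (single isoform, single probe) are
#' carried through directly; spike-in probes are ignored. For genes whose
#' design is not identifiable, isoforms inside a multi-member
#' indistinguishable group and untargeted isoforms are reported as NA
#' (not estimable); the gene total (the sum of the fitted vector) is still
#' well-defined. Group-level sums for those genes are available via
#' [collapse_to_groups()] with the returned identifiability reports.
#'
#' @param counts Normalized [probe_counts()], one column per sample
#'   (collapse replicates first; see [collapse_replicates()]).
#' @param panel A [probe_panel()].
#' @param tol Solver tolerance for [nnls_fit()].
#' @return List with `isoform` and `gene` raw-scale [expr_matrix()] objects
#'   and `identifiability`, a per-gene list of reports (NULL for trivially
#'   identifiable single-isoform genes).
#' @export
quantify_panel <- function(counts, panel, tol = NULL) {
  stopifnot(inherits(counts, "probe_counts"), inherits(panel, "probe_panel"))
  if (!counts$normalized)
    stop("counts must be housekeeping-normalized before deconvolution",
         call. = FALSE)
  samples <- colnames(counts$counts)
  iso_rows <- list(); gene_rows <- list(); reports <- list()
  for (g in panel$genes) {
    probes <- panel_gene_probes(panel, g$gene_id)
    probes <- Filter(function(p) p$probe_id %in% rownames(counts$counts),
                     probes)
    if (length(probes) == 0L) {
      warning("gene ", g$gene_id, " has no probes in the count matrix; ",
              "skipped", call. = FALSE)
      next
    }
    inc <- build_incidence_matrix(g, probes)
    rep <- check_identifiability(inc)
    estimable <- rep$identifiable
    grp_sizes <- lengths(rep$indistinguishable_groups)
    na_iso <- unlist(rep$indistinguishable_groups[grp_sizes > 1])
    na_iso <- union(na_iso, rep$untargeted)
    Y <- counts$counts[inc$probe_ids, , drop = FALSE]
    X <- matrix(NA_real_, nrow = length(g$isoform_ids), ncol = length(samples),
                dimnames = list(g$isoform_ids, samples))
    gene_tot <- numeric(length(samples))
    for (s in seq_along(samples)) {
      fit <- deconvolve_gene(Y[, s], inc, tol)
      v <- fit$values
      if (!estimable) v[names(v) %in% na_iso] <- NA_real_
      X[, s] <- v
      gene_tot[s] <- gene_expression_from_isoforms(fit)
    }
    iso_rows[[g$gene_id]] <- X
    gene_rows[[g$gene_id]] <- gene_tot
    reports[[g$gene_id]] <- rep
  }
  if (length(iso_rows) == 0L)
    stop("no quantifiable genes in the panel", call. = FALSE)
  iso_mat <- do.call(rbind, iso_rows)
  gene_mat <- do.call(rbind, gene_rows)
  rownames(gene_mat) <- names(gene_rows)
  colnames(gene_mat) <- samples
  list(isoform = expr_matrix(iso_mat, level = "isoform", transform = "raw"),
       gene = expr_matrix(gene_mat, level = "gene", transform = "raw"),
       identifiability = reports)
}

#' Collapse isoform features into indistinguishable groups
#'
#' Sums isoform rows that belong to the same indistinguishable group into a
#' single feature named by joining the member ids with `"+"`. Used to carry
#' out cross-platform comparisons at the resolution a probe design actually
#' supports: collapse both platforms to the same groups, then compare.
#'
#' @param M An isoform-level raw [expr_matrix()].
#' @param groups List of character vectors partitioning (a subset of) the
#'   feature ids, e.g. `indistinguishable_groups` from
#'   [check_identifiability()], or a per-gene list of such lists as returned
#'   in `quantify_panel()$identifiability`.
#' @return `expr_matrix` with grouped features; features not mentioned in
#'   `groups` are kept as-is.
#' @export
collapse_to_groups <- function(M, groups) {
  stopifnot(inherits(M, "expr_matrix"), M$level == "isoform",
            M$transform == "raw")
  if (length(groups) && is.list(groups[[1]]) &&
      !is.null(groups[[1]]$indistinguishable_groups))
    groups <- unlist(lapply(groups, `[[`, "indistinguishable_groups"),
                     recursive = FALSE)
  groups <- Filter(function(g) length(g) > 1, groups)
  V <- M$values
  keep <- rownames(V)
  out <- list()
  for (g in groups) {
    g <- intersect(g, rownames(V))
    if (length(g) < 2) next
    out[[paste(g, collapse = "+")]] <- colSums(V[g, , drop = FALSE])
    keep <- setdiff(keep, g)
  }
  res <- rbind(V[keep, , drop = FALSE],
               if (length(out)) do.call(rbind, out))
  expr_matrix(res, level = "isoform", transform = "raw")
}
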