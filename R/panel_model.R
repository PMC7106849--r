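#' Gene model: a gene and its ordered isoforms
#'
#' A minimal description of one gene as an ordered set of transcript
#' (isoform) identifiers. Probe panels are designed against gene models, and
#' the probe--isoform incidence matrix inherits its column order from the
#' gene model's isoform order.
#'
#' @param gene_id Single gene identifier.
#' @param isoform_ids Character vector of transcript identifiers, unique
#'   within the gene, length >= 1. Multi-isoform panel genes have >= 2.
#' @return An object of class `gene_model`.
#' @examples
#' fli1 <- gene_model("FLI1", c("NM_001271012", "NM_001167681",
#'                              "NM_001271010", "NM_002017"))
#' @export
gene_model <- function(gene_id, isoform_ids) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  isoform_ids <- as.character(isoform_ids)
  if (length(isoform_ids) < 1L)
    stop("gene ", gene_id, ": needs at least one isoform", call. = FALSE)
  if (anyDuplicated(isoform_ids))
    stop("gene ", gene_id, ": duplicated isoform ids: ",
         paste(unique(isoform_ids[duplicated(isoform_ids)]), collapse = ", "),
         call. = FALSE)
  structure(list(gene_id = gene_id, isoform_ids = isoform_ids),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, ": ", length(x$isoform_ids),
      " isoform(s): ", paste(x$isoform_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Capture probe definition
#'
#' One hybridization probe. An endogenous probe targets a non-empty subset of
#' one gene's isoforms (a "max" probe targets all of them and measures total
#' gene expression). Housekeeping probes target the single isoform of a
#' housekeeping gene; spike-in probes are synthetic controls with no
#' transcript target and are excluded from normalization and deconvolution.
#'
#' @param probe_id Single probe identifier.
#' @param gene_id Gene the probe belongs to.
#' @param targets Character vector of targeted isoform ids (may be empty only
#'   for spike-ins).
#' @param probe_class One of `"endogenous"`, `"housekeeping"`, `"spike_in"`.
#' @return An object of class `probe`.
#' @export
probe <- function(probe_id, gene_id, targets = character(),
                  probe_class = c("endogenous", "housekeeping", "spike_in")) {
  probe_class <- match.arg(probe_class)
  targets <- as.character(targets)
  if (probe_class != "spike_in" && length(targets) == 0L)
    stop("probe ", probe_id, ": ", probe_class,
         " probes must target at least one isoform", call. = FALSE)
  if (anyDuplicated(targets))
    stop("probe ", probe_id, ": duplicated targets", call. = FALSE)
  structure(list(probe_id = as.character(probe_id),
                 gene_id = as.character(gene_id),
                 targets = targets, probe_class = probe_class),
            class = "probe")
}

#' @export
print.probe <- function(x, ...) {
  cat("<probe> ", x$probe_id, " [", x$probe_class, "] gene ", x$gene_id,
      " -> {", paste(x$targets, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Probe panel: gene models plus their probes
#'
#' @param genes List of [gene_model()] objects (named or not).
#' @param probes List of [probe()] objects. Endogenous and housekeeping
#'   probes must reference a panel gene and only its isoforms.
#' @return An object of class `probe_panel` with elements `genes` (named list
#'   by gene_id) and `probes` (named list by probe_id).
#' @export
probe_panel <- function(genes, probes) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  if (inherits(probes, "probe")) probes <- list(probes)
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_model")),
            all(vapply(probes, inherits, logical(1), "probe")))
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(names(genes)))
    stop("duplicated gene ids in panel", call. = FALSE)
  names(probes) <- vapply(probes, `[[`, character(1), "probe_id")
  if (anyDuplicated(names(probes)))
    stop("duplicated probe ids in panel", call. = FALSE)
  for (p in probes) {
    if (p$probe_class == "spike_in") next
    g <- genes[[p$gene_id]]
    if (is.null(g))
      stop("probe ", p$probe_id, " references unknown gene ", p$gene_id,
           call. = FALSE)
    bad <- setdiff(p$targets, g$isoform_ids)
    if (length(bad))
      stop("probe ", p$probe_id, " targets isoform(s) not annotated to gene ",
           p$gene_id, ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(genes = genes, probes = probes), class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cls <- vapply(x$probes, `[[`, character(1), "probe_class")
  cat("<probe_panel> ", length(x$genes), " genes, ", length(x$probes),
      " probes (", sum(cls == "endogenous"), " endogenous, ",
      sum(cls == "housekeeping"), " housekeeping, ",
      sum(cls == "spike_in"), " spike-in)\n", sep = "")
  invisible(x)
}

#' Probes of a panel belonging to one gene
#' @param panel A `probe_panel`.
#' @param gene_id Gene identifier.
#' @param classes Probe classes to keep.
#' @return List of `probe` objects, in panel order.
#' @export
panel_gene_probes <- function(panel, gene_id,
                              classes = c("endogenous", "housekeeping")) {
  Filter(function(p) p$gene_id == gene_id && p$probe_class %in% classes,
         panel$probes)
}

#' Build the probe-isoform incidence matrix for one gene
#'
#' Entry (j, i) of the 0/1 matrix A is 1 iff probe j targets isoform i. Rows
#' follow the input probe order, columns the gene model's isoform order. The
#' probe intensity model is y = A x with x >= 0 the isoform expressions, so
#' this matrix is the design matrix of the deconvolution
#' ([deconvolve_gene()]).
#'
#' @param gene A [gene_model()].
#' @param probes List of [probe()] objects, all belonging to `gene`, each
#'   with a non-empty target set.
#' @return An object of class `incidence_matrix`: list with `A` (0/1 matrix,
#'   dimnames probe x isoform), `probe_ids`, `isoform_ids`.
#' @examples
#' g <- gene_model("FLI1", c("NM_001271012", "NM_001167681",
#'                           "NM_001271010", "NM_002017"))
#' probes <- list(
#'   probe("max", "FLI1", g$isoform_ids),
#'   probe("p1", "FLI1", "NM_001271012"),
#'   probe("p2", "FLI1", "NM_001167681"),
#'   probe("p3", "FLI1", "NM_001271010"))
#' build_incidence_matrix(g, probes)$A
#' @export
build_incidence_matrix <- function(gene, probes) {
  stopifnot(inherits(gene, "gene_model"))
  if (inherits(probes, "probe")) probes <- list(probes)
  if (length(probes) == 0L)
    stop("gene ", gene$gene_id, ": no probes supplied", call. = FALSE)
  iso <- gene$isoform_ids
  pid <- vapply(probes, `[[`, character(1), "probe_id")
  A <- matrix(0L, nrow = length(probes), ncol = length(iso),
              dimnames = list(pid, iso))
  for (j in seq_along(probes)) {
    p <- probes[[j]]
    if (p$gene_id != gene$gene_id)
      stop("probe ", p$probe_id, " belongs to gene ", p$gene_id,
           ", not ", gene$gene_id, call. = FALSE)
    bad <- setdiff(p$targets, iso)
    if (length(bad))
      stop("probe ", p$probe_id, " targets isoform(s) absent from gene ",
           gene$gene_id, ": ", paste(bad, collapse = ", "), call. = FALSE)
    if (length(p$targets) == 0L)
      stop("probe ", p$probe_id, ": empty target set", call. = FALSE)
    A[j, match(p$targets, iso)] <- 1L
  }
  structure(list(A = A, probe_ids = pid, isoform_ids = iso),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("<incidence_matrix> ", nrow(x$A), " probes x ", ncol(x$A),
      " isoforms\n", sep = "")
  print(x$A)
  invisible(x)
}

# Exact rank of a small integer matrix by Bareiss fraction-free elimination.
# Avoids floating-point rank ambiguity on 0/1 designs; all pivots stay
# integral. Intended for the small (m, n <= ~10) panel design matrices.
exact_integer_rank <- function(M) {
  M <- matrix(as.numeric(M), nrow = nrow(M))
  stopifnot(all(M == round(M)))
  m <- nrow(M); n <- ncol(M)
  r <- 0L
  prev <- 1
  for (col in seq_len(n)) {
    piv <- which(M[, col] != 0 & seq_len(m) > r)
    if (length(piv) == 0L) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    if (r < m) {
      rows <- (r + 1L):m
      M[rows, ] <- (M[rows, , drop = FALSE] * M[r, col] -
                      outer(M[rows, col], M[r, ])) / prev
    }
    prev <- M[r, col]
    if (r == m) break
  }
  r
}

#' Diagnose which isoforms a probe design can distinguish
#'
#' A design identifies every isoform of a gene exactly when its incidence
#' matrix has full column rank; then the deconvolution y = A x has a unique
#' least-squares solution. Rank is computed exactly by integer elimination.
#' Isoforms whose columns of A are identical receive identical coefficients
#' in any fit and are grouped: only the group's total expression is
#' constrained by the data. Rank deficiency that identical columns do not
#' explain (e.g. a column equal to a sum of others) is flagged as
#' `partially_identifiable`, and untargeted isoforms (all-zero columns,
#' never estimable) are listed separately.
#'
#' @param x An `incidence_matrix` (or plain 0/1 matrix with dimnames).
#' @return An object of class `identifiability_report`: list with `rank`,
#'   `identifiable`, `indistinguishable_groups` (partition of isoform ids;
#'   singletons for distinguishable isoforms), `partially_identifiable`,
#'   `untargeted` (isoform ids with no probe coverage).
#' @export
check_identifiability <- function(x) {
  if (inherits(x, "incidence_matrix")) A <- x$A
  else A <- as.matrix(x)
  stopifnot(all(A %in% c(0, 1)))
  iso <- colnames(A)
  if (is.null(iso)) iso <- paste0("iso", seq_len(ncol(A)))
  rk <- exact_integer_rank(A)
  # partition isoforms by identical columns of A
  key <- apply(A, 2, paste, collapse = "")
  groups <- split(iso, factor(key, levels = unique(key)))
  names(groups) <- NULL
  untargeted <- iso[colSums(A) == 0]
  n_distinct_cols <- length(groups)
  identifiable <- rk == ncol(A)
  # rank shortfall beyond what duplicate/zero columns account for
  explained <- n_distinct_cols - as.integer(length(untargeted) > 0)
  structure(list(rank = rk,
                 identifiable = identifiable,
                 indistinguishable_groups = groups,
                 partially_identifiable = !identifiable && rk < explained,
                 untargeted = untargeted),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("<identifiability_report> rank ", x$rank, "; ",
      if (x$identifiable) "identifiable" else "NOT identifiable", "\n",
      sep = "")
  if (!x$identifiable) {
    grp <- Filter(function(g) length(g) > 1, x$indistinguishable_groups)
    for (g in grp) cat("  group: {", paste(g, collapse = ", "), "}\n")
    if (length(x$untargeted))
      cat("  untargeted:", paste(x$untargeted, collapse = ", "), "\n")
    if (x$partially_identifiable)
      cat("  rank deficiency beyond duplicate columns\n")
  }
  invisible(x)
}

#' Design a max-probe panel for one gene
#'
#' The standard design for distinguishing all n isoforms of a gene with n
#' probes: one gene-level "max" probe targeting a region shared by every
#' isoform (it measures total gene expression), plus one isoform-specific
#' probe for each isoform except the last. The last isoform's expression is
#' recovered as the max-probe signal minus the others, so the resulting
#' incidence matrix always has full rank n.
#'
#' @param gene A [gene_model()] with >= 2 isoforms.
#' @return List of n [probe()] objects (`<gene>_max`, `<gene>_p1`, ...).
#' @export
design_max_probe_panel <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  n <- length(gene$isoform_ids)
  if (n < 2L)
    stop("gene ", gene$gene_id,
         ": max-probe design requires at least two isoforms ",
         "(a single-isoform gene needs only one probe)", call. = FALSE)
  probes <- vector("list", n)
  probes[[1]] <- probe(paste0(gene$gene_id, "_max"), gene$gene_id,
                       gene$isoform_ids, "endogenous")
  for (i in seq_len(n - 1L))
    probes[[i + 1]] <- probe(paste0(gene$gene_id, "_p", i), gene$gene_id,
                             gene$isoform_ids[i], "endogenous")
  probes
}
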