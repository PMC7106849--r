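# Independent oracles used to validate the package's own implementations.
# These deliberately use different algorithms from the code under test.

# Matrix rank by brute-force minor expansion: the rank is the largest k for
# which some k x k submatrix has a non-zero determinant. Determinants by
# recursive cofactor expansion on integer matrices (exact for the small 0/1
# designs used here). Feasible up to ~6 x 6.
oracle_det <- function(M) {
  n <- nrow(M)
  if (n == 1) return(M[1, 1])
  s <- 0
  for (j in seq_len(n))
    if (M[1, j] != 0)
      s <- s + (-1)^(1 + j) * M[1, j] *
        oracle_det(M[-1, -j, drop = FALSE])
  s
}

oracle_rank <- function(M) {
  M <- as.matrix(M)
  for (k in rev(seq_len(min(dim(M))))) {
    rows <- utils::combn(nrow(M), k, simplify = FALSE)
    cols <- utils::combn(ncol(M), k, simplify = FALSE)
    for (r in rows) for (cc in cols)
      if (oracle_det(M[r, cc, drop = FALSE]) != 0) return(k)
  }
  0L
}

# Dense grid-search NNLS oracle for 2-column designs: scans a refined grid
# around the best coarse point. Only used to cross-check tiny instances.
oracle_nnls_grid <- function(A, y, upper = NULL, n_grid = 201) {
  stopifnot(ncol(A) == 2)
  if (is.null(upper)) upper <- max(y) * 1.5 + 1
  obj <- function(x) sum((y - A %*% x)^2)
  g <- seq(0, upper, length.out = n_grid)
  best <- c(0, 0); best_obj <- obj(best)
  for (x1 in g) for (x2 in g) {
    o <- obj(c(x1, x2))
    if (o < best_obj) { best <- c(x1, x2); best_obj <- o }
  }
  for (refine in 1:3) {
    step <- (g[2] - g[1])
    g1 <- seq(max(0, best[1] - step), best[1] + step, length.out = 41)
    g2 <- seq(max(0, best[2] - step), best[2] + step, length.out = 41)
    for (x1 in g1) for (x2 in g2) {
      o <- obj(c(x1, x2))
      if (o < best_obj) { best <- c(x1, x2); best_obj <- o }
    }
    g <- g1
  }
  list(x = best, objective = best_obj)
}

# Random valid proportion table over a fixed gene set (one sample).
random_proportion_table <- function(genes, sizes, sample_id = "s1",
                                    concentrate = FALSE) {
  rows <- mapply(function(g, m) {
    p <- if (concentrate) {
      v <- numeric(m); v[sample.int(m, 1)] <- 1; v
    } else {
      v <- stats::rgamma(m, 1); v / sum(v)
    }
    data.frame(gene_id = g, isoform_id = paste0(g, ".", seq_len(m)),
               sample_id = sample_id, proportion = p)
  }, genes, sizes, SIMPLIFY = FALSE)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("proportion_table", "data.frame")
  out
}

# Eq.-2 style statistic computed independently (plain loops over a merged
# data frame), used to cross-check proportion_difference().
oracle_prop_diff <- function(P_a, P_b) {
  m <- merge(as.data.frame(P_a), as.data.frame(P_b),
             by = c("gene_id", "isoform_id", "sample_id"))
  terms <- tapply(abs(m$proportion.x - m$proportion.y), m$gene_id, mean)
  mean(terms)
}

# Permutation oracle for the one-way ANOVA p-value of a single gene.
oracle_perm_anova_p <- function(x, grp, n_perm = 10000) {
  fstat <- function(x, grp) {
    gm <- tapply(x, grp, mean); n <- tapply(x, grp, length)
    ssb <- sum(n * (gm - mean(x))^2)
    ssw <- sum((x - gm[grp])^2)
    k <- length(gm)
    (ssb / (k - 1)) / (ssw / (length(x) - k))
  }
  f0 <- fstat(x, grp)
  hits <- 0L
  for (i in seq_len(n_perm))
    if (fstat(x, sample(grp)) >= f0) hits <- hits + 1L
  (hits + 1) / (n_perm + 1)
}

# Tiny identifiable test panel shared by several test files.
make_fli1 <- function() {
  g <- gene_model("FLI1", c("NM_001271012", "NM_001167681",
                            "NM_001271010", "NM_002017"))
  probes <- list(
    probe("max", "FLI1", g$isoform_ids),
    probe("p1", "FLI1", "NM_001271012"),
    probe("p2", "FLI1", "NM_001167681"),
    probe("p3", "FLI1", "NM_001271010"))
  list(gene = g, probes = probes,
       inc = build_incidence_matrix(g, probes))
}
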