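hk_panel <- function() {
  # two housekeeping genes are enough to exercise the geometry
  genes <- c(lapply(c("HKA", "HKB"), function(h)
    gene_model(h, paste0(h, ".1"))),
    list(gene_model("G1", c("G1.1", "G1.2"))))
  probes <- c(lapply(c("HKA", "HKB"), function(h)
    probe(paste0(h, "_hk"), h, paste0(h, ".1"), "housekeeping")),
    design_max_probe_panel(gene_model("G1", c("G1.1", "G1.2"))))
  probe_panel(genes, probes)
}

test_that("housekeeping normalization scales to the cohort geometric mean", {
  panel <- hk_panel()
  # identical housekeeping counts: nothing changes
  C <- matrix(c(10, 40, 7, 3,
                10, 40, 9, 5), nrow = 4,
              dimnames = list(c("HKA_hk", "HKB_hk", "G1_max", "G1_p1"),
                              c("s1", "s2")))
  norm <- housekeeping_normalize(probe_counts(C), panel)
  expect_true(norm$normalized)
  expect_equal(unname(attr(norm, "scale_factors")), c(1, 1))
  expect_equal(norm$counts, C)

  # sample B geomean = 2x sample A's: factors (sqrt2, sqrt2/2)
  C2 <- C
  C2[1:2, "s2"] <- 2 * C2[1:2, "s1"]
  norm2 <- housekeeping_normalize(probe_counts(C2), panel)
  expect_equal(unname(attr(norm2, "scale_factors")),
               c(sqrt(2), sqrt(2) / 2))
  # across-sample geomean of housekeeping signal is invariant
  g_before <- exp(mean(log(apply(C2[1:2, ], 2, function(x) exp(mean(log(x)))))))
  g_after <- exp(mean(log(apply(norm2$counts[1:2, ], 2,
                                function(x) exp(mean(log(x)))))))
  expect_equal(g_after, g_before)
})

test_that("normalization error paths name the offender and refuse re-runs", {
  panel <- hk_panel()
  C <- matrix(1, 4, 1, dimnames = list(c("HKA_hk", "HKB_hk", "G1_max",
                                         "G1_p1"), "s1"))
  C["HKB_hk", 1] <- 0
  expect_error(housekeeping_normalize(probe_counts(C), panel), "HKB.*s1")
  C[] <- 1
  norm <- housekeeping_normalize(probe_counts(C), panel)
  expect_error(housekeeping_normalize(norm, panel), "twice")
  expect_error(housekeeping_normalize(
    probe_counts(C[3:4, , drop = FALSE]), panel), "HKA")
})

test_that("default housekeeping set matches the ten-gene panel", {
  expect_length(housekeeping_genes, 10)
  expect_true(all(c("TAF5L", "KHDRBS1", "KIAA1539") %in% housekeeping_genes))
})

test_that("deconvolution solves the max-probe system exactly", {
  fli1 <- make_fli1()
  fit <- deconvolve_gene(c(10, 2, 3, 1), fli1$inc)
  # residual isoform = max probe minus the three isoform-specific probes
  expect_equal(unname(fit$values), c(2, 3, 1, 4), tolerance = 1e-9)
  expect_equal(fit$values[["NM_002017"]], 10 - (2 + 3 + 1), tolerance = 1e-9)
  expect_lt(fit$objective, 1e-18)
  expect_true(fit$identifiable)

  expect_equal(unname(deconvolve_gene(c(0, 0, 0, 0), fli1$inc)$values),
               rep(0, 4))

  # inconsistent system: known minimizer (1.5, 0), objective 0.5
  A <- rbind(c(1, 1), c(1, 0))
  fit2 <- deconvolve_gene(c(1, 2), A)
  expect_equal(unname(fit2$values), c(1.5, 0), tolerance = 1e-9)
  expect_equal(fit2$objective, 0.5, tolerance = 1e-9)

  expect_error(deconvolve_gene(c(1, 2, 3), A), "rows")
})

test_that("NNLS matches grid and QP oracles on small instances", {
  skip_if_not_installed("pracma")
  set.seed(1)
  for (i in 1:60) {
    n <- sample(2:4, 1)
    g <- gene_model("G", paste0("i", seq_len(n)))
    probes <- design_max_probe_panel(g)
    # occasionally over-determine the design with an extra pair probe
    if (runif(1) < 0.3 && n >= 3)
      probes <- c(probes, list(probe("extra", "G",
                                     sample(g$isoform_ids, 2))))
    A <- build_incidence_matrix(g, probes)$A
    y <- rexp(nrow(A), 1 / 50)
    fit <- nnls_fit(A, y)
    qp <- pracma::lsqnonneg(A + 0, y)
    expect_lt(abs(fit$objective - qp$resid.norm), 1e-6)
    if (ncol(A) == 2) {
      grid <- oracle_nnls_grid(A, y)
      expect_lt(fit$objective, grid$objective + 1e-6)
    }
  }
  # the grid oracle also covers a rank-deficient 2-isoform design
  A1 <- matrix(c(1, 1), 1, 2)
  fit1 <- nnls_fit(A1, 8)
  expect_lt(fit1$objective, oracle_nnls_grid(A1, 8)$objective + 1e-6)
})

test_that("noiseless probe signals are inverted exactly and scale linearly", {
  set.seed(2)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    g <- gene_model("G", paste0("i", seq_len(n)))
    inc <- build_incidence_matrix(g, design_max_probe_panel(g))
    x_true <- rexp(n, 1 / 100)
    y <- drop(inc$A %*% x_true)
    fit <- deconvolve_gene(y, inc)
    expect_equal(unname(fit$values), x_true, tolerance = 1e-8)
    # scale equivariance
    c_scale <- runif(1, 0.1, 10)
    fit_c <- deconvolve_gene(c_scale * y, inc)
    expect_equal(unname(fit_c$values), c_scale * x_true, tolerance = 1e-8)
  }
})

test_that("rank-deficient designs still return a minimizer, flagged", {
  g <- gene_model("G", c("i1", "i2"))
  inc <- build_incidence_matrix(g, probe("p", "G", c("i1", "i2")))
  fit <- deconvolve_gene(8, inc)
  expect_false(fit$identifiable)
  expect_equal(sum(fit$values), 8, tolerance = 1e-9)  # group sum constrained
  expect_lt(fit$objective, 1e-18)
})

test_that("gene expression is the sum of isoform expressions", {
  expect_equal(gene_expression_from_isoforms(c(2, 3, 1, 4)), 10)
  expect_equal(gene_expression_from_isoforms(numeric(4)), 0)
  expect_equal(gene_expression_from_isoforms(5), 5)
})

test_that("log transform is base-2 log(x+1) and guards its domain", {
  M <- expr_matrix(matrix(c(0, 1, 3, 7), 2, 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))),
                   "gene", "raw")
  L <- log_transform(M)
  expect_equal(unname(L$values), matrix(c(0, 1, 2, 3), 2, 2))
  expect_identical(L$transform, "log1p")
  expect_error(log_transform(L), "already")
  # monotone bijection: sorted order preserved
  x <- sort(runif(50, 0, 1000))
  expect_true(all(diff(log(x + 1, 2)) > 0))
})

test_that("quantify_panel conserves gene totals and handles edge cases", {
  panel <- hk_panel()
  C <- matrix(c(10, 40, 12, 5,
                10, 40, 12, 5), nrow = 4,
              dimnames = list(c("HKA_hk", "HKB_hk", "G1_max", "G1_p1"),
                              c("s1", "s2")))
  norm <- housekeeping_normalize(probe_counts(C), panel)
  q <- quantify_panel(norm, panel)
  # identical samples -> identical columns
  expect_equal(q$isoform$values[, "s1"], q$isoform$values[, "s2"])
  # conservation: gene = sum of isoforms (pre-log), exactly
  iso_sums <- colSums(q$isoform$values[c("G1.1", "G1.2"), ])
  expect_equal(iso_sums, q$gene$values["G1", ])
  expect_equal(unname(q$isoform$values[c("G1.1", "G1.2"), "s1"]), c(5, 7))
  # raw counts refused
  expect_error(quantify_panel(probe_counts(C), panel), "normalized")
  # a gene with no probes in the matrix is skipped with a warning
  C2 <- C[1:2, , drop = FALSE]
  norm2 <- housekeeping_normalize(probe_counts(C2), panel)
  expect_warning(q2 <- quantify_panel(norm2, panel), "G1.*skipped")
  expect_false("G1" %in% rownames(q2$gene$values))
})

test_that("non-identifiable genes report group sums, members as NA", {
  genes <- list(gene_model("HKA", "HKA.1"),
                gene_model("G", c("i1", "i2", "i3")))
  probes <- list(probe("HKA_hk", "HKA", "HKA.1", "housekeeping"),
                 probe("pa", "G", c("i1", "i2", "i3")),
                 probe("pb", "G", "i1"))
  panel <- probe_panel(genes, probes)
  C <- matrix(c(10, 9, 4), 3, 1,
              dimnames = list(c("HKA_hk", "pa", "pb"), "s1"))
  q <- quantify_panel(housekeeping_normalize(probe_counts(C), panel), panel)
  expect_equal(unname(q$isoform$values["i1", "s1"]), 4, tolerance = 1e-9)
  expect_true(all(is.na(q$isoform$values[c("i2", "i3"), "s1"])))
  expect_equal(unname(q$gene$values["G", "s1"]), 9, tolerance = 1e-9)
  # group-level collapse makes the pair estimable as one feature
  M <- expr_matrix(matrix(c(4, 2, 3), 3, 1,
                          dimnames = list(c("i1", "i2", "i3"), "s1")),
                   "isoform", "raw")
  Mg <- collapse_to_groups(M, q$identifiability)
  expect_equal(unname(Mg$values["i2+i3", "s1"]), 5)
})

test_that("replicate collapse averages normalized counts per sample", {
  C <- matrix(c(2, 10, 4, 20, 6, 30), nrow = 2,
              dimnames = list(c("p1", "p2"),
                              c("s1_rep1", "s1_rep2", "s2_rep1")))
  col <- collapse_replicates(probe_counts(C))
  expect_identical(colnames(col$counts), c("s1", "s2"))
  expect_equal(unname(col$counts[, "s1"]), c(3, 15))
  expect_equal(unname(col$counts[, "s2"]), c(6, 30))
})
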