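mk_expr <- function(V, level = "gene", transform = "raw") {
  expr_matrix(V, level, transform)
}

test_that("per-sample Spearman is rank-exact and monotone-invariant", {
  V <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(paste0("f", 1:5), "s1"))
  W <- matrix(c(2, 1, 4, 3, 5), 5, 1, dimnames = list(paste0("f", 1:5), "s1"))
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4
  sp <- spearman_per_sample(mk_expr(V), mk_expr(W))
  expect_equal(sp$rho, 0.8)
  # monotone transform of either side changes nothing
  sp2 <- spearman_per_sample(mk_expr(V^2), mk_expr(W))
  sp3 <- spearman_per_sample(log_transform(mk_expr(V)), mk_expr(W))
  expect_equal(sp2$rho, 0.8)
  expect_equal(sp3$rho, 0.8)
  # perfect agreement / reversal
  expect_equal(spearman_per_sample(mk_expr(V), mk_expr(V * 10 + 2))$rho, 1)
  Wrev <- matrix(rev(V), 5, 1, dimnames = dimnames(V))
  expect_equal(spearman_per_sample(mk_expr(V), mk_expr(Wrev))$rho, -1)
  # constant vector: NA with warning
  Vc <- matrix(3, 5, 1, dimnames = dimnames(V))
  expect_warning(spc <- spearman_per_sample(mk_expr(V), mk_expr(Vc)),
                 "constant")
  expect_true(is.na(spc$rho))
  expect_error(spearman_per_sample(mk_expr(V),
                                   mk_expr(V, level = "isoform")), "level")
})

test_that("pooled correlation pools dots, not per-sample coefficients", {
  set.seed(20)
  V <- matrix(runif(30, 0, 100), 15, 2,
              dimnames = list(paste0("f", 1:15), c("s1", "s2")))
  expect_equal(pooled_correlation(mk_expr(V), mk_expr(V)), 1)
  # two samples each perfectly correlated, but with opposite offsets:
  # pooled R_s drops below the per-sample mean (which is 1)
  a <- matrix(c(1:5, 1:5), 5, 2, dimnames = list(paste0("f", 1:5),
                                                 c("s1", "s2")))
  b <- a; b[, 1] <- a[, 1] + 100; b[, 2] <- a[, 2]
  # per-sample both 1; pooled mixes offset groups
  ps <- spearman_per_sample(mk_expr(a), mk_expr(b))
  expect_equal(ps$rho, c(1, 1))
  expect_lt(pooled_correlation(mk_expr(a), mk_expr(b)), 1)
  # independent noise: near zero
  X <- matrix(runif(10000), 1000, 10,
              dimnames = list(paste0("f", 1:1000), paste0("s", 1:10)))
  Y <- matrix(runif(10000), 1000, 10, dimnames = dimnames(X))
  expect_lt(abs(pooled_correlation(mk_expr(X), mk_expr(Y))), 0.1)
})

test_that("low-expression subset takes the bottom third per platform", {
  V <- matrix(1:9, 9, 1, dimnames = list(paste0("f", 1:9), "s1"))
  expect_setequal(low_expression_subset(mk_expr(V), mk_expr(V)),
                  c("f1", "f2", "f3"))
  # floor convention: N = 10 -> 3 per platform
  V10 <- matrix(1:10, 10, 1, dimnames = list(paste0("f", 1:10), "s1"))
  expect_length(low_expression_subset(mk_expr(V10), mk_expr(V10)), 3)
  # anti-correlated ranks: disjoint bottom thirds
  Vr <- matrix(9:1, 9, 1, dimnames = dimnames(V))
  expect_length(low_expression_subset(mk_expr(V), mk_expr(Vr)), 0)
  # idempotent under monotone rescaling
  expect_identical(low_expression_subset(mk_expr(V), mk_expr(V)),
                   low_expression_subset(mk_expr(V^3), log_transform(mk_expr(V))))
})

test_that("fold changes enumerate target x non-target pairs on log scale", {
  V <- matrix(c(3, 3, 1, 1, 2, 2), 2, 3,
              dimnames = list(c("g1", "g2"), c("t1", "o1", "o2")))
  M <- mk_expr(V, transform = "log1p")
  labels <- data.frame(sample_id = c("t1", "o1", "o2"),
                       tissue = c("breast", "lung", "colon"))
  fc <- fold_change_pairs(M, labels, "breast")
  expect_equal(nrow(fc), 1 * 2 * 2)  # |target| x |non-target| x genes
  expect_equal(fc$fold_change[fc$other_sample == "o1"], c(2, 2))
  expect_equal(fc$fold_change[fc$other_sample == "o2"], c(1, 1))
  # identical columns -> zero fold change
  Vid <- V; Vid[, "o1"] <- V[, "t1"]
  fcid <- fold_change_pairs(mk_expr(Vid, transform = "log1p"), labels,
                            "breast")
  expect_true(all(fcid$fold_change[fcid$other_sample == "o1"] == 0))
  # counting on a larger design
  set.seed(21)
  V2 <- matrix(runif(5 * 50), 5, 50,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:50)))
  lab2 <- data.frame(sample_id = paste0("s", 1:50),
                     tissue = rep(c("breast", "other"), c(2, 48)))
  fc2 <- fold_change_pairs(mk_expr(V2, transform = "log1p"), lab2, "breast")
  expect_equal(nrow(fc2), 2 * 48 * 5)
  expect_error(fold_change_pairs(mk_expr(V, transform = "log1p"),
                                 labels[-1, ], "breast"), "missing")
  expect_error(fold_change_pairs(mk_expr(V), labels, "breast"), "log1p")
})

test_that("one-way ANOVA ranks by p with deterministic tie-break", {
  # two groups, identical values: F = 0, p = 1
  V <- matrix(c(1, 2, 1, 2), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  labels <- data.frame(sample_id = paste0("s", 1:4),
                       tissue = c("a", "a", "b", "b"))
  de <- anova_de(mk_expr(V), labels, k_top = 1)
  expect_equal(de$table$F, 0)
  expect_equal(de$table$p_value, 1)
  # a clearly shifted gene ranks first; ties break lexicographically
  set.seed(22)
  V2 <- matrix(rnorm(5 * 12, 10, 1), 5, 12,
               dimnames = list(c("gE", "gA", "gC", "gB", "gD"),
                               paste0("s", 1:12)))
  V2["gC", 7:12] <- V2["gC", 7:12] + 8
  lab2 <- data.frame(sample_id = paste0("s", 1:12),
                     tissue = rep(c("x", "y"), each = 6))
  de2 <- anova_de(mk_expr(abs(V2)), lab2, k_top = 3)
  expect_identical(de2$table$gene_id[1], "gC")
  expect_identical(de2$table$rank, 1:5)
  # single-sample groups are dropped with a warning
  lab3 <- rbind(lab2, data.frame(sample_id = "s13", tissue = "z"))
  V3 <- cbind(V2, s13 = rnorm(5, 10))
  expect_warning(de3 <- anova_de(mk_expr(abs(V3)), lab3), "z")
  expect_identical(de3$groups, c("x", "y"))
  expect_error(suppressWarnings(
    anova_de(mk_expr(abs(V2)),
             data.frame(sample_id = paste0("s", 1:12),
                        tissue = c("a", rep("b", 11))))),
    "fewer than 2")
})

test_that("ANOVA p-values match a permutation oracle on a small instance", {
  set.seed(23)
  grp <- factor(rep(c("a", "b", "c"), each = 4))
  for (shift in c(0, 1.5)) {
    x <- rnorm(12) + shift * (grp == "b")
    V <- matrix(abs(x) + 1, 1, 12,
                dimnames = list("g1", paste0("s", 1:12)))
    labels <- data.frame(sample_id = paste0("s", 1:12), tissue = grp)
    p_pkg <- anova_de(mk_expr(V), labels)$table$p_value
    p_perm <- oracle_perm_anova_p(V[1, ], grp, n_perm = 10000)
    # Monte-Carlo + F-approximation agreement
    expect_lt(abs(p_pkg - p_perm), 0.03)
  }
})

test_that("identical platforms give a degenerate all-agree report", {
  set.seed(24)
  cfg <- simulation_config(n_genes = 12, n_samples = 12, seed = 24)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  ann <- panel_annotation(truth)
  M <- truth$expression
  rep <- platform_agreement_report(list(a = M, b = M), ann, truth$labels)
  pair <- rep$pairs$a_vs_b
  expect_true(all(pair$spearman_isoform$rho == 1))
  expect_true(all(pair$spearman_gene$rho == 1))
  expect_equal(pair$pooled_isoform, 1)
  expect_true(all(pair$proportion_diff$d == 0))
  # serialization writes the per-pair tables
  dir <- withr::local_tempdir()
  write_concordance_report(rep, dir)
  expect_true(file.exists(file.path(dir, "a_vs_b",
                                    "spearman_per_sample.tsv")))
  expect_true(file.exists(file.path(dir, "anova_a.tsv")))
})
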