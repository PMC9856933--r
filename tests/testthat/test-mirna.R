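cmat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}

test_that("expression filter applies both count rules and is idempotent", {
  m <- cmat(lowmax = c(3, 3, 3, 3),      # sum 12 but max < 5
            kept = c(11, 0, 0, 0),       # sum 11, max 11
            boundary = c(5, 5, 0, 0),    # sum exactly 10: excluded
            strong = c(20, 30, 1, 0))
  f <- filter_expressed(m)
  expect_setequal(rownames(f), c("kept", "strong"))
  expect_identical(filter_expressed(f), f)
  perm <- m[c(3, 1, 4, 2), ]
  expect_setequal(rownames(filter_expressed(perm)), rownames(f))
})

test_that("normalization is scale-invariant and the DE flags control the null", {
  set.seed(21)
  counts <- matrix(rnbinom(200 * 12, mu = 100, size = 10), 200, 12,
                   dimnames = list(sprintf("m%03d", 1:200),
                                   sprintf("s%02d", 1:12)))
  groups <- rep(c("h", "o"), each = 6)
  de <- normalize_and_de(counts, groups)
  expect_false(any(de$significant))       # same distribution in both groups
  # doubling every count of one sample leaves its normalized values intact
  # up to the depth-dependent precision weights inside the trimmed mean
  doubled <- counts; doubled[, 1] <- doubled[, 1] * 2L
  l1 <- attr(normalize_and_de(counts, groups), "logcpm")[, 1]
  l2 <- attr(normalize_and_de(doubled, groups), "logcpm")[, 1]
  expect_equal(l1, l2, tolerance = 1e-3)
  expect_error(normalize_and_de(cbind(counts[, 1:3] * 0, counts[, 4:12]),
                                groups), "library")
})

test_that("true fourfold miRNA changes are flagged with family-wise error control", {
  set.seed(22)
  n_rep <- 15
  sens <- numeric(n_rep); any_fp <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    mu <- matrix(rep(exp(rnorm(150, log(80), 1)), 40), 150, 40)
    # 30 true DE at |log2FC| = 2, balanced up/down as in real group contrasts
    mu[1:15, 1:20] <- mu[1:15, 1:20] * 4
    mu[16:30, 1:20] <- mu[16:30, 1:20] / 4
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), 150, 40,
                     dimnames = list(sprintf("m%03d", 1:150),
                                     sprintf("s%02d", 1:40)))
    de <- normalize_and_de(counts, rep(c("h", "o"), each = 20))
    sens[r] <- mean(de$significant[1:30])
    any_fp[r] <- any(de$p_holm[31:150] < 0.05)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(any_fp), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("precursor expression averages mature forms", {
  m <- cmat(`miR-1-5p` = c(2, 4), `miR-1-3p` = c(4, 8), `miR-2-5p` = c(1, 1),
            orphan = c(9, 9))
  map <- data.frame(mature_id = c("miR-1-5p", "miR-1-3p", "miR-2-5p"),
                    pre_mirna_id = c("pre-1", "pre-1", "pre-2"))
  expect_message(pre <- premirna_expression(m, map), "without precursor")
  expect_equal(unname(pre["pre-1", ]), c(3, 6))
  expect_equal(unname(pre["pre-2", ]), c(1, 1))    # single mature: identity
  perm <- premirna_expression(m[c(3, 2, 1, 4), ], map)
  expect_equal(perm, pre)
  expect_error(premirna_expression(
    m, rbind(map, data.frame(mature_id = "miR-1-5p", pre_mirna_id = "pre-9"))),
    "more than one")
})

test_that("interaction integration applies all four published predicates", {
  set.seed(23)
  n <- 30
  z <- rnorm(n) + rep(c(2, 0), each = n / 2)      # DE miRNA, lfc 2
  mirna_expr <- rbind(`pre-1` = z, `pre-2` = rnorm(n))
  colnames(mirna_expr) <- sprintf("s%02d", 1:n)
  gene_expr <- rbind(T1 = 7 - z + rnorm(n, 0, 0.3),  # strong anti-correlation
                     N1 = rnorm(n, 7))
  colnames(gene_expr) <- colnames(mirna_expr)
  groups <- rep(c("h", "o"), each = n / 2)
  mde <- welch_de(mirna_expr, groups)
  mde_tab <- data.frame(mirna_id = mde$gene_id, log2fc = mde$log2fc,
                        p_holm = mde$p_holm)
  gde <- welch_de(gene_expr, groups)
  gde_tab <- data.frame(gene_id = gde$gene_id, log2fc = gde$log2fc,
                        p_holm = gde$p_holm)
  db <- data.frame(pre_mirna_id = "pre-1", gene_id = "T1", source = "db1")
  net <- integrate_interactions(mirna_expr, mde_tab, gene_expr, gde_tab, db)
  expect_equal(nrow(net), 1)
  expect_lt(net$pcc, -0.9)
  # identical signal absent from the database is dropped
  db2 <- data.frame(pre_mirna_id = "pre-2", gene_id = "N1", source = "db1")
  expect_equal(nrow(integrate_interactions(mirna_expr, mde_tab, gene_expr,
                                           gde_tab, db2)), 0)
  empty <- integrate_interactions(mirna_expr, mde_tab, gene_expr, gde_tab,
                                  db[0, ])
  expect_equal(nrow(empty), 0)
  # every retained record satisfies the four predicates on generated data
  mc <- gen_mirna_cohort(sim_config(seed = 24,
                                    n_samples_per_group = c(h = 20, o = 20)))
  de <- normalize_and_de(filter_expressed(mc$counts), mc$groups)
  pre <- premirna_expression(attr(de, "logcpm"), mc$mature_to_pre)
  pde <- welch_de(pre, mc$groups)
  pde_tab <- data.frame(mirna_id = pde$gene_id, log2fc = pde$log2fc,
                        p_holm = pde$p_holm)
  gde2 <- welch_de(mc$gene_expr, mc$groups)
  gde2_tab <- data.frame(gene_id = gde2$gene_id, log2fc = gde2$log2fc,
                         p_holm = gde2$p_holm)
  net2 <- integrate_interactions(pre, pde_tab, mc$gene_expr, gde2_tab, mc$db)
  expect_gt(nrow(net2), 0)
  in_db <- paste(net2$pre_mirna_id, net2$gene_id) %in%
    paste(mc$db$pre_mirna_id, mc$db$gene_id)
  expect_true(all(in_db))
  expect_true(all(abs(net2$mirna_log2fc) > 1))
  expect_true(all(abs(net2$gene_log2fc) > 1))
  expect_true(all(net2$pcc < 0))
  expect_true(all(net2$p_adj < 0.01))
})

test_that("fold-change concordance matches its closed form", {
  set.seed(25)
  b <- setNames(rnorm(2000, 0, 1), sprintf("m%04d", 1:2000))
  expect_equal(suppressWarnings(logfc_concordance(b, b)), 1)
  a <- 2 * b + rnorm(2000, 0, 1)
  # R^2 -> var(2b) / (var(2b) + sigma^2) = 4 / 5
  expect_equal(logfc_concordance(a, b), 0.8, tolerance = 0.05)
  noise <- setNames(residuals(lm(rnorm(2000) ~ b)), names(b))
  expect_lt(logfc_concordance(noise, b), 0.01)
  expect_error(logfc_concordance(setNames(rep(1, 5), letters[1:5]),
                                 setNames(1:5, letters[1:5])), "zero-variance")
  expect_error(logfc_concordance(b[1:2], b[1:2]), "3 shared")
})
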