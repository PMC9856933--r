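base_variant <- function(...) {
  v <- data.frame(patient_id = "p1", chrom = "chr1", pos = 100L,
                  ref = "C", alt = "A", gene = "TP53", class = "missense",
                  t_depth = 20L, t_af = 0.4, n_depth = 10L, n_af = 0,
                  pop_af = 0, coding = TRUE, synonymous = FALSE,
                  rna_depth = NA_integer_, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) v[[nm]] <- mods[[nm]]
  v
}

test_that("somatic filter enforces every rule at its boundary", {
  keep <- base_variant()
  expect_equal(nrow(filter_somatic(keep)), 1)
  cases <- list(
    t_depth = base_variant(t_depth = 13L),
    n_depth = base_variant(n_depth = 7L),
    t_af = base_variant(t_af = 0.29),
    n_af = base_variant(n_af = 0.01),
    pop_af = base_variant(pop_af = 0.002),
    coding = base_variant(coding = FALSE),
    synonymous = base_variant(synonymous = TRUE),
    rna_depth = base_variant(rna_depth = 4L))
  for (rule in names(cases)) {
    out <- filter_somatic(cases[[rule]])
    expect_equal(nrow(out), 0)
    expect_equal(attr(out, "rejections")$rule, rule)
  }
  # boundary keeps: exactly at each threshold
  expect_equal(nrow(filter_somatic(base_variant(t_depth = 14L, n_depth = 8L,
                                                t_af = 0.3, rna_depth = 5L))), 1)
  # idempotent and a subset of the input
  vc <- gen_variant_cohort(sim_config(seed = 41,
                                      n_samples_per_group = c(h = 2, o = 2),
                                      mutations_per_patient = 50))
  som <- filter_somatic(vc$variants)
  expect_true(all(som$variant_id %in% vc$variants$variant_id))
  expect_setequal(som$variant_id, vc$truth$pass_ids)
  som2 <- filter_somatic(som)
  expect_equal(nrow(som2), nrow(som))
  expect_equal(nrow(attr(som2, "rejections")), 0)
  # a relaxed normal-AF tolerance readmits low-level noise
  expect_equal(nrow(filter_somatic(base_variant(n_af = 0.01),
                                   n_af_tol = 0.02)), 1)
})

test_that("alteration aggregation counts patients once per category", {
  groups <- setNames(rep(c("h", "o"), c(4, 2)), sprintf("p%d", 1:6))
  alts <- data.frame(
    patient_id = c("p1", "p1", "p2", "p5"),
    gene = "RB1",
    class = c("SV", "loss", "missense", "frameshift"),
    stringsAsFactors = FALSE)
  agg <- aggregate_alterations(alts, groups, "RB1")
  get <- function(grp, cat)
    agg[agg$group == grp & agg$category == cat, ]
  expect_equal(get("h", "total")$count, 2)     # p1 counted once
  expect_equal(get("h", "SV")$count, 1)
  expect_equal(get("h", "mutation")$count, 1)
  expect_equal(get("h", "mutation")$percent, 25)
  expect_equal(get("o", "mutation")$percent, 50)
  expect_equal(get("all", "total")$percent, 50)
  expect_warning(
    aggregate_alterations(rbind(alts, data.frame(patient_id = "ghost",
                                                 gene = "RB1",
                                                 class = "loss")),
                          groups, "RB1"), "no group")
})

test_that("biallelic mechanism comparison classifies allele pairs", {
  st <- data.frame(
    patient_id = sprintf("p%d", 1:6),
    allele1 = c("L", "MS", "WT", "FS", "L", "MS"),
    allele2 = c("L", "L", "MS", "FS", "MS", "MS"),
    group = c("h", "h", "h", "o", "o", "o"),
    stringsAsFactors = FALSE)
  bp <- biallelic_pattern(st)
  expect_equal(unname(bp$mechanism["p1"]), "one_mechanism")   # (L, L)
  expect_equal(unname(bp$mechanism["p2"]), "two_mechanism")   # (MS, L)
  expect_false("p3" %in% names(bp$mechanism))                 # intact allele
  expect_equal(sum(bp$table), 5)
  expect_equal(bp$fisher_p,
               fisher_oracle_two_sided(bp$table[1, 1], bp$table[1, 2],
                                       bp$table[2, 1], bp$table[2, 2]),
               tolerance = 1e-12)
})

test_that("tumor mutation burden is variants per megabase", {
  v <- data.frame(patient_id = rep("p1", 3000))
  expect_equal(unname(tmb(v, 3e9)), 1.0)
  expect_length(tmb(v[0, , drop = FALSE], 3e9), 0)
  v2 <- data.frame(patient_id = rep("outlier", 120))
  expect_equal(unname(tmb(v2, 1e6)), 120)     # the hypermutator magnitude
})

test_that("context matrix applies the pyrimidine strand rule and conserves counts", {
  v <- data.frame(patient_id = "p1", chrom = "chr1", pos = 10L,
                  ref = "G", alt = "T", stringsAsFactors = FALSE)
  ctx <- data.frame(chrom = "chr1", pos = 10L, triplet = "AGA",
                    stringsAsFactors = FALSE)
  cm <- context_matrix(v, ctx)
  expect_equal(cm["T[C>A]T", "p1"], 1L)       # revcomp of G>T in AGA
  expect_equal(sum(cm), 1L)
  # non-SNV records are ignored
  v2 <- rbind(v, data.frame(patient_id = "p1", chrom = "chr1", pos = 11L,
                            ref = "GT", alt = "G"))
  expect_equal(sum(context_matrix(v2, ctx)), 1L)
  # conservation on generated data
  vc <- gen_variant_cohort(sim_config(seed = 42,
                                      n_samples_per_group = c(h = 2, o = 2),
                                      mutations_per_patient = 200))
  som <- filter_somatic(vc$variants)
  cmg <- context_matrix(som, vc$contexts)
  expect_equal(colSums(cmg),
               setNames(as.numeric(table(som$patient_id)[colnames(cmg)]),
                        colnames(cmg)))
})

test_that("signature refitting recovers pure profiles and matches grid search", {
  catalog <- synthetic_signature_catalog(3, 5)
  pure <- matrix(catalog[, 2] * 1000, 96, 1,
                 dimnames = list(rownames(catalog), "p1"))
  fs <- fit_signatures(pure, catalog)
  expect_equal(fs$exposures["SBS_syn02", "p1"], 1000, tolerance = 1e-6)
  expect_equal(sum(fs$exposures[-2, "p1"]), 0, tolerance = 1e-6)
  expect_gte(fs$reconstruction_cosine[["p1"]], 0.999)
  # a profile concentrated far from every signature finds no candidate
  noise <- matrix(0, 96, 1, dimnames = list(rownames(catalog), "p1"))
  noise[which.min(rowSums(catalog)), 1] <- 100
  fn <- fit_signatures(noise, catalog)
  expect_true(fn$no_candidate[["p1"]])
  expect_equal(sum(fn$exposures), 0)
  # NNLS beats (or ties) a dense grid of non-negative two-signature fits
  set.seed(43)
  y <- 600 * catalog[, 1] + 400 * catalog[, 2] + runif(96, 0, 2)
  obs <- matrix(y, 96, 1, dimnames = list(rownames(catalog), "p1"))
  fg <- fit_signatures(obs, catalog[, 1:2])
  resid_fit <- sum((as.vector(catalog[, 1:2] %*% fg$exposures[, 1]) - y)^2)
  grid <- expand.grid(a = seq(0, 1200, by = 10), b = seq(0, 1200, by = 10))
  resid_grid <- min(vapply(seq_len(nrow(grid)), function(i)
    sum((grid$a[i] * catalog[, 1] + grid$b[i] * catalog[, 2] - y)^2), 0))
  expect_lte(resid_fit, resid_grid + 1e-8)
  expect_true(all(fg$exposures >= 0))
})
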