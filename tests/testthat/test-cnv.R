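toy_genes <- function() data.frame(
  gene_id = c("gA", "gB", "gC"), chrom = c("chr1", "chr1", "chr2"),
  start = c(100L, 500L, 100L), end = c(200L, 600L, 200L),
  stringsAsFactors = FALSE)

test_that("segment projection applies the lowest-CN, artifact and missingness rules", {
  segs <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr2", "chr1"),
    start = c(0L, 150L, 0L, 0L, 0L, 0L),
    end = c(160L, 700L, 300L, 700L, 300L, 700L),
    copy_number = c(1L, 3L, 2L, 2L, 128L, 2L),
    stringsAsFactors = FALSE)
  cn <- segments_to_genes(segs, toy_genes(), max_missing_fraction = 0.99)
  expect_equal(cn["gA", "p1"], 1L)        # spans CN 1 and CN 3: lowest wins
  expect_equal(cn["gB", "p1"], 3L)
  expect_true(is.na(cn["gC", "p2"]))      # only a CN = 128 artifact covers it
  expect_true(is.na(cn["gC", "p3"]))      # no overlap at all
  # default missingness rule: gC absent in 2/3 patients > 1/3 is dropped
  cn_strict <- segments_to_genes(segs, toy_genes())
  expect_false("gC" %in% rownames(cn_strict))
  bad <- segs; bad$end[1] <- bad$start[1]
  expect_error(segments_to_genes(bad, toy_genes()), "malformed")
})

test_that("segment projection equals the brute-force interval scan", {
  set.seed(31)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:50),
                      chrom = sample(c("chr1", "chr2"), 50, TRUE),
                      start = sample.int(9000, 50))
  genes$end <- genes$start + 100L
  segs <- data.frame(patient_id = rep(sprintf("p%02d", 1:8), each = 25),
                     chrom = sample(c("chr1", "chr2"), 200, TRUE),
                     start = sample.int(9000, 200, replace = TRUE))
  segs$end <- segs$start + sample.int(800, 200, replace = TRUE)
  segs$copy_number <- sample(c(0:6, 128L), 200, replace = TRUE)
  expect_identical(segments_to_genes(segs, genes),
                   brute_force_gene_cn(segs, genes))
})

test_that("event classification follows the copy-number mapping", {
  cn <- matrix(c(0L, 1L, 2L, 3L, 5L, 6L, 9L, NA), 8, 1,
               dimnames = list(sprintf("g%d", 1:8), "p1"))
  ev <- classify_events(cn)
  expect_equal(unname(ev[, 1]),
               c("homdel", "hetdel", "normal", "gain", "gain", "amp", "amp",
                 NA))
  # configurable amplification boundary
  ev4 <- classify_events(cn, amp_min = 4L)
  expect_equal(unname(ev4[c(4, 5), 1]), c("gain", "amp"))
})

test_that("penetrance counts events among informative patients only", {
  ev <- matrix("normal", 1, 10, dimnames = list("g1", sprintf("p%02d", 1:10)))
  ev[1, 1:4] <- "hetdel"; ev[1, 5] <- "homdel"
  groups <- setNames(rep("h", 10), colnames(ev))
  groups[9:10] <- "o"
  pen <- cnv_penetrance(ev, groups)
  loss_h <- pen[pen$gene_id == "g1" & pen$group == "h" & pen$event == "loss", ]
  expect_equal(loss_h$frequency, 5 / 8)
  # with two missing h patients the denominator shrinks
  ev2 <- ev; ev2[1, 7:8] <- NA
  pen2 <- cnv_penetrance(ev2, groups)
  expect_equal(pen2[pen2$group == "h" & pen2$event == "loss", "frequency"],
               5 / 6)
  expect_equal(pen2[pen2$group == "h" & pen2$event == "loss", "n_informative"],
               6)
  # frequencies over the five elementary events sum to 1 within non-missing
  elem <- pen2[pen2$group == "h" &
                 pen2$event %in% c("homdel", "hetdel", "normal", "gain", "amp"), ]
  expect_equal(sum(elem$frequency), 1)
  # all-normal group has zero non-normal frequencies
  pen_o <- pen[pen$group == "o" & pen$event != "normal", ]
  expect_true(all(pen_o$frequency == 0))
})

test_that("group enrichment is one-tailed toward group h and matches the oracle", {
  ev <- matrix("normal", 1, 20, dimnames = list("g1", sprintf("p%02d", 1:20)))
  groups <- setNames(rep(c("h", "o"), each = 10), colnames(ev))
  ev[1, 1:9] <- "hetdel"; ev[1, 11] <- "homdel"   # 9/10 h vs 1/10 o
  en <- cnv_group_enrichment(ev, groups)
  loss <- en[en$direction == "loss", ]
  expect_equal(loss$p_value, fisher_oracle_greater(9, 1, 1, 9),
               tolerance = 1e-12)
  expect_true(loss$significant)
  # equal rates and o-dominant signals are not h-enriched
  ev_eq <- ev; ev_eq[1, ] <- rep(c("hetdel", "normal"), 10)
  expect_false(any(cnv_group_enrichment(ev_eq, groups)$significant))
  ev_rev <- ev; ev_rev[1, ] <- "normal"; ev_rev[1, 11:19] <- "hetdel"
  expect_false(any(cnv_group_enrichment(ev_rev, groups)$significant))
})

test_that("cytoband enrichment flags the loaded band and keeps the strongest event", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:500), chrom = "chr1",
                      start = (0:499) * 100L)
  genes$end <- genes$start + 50L
  bands <- data.frame(band_id = sprintf("chr1:b%02d", 1:20), chrom = "chr1",
                      start = (0:19) * 2500L, end = (1:20) * 2500L)
  # 20 significant loss genes all inside band 1 (which holds 25 genes)
  sig <- list(loss = sprintf("g%03d", 1:20))
  ce <- cytoband_enrichment(sig, genes, bands)
  expect_equal(ce$band_id, "chr1:b01")
  expect_equal(ce$event, "loss")
  p_raw <- fisher_oracle_greater(20, 5, 0, 475)
  expect_equal(ce$p_holm, min(1, p_raw * 20), tolerance = 1e-10)
  # empty significant sets produce no bands
  expect_equal(nrow(cytoband_enrichment(list(loss = character(0)),
                                        genes, bands)), 0)
  # when two events are enriched in one band, the more significant wins
  sig2 <- list(loss = sprintf("g%03d", 1:20), gain = sprintf("g%03d", 1:10))
  ce2 <- cytoband_enrichment(sig2, genes, bands)
  expect_equal(ce2$event[ce2$band_id == "chr1:b01"], "loss")
  # genes outside all bands are excluded with a warning
  genes_out <- rbind(genes, data.frame(gene_id = "gX", chrom = "chr9",
                                       start = 0L, end = 50L))
  expect_warning(cytoband_enrichment(sig, genes_out, bands), "outside")
})
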