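#' Simulate per-patient copy-number segments on a toy genome
#'
#' The toy genome has two chromosomes of 1 Mb, each split into ten 100 kb
#' cytobands; every band holds \code{n_genes_per_band} genes of 1 kb spaced
#' 5 kb apart (BED half-open, 0-based). Per patient, one segment per band is
#' emitted with an integer copy number: 2 by default, sporadic losses/gains
#' at \code{background_alteration_rate}, and the configured event in
#' \code{enriched_band_ids} at group-specific penetrance. Three deliberate
#' fixtures exercise downstream rules: the first patient's third band is
#' split into CN 1 / CN 3 segments with the boundary inside a gene (lowest
#' copy number wins), the second patient carries a CN = 128 artifact
#' segment, and the last band of chr2 is left uncovered in half the
#' patients so its genes are dropped by the missingness rule.
#'
#' @param cfg a [sim_config()].
#' @return List with \code{segments} (patient_id, chrom, start, end,
#'   copy_number), \code{genes} and \code{bands} (BED-like data.frames),
#'   \code{groups}, and \code{truth} (\code{enriched_bands},
#'   \code{enriched_event}).
#' @export
gen_cnv_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nh <- cfg$n_samples_per_group[["h"]]; no <- cfg$n_samples_per_group[["o"]]
  with_seed(sim_seed(cfg, 404L), {
    chroms <- c("chr1", "chr2")
    bands <- do.call(rbind, lapply(chroms, function(ch) {
      data.frame(band_id = sprintf("%s:b%02d", ch, 1:10), chrom = ch,
                 start = seq(0L, 9L) * 100000L,
                 end = seq(1L, 10L) * 100000L, stringsAsFactors = FALSE)
    }))
    genes <- do.call(rbind, lapply(seq_len(nrow(bands)), function(i) {
      st <- bands$start[i] + (seq_len(cfg$n_genes_per_band) - 1L) * 5000L
      data.frame(gene_id = sprintf("%s_g%02d", sub(":", "_", bands$band_id[i]),
                                   seq_len(cfg$n_genes_per_band)),
                 chrom = bands$chrom[i], start = st, end = st + 1000L,
                 band_id = bands$band_id[i], stringsAsFactors = FALSE)
    }))

    patients <- sprintf("LMS%03d", seq_len(nh + no))
    groups <- setNames(rep(c("h", "o"), c(nh, no)), patients)
    ev_cn <- if (cfg$enriched_event == "loss") 1L else 6L
    drop_band <- "chr2:b10"

    seg_list <- vector("list", length(patients))
    for (pi in seq_along(patients)) {
      pat <- patients[pi]
      cn <- rep(2L, nrow(bands))
      bg <- stats::runif(nrow(bands)) < cfg$background_alteration_rate
      cn[bg] <- sample(c(1L, 3L), sum(bg), replace = TRUE)
      pen <- if (groups[pat] == "h") cfg$band_penetrance_h else cfg$band_penetrance_o
      hit <- bands$band_id %in% cfg$enriched_band_ids & stats::runif(nrow(bands)) < pen
      cn[hit] <- ev_cn
      segs <- data.frame(patient_id = pat, chrom = bands$chrom,
                         start = bands$start, end = bands$end,
                         copy_number = cn, stringsAsFactors = FALSE)
      # uncovered band in alternating patients (missing genes downstream)
      if (pi %% 2 == 0) segs <- segs[bands$band_id != drop_band, ]
      if (pi == 1) {
        i <- which(bands$band_id == "chr1:b03")
        split_at <- bands$start[i] + 500L          # inside the band's 1st gene
        segs <- segs[!(segs$chrom == "chr1" & segs$start == bands$start[i]), ]
        segs <- rbind(segs,
                      data.frame(patient_id = pat, chrom = "chr1",
                                 start = bands$start[i], end = split_at,
                                 copy_number = 1L),
                      data.frame(patient_id = pat, chrom = "chr1",
                                 start = split_at, end = bands$end[i],
                                 copy_number = 3L))
      }
      if (pi == 2) {
        i <- which(bands$band_id == "chr1:b04")
        segs$copy_number[segs$chrom == "chr1" &
                           segs$start == bands$start[i]] <- 128L
      }
      seg_list[[pi]] <- segs
    }
    segments <- do.call(rbind, seg_list)
    rownames(segments) <- NULL

    list(segments = segments,
         genes = genes[, c("gene_id", "chrom", "start", "end")],
         bands = bands, groups = groups,
         truth = list(enriched_bands = cfg$enriched_band_ids,
                      enriched_event = cfg$enriched_event))
  })
}
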