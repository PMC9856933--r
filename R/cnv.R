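#' Project copy-number segments onto genes
#'
#' Segments with the CN = 128 artifact value are discarded; every
#' (gene, patient) cell receives the minimum copy number over the
#' patient's segments overlapping the gene (half-open 0-based intervals),
#' or missing (NA) when no segment overlaps; genes missing in more than
#' \code{max_missing_fraction} of the patients are dropped.
#'
#' @param segments data.frame \code{patient_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{copy_number}.
#' @param genes data.frame \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}.
#' @param artifact_cn copy number treated as an artifact (default 128).
#' @param max_missing_fraction missingness tolerance per gene (default 1/3).
#' @return Integer gene x patient matrix with NA for missing.
#' @export
segments_to_genes <- function(segments, genes, artifact_cn = 128L,
                              max_missing_fraction = 1 / 3) {
  bad <- segments$start >= segments$end | segments$copy_number < 0
  if (any(bad))
    stop("malformed segment interval(s) at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  segments <- segments[segments$copy_number != artifact_cn, , drop = FALSE]
  patients <- sort(unique(segments$patient_id))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  gr_segs <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1L, segments$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_segs)
  cn <- matrix(NA_integer_, nrow(genes), length(patients),
               dimnames = list(genes$gene_id, patients))
  if (length(hits) > 0) {
    gi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    key <- paste(genes$gene_id[gi], segments$patient_id[si], sep = "\r")
    mins <- tapply(segments$copy_number[si], key, min)
    parts <- strsplit(names(mins), "\r", fixed = TRUE)
    g <- vapply(parts, `[`, "", 1); p <- vapply(parts, `[`, "", 2)
    cn[cbind(match(g, rownames(cn)), match(p, colnames(cn)))] <-
      as.integer(mins)
  }
  keep <- rowMeans(is.na(cn)) <= max_missing_fraction
  cn[keep, , drop = FALSE]
}

#' Map integer copy numbers to categorical events
#'
#' Default mapping: 0 homozygous deletion, 1 heterozygous deletion,
#' 2 normal, 3-5 gain of one or more copies, >= 6 amplification (aligned
#' with the in-situ hybridization rule that six or more signals define
#' amplification); the amplification boundary is configurable.
#'
#' @param cn integer gene x patient matrix (NA = missing).
#' @param amp_min smallest copy number called an amplification (default 6).
#' @return Character matrix of events in \{homdel, hetdel, normal, gain,
#'   amp\} with NA for missing.
#' @export
classify_events <- function(cn, amp_min = 6L) {
  ev <- matrix(NA_character_, nrow(cn), ncol(cn), dimnames = dimnames(cn))
  ev[!is.na(cn) & cn == 0] <- "homdel"
  ev[!is.na(cn) & cn == 1] <- "hetdel"
  ev[!is.na(cn) & cn == 2] <- "normal"
  ev[!is.na(cn) & cn >= 3 & cn < amp_min] <- "gain"
  ev[!is.na(cn) & cn >= amp_min] <- "amp"
  ev
}

#' Per-gene, per-group event penetrance
#'
#' For each gene, group and event type, the fraction of patients of that
#' group carrying the event among patients with non-missing data; the
#' merged \code{loss} (homdel + hetdel) and \code{gain_amp} (gain + amp)
#' frequencies are reported alongside.
#'
#' @param events character gene x patient event matrix
#'   (see [classify_events()]).
#' @param groups labels ("h"/"o") named by patient or aligned to columns.
#' @return Long data.frame \code{gene_id}, \code{group}, \code{event},
#'   \code{frequency}, \code{n_informative}; frequency is NA when a
#'   gene/group has no informative patient.
#' @export
cnv_penetrance <- function(events, groups) {
  if (!is.null(names(groups))) groups <- groups[colnames(events)]
  groups <- check_two_groups(groups, c("h", "o"))
  ev_levels <- c("homdel", "hetdel", "normal", "gain", "amp",
                 "loss", "gain_amp")
  rows <- list()
  for (g in c("h", "o")) {
    sub <- events[, groups == g, drop = FALSE]
    n_inf <- rowSums(!is.na(sub))
    cnt <- vapply(c("homdel", "hetdel", "normal", "gain", "amp"),
                  function(e) rowSums(sub == e, na.rm = TRUE),
                  numeric(nrow(events)))
    if (nrow(events) == 1) cnt <- matrix(cnt, 1, dimnames = list(
      rownames(events), c("homdel", "hetdel", "normal", "gain", "amp")))
    cnt <- cbind(cnt, loss = cnt[, "homdel"] + cnt[, "hetdel"],
                 gain_amp = cnt[, "gain"] + cnt[, "amp"])
    for (e in ev_levels) {
      rows[[paste(g, e)]] <- data.frame(
        gene_id = rownames(events), group = g, event = e,
        frequency = ifelse(n_inf > 0, cnt[, e] / n_inf, NA_real_),
        n_informative = n_inf, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene group enrichment of merged loss / gain events
#'
#' For each gene and each merged direction (loss = homdel + hetdel,
#' gain = gain + amp), tests enrichment of the event in group "h" with a
#' one-tailed Fisher exact test on the event x group 2x2 table (missing
#' patients discarded). To test the "o" direction, swap the labels.
#'
#' @param events gene x patient event matrix.
#' @param groups labels ("h"/"o").
#' @param p_max significance cut-off (default 0.01).
#' @return data.frame \code{gene_id}, \code{direction}, \code{p_value},
#'   \code{significant}, with group event counts.
#' @export
cnv_group_enrichment <- function(events, groups, p_max = 0.01) {
  if (!is.null(names(groups))) groups <- groups[colnames(events)]
  groups <- check_two_groups(groups, c("h", "o"))
  dirs <- list(loss = c("homdel", "hetdel"), gain = c("gain", "amp"))
  rows <- list()
  for (d in names(dirs)) {
    hit <- matrix(events %in% dirs[[d]], nrow(events))
    inf <- !is.na(events)
    a <- rowSums(hit[, groups == "h", drop = FALSE])       # h with event
    b <- rowSums(inf[, groups == "h", drop = FALSE]) - a   # h without
    c_ <- rowSums(hit[, groups == "o", drop = FALSE])
    d_ <- rowSums(inf[, groups == "o", drop = FALSE]) - c_
    p <- vapply(seq_len(nrow(events)), function(i)
      stats::fisher.test(matrix(c(a[i], b[i], c_[i], d_[i]), 2,
                                byrow = TRUE),
                         alternative = "greater")$p.value, 0)
    rows[[d]] <- data.frame(gene_id = rownames(events), direction = d,
                            n_event_h = a, n_event_o = c_,
                            p_value = p, significant = p < p_max,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cytoband enrichment of significantly altered genes
#'
#' Genes are assigned to the single band containing their start position.
#' Per event type, each band is tested for over-representation of the
#' significantly altered genes (one-tailed Fisher exact on in-band vs
#' out-of-band against significant vs not), with Holm correction across
#' bands within the event type; when several event types survive for a
#' band, only the most significant is kept.
#'
#' @param sig_genes named list of character vectors of significant gene
#'   ids per event type (e.g. \code{list(loss = ..., gain = ...)}).
#' @param genes GeneModel data.frame \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param bands CytobandMap data.frame \code{band_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param p_max Holm-adjusted significance cut-off (default 0.01).
#' @return data.frame \code{band_id}, \code{event}, \code{n_sig_in_band},
#'   \code{n_in_band}, \code{p_holm}; one row per enriched band.
#' @export
cytoband_enrichment <- function(sig_genes, genes, bands, p_max = 0.01) {
  band_of <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(bands))) {
    inb <- genes$chrom == bands$chrom[i] &
      genes$start >= bands$start[i] & genes$start < bands$end[i]
    band_of[inb] <- bands$band_id[i]
  }
  if (any(is.na(band_of))) {
    warning(sum(is.na(band_of)), " gene(s) outside all bands excluded")
    genes <- genes[!is.na(band_of), , drop = FALSE]
    band_of <- band_of[!is.na(band_of)]
  }
  res <- list()
  for (ev in names(sig_genes)) {
    sig <- genes$gene_id %in% sig_genes[[ev]]
    if (!any(sig)) next
    p <- vapply(bands$band_id, function(b) {
      inb <- band_of == b
      stats::fisher.test(matrix(c(sum(sig & inb), sum(!sig & inb),
                                  sum(sig & !inb), sum(!sig & !inb)),
                                2, byrow = TRUE),
                         alternative = "greater")$p.value
    }, 0)
    ph <- stats::p.adjust(p, "holm")
    keep <- ph < p_max
    if (any(keep)) {
      res[[ev]] <- data.frame(
        band_id = bands$band_id[keep], event = ev,
        n_sig_in_band = vapply(bands$band_id[keep], function(b)
          sum(genes$gene_id %in% sig_genes[[ev]] & band_of == b), 0L),
        n_in_band = vapply(bands$band_id[keep], function(b)
          sum(band_of == b), 0L),
        p_holm = ph[keep], stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (length(res) == 0)
    return(data.frame(band_id = character(0), event = character(0),
                      n_sig_in_band = integer(0), n_in_band = integer(0),
                      p_holm = numeric(0)))
  out <- do.call(rbind, res)
  # one row per band: keep the most significant event
  out <- out[order(out$band_id, out$p_holm), , drop = FALSE]
  out <- out[!duplicated(out$band_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
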