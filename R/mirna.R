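#' Filter mature miRNAs by expression
#'
#' Keeps a miRNA when its summed raw count over all samples exceeds 10 AND
#' at least one sample carries a minimum of five reads. Idempotent and
#' order-invariant.
#'
#' @param counts mature x samples integer count matrix.
#' @return The filtered count matrix.
#' @export
filter_expressed <- function(counts) {
  keep <- rowSums(counts) > 10 & apply(counts, 1, max) >= 5
  counts[keep, , drop = FALSE]
}

#' Normalize miRNA counts and test group differential expression
#'
#' Counts are scaled to counts-per-million with TMM library-size factors
#' (trimmed mean of M-values: 30% M-trim, 5% A-trim, reference library
#' closest to the mean upper quartile). The group log2 fold-change is the
#' difference of group means of log2(CPM + 0.5); the per-miRNA test is a
#' Welch t-test on the same log values with Holm family-wise correction (a
#' deliberately simple test kept behind this interface so a moderated
#' count-model fit can be swapped in). The significance flag applies the
#' three selection cut-offs jointly: |log2FC| > 1, Holm-adjusted p < 0.01,
#' and median normalized count > 1 in at least one group.
#'
#' @param counts mature (or precursor) x samples count matrix.
#' @param groups labels ("h"/"o"), named by sample or aligned to columns.
#' @param lfc_min,p_max,min_median_cpm the three published cut-offs.
#' @return data.frame \code{mirna_id}, \code{log2fc}, \code{p_raw},
#'   \code{p_holm}, \code{median_cpm_h}, \code{median_cpm_o},
#'   \code{significant}; the log2(CPM + 0.5) matrix is attached as
#'   attribute \code{logcpm}.
#' @export
normalize_and_de <- function(counts, groups, lfc_min = 1, p_max = 0.01,
                             min_median_cpm = 1) {
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- check_two_groups(groups, c("h", "o"))
  if (sum(groups == "h") < 2 || sum(groups == "o") < 2)
    stop("each group needs >= 2 samples")
  if (any(colSums(counts) == 0)) stop("zero library size")
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  cpm <- edgeR::cpm(dge, normalized.lib.sizes = TRUE)
  logcpm <- log2(cpm + 0.5)
  de <- welch_de(logcpm, groups)
  med_h <- apply(cpm[, groups == "h", drop = FALSE], 1, stats::median)
  med_o <- apply(cpm[, groups == "o", drop = FALSE], 1, stats::median)
  out <- data.frame(mirna_id = rownames(counts), log2fc = de$log2fc,
                    p_raw = de$p_raw, p_holm = de$p_holm,
                    median_cpm_h = med_h, median_cpm_o = med_o,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- abs(out$log2fc) > lfc_min & out$p_holm < p_max &
    (out$median_cpm_h > min_median_cpm | out$median_cpm_o > min_median_cpm)
  attr(out, "logcpm") <- logcpm
  out
}

#' Summarize mature miRNA expression at the precursor level
#'
#' Pre-miRNA expression is the arithmetic mean of the (normalized-scale)
#' rows of its derived mature forms. Mature ids without a mapping are
#' excluded with a message.
#'
#' @param mature_matrix mature x samples matrix (normalized scale).
#' @param mapping data.frame \code{mature_id}, \code{pre_mirna_id}; every
#'   mature id maps to at most one precursor.
#' @return precursor x samples matrix.
#' @export
premirna_expression <- function(mature_matrix, mapping) {
  if (anyDuplicated(mapping$mature_id))
    stop("a mature id maps to more than one precursor")
  mapped <- rownames(mature_matrix) %in% mapping$mature_id
  if (any(!mapped))
    message(sum(!mapped), " mature miRNA(s) without precursor mapping excluded")
  mm <- mature_matrix[mapped, , drop = FALSE]
  pre <- mapping$pre_mirna_id[match(rownames(mm), mapping$mature_id)]
  sums <- rowsum(mm, pre)
  counts <- as.vector(table(pre)[rownames(sums)])
  sums / counts
}

#' Integrate miRNA and mRNA differential expression into a regulatory network
#'
#' Candidate pairs are the database interactions whose precursor miRNA and
#' target gene both pass the differential-expression filter (absolute
#' log2FC above \code{lfc_min} and DE p below \code{de_p_max}). For each
#' candidate the Pearson correlation between precursor and gene expression
#' is computed across the shared samples and tested one-sided for negative
#' correlation; p-values are adjusted across all candidates
#' (Benjamini-Hochberg by default, Holm optionally) and pairs with adjusted
#' p below \code{cor_p_max} and negative correlation are retained.
#'
#' @param mirna_expr precursor x samples expression matrix (log scale).
#' @param mirna_de data.frame with \code{mirna_id}, \code{log2fc},
#'   \code{p_holm} (or \code{p_raw}) at the precursor level.
#' @param gene_expr genes x samples matrix (log scale).
#' @param gene_de data.frame with \code{gene_id}, \code{log2fc} and a
#'   p-value column (\code{p_holm} or \code{p_raw}).
#' @param db data.frame \code{pre_mirna_id}, \code{gene_id}, \code{source}.
#' @param lfc_min,de_p_max,cor_p_max filter thresholds (published values
#'   1, 0.01, 0.01).
#' @param de_p_column which DE p-value column to filter on.
#' @param adjust "BH" (default) or "holm" for the correlation p-values.
#' @return data.frame of retained \code{InteractionRecord}s:
#'   \code{pre_mirna_id}, \code{gene_id}, \code{pcc}, \code{p_cor},
#'   \code{p_adj}, \code{mirna_log2fc}, \code{gene_log2fc}, \code{source}.
#' @export
integrate_interactions <- function(mirna_expr, mirna_de, gene_expr, gene_de,
                                   db, lfc_min = 1, de_p_max = 0.01,
                                   cor_p_max = 0.01,
                                   de_p_column = "p_holm",
                                   adjust = c("BH", "holm")) {
  adjust <- match.arg(adjust)
  shared <- intersect(colnames(mirna_expr), colnames(gene_expr))
  if (length(shared) < 5) stop("need >= 5 shared samples")
  if (nrow(db) == 0)
    return(data.frame(pre_mirna_id = character(0), gene_id = character(0),
                      pcc = numeric(0), p_cor = numeric(0),
                      p_adj = numeric(0), mirna_log2fc = numeric(0),
                      gene_log2fc = numeric(0), source = character(0)))
  m_ok <- mirna_de$mirna_id[abs(mirna_de$log2fc) > lfc_min &
                              mirna_de[[de_p_column]] < de_p_max]
  g_ok <- gene_de$gene_id[abs(gene_de$log2fc) > lfc_min &
                            gene_de[[de_p_column]] < de_p_max]
  cand <- db[db$pre_mirna_id %in% intersect(m_ok, rownames(mirna_expr)) &
               db$gene_id %in% intersect(g_ok, rownames(gene_expr)), ,
             drop = FALSE]
  if (nrow(cand) == 0) return(cand[, c("pre_mirna_id", "gene_id")])
  n <- length(shared)
  pcc <- vapply(seq_len(nrow(cand)), function(i)
    stats::cor(mirna_expr[cand$pre_mirna_id[i], shared],
               gene_expr[cand$gene_id[i], shared]), 0)
  tstat <- pcc * sqrt(n - 2) / sqrt(pmax(1 - pcc^2, .Machine$double.eps))
  p_cor <- stats::pt(tstat, df = n - 2)      # one-sided, negative tail
  p_adj <- stats::p.adjust(p_cor, method = adjust)
  out <- data.frame(
    pre_mirna_id = cand$pre_mirna_id, gene_id = cand$gene_id,
    pcc = pcc, p_cor = p_cor, p_adj = p_adj,
    mirna_log2fc = mirna_de$log2fc[match(cand$pre_mirna_id, mirna_de$mirna_id)],
    gene_log2fc = gene_de$log2fc[match(cand$gene_id, gene_de$gene_id)],
    source = cand$source, stringsAsFactors = FALSE, row.names = NULL)
  out[out$p_adj < cor_p_max & out$pcc < 0, , drop = FALSE]
}

#' Fold-change concordance between two cohorts
#'
#' Ordinary least-squares fit of one cohort's log2 fold-changes on the
#' other's over the shared miRNAs; returns the coefficient of
#' determination.
#'
#' @param lfc_a,lfc_b named numeric vectors of log2 fold-changes.
#' @return R-squared of the regression of \code{lfc_a} on \code{lfc_b}.
#' @export
logfc_concordance <- function(lfc_a, lfc_b) {
  shared <- intersect(names(lfc_a), names(lfc_b))
  if (length(shared) < 3) stop("need >= 3 shared miRNAs")
  a <- lfc_a[shared]; b <- lfc_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance fold-change vector; R^2 undefined")
  summary(stats::lm(a ~ b))$r.squared
}
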