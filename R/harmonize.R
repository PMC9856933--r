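#' Select genes measured reproducibly on two platforms
#'
#' For every gene present on both platforms, computes the Pearson
#' correlation of its two measurement vectors over the shared samples
#' (self-PCC). A gene is selected if its self-PCC exceeds
#' \code{self_pcc_min}, or if its self-PCC beats its cross-correlation with
#' every other gene in both directions (a gene that tracks itself better
#' than it tracks anything else, even when its absolute self-correlation is
#' modest). Genes with zero variance on either platform have undefined
#' correlations and are excluded with a warning.
#'
#' @param a,b genes x samples log2 matrices (shared genes by rowname).
#' @param shared character vector of sample ids present in both matrices
#'   (>= 3).
#' @param self_pcc_min self-correlation threshold (default 0.8).
#' @param both_directions if \code{TRUE} (default) the "better than any
#'   other gene" clause must hold in both a-vs-b and b-vs-a directions;
#'   \code{FALSE} requires only the a-vs-b direction.
#' @return List of class \code{harmonization_report}:
#'   \code{selected_genes}, \code{per_gene_self_pcc} (named, all common
#'   non-degenerate genes), \code{n_common}, \code{dropped_constant}.
#' @export
select_reproducible_genes <- function(a, b, shared,
                                      self_pcc_min = 0.8,
                                      both_directions = TRUE) {
  if (length(shared) < 3) stop("need at least 3 shared samples")
  common <- intersect(rownames(a), rownames(b))
  if (length(common) == 0) stop("no genes in common")
  if (!all(shared %in% colnames(a)) || !all(shared %in% colnames(b)))
    stop("shared samples missing from an input matrix")
  xa <- t(a[common, shared, drop = FALSE])
  xb <- t(b[common, shared, drop = FALSE])
  const <- apply(xa, 2, stats::sd) == 0 | apply(xb, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant-expression gene(s) excluded: ",
            paste(utils::head(common[const], 5), collapse = ", "))
    xa <- xa[, !const, drop = FALSE]
    xb <- xb[, !const, drop = FALSE]
    common <- common[!const]
  }
  cc <- stats::cor(xa, xb)              # cc[g, h] = cor(a_g, b_h)
  self <- diag(cc)
  best_row <- apply(cc, 1, max)         # best b-partner for a_g
  best_col <- apply(cc, 2, max)         # best a-partner for b_g
  better <- if (both_directions) {
    self >= best_row & self >= best_col
  } else self >= best_row
  sel <- self > self_pcc_min | better
  structure(list(selected_genes = common[sel],
                 per_gene_self_pcc = setNames(self, common),
                 n_common = length(common),
                 dropped_constant = sum(const)),
            class = "harmonization_report")
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("Reproducible-gene selection: ", length(x$selected_genes), " of ",
      x$n_common, " common genes selected",
      if (x$dropped_constant) paste0(" (", x$dropped_constant,
                                     " constant genes excluded)"), "\n",
      sep = "")
  invisible(x)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' given by the mean of the per-rank sorted values, averaging tied ranks.
#' Row and column order are preserved; the operation is idempotent.
#'
#' @param m genes x samples matrix with >= 2 samples.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  if (nrow(m) == 1) {                  # one rank: every sample gets the mean
    out <- m; out[] <- mean(m)
    return(out)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Merge two single-platform cohorts into one harmonized matrix
#'
#' Restricted to the selected genes, each experiment is quantile-normalized
#' separately, the two are concatenated and quantile-normalized jointly,
#' and finally each gene is median-centred within each experiment and
#' shifted back by the mean of its two experiment medians. By construction
#' the per-gene medians of the two platforms agree exactly afterwards, so
#' the platform label carries no location information.
#'
#' @param a,b genes x samples log2 matrices with disjoint sample ids.
#' @param genes genes to retain (must exist in both inputs).
#' @return Harmonized genes x (samples(a) + samples(b)) matrix with a
#'   \code{platform} attribute naming each sample's origin.
#' @export
merge_and_harmonize <- function(a, b, genes) {
  if (is.null(b) || ncol(b) == 0 || ncol(a) == 0)
    stop("both platforms must contribute samples")
  if (length(intersect(colnames(a), colnames(b))) > 0)
    stop("sample ids overlap between platforms; disambiguate first")
  miss <- setdiff(genes, intersect(rownames(a), rownames(b)))
  if (length(miss) > 0)
    stop("genes absent from an input: ", paste(utils::head(miss, 5), collapse = ", "))
  qa <- quantile_normalize(a[genes, , drop = FALSE])
  qb <- quantile_normalize(b[genes, , drop = FALSE])
  merged <- quantile_normalize(cbind(qa, qb))
  ia <- colnames(a); ib <- colnames(b)
  med_a <- apply(merged[, ia, drop = FALSE], 1, stats::median)
  med_b <- apply(merged[, ib, drop = FALSE], 1, stats::median)
  grand <- (med_a + med_b) / 2
  merged[, ia] <- merged[, ia] - med_a + grand
  merged[, ib] <- merged[, ib] - med_b + grand
  attr(merged, "platform") <- setNames(rep(c("A", "B"),
                                           c(length(ia), length(ib))),
                                       c(ia, ib))
  merged
}
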