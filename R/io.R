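#' Read and write the pipeline's plain-text formats
#'
#' Expression and count matrices travel as TSV with genes as rows and a
#' leading \code{gene_id} column; genomic inputs as BED-like TSV (0-based,
#' half-open) with optional copy-number column; variant tables as a
#' tab-delimited VCF-like file. Writers are deterministic: the same object
#' always produces byte-identical files.
#'
#' @param m matrix to write (genes/miRNAs as rows).
#' @param path file path.
#' @name lms_io
NULL

#' @rdname lms_io
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname lms_io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname lms_io
#' @param df BED-like data.frame whose first columns are chrom, start, end.
#' @export
write_bed_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname lms_io
#' @param variants variant table as produced by [gen_variant_cohort()].
#' @export
write_variants_tsv <- function(variants, path) {
  cols <- c("patient_id", "chrom", "pos", "ref", "alt", "gene", "class",
            "t_depth", "t_af", "n_depth", "n_af", "pop_af", "coding",
            "synonymous", "rna_depth", "variant_id")
  out <- variants[, intersect(cols, names(variants)), drop = FALSE]
  names(out) <- toupper(names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detected gene modules as a GMT file
#'
#' @param modules list of [detect_communities()] results (a data.frame) or a
#'   named list of gene-id vectors.
#' @param path output path.
#' @export
write_modules_gmt <- function(modules, path) {
  if (is.data.frame(modules))
    modules <- split(modules$gene_id, modules$module_id)
  lines <- vapply(names(modules), function(id) {
    paste(c(id, "coexpression_module", modules[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
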