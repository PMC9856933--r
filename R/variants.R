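#' Filter candidate variants to high-confidence somatic calls
#'
#' A record is retained when all rules hold: tumor depth >= 14, normal
#' depth >= 8, tumor allele fraction >= 0.3, normal allele fraction
#' exactly 0 (a small tolerance is available for sequencing noise),
#' population allele frequency below 0.1%, located in a coding region and
#' non-synonymous; records with a reported RNA depth below 5 are dropped.
#' The first failing rule of every rejected record is recorded in the
#' \code{rejections} attribute. The filter is idempotent.
#'
#' @param variants data.frame with \code{t_depth}, \code{n_depth},
#'   \code{t_af}, \code{n_af}, \code{pop_af}, \code{coding},
#'   \code{synonymous} and optional \code{rna_depth}.
#' @param n_af_tol tolerance on the normal allele fraction (default 0).
#' @return The retained subset, with attribute \code{rejections}
#'   (data.frame \code{row}, \code{rule}).
#' @export
filter_somatic <- function(variants, n_af_tol = 0) {
  rules <- list(
    t_depth = variants$t_depth >= 14,
    n_depth = variants$n_depth >= 8,
    t_af = variants$t_af >= 0.3,
    n_af = variants$n_af <= n_af_tol,
    pop_af = variants$pop_af < 0.001,
    coding = variants$coding,
    synonymous = !variants$synonymous,
    rna_depth = if (is.null(variants$rna_depth)) rep(TRUE, nrow(variants))
    else is.na(variants$rna_depth) | variants$rna_depth >= 5
  )
  pass <- Reduce(`&`, rules)
  first_fail <- rep(NA_character_, nrow(variants))
  for (r in rev(names(rules))) first_fail[!rules[[r]]] <- r
  out <- variants[pass, , drop = FALSE]
  attr(out, "rejections") <- data.frame(row = which(!pass),
                                        rule = first_fail[!pass],
                                        stringsAsFactors = FALSE)
  out
}

#' Aggregate per-gene alterations into a subtype summary table
#'
#' For each gene of interest and each group, counts the patients carrying
#' at least one mutation-class record (missense, nonsense, frameshift,
#' non-frameshift indel, splicing), at least one structural variant, at
#' least one loss, and at least one alteration of any kind (each patient
#' counted once per category). Percentages are count / group size, rounded
#' half away from zero to \code{digits} decimals.
#'
#' @param alterations data.frame \code{patient_id}, \code{gene},
#'   \code{class}; classes beyond the mutation classes are "SV" and
#'   "loss".
#' @param groups named group labels ("h"/"o") covering every patient
#'   (patients absent from \code{groups} are excluded with a warning);
#'   group sizes are taken from this vector.
#' @param genes_of_interest genes to tabulate.
#' @param digits decimals for the percentage display (default 1).
#' @return data.frame \code{gene}, \code{group} (h, o, all),
#'   \code{category} (mutation, SV, loss, total), \code{count},
#'   \code{percent}.
#' @export
aggregate_alterations <- function(alterations, groups, genes_of_interest,
                                  digits = 1) {
  mut_classes <- c("missense", "nonsense", "frameshift", "nonFS", "splicing")
  unknown <- setdiff(unique(alterations$patient_id), names(groups))
  if (length(unknown) > 0) {
    warning(length(unknown), " patient(s) in no group excluded: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    alterations <- alterations[!alterations$patient_id %in% unknown, ,
                               drop = FALSE]
  }
  groups <- check_two_groups(groups, c("h", "o"))
  sizes <- c(h = sum(groups == "h"), o = sum(groups == "o"),
             all = length(groups))
  round_half_away <- function(x, d) {
    m <- 10^d
    sign(x) * floor(abs(x) * m + 0.5) / m
  }
  cat_of <- function(cl) ifelse(cl %in% mut_classes, "mutation", cl)
  alterations$category <- cat_of(alterations$class)
  rows <- list()
  for (gene in genes_of_interest) {
    sub <- alterations[alterations$gene == gene, , drop = FALSE]
    for (grp in c("h", "o", "all")) {
      pats <- if (grp == "all") names(groups) else
        names(groups)[groups == grp]
      gsub <- sub[sub$patient_id %in% pats, , drop = FALSE]
      for (categ in c("mutation", "SV", "loss", "total")) {
        cnt <- if (categ == "total") length(unique(gsub$patient_id)) else
          length(unique(gsub$patient_id[gsub$category == categ]))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, group = grp, category = categ, count = cnt,
          percent = round_half_away(100 * cnt / sizes[[grp]], digits),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare biallelic inactivation mechanisms between subtypes
#'
#' Patients whose two alleles of a tumor suppressor are both inactivated
#' are split into "one-mechanism" (both alleles hit by the same event
#' class, e.g. two losses) and "two-mechanism" (two different classes,
#' e.g. missense + loss); patients with an intact (WT) allele are
#' excluded. The 2x2 mechanism x group table is tested with the two-sided
#' Fisher exact test.
#'
#' @param statuses data.frame \code{patient_id}, \code{allele1},
#'   \code{allele2} with values in \{L, MS, FS, WT\}, and \code{group}
#'   ("h"/"o").
#' @return List \code{table} (2x2 contingency), \code{fisher_p},
#'   \code{mechanism} (per-patient classification).
#' @export
biallelic_pattern <- function(statuses) {
  groups <- check_two_groups(statuses$group, c("h", "o"))
  inact <- statuses$allele1 != "WT" & statuses$allele2 != "WT"
  sub <- statuses[inact, , drop = FALSE]
  mech <- ifelse(sub$allele1 == sub$allele2, "one_mechanism",
                 "two_mechanism")
  tab <- table(mechanism = factor(mech, c("two_mechanism", "one_mechanism")),
               group = factor(sub$group, c("h", "o")))
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, fisher_p = p,
       mechanism = setNames(mech, sub$patient_id))
}

#' Tumor mutation burden
#'
#' Somatic variant count per patient divided by the genome length in
#' megabases.
#'
#' @param variants filtered somatic variant data.frame with
#'   \code{patient_id}.
#' @param genome_length_bp total genome length in base pairs.
#' @return Named numeric vector of mutations per Mb.
#' @export
tmb <- function(variants, genome_length_bp) {
  if (genome_length_bp <= 0) stop("genome length must be positive")
  cnt <- table(variants$patient_id)
  setNames(as.numeric(cnt) / (genome_length_bp / 1e6), names(cnt))
}

#' Build the 96-trinucleotide mutation count matrix
#'
#' Each SNV is resolved to its pyrimidine-strand trinucleotide context:
#' records whose reference base is a purine are reverse-complemented first.
#' Counts are binned into the fixed context order of [contexts_96()];
#' non-SNV records and records whose context cannot be resolved are
#' skipped (with a message).
#'
#' @param variants data.frame \code{patient_id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @param contexts reference contexts: data.frame \code{chrom}, \code{pos},
#'   \code{triplet} (reference-strand trinucleotide around the position).
#' @return 96 x patients integer matrix (rows in canonical context order).
#' @export
context_matrix <- function(variants, contexts) {
  ctx <- contexts_96()
  patients <- sort(unique(variants$patient_id))
  out <- matrix(0L, 96, length(patients), dimnames = list(ctx, patients))
  is_snv <- variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T") & variants$ref != variants$alt
  v <- variants[is_snv, , drop = FALSE]
  key <- paste(v$chrom, v$pos)
  tri <- contexts$triplet[match(key, paste(contexts$chrom, contexts$pos))]
  unresolved <- is.na(tri) | substr(tri, 2, 2) != v$ref
  if (any(unresolved))
    message(sum(unresolved), " SNV(s) without resolvable context skipped")
  v <- v[!unresolved, , drop = FALSE]; tri <- tri[!unresolved]
  flip <- v$ref %in% c("A", "G")
  tri[flip] <- revcomp(tri[flip])
  alt <- ifelse(flip, chartr("ACGT", "TGCA", v$alt), v$alt)
  lab <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt, "]",
                substr(tri, 3, 3))
  tt <- table(factor(lab, ctx), factor(v$patient_id, patients))
  out[, ] <- as.integer(tt)
  out
}

#' Refit mutational-signature exposures by non-negative least squares
#'
#' Per patient, catalog signatures with cosine similarity to the observed
#' 96-context profile above \code{cos_min} enter a non-negative
#' least-squares fit of the count vector; exposures of non-candidate
#' signatures are zero. The cosine similarity between the reconstruction
#' and the observed profile is reported; a patient with no candidate
#' signature gets an all-zero exposure row and is flagged.
#'
#' @param counts 96 x patients count matrix.
#' @param catalog 96 x signatures probability matrix (columns sum to 1).
#' @param cos_min candidate-selection cosine threshold (default 0.75).
#' @return List \code{exposures} (signatures x patients),
#'   \code{reconstruction_cosine} (per patient), \code{no_candidate}
#'   (logical per patient).
#' @export
fit_signatures <- function(counts, catalog, cos_min = 0.75) {
  if (any(counts < 0)) stop("counts must be non-negative")
  patients <- colnames(counts)
  expo <- matrix(0, ncol(catalog), length(patients),
                 dimnames = list(colnames(catalog), patients))
  rc <- setNames(rep(NA_real_, length(patients)), patients)
  none <- setNames(logical(length(patients)), patients)
  for (j in seq_along(patients)) {
    y <- counts[, j]
    cs <- apply(catalog, 2, cosine_sim, b = y)
    cand <- which(!is.na(cs) & cs > cos_min)
    if (length(cand) == 0) { none[j] <- TRUE; next }
    fit <- pracma::lsqnonneg(as.matrix(catalog[, cand, drop = FALSE]), y)
    expo[cand, j] <- fit$x
    rc[j] <- cosine_sim(as.vector(catalog[, cand, drop = FALSE] %*% fit$x), y)
  }
  list(exposures = expo, reconstruction_cosine = rc, no_candidate = none)
}
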