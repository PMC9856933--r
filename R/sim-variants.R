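#' The canonical 96 trinucleotide mutation contexts
#'
#' Pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C, T>G),
#' each with the 16 A/C/G/T flank combinations, in the fixed order
#' A[C>A]A ... T[T>G]T used by mutational-signature catalogs.
#'
#' @return Character vector of length 96.
#' @export
contexts_96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, t3)
      paste0(f, "[", s, "]", t3))))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), ""))
}

#' Generate a synthetic mutational-signature catalog
#'
#' Each synthetic signature places 30% of its probability mass on the 16
#' contexts of one substitution class (cycled through C>A, C>T, T>C, ...)
#' and the remaining 70% on a flat Gamma-weighted background shared by the
#' whole catalog, mimicking the peak-plus-flat-background shape of
#' published catalogs: distinct signatures have a cosine similarity around
#' 0.5 (distinguishable, but any mixture stays similar to its members,
#' which is what makes cosine-gated refitting workable in practice).
#'
#' @param n_signatures number of signatures.
#' @param seed RNG seed.
#' @return 96 x n_signatures matrix; columns sum to 1.
#' @export
synthetic_signature_catalog <- function(n_signatures = 3L, seed = 1L) {
  ctx <- contexts_96()
  with_seed(seed * 1000L + 606L, {
    home <- c(1L, 3L, 5L, 2L, 4L, 6L)  # substitution class per signature
    bg <- stats::rgamma(96, 1.5)
    bg <- bg / sum(bg) * 0.7
    sig <- sapply(seq_len(n_signatures), function(k) {
      idx <- (home[((k - 1L) %% 6L) + 1L] - 1L) * 16L + 1:16
      hm <- stats::rgamma(16, 2)
      w <- bg
      w[idx] <- w[idx] + hm / sum(hm) * 0.3
      w / sum(w)
    })
    dimnames(sig) <- list(ctx, sprintf("SBS_syn%02d", seq_len(n_signatures)))
    sig
  })
}

#' Simulate a somatic variant cohort with signature structure
#'
#' Draws per-patient SNVs from the 96-context distribution implied by the
#' configured signature mixture, places them on the toy two-chromosome
#' genome, and records tumor/normal depths and allele fractions such that
#' the bulk of records pass the somatic filter while a fixed panel of
#' fixture records each fails exactly one rule (tumor depth 13, normal
#' depth 7, tumor AF 0.29, normal AF 0.1, population AF 0.002, non-coding,
#' synonymous, RNA depth 4). Half the SNVs are recorded on the purine
#' reference strand to exercise the reverse-complement rule. A per-patient
#' gene-level alteration table (mutation classes, SV, loss) is generated
#' alongside for summary-table scenarios.
#'
#' @param cfg a [sim_config()].
#' @return List with \code{variants} (VCF-like data.frame), \code{catalog},
#'   \code{contexts} (chrom, pos, triplet reference contexts),
#'   \code{alterations} (patient_id, gene, class), \code{groups}, and
#'   \code{truth} (\code{exposures}, \code{pass_ids}).
#' @export
gen_variant_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nh <- cfg$n_samples_per_group[["h"]]; no <- cfg$n_samples_per_group[["o"]]
  n_pat <- nh + no
  catalog <- synthetic_signature_catalog(cfg$n_signatures, cfg$seed)
  mix <- cfg$signature_mixture
  if (nrow(mix) == 1L) mix <- mix[rep(1L, n_pat), , drop = FALSE]
  if (nrow(mix) != n_pat) stop("signature_mixture must have one row per patient")
  with_seed(sim_seed(cfg, 505L), {
    patients <- sprintf("LMS%03d", seq_len(n_pat))
    groups <- setNames(rep(c("h", "o"), c(nh, no)), patients)
    rownames(mix) <- patients
    ctx <- contexts_96()
    gene_pool <- c("TP53", "RB1", "PTEN", "ATRX", "DMD",
                   sprintf("GENE%02d", 1:30))

    parse_ctx <- function(lab) {
      data.frame(five = substr(lab, 1, 1), ref = substr(lab, 3, 3),
                 alt = substr(lab, 5, 5), three = substr(lab, 7, 7),
                 stringsAsFactors = FALSE)
    }
    rows <- vector("list", n_pat)
    for (i in seq_len(n_pat)) {
      m <- cfg$mutations_per_patient
      pvec <- as.vector(catalog %*% mix[i, ])
      lab <- sample(ctx, m, replace = TRUE, prob = pvec)
      pc <- parse_ctx(lab)
      flip <- stats::runif(m) < 0.5            # record on purine strand
      ref <- ifelse(flip, chartr("ACGT", "TGCA", pc$ref), pc$ref)
      alt <- ifelse(flip, chartr("ACGT", "TGCA", pc$alt), pc$alt)
      triplet <- paste0(pc$five, pc$ref, pc$three)
      triplet[flip] <- revcomp(triplet[flip])
      rows[[i]] <- data.frame(
        patient_id = patients[i],
        ref = ref, alt = alt,
        gene = sample(gene_pool, m, replace = TRUE),
        class = sample(c("missense", "nonsense", "frameshift",
                         "nonFS", "splicing"), m, replace = TRUE,
                       prob = c(0.6, 0.1, 0.15, 0.05, 0.1)),
        t_depth = 14L + stats::rpois(m, 50),
        t_af = round(stats::runif(m, 0.3, 0.9), 3),
        n_depth = 8L + stats::rpois(m, 30),
        n_af = 0, pop_af = 0,
        coding = TRUE, synonymous = FALSE, rna_depth = NA_integer_,
        triplet = triplet, stringsAsFactors = FALSE
      )
    }
    v <- do.call(rbind, rows)
    # genome positions globally unique so reference contexts are unambiguous
    v$chrom <- sample(c("chr1", "chr2"), nrow(v), replace = TRUE)
    v$pos <- NA_integer_
    for (ch in c("chr1", "chr2")) {
      idx <- v$chrom == ch
      v$pos[idx] <- sample.int(990000L, sum(idx))
    }

    # fixture records, one failing rule each, attached to the first patient
    fx <- v[rep(1L, 8L), ]
    fx$patient_id <- patients[1]
    fx$pos <- 999000L + 1:8
    fx$t_depth[1] <- 13L
    fx$n_depth[2] <- 7L
    fx$t_af[3] <- 0.29
    fx$n_af[4] <- 0.1
    fx$pop_af[5] <- 0.002
    fx$coding[6] <- FALSE
    fx$synonymous[7] <- TRUE
    fx$rna_depth[8] <- 4L
    v <- rbind(v, fx)
    v$variant_id <- sprintf("v%05d", seq_len(nrow(v)))
    pass_ids <- v$variant_id[seq_len(nrow(v) - 8L)]

    contexts <- v[, c("chrom", "pos", "triplet")]
    v$triplet <- NULL

    # gene-level alterations for Table-style aggregation scenarios
    alt_rows <- lapply(patients, function(pat) {
      k <- stats::rpois(1, 3) + 1L
      data.frame(patient_id = pat,
                 gene = sample(gene_pool[1:5], k, replace = TRUE),
                 class = sample(c("missense", "frameshift", "SV", "loss"),
                                k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })

    list(variants = v, catalog = catalog, contexts = contexts,
         alterations = do.call(rbind, alt_rows), groups = groups,
         truth = list(exposures = mix, pass_ids = pass_ids))
  })
}
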