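#' Simulate a mature-miRNA count cohort with a target-gene matrix
#'
#' Mature-miRNA counts are drawn negative-binomially around a latent
#' log2-expression layer in which a configured subset carries a group
#' log2 fold-change above 1. The first precursors each derive two mature
#' forms (-5p/-3p), the rest one. For each true interaction the target
#' gene's log2 expression is built as a negative linear response to the
#' precursor's latent expression, calibrated so the Pearson correlation is
#' \code{interaction_pcc} in expectation; decoy database pairs link
#' unrelated miRNAs and null genes. Two filter fixtures are always present:
#' an all-zero miRNA and one with max count below 5.
#'
#' @param cfg a [sim_config()].
#' @return List with \code{counts} (mature x samples integer matrix),
#'   \code{gene_expr} (log2 genes x samples), \code{mature_to_pre}
#'   (data.frame mature_id, pre_mirna_id), \code{db} (data.frame
#'   pre_mirna_id, gene_id, source), \code{groups}, and \code{truth}
#'   (\code{interactions}, \code{de_matures}, \code{de_pres}).
#' @export
gen_mirna_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$interaction_pcc >= 0) stop("interaction_pcc must be negative")
  nh <- cfg$n_samples_per_group[["h"]]; no <- cfg$n_samples_per_group[["o"]]
  n <- nh + no
  with_seed(sim_seed(cfg, 303L), {
    samples <- sprintf("P%03d", seq_len(n))
    groups <- setNames(rep(c("h", "o"), c(nh, no)), samples)

    # precursor scaffold: first half carry two mature forms
    n_mat <- cfg$n_mirnas
    n_dual <- floor(n_mat / 3)
    n_pre <- n_dual + (n_mat - 2L * n_dual)
    pre_ids <- sprintf("pre-mir-%03d", seq_len(n_pre))
    mature <- character(0); pre_of <- character(0)
    for (i in seq_len(n_pre)) {
      if (i <= n_dual) {
        mature <- c(mature, sprintf("miR-%03d-5p", i), sprintf("miR-%03d-3p", i))
        pre_of <- c(pre_of, pre_ids[i], pre_ids[i])
      } else {
        mature <- c(mature, sprintf("miR-%03d-5p", i))
        pre_of <- c(pre_of, pre_ids[i])
      }
    }
    mapping <- data.frame(mature_id = mature, pre_mirna_id = pre_of,
                          stringsAsFactors = FALSE)

    # latent log2 expression; DE assigned at precursor level so both mature
    # forms share the fold-change and the averaged precursor keeps it
    n_de_pre <- min(cfg$n_de_mirnas, n_pre - 2L)
    de_pres <- sample(pre_ids, n_de_pre)
    pre_lfc <- setNames(rep(0, n_pre), pre_ids)
    pre_lfc[de_pres] <- rep_len(c(1, -1), n_de_pre) * cfg$mirna_log2fc

    base <- setNames(stats::rnorm(length(mature), 8, 1), mature)
    L <- matrix(base, length(mature), n,
                dimnames = list(mature, samples))
    lfc_mat <- pre_lfc[mapping$pre_mirna_id]
    L[, groups == "h"] <- L[, groups == "h"] + lfc_mat
    L <- L + matrix(stats::rnorm(length(L), 0, 0.7), nrow(L), ncol(L))

    sf <- stats::runif(n, 0.7, 1.3)
    mu <- sweep(2^L, 2, sf, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = cfg$mirna_dispersion),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))
    # deliberate filter fixtures on two non-DE single-form miRNAs
    fix <- utils::tail(mature, 2)
    counts[fix[1], ] <- 0L
    counts[fix[2], ] <- rep_len(c(3L, 0L), n)

    # precursor latent expression = mean of its mature rows
    pre_L <- rowsum(L[mapping$mature_id, , drop = FALSE],
                    mapping$pre_mirna_id) /
      as.vector(table(mapping$pre_mirna_id)[sort(unique(mapping$pre_mirna_id))])
    pre_L <- pre_L[pre_ids, , drop = FALSE]

    # target genes: anti-correlated responses to true-interaction precursors
    n_true <- cfg$n_true_interactions
    true_pres <- sample(de_pres, n_true, replace = n_true > length(de_pres))
    n_genes <- max(500L, n_true + cfg$n_decoy_interactions)
    gene_ids <- sprintf("tg%04d", seq_len(n_genes))
    gexpr <- matrix(stats::rnorm(n_genes * n, 7, 1), n_genes, n,
                    dimnames = list(gene_ids, samples))
    true_genes <- gene_ids[seq_len(n_true)]
    r <- abs(cfg$interaction_pcc)
    for (k in seq_len(n_true)) {
      z <- pre_L[true_pres[k], ]
      sdz <- stats::sd(z)
      sigma <- sdz * sqrt(1 / r^2 - 1)
      gexpr[true_genes[k], ] <- 7 - (z - mean(z)) + stats::rnorm(n, 0, sigma)
    }
    interactions <- data.frame(pre_mirna_id = true_pres,
                               gene_id = true_genes,
                               stringsAsFactors = FALSE)

    # database = truth + decoys among null genes / non-interaction pairs
    decoy_pool <- expand.grid(pre_mirna_id = pre_ids,
                              gene_id = setdiff(gene_ids, true_genes),
                              stringsAsFactors = FALSE)
    decoys <- decoy_pool[sample(nrow(decoy_pool), cfg$n_decoy_interactions), ]
    db <- rbind(interactions, decoys)
    db$source <- sample(c("db1", "db2", "both"), nrow(db), replace = TRUE)
    db <- db[!duplicated(db[c("pre_mirna_id", "gene_id")]), ]
    rownames(db) <- NULL

    list(counts = counts, gene_expr = as_expression_matrix(gexpr),
         mature_to_pre = mapping, db = db, groups = groups,
         truth = list(interactions = interactions,
                      de_pres = de_pres,
                      de_matures = mapping$mature_id[
                        mapping$pre_mirna_id %in% de_pres]))
  })
}
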