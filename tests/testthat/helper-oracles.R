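# Independent oracles used to cross-check the package implementations.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins (sum of probabilities not exceeding
# the observed one, with the conventional 1e-7 relative tie tolerance).
fisher_oracle_two_sided <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# One-tailed (enrichment of cell a) Fisher exact p.
fisher_oracle_greater <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  sum(stats::dhyper(a:min(k, m), m, n, k))
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
wilcox_oracle_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- apply(utils::combn(N, nx), 2,
              function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  p <- if (wobs > mu) mean(ws >= wobs) else mean(ws <= wobs)
  min(2 * p, 1)
}

# Hand-computed two-group log-rank statistic (O - E)^2 / V.
logrank_oracle_chisq <- function(times, events, groups) {
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(times[events == 1]))) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & groups == "h")
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == "h")
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Brute-force co-expression scan: O(p^2) pairwise correlations.
brute_force_edges <- function(m, var_min = 2, pcc_min = 0.7) {
  keep <- apply(m, 1, stats::var) > var_min
  g <- rownames(m)[keep]
  edges <- list()
  if (length(g) >= 2) {
    for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g)) {
      if (stats::cor(m[g[i], ], m[g[j], ]) > pcc_min)
        edges[[length(edges) + 1]] <- sort(c(g[i], g[j]))
    }
  }
  list(nodes = g,
       edges = if (length(edges)) do.call(rbind, edges) else
         matrix(character(0), 0, 2))
}

# Brute-force segment-to-gene projection (triple loop over patients,
# genes and segments), same artifact and missingness rules.
brute_force_gene_cn <- function(segments, genes, artifact_cn = 128L,
                                max_missing_fraction = 1 / 3) {
  segments <- segments[segments$copy_number != artifact_cn, , drop = FALSE]
  patients <- sort(unique(segments$patient_id))
  cn <- matrix(NA_integer_, nrow(genes), length(patients),
               dimnames = list(genes$gene_id, patients))
  for (p in patients) {
    sp <- segments[segments$patient_id == p, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      ov <- sp$chrom == genes$chrom[i] & sp$start < genes$end[i] &
        sp$end > genes$start[i]
      if (any(ov)) cn[i, p] <- min(sp$copy_number[ov])
    }
  }
  cn[rowMeans(is.na(cn)) <= max_missing_fraction, , drop = FALSE]
}

# Shared two-block co-expression fixture: two latent-factor blocks plus
# inert background genes.
make_two_block_fixture <- function(n_per_block = 10, n_samples = 100,
                                   seed = 42) {
  set.seed(seed)
  genes <- c(sprintf("a%02d", 1:n_per_block), sprintf("b%02d", 1:n_per_block),
             sprintf("n%02d", 1:5))
  x <- matrix(rnorm(length(genes) * n_samples, 7, 0.5), length(genes),
              n_samples, dimnames = list(genes, sprintf("S%03d", 1:n_samples)))
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  x[1:n_per_block, ] <- x[1:n_per_block, ] +
    3 * matrix(f1, n_per_block, n_samples, byrow = TRUE)
  x[n_per_block + 1:n_per_block, ] <- x[n_per_block + 1:n_per_block, ] +
    3 * matrix(f2, n_per_block, n_samples, byrow = TRUE)
  truth <- rep(c(1, 2), each = n_per_block)
  names(truth) <- genes[1:(2 * n_per_block)]
  list(expr = x, truth = truth)
}

# Annotation table realizing a 2x2 clinical contingency:
# a/b = reference-level counts in groups h/o, c/d = other-level counts.
ann_from_table <- function(a, b, c, d) {
  data.frame(
    group = rep(c("h", "o", "h", "o"), c(a, b, c, d)),
    feat = rep(c("ref", "ref", "other", "other"), c(a, b, c, d)),
    stringsAsFactors = FALSE)
}

# The published per-gene alteration summary encoded as bracketed counts
# (group sizes 28 h / 11 o), used to rebuild a patient-level fixture.
table2_counts <- function() {
  data.frame(
    gene = rep(c("TP53", "RB1", "PTEN", "ATRX", "DMD"), each = 3),
    category = rep(c("mutation", "SV", "loss"), times = 5),
    h = c(17, 7, 25, 6, 10, 26, 0, 1, 23, 2, 2, 2, 2, 4, 1),
    o = c(2, 4, 10, 1, 4, 9, 0, 0, 9, 3, 0, 2, 1, 4, 0),
    stringsAsFactors = FALSE
  )
}

# Rebuild a patient x gene x category alteration table consistent with the
# bracketed counts: categories are laid out consecutively with wrap-around
# over the first `total` patients of the group, which preserves every
# category count and makes the union of altered patients exactly the
# printed per-gene total.
table2_fixture <- function() {
  counts <- table2_counts()
  totals <- data.frame(
    gene = c("TP53", "RB1", "PTEN", "ATRX", "DMD"),
    h = c(28, 28, 23, 6, 5),
    o = c(11, 10, 9, 5, 5))
  pats <- list(h = sprintf("H%02d", 1:28), o = sprintf("O%02d", 1:11))
  cls <- c(mutation = "missense", SV = "SV", loss = "loss")
  rows <- list()
  for (g in unique(counts$gene)) {
    for (grp in c("h", "o")) {
      tot <- totals[[grp]][totals$gene == g]
      sub <- counts[counts$gene == g, ]
      offset <- 0L
      for (k in seq_len(nrow(sub))) {
        n_k <- sub[[grp]][k]
        if (n_k > 0) {
          ids <- pats[[grp]][((offset + seq_len(n_k) - 1L) %% tot) + 1L]
          rows[[length(rows) + 1]] <- data.frame(
            patient_id = ids, gene = g,
            class = cls[[sub$category[k]]], stringsAsFactors = FALSE)
          offset <- offset + n_k
        }
      }
    }
  }
  groups <- setNames(rep(c("h", "o"), c(28, 11)), c(pats$h, pats$o))
  list(alterations = do.call(rbind, rows), groups = groups,
       totals = totals)
}
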