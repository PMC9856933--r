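#' Build the gene co-expression graph
#'
#' Nodes are genes whose expression variance across samples exceeds
#' \code{var_min} (on the log2 scale of the input); an undirected edge links
#' two genes when their Pearson correlation exceeds \code{pcc_min}. No
#' self-loops.
#'
#' @param m genes x samples log2 matrix (>= 2 samples).
#' @param var_min variance threshold for node inclusion (default 2).
#' @param pcc_min correlation threshold for edges (default 0.7).
#' @return An \pkg{igraph} graph whose vertex names are gene ids; empty
#'   graph (with a warning) if no gene passes the variance filter.
#' @export
build_coexpression_graph <- function(m, var_min = 2, pcc_min = 0.7) {
  if (ncol(m) < 2) stop("need >= 2 samples")
  keep <- row_vars(m) > var_min
  if (!any(keep)) {
    warning("no gene passes the variance filter; returning empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  x <- t(m[keep, , drop = FALSE])
  cc <- stats::cor(x)
  adj <- (cc > pcc_min)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g
}

#' Detect co-expression modules by edge-betweenness communities
#'
#' Girvan-Newman community detection: edges are iteratively removed in
#' order of highest edge betweenness and the partition with maximum
#' modularity along the resulting dendrogram is kept. All communities are
#' returned; those with at least \code{min_size} genes are flagged as
#' modules.
#'
#' @param g graph from [build_coexpression_graph()].
#' @param min_size minimum module size to flag (default 5).
#' @return data.frame with \code{module_id}, \code{gene_id}, \code{size},
#'   \code{flagged}; zero rows for an empty graph.
#' @export
detect_communities <- function(g, min_size = 5) {
  if (igraph::vcount(g) == 0)
    return(data.frame(module_id = character(0), gene_id = character(0),
                      size = integer(0), flagged = logical(0)))
  comm <- igraph::cluster_edge_betweenness(g, weights = NULL)
  memb <- igraph::membership(comm)
  ids <- sprintf("M%03d", as.integer(memb))
  sizes <- table(ids)
  data.frame(module_id = ids,
             gene_id = igraph::V(g)$name,
             size = as.integer(sizes[ids]),
             flagged = as.integer(sizes[ids]) >= min_size,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster samples on module genes (PCA + Ward + consolidation)
#'
#' Principal components are computed on the centred (unscaled) feature
#' submatrix with samples as observations; the smallest number of
#' components explaining at least \code{var_explained} of the variance is
#' retained. Samples are then clustered by Ward-linkage hierarchical
#' clustering on the component scores (Euclidean distance); the number of
#' clusters is chosen where the relative loss of within-cluster inertia
#' between successive merges is largest, and the partition is consolidated
#' by one k-means pass initialized at the cluster means.
#'
#' @param m genes x samples matrix.
#' @param feature_genes genes to cluster on (subset of rownames).
#' @param var_explained variance fraction retained in the PCA (default
#'   0.95).
#' @param k_max largest number of clusters considered (default 10).
#' @return List of class \code{sample_clustering}: \code{labels} (named
#'   integer cluster ids), \code{n_components_retained},
#'   \code{linkage_heights}, \code{k}.
#' @export
cluster_samples <- function(m, feature_genes, var_explained = 0.95,
                            k_max = 10) {
  miss <- setdiff(feature_genes, rownames(m))
  if (length(miss) > 0)
    stop("feature genes absent from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  n <- ncol(m)
  if (n < 3) stop("need at least 3 samples")
  x <- t(m[feature_genes, , drop = FALSE])
  # stable against gene/sample order: fix both orders before PCA
  x <- x[order(rownames(x)), sort(feature_genes), drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) == 0) {                   # all samples identical
    labels <- setNames(rep(1L, n), rownames(x))[colnames(m)]
    return(structure(list(labels = labels, n_components_retained = 0L,
                          linkage_heights = numeric(0), k = 1L),
                     class = "sample_clustering"))
  }
  ncomp <- which(cumsum(ev) / sum(ev) >= var_explained)[1]
  ncomp <- min(ncomp, n - 1L, ncol(x))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]

  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  k_max <- min(k_max, n - 1L)
  within <- function(lab) {
    sum(vapply(split(seq_len(n), lab), function(ix) {
      s <- scores[ix, , drop = FALSE]
      sum(sweep(s, 2, colMeans(s))^2)
    }, 0))
  }
  W <- vapply(1:(k_max + 1L), function(k) within(stats::cutree(hc, k)), 0)
  gain <- -diff(W)                      # inertia explained by each extra split
  crit <- gain[1:(k_max - 1L)] / pmax(gain[2:k_max], .Machine$double.eps)
  k <- which.max(crit) + 1L
  lab0 <- stats::cutree(hc, k)
  centers <- do.call(rbind, lapply(split(seq_len(n), lab0), function(ix)
    colMeans(scores[ix, , drop = FALSE])))
  km <- suppressWarnings(
    stats::kmeans(scores, centers = centers, iter.max = 1,
                  algorithm = "Lloyd"))
  labels <- setNames(as.integer(km$cluster), rownames(scores))[colnames(m)]
  names(labels) <- colnames(m)
  structure(list(labels = labels, n_components_retained = ncomp,
                 linkage_heights = hc$height, k = k),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Sample clustering: ", length(x$labels), " samples, ",
      x$n_components_retained, " PCs retained, k = ", x$k, "\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}
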