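#' Per-gene Welch differential expression with Holm correction
#'
#' Two-tailed Welch t-test (unequal variances, Satterthwaite degrees of
#' freedom) per gene between the two groups, oriented group "h" minus
#' group "o"; p-values receive a Holm step-down family-wise correction over
#' all tested genes. Genes with zero variance in both groups are reported
#' with t = 0, p = 1.
#'
#' @param m genes x samples log2 matrix.
#' @param labels per-sample group labels ("h"/"o"), aligned to columns or
#'   named by sample id; each group needs >= 2 samples.
#' @return data.frame \code{gene_id}, \code{t_score}, \code{df},
#'   \code{p_raw}, \code{p_holm}, \code{log2fc} (mean difference h - o).
#' @export
welch_de <- function(m, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- check_two_groups(labels, c("h", "o"))
  ih <- labels == "h"; io <- labels == "o"
  nh <- sum(ih); no <- sum(io)
  if (nh < 2 || no < 2) stop("each group needs >= 2 samples")
  mh <- rowMeans(m[, ih, drop = FALSE]); mo <- rowMeans(m[, io, drop = FALSE])
  vh <- row_vars(m[, ih, drop = FALSE]); vo <- row_vars(m[, io, drop = FALSE])
  se2 <- vh / nh + vo / no
  t <- (mh - mo) / sqrt(se2)
  df <- se2^2 / ((vh / nh)^2 / (nh - 1) + (vo / no)^2 / (no - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  t[degen] <- 0; p[degen] <- 1; df[degen] <- nh + no - 2
  out <- data.frame(gene_id = rownames(m), t_score = t, df = df,
                    p_raw = p, p_holm = stats::p.adjust(p, "holm"),
                    log2fc = mh - mo, stringsAsFactors = FALSE,
                    row.names = NULL)
  out
}

#' Fit a two-group nearest-centroid classifier
#'
#' Builds per-group centroid profiles over the signature genes (per-gene
#' group mean by default, median optionally) together with the assignment
#' policy: distance is 1 - Spearman correlation between a sample profile
#' and each centroid, and a sample is assigned to the closer centroid only
#' when that distance is below \code{assign_threshold}; otherwise it stays
#' unclassified. An alternative assignment mode fits 1-D Gaussian mixtures
#' to the distance-to-h distribution (see [classify_samples()]).
#'
#' @param m genes x samples training matrix.
#' @param labels training group labels ("h"/"o").
#' @param signature signature gene ids (must all be present in \code{m}).
#' @param aggregate "mean" (default) or "median" centroid aggregation.
#' @param assign_threshold assignment distance cutoff in (0, 2), default
#'   0.6.
#' @param gmm_max_components largest mixture size tried in gmm mode.
#' @return An object of class \code{centroid_model}.
#' @export
build_centroids <- function(m, labels, signature,
                            aggregate = c("mean", "median"),
                            assign_threshold = 0.6,
                            gmm_max_components = 4L) {
  aggregate <- match.arg(aggregate)
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- check_two_groups(labels, c("h", "o"))
  miss <- setdiff(signature, rownames(m))
  if (length(miss) > 0)
    stop("signature genes absent from training matrix: ",
         paste(utils::head(miss, 10), collapse = ", "))
  if (assign_threshold <= 0 || assign_threshold >= 2)
    stop("assign_threshold must lie in (0, 2)")
  agg <- if (aggregate == "mean") rowMeans else
    function(x) apply(x, 1, stats::median)
  sub <- m[signature, , drop = FALSE]
  structure(list(
    signature_genes = signature,
    centroid_h = setNames(agg(sub[, labels == "h", drop = FALSE]), signature),
    centroid_o = setNames(agg(sub[, labels == "o", drop = FALSE]), signature),
    distance = "1 - Spearman correlation",
    assign_threshold = assign_threshold,
    gmm_max_components = as.integer(gmm_max_components),
    aggregate = aggregate
  ), class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Nearest-centroid subtype classifier\n")
  cat("  signature genes :", length(x$signature_genes), "\n")
  cat("  distance        :", x$distance, "\n")
  cat("  threshold       :", x$assign_threshold, "\n")
  cat("  aggregation     :", x$aggregate, "\n")
  invisible(x)
}

#' @export
summary.centroid_model <- function(object, ...) {
  print(object)
  d <- object$centroid_h - object$centroid_o
  cat("  centroid gap    : mean |h - o| =", round(mean(abs(d)), 3), "\n")
  invisible(object)
}

#' Classify samples against fitted centroids
#'
#' For every sample, computes the distance 1 - Spearman rho between its
#' profile and each centroid over the signature genes present in the
#' matrix (average ranks for ties; missing signature genes are dropped
#' pairwise and the missing fraction reported, with a warning above 10%
#' and an error above 50% or below 3 shared genes). In \code{threshold}
#' mode the sample takes the label of the nearer centroid if that distance
#' is below the model's threshold, otherwise "unclassified". In \code{gmm}
#' mode 1-D Gaussian mixtures with 1..\code{gmm_max_components} components
#' (equal and unequal variance) are fitted to the distance-to-h
#' distribution, the fit with the best BIC is kept, and samples in the
#' lowest-mean component are labeled "h", the highest-mean component "o",
#' intermediate components "unclassified" (with a single component the
#' threshold rule is applied instead).
#'
#' @param m genes x samples matrix to classify.
#' @param model a [build_centroids()] fit.
#' @param mode "threshold" (default) or "gmm".
#' @return data.frame \code{sample_id}, \code{dist_h}, \code{dist_o},
#'   \code{label} in \{h, o, unclassified\}, and \code{gmm_component} in
#'   gmm mode; the fraction of missing signature genes is attached as
#'   attribute \code{missing_fraction}.
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_samples <- function(m, model, mode = c("threshold", "gmm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "centroid_model"))
  shared <- intersect(model$signature_genes, rownames(m))
  frac_missing <- 1 - length(shared) / length(model$signature_genes)
  if (length(shared) < 3)
    stop("fewer than 3 signature genes present; rank correlation meaningless")
  if (frac_missing > 0.5)
    stop("more than half of the signature genes are missing (",
         round(100 * frac_missing), "%)")
  if (frac_missing > 0.1)
    warning(round(100 * frac_missing), "% of signature genes missing; ",
            "distances computed on the remainder")
  sub <- m[shared, , drop = FALSE]
  dist_h <- 1 - suppressWarnings(
    stats::cor(sub, model$centroid_h[shared], method = "spearman"))[, 1]
  dist_o <- 1 - suppressWarnings(
    stats::cor(sub, model$centroid_o[shared], method = "spearman"))[, 1]
  out <- data.frame(sample_id = colnames(m), dist_h = dist_h,
                    dist_o = dist_o, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (mode == "threshold") {
    nearer <- ifelse(dist_h <= dist_o, "h", "o")
    out$label <- ifelse(pmin(dist_h, dist_o) < model$assign_threshold,
                        nearer, "unclassified")
  } else {
    fit <- mclust::Mclust(dist_h, G = seq_len(model$gmm_max_components),
                          modelNames = c("E", "V"), verbose = FALSE)
    comp <- fit$classification
    mu <- fit$parameters$mean
    out$gmm_component <- as.integer(comp)
    if (fit$G == 1L) {
      nearer <- ifelse(dist_h <= dist_o, "h", "o")
      out$label <- ifelse(pmin(dist_h, dist_o) < model$assign_threshold,
                          nearer, "unclassified")
    } else {
      lab <- rep("unclassified", fit$G)
      lab[which.min(mu)] <- "h"
      lab[which.max(mu)] <- "o"
      out$label <- lab[comp]
    }
  }
  attr(out, "missing_fraction") <- frac_missing
  out
}

#' @export
predict.centroid_model <- function(object, newdata,
                                   mode = c("threshold", "gmm"), ...) {
  classify_samples(newdata, object, mode = match.arg(mode))
}

#' Serialize / restore a centroid model as JSON
#'
#' @param model a \code{centroid_model}.
#' @param path file path.
#' @return \code{write_centroid_model} returns the path invisibly;
#'   \code{read_centroid_model} returns the restored model.
#' @export
write_centroid_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centroid_model
#' @export
read_centroid_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$centroid_h <- setNames(as.numeric(x$centroid_h), x$signature_genes)
  x$centroid_o <- setNames(as.numeric(x$centroid_o), x$signature_genes)
  x$gmm_max_components <- as.integer(x$gmm_max_components)
  structure(x, class = "centroid_model")
}

#' Flag samples with high expression of one gene
#'
#' A sample's expression of \code{gene} is called high when it exceeds
#' (strictly) the third quartile of the pooled expression distribution of
#' all genes in all samples, computed separately within each platform when
#' a platform tag partitions the samples.
#'
#' @param m genes x samples matrix, optionally with a \code{platform}
#'   attribute (named per-sample vector).
#' @param gene gene id (must be present).
#' @param probs quantile level (default 0.75); linear-interpolation
#'   (type 7) quantiles.
#' @return Named logical vector over samples.
#' @export
call_high_expression <- function(m, gene, probs = 0.75) {
  if (!gene %in% rownames(m)) stop("gene not present: ", gene)
  platform <- attr(m, "platform")
  if (is.null(platform)) platform <- setNames(rep("all", ncol(m)), colnames(m))
  out <- setNames(logical(ncol(m)), colnames(m))
  for (pl in unique(platform)) {
    cols <- names(platform)[platform == pl]
    q3 <- stats::quantile(as.vector(m[, cols, drop = FALSE]), probs,
                          type = 7, names = FALSE)
    out[cols] <- m[gene, cols] > q3
  }
  out
}
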