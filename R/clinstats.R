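#' Fisher enrichment of a categorical clinical feature between subtypes
#'
#' Collapses the feature to reference level vs all others, builds the 2x2
#' table against the two groups and applies the two-sided Fisher exact test
#' (hypergeometric enumeration). The reported direction is the group with
#' the higher reference-level proportion.
#'
#' @param ann annotation data.frame with a \code{group} column ("h"/"o").
#' @param feature column name of the categorical feature.
#' @param reference_level level compared against all others.
#' @return One-row data.frame \code{feature}, \code{test},
#'   \code{statistic} (odds ratio estimate), \code{p_value},
#'   \code{direction}, \code{prop_h}, \code{prop_o}.
#' @export
categorical_enrichment <- function(ann, feature, reference_level) {
  groups <- check_two_groups(ann$group, c("h", "o"))
  x <- ann[[feature]]
  if (is.null(x)) stop("feature column not found: ", feature)
  is_ref <- x == reference_level
  tab <- table(factor(is_ref, c(TRUE, FALSE)), factor(groups, c("h", "o")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in 2x2 table; p set to 1")
    p <- 1; or <- NA_real_
  } else {
    ft <- stats::fisher.test(tab)
    p <- ft$p.value; or <- unname(ft$estimate)
  }
  ph <- tab[1, "h"] / sum(tab[, "h"]); po <- tab[1, "o"] / sum(tab[, "o"])
  data.frame(feature = feature, test = "fisher", statistic = or,
             p_value = p, direction = if (ph >= po) "h" else "o",
             prop_h = ph, prop_o = po, stringsAsFactors = FALSE)
}

#' Rank-sum enrichment of a continuous clinical feature
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison of the feature
#' between groups: exact enumeration when both groups are small (total
#' n <= 50) and no ties are present, normal approximation with tie
#' correction otherwise. If every value is tied, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels ("h"/"o") aligned with \code{values}.
#' @param feature label for the output row.
#' @return One-row data.frame as in [categorical_enrichment()] with
#'   medians per group.
#' @export
continuous_enrichment <- function(values, groups, feature = "feature") {
  groups <- check_two_groups(groups, c("h", "o"))
  vh <- values[groups == "h"]; vo <- values[groups == "o"]
  if (length(vh) < 1 || length(vo) < 1) stop("each group needs >= 1 value")
  if (length(unique(values)) == 1L) {
    p <- 1; w <- NA_real_
  } else {
    ties <- any(duplicated(values))
    exact <- (length(values) <= 50) && !ties
    wt <- suppressWarnings(stats::wilcox.test(vh, vo, exact = exact,
                                              correct = !exact))
    p <- wt$p.value; w <- unname(wt$statistic)
  }
  data.frame(feature = feature, test = "wilcoxon", statistic = w,
             p_value = p,
             direction = if (stats::median(vh) >= stats::median(vo)) "h" else "o",
             median_h = stats::median(vh), median_o = stats::median(vo),
             stringsAsFactors = FALSE)
}

#' Compare within-group expression homogeneity
#'
#' Computes the per-gene sample variance within each group and compares the
#' two per-gene variance vectors with a two-sided Wilcoxon rank-sum test;
#' lower variance means a more homogeneous transcriptional profile. The
#' alternative \code{per = "patient"} reading compares per-patient variances
#' across genes instead.
#'
#' @param m genes x samples matrix.
#' @param groups labels ("h"/"o"), named by sample or aligned to columns.
#' @param per "gene" (default) or "patient".
#' @return List \code{median_var_h}, \code{median_var_o}, \code{p}.
#' @export
homogeneity_test <- function(m, groups, per = c("gene", "patient")) {
  per <- match.arg(per)
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  groups <- check_two_groups(groups, c("h", "o"))
  if (sum(groups == "h") < 3 || sum(groups == "o") < 3)
    stop("each group needs >= 3 samples")
  if (per == "gene") {
    vh <- row_vars(m[, groups == "h", drop = FALSE])
    vo <- row_vars(m[, groups == "o", drop = FALSE])
  } else {
    vh <- apply(m[, groups == "h", drop = FALSE], 2, stats::var)
    vo <- apply(m[, groups == "o", drop = FALSE], 2, stats::var)
  }
  p <- if (identical(vh, vo) || length(unique(c(vh, vo))) == 1L) 1 else
    suppressWarnings(stats::wilcox.test(vh, vo)$p.value)
  list(median_var_h = stats::median(vh), median_var_o = stats::median(vo),
       p = p)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimate per group and the two-group log-rank
#' chi-square test (1 df).
#'
#' @param times survival times (>= 0).
#' @param events event indicators in \{0, 1\}.
#' @param groups group labels ("h"/"o").
#' @return List \code{curves} (data.frame group, time, n_risk, survival),
#'   \code{chisq}, \code{logrank_p}.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- check_two_groups(groups, c("h", "o"))
  if (any(table(groups) == 0)) stop("a group has zero subjects")
  if (sum(events) < 1) stop("need at least one event")
  if (any(times < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(group = strata, time = fit$time,
                       n_risk = fit$n.risk, survival = fit$surv,
                       stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd$chisq), logrank_p = p)
}

#' Clinical enrichment table for a classified cohort
#'
#' Convenience wrapper reproducing the structure of a subtype clinical
#' summary: Fisher tests on the categorical fields, rank-sum tests on the
#' continuous ones, and the per-gene expression-homogeneity comparison when
#' an expression matrix is supplied.
#'
#' @param ann annotation data.frame with \code{group} plus clinical fields.
#' @param categorical named character vector: field -> reference level.
#' @param continuous character vector of continuous field names.
#' @param expr optional genes x samples matrix for the homogeneity row.
#' @return data.frame of enrichment rows.
#' @export
clinical_enrichment_table <- function(ann,
                                      categorical = c(
                                        differentiation = "well",
                                        grade = "low",
                                        sex = "F",
                                        location = "internal_trunk"),
                                      continuous = "mitotic_count",
                                      expr = NULL) {
  rows <- lapply(names(categorical), function(f)
    categorical_enrichment(ann, f, categorical[[f]]))
  for (f in continuous) {
    r <- continuous_enrichment(ann[[f]], ann$group, feature = f)
    rows <- c(rows, list(r[, c("feature", "test", "statistic", "p_value",
                               "direction")]))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    r[, c("feature", "test", "statistic", "p_value", "direction")]))
  if (!is.null(expr)) {
    groups <- setNames(ann$group, ann$sample_id)
    h <- homogeneity_test(expr, groups)
    out <- rbind(out, data.frame(
      feature = "gene_expression_variance", test = "wilcoxon",
      statistic = h$median_var_h / h$median_var_o, p_value = h$p,
      direction = if (h$median_var_h >= h$median_var_o) "h" else "o",
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
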