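#' Simulate a dual-platform expression cohort
#'
#' Emulates the situation where the same tumors were hybridized on two
#' microarray platforms: a configurable subset of genes is measured
#' concordantly (same latent signal plus platform-specific additive shift
#' and technical noise) while the complement is scrambled (independent
#' values on each platform), so that reproducible-gene selection has a known
#' answer.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements \code{a}, \code{b} (genes x samples log2
#'   matrices tagged with a \code{platform} attribute), \code{shared_samples}
#'   and \code{truth} (with \code{concordant_genes}).
#' @export
gen_dual_platform_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 20) stop("n_genes must be >= 20")
  if (cfg$n_shared_samples < 3) stop("need >= 3 shared samples")
  with_seed(sim_seed(cfg, 101L), {
    p <- cfg$n_genes; n <- cfg$n_shared_samples
    genes <- sprintf("g%04d", seq_len(p))
    samples <- sprintf("S%03d", seq_len(n))
    n_conc <- round(cfg$concordant_fraction * p)
    conc <- genes[seq_len(n_conc)]
    mu <- stats::rnorm(p, 7, 2)
    signal <- matrix(mu, p, n) + matrix(stats::rnorm(p * n), p, n)
    dimnames(signal) <- list(genes, samples)
    a <- signal + matrix(stats::rnorm(p * n, 0, cfg$tech_sd), p, n)
    shift <- stats::rnorm(p, 0, cfg$platform_shift_sd)
    b <- signal + shift + matrix(stats::rnorm(p * n, 0, cfg$tech_sd), p, n)
    if (n_conc < p) {
      idx <- (n_conc + 1L):p
      b[idx, ] <- matrix(mu[idx], length(idx), n) +
        matrix(stats::rnorm(length(idx) * n), length(idx), n) +
        matrix(stats::rnorm(length(idx) * n, 0, cfg$tech_sd), length(idx), n)
    }
    list(
      a = as_expression_matrix(a, platform = "A"),
      b = as_expression_matrix(b, platform = "B"),
      shared_samples = samples,
      truth = list(concordant_genes = conc)
    )
  })
}

#' Simulate a two-subtype expression cohort with clinical annotation
#'
#' Generates a log2-scale genes x samples matrix carrying (i) a configurable
#' fraction of DE genes shifted between groups "h" and "o" (alternating
#' sign), (ii) implanted co-expression blocks driven by shared latent
#' factors, and (iii) heavier per-gene noise in group "o"
#' (\code{variance_ratio_o_vs_h}). The accompanying annotation table holds
#' categorical clinical fields sampled from per-group multinomials, a
#' continuous mitotic count, and an exponential survival endpoint with a
#' configurable group hazard ratio and uniform censoring.
#'
#' Gene-level structure (baseline means, which genes are DE with which
#' sign, which genes form modules) is a property of the simulated disease,
#' not of the cohort: it depends only on the structural configuration
#' (gene count, DE fraction, module layout), so two cohorts drawn with
#' different seeds share the same true signature and can play the
#' train-cohort / validation-cohort roles of an independent replication.
#'
#' @param cfg a [sim_config()].
#' @return List with \code{expr}, \code{annotation} (data.frame), and
#'   \code{truth} (\code{labels}, \code{de_genes}, \code{de_signs},
#'   \code{modules}).
#' @export
gen_subtype_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nh <- cfg$n_samples_per_group[["h"]]; no <- cfg$n_samples_per_group[["o"]]
  if (nh < 3 || no < 3) stop("each group needs >= 3 samples")
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  p <- cfg$n_genes
  genes <- sprintf("g%04d", seq_len(p))
  # disease-level structure: fixed given the structural parameters only
  mu <- with_seed(777000L + p, stats::rnorm(p, 7, 2))
  n_de <- round(cfg$de_fraction * p)
  de_genes <- genes[seq_len(n_de)]
  de_signs <- setNames(rep_len(c(1, -1), n_de), de_genes)
  modules <- list()
  if (cfg$n_modules > 0 && cfg$module_size > 1) {
    n_mod_genes <- cfg$n_modules * cfg$module_size
    if (n_de + n_mod_genes > p) stop("too few genes for DE set plus modules")
    picked <- genes[(p - n_mod_genes + 1L):p]
    modules <- split(picked, rep(seq_len(cfg$n_modules),
                                 each = cfg$module_size))
    names(modules) <- sprintf("M%02d", seq_len(cfg$n_modules))
  }
  with_seed(sim_seed(cfg, 202L), {
    n <- nh + no
    samples <- sprintf("P%03d", seq_len(n))
    labels <- setNames(rep(c("h", "o"), c(nh, no)), samples)

    x <- matrix(mu, p, n, dimnames = list(genes, samples))
    x[de_genes, labels == "h"] <- x[de_genes, labels == "h"] +
      de_signs * cfg$effect_size
    for (m in names(modules)) {
      f <- stats::rnorm(n)
      x[modules[[m]], ] <- x[modules[[m]], ] +
        cfg$module_loading * matrix(f, length(modules[[m]]), n, byrow = TRUE)
    }

    sd_vec <- ifelse(labels == "h", cfg$noise_sd,
                     cfg$noise_sd * sqrt(cfg$variance_ratio_o_vs_h))
    x <- x + matrix(stats::rnorm(p * n, 0, rep(sd_vec, each = p)), p, n)

    cp <- cfg$clinical_probs
    draw_cat <- function(pr, lev) {
      ifelse(stats::runif(n) < pr[labels], lev[1], lev[2])
    }
    rate_o <- log(2) / 60                 # median ~60 months in group o
    rate <- ifelse(labels == "h", rate_o * cfg$hazard_ratio, rate_o)
    t_event <- stats::rexp(n, rate)
    t_cens <- stats::runif(n, 12, 120)
    ann <- data.frame(
      sample_id = samples,
      group = unname(labels),
      location = draw_cat(cp$location, c("internal_trunk", "other")),
      sex = draw_cat(cp$sex, c("F", "M")),
      grade = draw_cat(cp$grade, c("low", "high")),
      differentiation = draw_cat(cp$differentiation, c("well", "poor")),
      mitotic_count = round(stats::rlnorm(n, ifelse(labels == "h",
                                                    log(17), log(24.5)), 0.6)),
      survival_time = pmin(t_event, t_cens),
      survival_event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE
    )

    list(
      expr = as_expression_matrix(x),
      annotation = ann,
      truth = list(labels = labels, de_genes = de_genes,
                   de_signs = de_signs, modules = modules)
    )
  })
}
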