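#' Paired count-matrix container
#'
#' @param counts Feature-by-sample non-negative integer matrix with row and
#'   column names.
#' @param design data.frame with columns `sample`, `patient`, `condition`
#'   (`lesion`/`normal`), one row per count column, in column order.
#' @param class_of Named character vector mapping feature id to
#'   `mRNA`/`lncRNA`/`miRNA`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, design, class_of) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix: counts need row and column names")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("count_matrix: counts must be finite and >= 0")
  stopifnot(all(c("sample", "patient", "condition") %in% names(design)),
            nrow(design) == ncol(counts),
            all(design$sample == colnames(counts)))
  if (!all(design$condition %in% c("lesion", "normal")))
    stop("count_matrix: condition must be 'lesion' or 'normal'")
  tab <- table(design$patient, design$condition)
  if (!all(tab == 1))
    stop("count_matrix: every patient needs exactly one sample per condition")
  if (!all(rownames(counts) %in% names(class_of)))
    stop("count_matrix: class_of must cover every feature")
  structure(list(counts = counts, design = design,
                 class_of = class_of[rownames(counts)]),
            class = "count_matrix")
}

cond01_vec <- function(condition) as.numeric(condition == "lesion")

locus_tad_spans <- function(cfg) {
  idx <- vapply(cfg$loci_plan, `[[`, integer(1), "target_tad")
  lapply(cfg$tad_plan[idx], function(td)
    list(chrom = td$chrom, start = td$start_bin * cfg$bin_size,
         end = td$end_bin * cfg$bin_size))
}

in_locus_tad <- function(ann, cfg, margin_bins = 1L) {
  # margin: a called TAD boundary may legitimately sit one bin off the
  # planted one, so boundary-adjacent features count as locus content too
  m <- margin_bins * cfg$bin_size
  hit <- rep(FALSE, nrow(ann))
  for (sp in locus_tad_spans(cfg))
    hit <- hit | (ann$chrom == sp$chrom & ann$tss >= sp$start - m &
                  ann$tss < sp$end + m)
  hit
}

#' Generate paired negative-binomial counts with planted truth
#'
#' For feature g in sample i (patient p, condition c in \{0 = normal,
#' 1 = lesion\}) the count is NB with mean
#' `s_i * exp(mu_g + eta_p + c * beta_g * ln 2)` and dispersion `alpha`
#' (`var = mu + alpha mu^2`). `beta_g` is the planted log2 fold change for
#' DE features and 0 otherwise. Members of a planted co-expression module
#' additionally have their mean multiplied by `2^(loading * f_i)` where
#' `f` is the module's per-sample factor score vector; the factor score
#' vectors of distinct modules are orthogonal.
#'
#' Randomly DE features never have their TSS inside a risk-locus target
#' TAD, so each locus's DE content is exactly its plan; module members are
#' likewise drawn outside locus TADs and outside the DE set.
#'
#' @param cfg A [simulation_config()].
#' @param ann Annotation from [generate_annotation()] under the same cfg.
#' @return A list: `cm` ([count_matrix()]), `size_factors` (true per-sample
#'   library factors), `expected_mean` (the NB mean matrix the counts were
#'   drawn from), `de_truth` (feature_id, class, is_de, true_log2fc),
#'   `module_truth` (feature_id, module), `module_scores` (factor score
#'   matrix, samples x modules).
#' @export
generate_counts <- function(cfg, ann) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$dispersion <= 0)
    stop("configuration error: dispersion must be > 0")
  set.seed(sim_seed(cfg, "counts"))

  n_feat <- nrow(ann)
  n_pat <- cfg$n_patients
  ns <- 2L * n_pat
  patient <- rep(seq_len(n_pat), each = 2L)
  condition <- rep(c("normal", "lesion"), n_pat)
  sample_id <- paste0("P", patient, "_", condition)
  design <- data.frame(sample = sample_id, patient = paste0("P", patient),
                       condition = condition)

  s <- exp(stats::rnorm(ns, 0, cfg$lib_size_sd))
  s <- s / exp(mean(log(s)))
  names(s) <- sample_id

  # planted DE truth
  beta <- stats::setNames(rep(0, n_feat), ann$feature_id)
  planted <- do.call(rbind, lapply(cfg$loci_plan,
                                   function(l) l$planted_candidates))
  if (!is.null(planted) && nrow(planted) > 0)
    beta[planted$feature_id] <- planted$log2fc
  protected <- in_locus_tad(ann, cfg) | ann$planted_candidate
  for (cl in names(cfg$de_fraction_per_class)) {
    pool <- which(ann$class == cl & !protected)
    n_de <- round(cfg$de_fraction_per_class[[cl]] * length(pool))
    if (n_de > 0) {
      pick <- sample(pool, n_de)
      beta[pick] <- sample(c(-1, 1), n_de, replace = TRUE) *
        cfg$de_log2fc_by_class[[cl]]
    }
  }

  # baseline means; planted candidates drawn from the upper half of the
  # range so downregulated candidates stay above the detection floor
  r <- cfg$baseline_log_mean_range
  log_mu <- stats::runif(n_feat, r[1], r[2])
  hi <- ann$planted_candidate
  log_mu[hi] <- stats::runif(sum(hi), mean(r), r[2])

  eta <- stats::rnorm(n_pat, 0, cfg$patient_effect_sd)

  # planted co-expression modules among non-DE, non-locus mRNA/lncRNA
  module <- stats::setNames(rep("none", n_feat), ann$feature_id)
  loading <- stats::setNames(rep(0, n_feat), ann$feature_id)
  n_mod <- cfg$n_modules
  scores <- matrix(0, ns, 0)
  if (n_mod > 0 && cfg$module_size > 0) {
    pool <- which(ann$class %in% c("mRNA", "lncRNA") & beta == 0 &
                  !protected)
    need <- n_mod * cfg$module_size
    if (length(pool) < need)
      stop("generate_counts: not enough null features to plant modules")
    members <- sample(pool, need)
    module[members] <- rep(paste0("module_", seq_len(n_mod)),
                           each = cfg$module_size)
    loading[members] <- stats::runif(need, 0.8, 1.2)
    # factor scores orthogonal to intercept and condition contrast (so
    # module structure cannot masquerade as differential expression) and
    # to each other (so the planted partition is identifiable at small n)
    B <- cbind(rep(1, ns), ifelse(cond01_vec(condition) == 1, 1, -1))
    F0 <- matrix(stats::rnorm(ns * n_mod), ns, n_mod)
    Q <- qr.Q(qr(cbind(B, F0)))[, 2L + seq_len(n_mod), drop = FALSE]
    scores <- Q * sqrt(ns) * cfg$module_factor_sd
    colnames(scores) <- paste0("module_", seq_len(n_mod))
    rownames(scores) <- sample_id
  }

  cond01 <- as.numeric(condition == "lesion")
  log_lambda <- outer(log_mu, log(s), `+`) +
    matrix(eta[patient], n_feat, ns, byrow = TRUE) +
    outer(beta * log(2), cond01)
  if (ncol(scores) > 0) {
    mod_idx <- match(module, colnames(scores))
    has <- !is.na(mod_idx)
    log_lambda[has, ] <- log_lambda[has, , drop = FALSE] +
      log(2) * (loading[has] * t(scores[, mod_idx[has], drop = FALSE]))
  }
  counts <- matrix(stats::rnbinom(n_feat * ns, mu = exp(log_lambda),
                                  size = 1 / cfg$dispersion),
                   n_feat, ns,
                   dimnames = list(ann$feature_id, sample_id))

  cm <- count_matrix(counts, design,
                     stats::setNames(ann$class, ann$feature_id))
  mu <- exp(log_lambda)
  dimnames(mu) <- dimnames(counts)
  list(cm = cm, size_factors = s, expected_mean = mu,
       de_truth = data.frame(feature_id = ann$feature_id,
                             class = ann$class,
                             is_de = beta != 0, true_log2fc = unname(beta)),
       module_truth = data.frame(feature_id = ann$feature_id,
                                 module = unname(module)),
       module_scores = scores)
}
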