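#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each feature with all-positive counts the
#' per-sample ratio to the feature's geometric mean is formed; a sample's
#' size factor is the median ratio, rescaled so size factors have geometric
#' mean 1.
#'
#' @param cm A [count_matrix()] or a bare counts matrix.
#' @param pseudo_reference With no all-positive feature, fall back to a
#'   reference built from positive counts only (otherwise this situation is
#'   an error suggesting the flag).
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors_median_of_ratios <- function(cm, pseudo_reference = FALSE) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) {
    if (!pseudo_reference)
      stop("size_factors_median_of_ratios: no feature with all-positive ",
           "counts; rerun with pseudo_reference = TRUE")
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    ref <- exp(rowMeans(lg, na.rm = TRUE))
    use <- is.finite(ref) & ref > 0
    if (!any(use))
      stop("size_factors_median_of_ratios: all-zero count matrix")
    s <- apply(counts[use, , drop = FALSE], 2, function(k)
      stats::median((k / ref[use])[k > 0]))
  } else {
    ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
    s <- apply(counts[all_pos, , drop = FALSE], 2,
               function(k) stats::median(k / ref))
  }
  if (any(!is.finite(s) | s <= 0))
    stop("size_factors_median_of_ratios: non-positive size factor")
  s / exp(mean(log(s)))
}

#' Normalized counts and log2 expression
#'
#' @param cm A [count_matrix()] or counts matrix.
#' @param sf Size factors; computed by [size_factors_median_of_ratios()]
#'   when omitted.
#' @return `normalized_counts`: matrix of `counts[, i] / s_i`.
#' @export
normalized_counts <- function(cm, sf = NULL) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(sf)) sf <- size_factors_median_of_ratios(counts)
  sweep(counts, 2, sf, `/`)
}

#' @rdname normalized_counts
#' @return `log_normalized`: `log2(normalized + 1)`.
#' @export
log_normalized <- function(cm, sf = NULL) {
  log2(normalized_counts(cm, sf) + 1)
}

#' Detection filter: uniformly detected in every paired sample
#'
#' A feature is detected when its count is positive in both samples of
#' every patient.
#'
#' @param cm A [count_matrix()].
#' @return Named logical vector over features.
#' @export
detection_filter <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  stats::setNames(rowSums(cm$counts <= 0) == 0, rownames(cm$counts))
}

# design-based Pearson moment estimate of the NB dispersion:
# solve sum (k - mu)^2 / (mu + a mu^2) = residual df
pearson_dispersion <- function(k, mu, npar, floor = 1e-4, cap = 100) {
  df <- length(k) - npar
  f <- function(a) sum((k - mu)^2 / (mu + a * mu^2)) - df
  if (!is.finite(f(floor)) || f(floor) <= 0) return(floor)
  if (f(cap) >= 0) return(cap)
  stats::uniroot(f, c(floor, cap))$root
}

mom_dispersion <- function(k, s, cond, floor = 1e-4) {
  z <- k / s
  m <- tapply(z, cond, mean)
  v <- tapply(z, cond, stats::var)
  a <- sum(v - m, na.rm = TRUE) / sum(m^2, na.rm = TRUE)
  min(100, max(floor, if (is.finite(a)) a else floor))
}

fit_nb_feature <- function(k, s, patient, cond01, theta) {
  dat <- data.frame(k = k, patient = factor(patient), cond = cond01,
                    off = log(s))
  form <- if (nlevels(dat$patient) > 1) k ~ patient + cond else k ~ cond
  fit <- try(suppressWarnings(stats::glm(
    form, offset = off, data = dat,
    family = MASS::negative.binomial(theta = theta))), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$converged) return(NULL)
  fit
}

#' Paired negative-binomial Wald test
#'
#' Per feature, fits the NB log-linear model
#' `mean = s_i * exp(mu + patient effects + beta * lesion)` by iteratively
#' reweighted least squares at a fixed dispersion, and reports the Wald
#' test on `beta` (`log2FC = beta / ln 2`; positive = higher in lesion).
#'
#' Dispersion: an initial per-feature method-of-moments estimate seeds a
#' design-based Pearson estimate; with `dispersion_method = "common"`
#' (default) a single pooled dispersion is estimated across all tested
#' features and used for every fit — at a handful of paired samples the
#' per-feature estimate has almost no residual degrees of freedom and a
#' per-feature Wald test is badly miscalibrated (see the methods
#' vignette). `"per-feature"` uses the unpooled estimates. Floor 1e-4.
#'
#' Features that fail the detection filter are reported with NA statistics;
#' one-condition-all-zero features are refit on counts + 0.5 and flagged
#' `pseudo_count`; non-converged fits get `p = 1` and flag
#' `not_converged` (never an exception).
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors (computed when omitted).
#' @param dispersion_method `"common"` or `"per-feature"`.
#' @param detected Logical vector; defaults to [detection_filter()].
#' @return A `de_result` data.frame: feature_id, class, base_mean, log2fc,
#'   p, q, dispersion, detected, flag.
#' @export
paired_nb_test <- function(cm, sf = NULL,
                           dispersion_method = c("common", "per-feature"),
                           detected = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  dispersion_method <- match.arg(dispersion_method)
  if (is.null(sf)) sf <- size_factors_median_of_ratios(cm)
  if (is.null(detected)) detected <- detection_filter(cm)
  counts <- cm$counts
  patient <- cm$design$patient
  cond01 <- as.numeric(cm$design$condition == "lesion")
  npar <- length(unique(patient)) + 1L
  norm <- normalized_counts(counts, sf)
  feats <- rownames(counts)
  n <- length(feats)

  res <- data.frame(feature_id = feats,
                    class = unname(cm$class_of[feats]),
                    base_mean = rowMeans(norm),
                    log2fc = NA_real_, p = NA_real_, q = NA_real_,
                    dispersion = NA_real_, detected = unname(detected),
                    flag = "", stringsAsFactors = FALSE)
  idx <- which(detected)
  if (!length(idx)) { res$q <- adjust_bh(res$p); return(de_result(res)) }

  # pass 1: fits at per-feature MoM dispersion -> Pearson estimates
  a_pf <- rep(NA_real_, n)
  mus <- vector("list", n)
  for (g in idx) {
    k <- counts[g, ]
    a0 <- mom_dispersion(k, sf, cond01)
    fit <- fit_nb_feature(k, sf, patient, cond01, 1 / a0)
    if (is.null(fit)) next
    mus[[g]] <- stats::fitted(fit)
    a_pf[g] <- pearson_dispersion(k, mus[[g]], npar)
  }
  ok <- idx[!vapply(mus[idx], is.null, TRUE)]
  alpha <- a_pf
  if (dispersion_method == "common" && length(ok)) {
    K <- counts[ok, , drop = FALSE]
    MU <- do.call(rbind, mus[ok])
    f <- function(a) sum((K - MU)^2 / (MU + a * MU^2)) -
      length(ok) * (ncol(K) - npar)
    a_common <- if (!is.finite(f(1e-4)) || f(1e-4) <= 0) 1e-4
                else if (f(100) >= 0) 100
                else stats::uniroot(f, c(1e-4, 100))$root
    alpha[idx] <- a_common
  }

  # pass 2: final fits and Wald statistics at the fixed dispersion
  for (g in idx) {
    k <- counts[g, ]
    a <- max(alpha[g], 1e-4, na.rm = TRUE)
    res$dispersion[g] <- a
    flag <- ""
    zero_cond <- all(k[cond01 == 1] == 0) || all(k[cond01 == 0] == 0)
    if (zero_cond) { k <- k + 0.5; flag <- "pseudo_count" }
    fit <- fit_nb_feature(k, sf, patient, cond01, 1 / a)
    if (is.null(fit)) {
      res$p[g] <- 1; res$flag[g] <- "not_converged"
      next
    }
    co <- summary(fit, dispersion = 1)$coefficients
    b <- co["cond", "Estimate"]; se <- co["cond", "Std. Error"]
    res$log2fc[g] <- b / log(2)
    res$p[g] <- 2 * stats::pnorm(-abs(b / se))
    res$flag[g] <- flag
  }
  res$q <- adjust_bh(res$p)
  de_result(res)
}

de_result <- function(df) {
  stopifnot(all(c("feature_id", "class", "base_mean", "log2fc", "p", "q",
                  "detected", "flag") %in% names(df)))
  class(df) <- c("de_result", "data.frame")
  df
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with monotonicity enforcement; NA p-values
#' propagate as NA and are excluded from the ranking. Stable under input
#' reordering.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("adjust_bh: p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Per-class DE selection thresholds
#'
#' Defaults follow the study's genome-wide filters: mRNA and lncRNA at
#' adjusted P < 0.05 and |log2FC| >= 2; miRNA at adjusted P < 0.05 and
#' |log2FC| >= 0.67. The p-value field is switchable to raw per class.
#'
#' @param mrna,lncrna,mirna Each a list `(p_field, p_cut, lfc_cut)`.
#' @return A `de_thresholds` list keyed by class.
#' @export
de_thresholds <- function(
    mrna = list(p_field = "adjusted", p_cut = 0.05, lfc_cut = 2),
    lncrna = list(p_field = "adjusted", p_cut = 0.05, lfc_cut = 2),
    mirna = list(p_field = "adjusted", p_cut = 0.05, lfc_cut = 0.67)) {
  th <- list(mRNA = mrna, lncRNA = lncrna, miRNA = mirna)
  for (t in th) {
    stopifnot(t$p_field %in% c("raw", "adjusted"),
              t$p_cut > 0, t$p_cut <= 1, t$lfc_cut >= 0)
  }
  structure(th, class = "de_thresholds")
}

#' Filter a DE result by the class-specific thresholds
#'
#' A feature is kept iff it is detected, its chosen p-value field is
#' strictly below `p_cut` and `|log2FC| >= lfc_cut` (inclusive at the fold
#' change cut, strict at the p cut).
#'
#' @param de A `de_result` from [paired_nb_test()].
#' @param th A [de_thresholds()] object.
#' @param class One of `mRNA`, `lncRNA`, `miRNA`.
#' @return List with `up`, `down` (feature id vectors) and `table` (the
#'   kept rows).
#' @export
filter_de <- function(de, th = de_thresholds(), class) {
  if (!class %in% names(th)) stop("filter_de: unknown class '", class, "'")
  t <- th[[class]]
  rows <- de[de$class == class & de$detected, , drop = FALSE]
  pv <- if (t$p_field == "adjusted") rows$q else rows$p
  keep <- !is.na(pv) & pv < t$p_cut & !is.na(rows$log2fc) &
    abs(rows$log2fc) >= t$lfc_cut
  kept <- rows[keep, , drop = FALSE]
  list(up = kept$feature_id[kept$log2fc > 0],
       down = kept$feature_id[kept$log2fc < 0],
       table = kept)
}

#' Hierarchical-clustering leaf orders for expression heatmaps
#'
#' Average-linkage clustering on Euclidean distance of the supplied matrix
#' (callers typically pass `log2(normalized + 1)` expression); leaf order
#' is deterministic, with ties resolved by input index.
#'
#' @param x Numeric matrix, >= 2 rows.
#' @return List with `row_order`, `col_order` (NULL when < 3 columns) and
#'   the two hclust objects.
#' @export
heatmap_order <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("heatmap_order: need >= 2 rows")
  hr <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  hc <- if (ncol(x) >= 3)
    stats::hclust(stats::dist(t(x), method = "euclidean"),
                  method = "average") else NULL
  list(row_order = hr$order,
       col_order = if (is.null(hc)) seq_len(ncol(x)) else hc$order,
       row_hclust = hr, col_hclust = hc)
}

#' Write / read DE results as TSV
#' @param de A `de_result`.
#' @param path Output path.
#' @return Invisibly, `path` (writer); a `de_result` (reader).
#' @export
write_de_results <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_results
#' @export
read_de_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (is.null(df$flag)) df$flag <- ""
  df$flag[is.na(df$flag)] <- ""
  de_result(df)
}
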