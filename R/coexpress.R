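#' Co-expressed lncRNA-mRNA pairs by Pearson correlation
#'
#' Pearson correlation of each lncRNA-mRNA pair across all samples of the
#' paired design; pairs with `r > r_min` (the study's one-sided reading of
#' "PCC > 0.9") are retained. `use_abs = TRUE` switches to `|r| > r_min`,
#' admitting negative regulation.
#'
#' @param expr_lnc,expr_mrna Feature-by-sample expression matrices on the
#'   `log2(normalized + 1)` scale, same sample columns.
#' @param r_min Correlation threshold (default 0.9).
#' @param use_abs Threshold `|r|` instead of `r`.
#' @return data.frame `lnc_id`, `mrna_id`, `r`; attribute `n_skipped`
#'   counts pairs dropped for an undefined correlation (zero variance).
#' @export
pcc_pairs <- function(expr_lnc, expr_mrna, r_min = 0.9, use_abs = FALSE) {
  expr_lnc <- as.matrix(expr_lnc); expr_mrna <- as.matrix(expr_mrna)
  if (ncol(expr_lnc) < 3) stop("pcc_pairs: need >= 3 samples")
  stopifnot(ncol(expr_lnc) == ncol(expr_mrna))
  r <- suppressWarnings(stats::cor(t(expr_lnc), t(expr_mrna)))
  und <- is.na(r)
  n_skipped <- sum(und)
  if (n_skipped > 0)
    message("pcc_pairs: ", n_skipped,
            " pair(s) skipped (zero-variance feature)")
  score <- if (use_abs) abs(r) else r
  hit <- which(!und & score > r_min, arr.ind = TRUE)
  out <- data.frame(
    lnc_id = rownames(expr_lnc)[hit[, 1]],
    mrna_id = colnames(r)[hit[, 2]],
    r = r[hit])
  out <- out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "r_min") <- r_min
  out
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta`, diagonal 1 (treated as 0 for
#' connectivity). Undefined correlations (zero variance) contribute 0.
#'
#' @param expr Feature-by-sample expression matrix.
#' @param beta Soft power, integer >= 1.
#' @return Symmetric adjacency matrix in \[0, 1\].
#' @export
adjacency_matrix <- function(expr, beta) {
  stopifnot(beta >= 1)
  r <- suppressWarnings(stats::cor(t(as.matrix(expr))))
  r[is.na(r)] <- 0
  a <- abs(r)^beta
  diag(a) <- 1
  a
}

#' Scale-free-topology soft power selection
#'
#' For each candidate power, builds the unsigned adjacency, computes the
#' connectivity distribution, and fits `log10 p(k)` against `log10 k` over
#' a connectivity histogram; the selected power is the smallest with fit
#' R-squared >= `rsq_min`, else the power with maximal R-squared (with a
#' warning).
#'
#' @param expr Feature-by-sample expression matrix, >= 30 features.
#' @param powers Candidate integer powers.
#' @param rsq_min Scale-free fit target (default 0.8).
#' @param n_breaks Histogram bins for the connectivity distribution.
#' @return List: `beta` (selected power) and `fit_table` (power, rsq,
#'   mean_k).
#' @export
pick_soft_power <- function(expr, powers = 1:12, rsq_min = 0.8,
                            n_breaks = 10) {
  expr <- as.matrix(expr)
  if (!length(powers)) stop("pick_soft_power: no candidate powers")
  if (nrow(expr) < 30)
    stop("pick_soft_power: need >= 30 features for a meaningful fit")
  r <- suppressWarnings(stats::cor(t(expr)))
  r[is.na(r)] <- 0
  absr <- abs(r)
  fit_one <- function(beta) {
    a <- absr^beta
    k <- rowSums(a) - 1          # exclude self
    if (stats::sd(k) == 0) return(c(rsq = 0, mean_k = mean(k)))
    br <- seq(min(k), max(k), length.out = n_breaks + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    km <- tapply(k, bin, mean)
    use <- !is.na(pk) & pk > 0 & km > 0
    if (sum(use) < 3) return(c(rsq = 0, mean_k = mean(k)))
    fit <- stats::lm(log10(pk[use]) ~ log10(km[use]))
    c(rsq = summary(fit)$r.squared, mean_k = mean(k))
  }
  tab <- t(vapply(powers, fit_one, c(rsq = 0, mean_k = 0)))
  fit_table <- data.frame(power = powers, rsq = tab[, "rsq"],
                          mean_k = tab[, "mean_k"])
  hit <- which(fit_table$rsq >= rsq_min)
  if (length(hit)) {
    beta <- powers[hit[1]]
  } else {
    beta <- powers[which.max(fit_table$rsq)]
    warning("pick_soft_power: no candidate reaches R^2 >= ", rsq_min,
            "; using the best (power ", beta, ")")
  }
  list(beta = beta, fit_table = fit_table)
}

#' Topological overlap matrix
#'
#' `t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and connectivity `k` excluding
#' the diagonal; `t_ii = 1` by convention.
#'
#' @param a Symmetric adjacency in \[0, 1\].
#' @return Symmetric TOM similarity matrix in \[0, 1\].
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  stopifnot(nrow(a) == ncol(a))
  if (max(abs(a - t(a))) > 1e-12) stop("tom_similarity: not symmetric")
  if (any(a < 0 | a > 1)) stop("tom_similarity: entries outside [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                       # u = i or j contribute 0 (diag 0)
  tm <- (l + a) / (outer(k, k, pmin) + 1 - a)
  diag(tm) <- 1
  dimnames(tm) <- dimnames(a)
  tm
}

#' Module eigengene
#'
#' First principal component over samples of the row-standardized module
#' expression submatrix, sign-oriented so the mean member correlation with
#' it is positive.
#'
#' @param x Member-by-sample expression matrix (>= 1 row).
#' @return Numeric per-sample score vector (unit norm).
#' @export
module_eigengene <- function(x) {
  x <- as.matrix(x)
  xs <- t(scale(t(x)))
  xs[!is.finite(xs)] <- 0
  v <- svd(xs, nu = 0, nv = 1)$v[, 1]
  if (mean(stats::cor(t(x), v), na.rm = TRUE) < 0) v <- -v
  stats::setNames(v, colnames(x))
}

wgcna_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                  "black", "pink", "magenta", "purple", "greenyellow",
                  "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Detect co-expression modules from a TOM
#'
#' Average-linkage clustering of the TOM dissimilarity `1 - t`, cut
#' statically at `cut_frac` of the maximal merge height; clusters below
#' `min_size` become `grey`. Each surviving cluster is then refined by
#' module membership (kME): members with `|cor(expr, eigengene)| <
#' kme_min` are dropped, the eigengene is recomputed on the purified set,
#' and the original cluster members are re-admitted against the refined
#' eigengene. Labels follow the conventional color order by decreasing
#' module size.
#'
#' @param tm TOM similarity matrix (features in rows/cols, named).
#' @param expr Matching feature-by-sample expression matrix (for
#'   eigengenes and the kME refinement).
#' @param min_size Minimum module size (default 30).
#' @param cut_frac Static cut height as a fraction of the maximal merge
#'   height (default 0.9).
#' @param kme_min Module-membership threshold (default 0.9); set to 0 to
#'   disable the refinement.
#' @return A `module_set` list: `labels` (named character, `grey` =
#'   unassigned), `eigengenes` (sample-by-module matrix), `sizes`.
#' @export
detect_modules <- function(tm, expr, min_size = 30, cut_frac = 0.9,
                           kme_min = 0.9) {
  expr <- as.matrix(expr)
  stopifnot(nrow(tm) == nrow(expr))
  feats <- rownames(expr)
  if (is.null(feats)) feats <- paste0("f", seq_len(nrow(expr)))
  h <- stats::hclust(stats::as.dist(1 - tm), method = "average")
  raw <- stats::cutree(h, h = cut_frac * max(h$height))
  lab <- rep("grey", length(raw))
  sizes <- table(raw)
  keep_cl <- as.integer(names(sizes)[sizes >= min_size])
  for (cl in keep_cl) {
    idx <- which(raw == cl)
    if (kme_min > 0) {
      em <- module_eigengene(expr[idx, , drop = FALSE])
      kme <- abs(stats::cor(t(expr[idx, , drop = FALSE]), em))
      core <- idx[!is.na(kme) & kme >= kme_min]
      if (length(core) >= 3) {
        em2 <- module_eigengene(expr[core, , drop = FALSE])
        kme2 <- abs(stats::cor(t(expr[idx, , drop = FALSE]), em2))
        idx <- idx[!is.na(kme2) & kme2 >= kme_min]
      } else idx <- integer(0)
    }
    if (length(idx) >= min_size) lab[idx] <- paste0("cl", cl)
  }
  # color labels by decreasing size, ties by first appearance
  tab <- sort(table(lab[lab != "grey"]), decreasing = TRUE)
  mapping <- stats::setNames(
    c(wgcna_colors, paste0("module_",
                           seq_len(max(0, length(tab) -
                                       length(wgcna_colors)))))[
                                         seq_along(tab)],
    names(tab))
  lab[lab != "grey"] <- mapping[lab[lab != "grey"]]
  names(lab) <- feats
  mods <- names(sort(table(lab[lab != "grey"]), decreasing = TRUE))
  eg <- if (length(mods))
    vapply(mods, function(m)
      module_eigengene(expr[lab == m, , drop = FALSE]),
      numeric(ncol(expr)))
  else matrix(numeric(0), ncol(expr), 0)
  if (!length(mods))
    warning("detect_modules: no module reached min_size; all grey")
  structure(list(labels = lab, eigengenes = eg,
                 sizes = table(factor(lab))), class = "module_set")
}

#' Module significance from differential-expression p-values
#'
#' Significance of a module is the mean `-log10 p` of its members'
#' differential-expression p-values (the DE p-value is treated as a
#' feature of each gene module); modules are ranked and the top `top_k`
#' selected.
#'
#' @param ms A `module_set` from [detect_modules()].
#' @param de A `de_result` (members missing from it are excluded with a
#'   message).
#' @param top_k Number of modules to select (default 3); `sig_min`
#'   alternatively selects by threshold when non-NULL.
#' @param sig_min Optional minimum significance.
#' @return List: `table` (module, size, significance, selected) sorted by
#'   significance, `selected` (module names).
#' @export
module_significance <- function(ms, de, top_k = 3, sig_min = NULL) {
  stopifnot(inherits(ms, "module_set"))
  mods <- setdiff(unique(ms$labels), "grey")
  p_of <- stats::setNames(de$p, de$feature_id)
  rows <- lapply(mods, function(m) {
    members <- names(ms$labels)[ms$labels == m]
    pv <- p_of[members]
    missing <- sum(!members %in% names(p_of) | is.na(pv))
    if (missing > 0)
      message("module_significance: ", missing, " member(s) of ", m,
              " missing from DE result")
    pv <- pv[!is.na(pv)]
    data.frame(module = m, size = length(members),
               significance = if (length(pv))
                 mean(-log10(pmax(pv, .Machine$double.xmin))) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(list(table = data.frame(module = character(), size = integer(),
                                   significance = numeric(),
                                   selected = logical()),
                selected = character()))
  tab <- tab[order(-tab$significance, tab$module), , drop = FALSE]
  rownames(tab) <- NULL
  tab$selected <- if (is.null(sig_min))
    seq_len(nrow(tab)) <= top_k else tab$significance >= sig_min
  list(table = tab, selected = tab$module[tab$selected])
}
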