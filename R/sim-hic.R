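#' Generate block-structured Hi-C contact matrices with planted TADs
#'
#' Expected contact for bin pair (i, j) is `rate * d(i, j)` with distance
#' decay `d(i, j) = (1 + |i - j|)^-1`; `rate` is `intra_tad_rate` when both
#' bins share a planted TAD (`intra_tad_rate * sub_tad_boost` inside a
#' nested sub-TAD) and `inter_tad_rate` otherwise. Poisson noise is drawn
#' on the upper triangle and mirrored, so each matrix is exactly symmetric.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `matrices` (named list of [contact_matrix()] per
#'   chromosome) and `tad_truth` (data.frame chrom, start_bp, end_bp,
#'   level in \{tad, sub_tad\}).
#' @export
generate_hic <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(sim_seed(cfg, "hic"))
  mats <- list()
  for (chrom in names(cfg$genome)) {
    n_bins <- as.integer(cfg$genome[[chrom]] / cfg$bin_size)
    tad_of <- rep(0L, n_bins)   # 0 = outside any planted TAD
    sub_of <- rep(0L, n_bins)
    tds <- Filter(function(t) t$chrom == chrom, cfg$tad_plan)
    for (k in seq_along(tds)) {
      td <- tds[[k]]
      tad_of[(td$start_bin + 1):td$end_bin] <- k
      if (!is.null(td$nested_sub))
        sub_of[(td$nested_sub[1] + 1):td$nested_sub[2]] <- k
    }
    d <- 1 / (1 + abs(outer(seq_len(n_bins), seq_len(n_bins), `-`)))
    same_tad <- outer(tad_of, tad_of, `==`) & tad_of > 0
    same_sub <- outer(sub_of, sub_of, `==`) & sub_of > 0
    rate <- matrix(cfg$inter_tad_rate, n_bins, n_bins)
    rate[same_tad] <- cfg$intra_tad_rate
    rate[same_sub] <- cfg$intra_tad_rate * cfg$sub_tad_boost
    lambda <- rate * d
    m <- matrix(0, n_bins, n_bins)
    up <- upper.tri(m, diag = TRUE)
    m[up] <- stats::rpois(sum(up), lambda[up])
    m <- m + t(m) - diag(diag(m))
    mats[[chrom]] <- contact_matrix(chrom, cfg$bin_size, m)
  }
  truth <- do.call(rbind, lapply(cfg$tad_plan, function(td) {
    rows <- data.frame(chrom = td$chrom,
                       start_bp = td$start_bin * cfg$bin_size,
                       end_bp = td$end_bin * cfg$bin_size,
                       level = "tad")
    if (!is.null(td$nested_sub))
      rows <- rbind(rows, data.frame(
        chrom = td$chrom,
        start_bp = td$nested_sub[1] * cfg$bin_size,
        end_bp = td$nested_sub[2] * cfg$bin_size,
        level = "sub_tad"))
    rows
  }))
  list(matrices = mats, tad_truth = truth)
}

#' Planted boundary bins of a TAD plan
#'
#' Internal TAD-to-TAD transition bins per chromosome (a boundary bin is the
#' first bin of the downstream TAD, 0-based). Chromosome edges are not
#' boundaries.
#'
#' @param cfg A [simulation_config()].
#' @return Named list of integer vectors, one per chromosome.
#' @export
planted_boundaries <- function(cfg) {
  out <- list()
  for (chrom in names(cfg$genome)) {
    tds <- Filter(function(t) t$chrom == chrom, cfg$tad_plan)
    if (length(tds) < 2) { out[[chrom]] <- integer(0); next }
    edges <- sort(unique(unlist(lapply(tds, function(t)
      c(t$start_bin, t$end_bin)))))
    n_bins <- cfg$genome[[chrom]] / cfg$bin_size
    out[[chrom]] <- edges[edges > 0 & edges < n_bins]
  }
  out
}
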