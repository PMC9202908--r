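#' Features whose TSS falls inside a TAD
#'
#' Default rule is promoter-centric TSS containment in the half-open span
#' `[start_bp, end_bp)` (genes in one TAD share its cis-regulatory
#' context); `overlap = "any"` instead keeps any feature whose body
#' overlaps the TAD.
#'
#' @param ann Annotation data.frame (0-based half-open, with `tss`).
#' @param tad One row of a `tad_set` (list or single-row data.frame with
#'   `chrom`, `start_bp`, `end_bp`).
#' @param overlap `"tss"` (default) or `"any"`.
#' @return Character vector of feature ids.
#' @export
features_in_tad <- function(ann, tad, overlap = c("tss", "any")) {
  overlap <- match.arg(overlap)
  if (nrow(ann) == 0) return(character(0))
  tad_gr <- GenomicRanges::GRanges(
    tad$chrom, IRanges::IRanges(start = tad$start_bp + 1,
                                end = tad$end_bp))
  if (overlap == "tss") {
    q <- GenomicRanges::GRanges(ann$chrom,
                                IRanges::IRanges(start = ann$tss + 1,
                                                 width = 1))
  } else {
    q <- GenomicRanges::GRanges(ann$chrom,
                                IRanges::IRanges(start = ann$start + 1,
                                                 end = ann$end))
  }
  hit <- GenomicRanges::findOverlaps(q, tad_gr)
  ann$feature_id[unique(S4Vectors::queryHits(hit))]
}

#' TAD-local candidate filter
#'
#' The study's in-TAD screen: keep a feature iff its chosen p-value field
#' is strictly below `p_cut` and `|log2FC| >= lfc_cut`. The default uses
#' the raw p-value at 0.05 with |log2FC| >= 1, the in-locus criteria
#' (unlike the stricter genome-wide adjusted filter). Pure filter:
#' idempotent on its own output.
#'
#' @param features Feature ids to screen.
#' @param de A `de_result`; features missing from it are dropped with a
#'   message.
#' @param p_cut,lfc_cut Thresholds (defaults 0.05 and 1).
#' @param p_field `"raw"` or `"adjusted"`.
#' @return data.frame `feature_id`, `class`, `log2fc`, `p`, `q`,
#'   `direction`, sorted by p.
#' @export
prioritize <- function(features, de, p_cut = 0.05, lfc_cut = 1,
                       p_field = c("raw", "adjusted")) {
  p_field <- match.arg(p_field)
  miss <- setdiff(features, de$feature_id)
  if (length(miss))
    message("prioritize: ", length(miss),
            " feature(s) missing from DE result dropped")
  rows <- de[de$feature_id %in% features, , drop = FALSE]
  pv <- if (p_field == "adjusted") rows$q else rows$p
  keep <- !is.na(pv) & pv < p_cut & !is.na(rows$log2fc) &
    abs(rows$log2fc) >= lfc_cut
  out <- rows[keep, c("feature_id", "class", "log2fc", "p", "q"),
              drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out <- out[order(out$p, out$feature_id), ]
  rownames(out) <- NULL
  out
}

#' Per-locus candidate table (the pipeline's terminal output)
#'
#' For every susceptibility locus: find the containing TAD(s) at both
#' levels, collect the features whose TSS falls inside each, and apply the
#' TAD-local filter. Loci with no containing TAD are reported with status
#' `no_tad`; loci whose TAD yields no passing feature are still reported
#' (status `empty`). Sub-TAD rows are flagged by their `level` column.
#'
#' @param loci List of locus lists (`name`, `chrom`, `snp_pos`).
#' @param tads A `tad_set`.
#' @param ann Annotation data.frame.
#' @param de A `de_result`.
#' @param p_cut,lfc_cut,p_field See [prioritize()].
#' @param overlap Gene-in-TAD rule, see [features_in_tad()].
#' @return List: `candidates` (data.frame locus, chrom, tad_start_bp,
#'   tad_end_bp, level, feature_id, class, log2fc, p, q, direction,
#'   sorted by locus then p) and `locus_status` (locus, status in
#'   \{ok, empty, no_tad\}).
#' @export
prioritize_loci <- function(loci, tads, ann, de, p_cut = 0.05,
                            lfc_cut = 1, p_field = "raw",
                            overlap = "tss") {
  cand <- list(); status <- list()
  for (lc in loci) {
    hit <- locate_tad(tads, lc)
    if (nrow(hit) == 0) {
      status[[lc$name]] <- "no_tad"
      next
    }
    rows <- list()
    for (i in seq_len(nrow(hit))) {
      td <- hit[i, ]
      feats <- features_in_tad(ann, td, overlap = overlap)
      tab <- prioritize(feats, de, p_cut = p_cut, lfc_cut = lfc_cut,
                        p_field = p_field)
      if (nrow(tab) > 0)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(locus = lc$name, chrom = td$chrom,
                     tad_start_bp = td$start_bp, tad_end_bp = td$end_bp,
                     level = td$level), tab)
    }
    if (length(rows)) {
      cand[[lc$name]] <- do.call(rbind, rows)
      status[[lc$name]] <- "ok"
    } else {
      status[[lc$name]] <- "empty"
    }
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(locus = character(), chrom = character(),
               tad_start_bp = numeric(), tad_end_bp = numeric(),
               level = character(), feature_id = character(),
               class = character(), log2fc = numeric(), p = numeric(),
               q = numeric(), direction = character())
  candidates <- candidates[order(candidates$locus, candidates$p,
                                 candidates$feature_id), ]
  rownames(candidates) <- NULL
  list(candidates = candidates,
       locus_status = data.frame(
         locus = names(status),
         status = unlist(status, use.names = FALSE)))
}

#' Write / read a susceptibility-locus BED file
#'
#' BED4: chrom, snp_pos, snp_pos + 1, name (0-based half-open single-bp
#' intervals). The reader also accepts a plain `chrom:pos` SNP list (one
#' per line, optional trailing label).
#'
#' @param loci List of locus lists.
#' @param path File path.
#' @return Invisibly `path` (writer); list of locus lists (reader).
#' @export
write_loci_bed <- function(loci, path) {
  df <- do.call(rbind, lapply(loci, function(l)
    data.frame(chrom = l$chrom,
               start = format(l$snp_pos, scientific = FALSE, trim = TRUE),
               end = format(l$snp_pos + 1, scientific = FALSE,
                            trim = TRUE),
               name = l$name)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_loci_bed
#' @export
read_loci <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (all(grepl(":", sub("\\s.*", "", lines)))) {
    out <- lapply(seq_along(lines), function(i) {
      fld <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      cp <- strsplit(fld[1], ":")[[1]]
      list(name = if (length(fld) > 1) fld[2] else paste0("locus_", i),
           chrom = cp[1], snp_pos = as.numeric(cp[2]))
    })
    return(out)
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    list(name = if (ncol(df) >= 4) df[i, 4] else paste0("locus_", i),
         chrom = df[i, 1], snp_pos = as.numeric(df[i, 2])))
}
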