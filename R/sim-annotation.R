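#' Generate a synthetic gene annotation
#'
#' Places mRNA, lncRNA and miRNA features with mutually distinct TSS
#' positions, uniformly over the genome except for planted locus candidates,
#' whose TSS is placed inside their locus's target TAD (or inside its nested
#' sub-TAD when the candidate is flagged `in_sub_tad`). Coordinates are
#' 0-based half-open internally; the TSS is `start` on the + strand and
#' `end - 1` on the - strand.
#'
#' @param cfg A [simulation_config()].
#' @return A data.frame with columns `feature_id`, `class`, `chrom`,
#'   `start`, `end`, `strand`, `tss` and logical `planted_candidate`.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(cfg$genome) == 0) stop("generate_annotation: empty genome")
  set.seed(sim_seed(cfg, "annotation"))

  cand <- do.call(rbind, lapply(cfg$loci_plan, function(lc) {
    pc <- lc$planted_candidates
    if (nrow(pc) == 0) return(NULL)
    td <- cfg$tad_plan[[lc$target_tad]]
    span <- cbind(rep(td$start_bin, nrow(pc)), rep(td$end_bin, nrow(pc)))
    if (!is.null(td$nested_sub) && !is.null(pc$in_sub_tad)) {
      span[pc$in_sub_tad, 1] <- td$nested_sub[1]
      span[pc$in_sub_tad, 2] <- td$nested_sub[2]
    }
    data.frame(feature_id = pc$feature_id, class = pc$class,
               chrom = lc$chrom,
               lo = span[, 1] * cfg$bin_size,
               hi = span[, 2] * cfg$bin_size)
  }))

  n_rand <- c(mRNA = cfg$n_mrna, lncRNA = cfg$n_lnc, miRNA = cfg$n_mir)
  rand <- data.frame(
    feature_id = c(sprintf("mrna_%04d", seq_len(n_rand["mRNA"])),
                   sprintf("lnc_%04d", seq_len(n_rand["lncRNA"])),
                   sprintf("mir_%04d", seq_len(n_rand["miRNA"]))),
    class = rep(names(n_rand), n_rand))

  n_all <- nrow(rand) + if (is.null(cand)) 0L else nrow(cand)
  if (n_all == 0L) {
    ann <- data.frame(feature_id = character(), class = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      tss = numeric(), planted_candidate = logical())
    return(ann)
  }

  # distinct TSS positions: sample genome-wide offsets without replacement
  chrom_len <- cfg$genome
  offsets <- c(0, cumsum(as.numeric(chrom_len)))[seq_along(chrom_len)]
  names(offsets) <- names(chrom_len)
  total <- sum(as.numeric(chrom_len))
  taken <- numeric(0)

  # gene-desert exclusion zones (target TAD +/- one bin) in global offsets
  deserts <- do.call(rbind, lapply(cfg$loci_plan, function(lc) {
    if (!isTRUE(lc$gene_desert)) return(NULL)
    td <- cfg$tad_plan[[lc$target_tad]]
    c(offsets[[td$chrom]] + (td$start_bin - 1) * cfg$bin_size,
      offsets[[td$chrom]] + (td$end_bin + 1) * cfg$bin_size)
  }))
  in_desert <- function(p) {
    if (is.null(deserts)) return(rep(FALSE, length(p)))
    hit <- rep(FALSE, length(p))
    for (i in seq_len(nrow(deserts)))
      hit <- hit | (p >= deserts[i, 1] & p < deserts[i, 2])
    hit
  }

  draw_pos <- function(n, lo = NULL, hi = NULL, chrom = NULL) {
    # draws n distinct global offsets, optionally restricted to a window
    out <- numeric(0)
    while (length(out) < n) {
      m <- (n - length(out)) * 2L + 8L
      if (is.null(lo)) {
        p <- floor(stats::runif(m, 0, total))
        p <- p[!in_desert(p)]
      } else {
        p <- floor(stats::runif(m, offsets[[chrom]] + lo,
                                offsets[[chrom]] + hi))
      }
      p <- setdiff(unique(p), taken)
      out <- c(out, utils::head(p, n - length(out)))
    }
    taken <<- c(taken, out)
    out
  }

  rows <- list()
  if (!is.null(cand)) {
    gp <- numeric(nrow(cand))
    for (i in seq_len(nrow(cand)))
      gp[i] <- draw_pos(1L, cand$lo[i], cand$hi[i], cand$chrom[i])
    rows$cand <- data.frame(feature_id = cand$feature_id,
                            class = cand$class, gpos = gp,
                            planted_candidate = TRUE)
  }
  if (nrow(rand) > 0) {
    rows$rand <- data.frame(feature_id = rand$feature_id,
                            class = rand$class,
                            gpos = draw_pos(nrow(rand)),
                            planted_candidate = FALSE)
  }
  ann <- do.call(rbind, rows)

  ci <- findInterval(ann$gpos, c(offsets, total), rightmost.closed = FALSE)
  ann$chrom <- names(chrom_len)[ci]
  ann$tss <- ann$gpos - offsets[ci]
  ann$strand <- sample(c("+", "-"), nrow(ann), replace = TRUE)
  len <- ifelse(ann$class == "miRNA",
                sample(80:120, nrow(ann), replace = TRUE),
                sample(1000:10000, nrow(ann), replace = TRUE))
  plus <- ann$strand == "+"
  ann$start <- ifelse(plus, ann$tss, pmax(0, ann$tss + 1 - len))
  ann$end <- ifelse(plus, pmin(chrom_len[ann$chrom], ann$tss + len),
                    ann$tss + 1)
  ann <- ann[order(ann$chrom, ann$start, ann$feature_id), ]
  rownames(ann) <- NULL
  ann[, c("feature_id", "class", "chrom", "start", "end", "strand", "tss",
          "planted_candidate")]
}

annotation_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1, end = ann$end),
    strand = ann$strand,
    feature_id = ann$feature_id, class = ann$class)
}

#' Write annotation files (GTF and BED)
#'
#' GTF is 1-based closed, BED 0-based half-open (standard dialects); both
#' are written through `rtracklayer`. Date-stamped comment headers are
#' stripped so identical configurations give byte-identical files.
#'
#' @param ann Annotation data.frame from [generate_annotation()].
#' @param gtf_path,bed_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(ann, gtf_path, bed_path) {
  if (nrow(ann) == 0) {
    writeLines("##gff-version 2", gtf_path)
    file.create(bed_path)
    return(invisible(c(gtf = gtf_path, bed = bed_path)))
  }
  gr <- annotation_granges(ann)
  S4Vectors::mcols(gr)$type <- "gene"
  rtracklayer::export(gr, gtf_path, format = "gtf")
  lines <- readLines(gtf_path)
  writeLines(lines[!grepl("^##(date|source-version)", lines)], gtf_path)
  bed <- gr
  S4Vectors::mcols(bed) <- S4Vectors::DataFrame(name = ann$feature_id,
                                                score = 0L)
  rtracklayer::export(bed, bed_path, format = "bed")
  invisible(c(gtf = gtf_path, bed = bed_path))
}

#' Read an annotation written by [write_annotation()]
#'
#' @param gtf_path Path to the GTF file.
#' @return An annotation data.frame (0-based half-open, with TSS).
#' @export
read_annotation_gtf <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  strand <- as.character(BiocGenerics::strand(gr))
  start0 <- BiocGenerics::start(gr) - 1
  end0 <- BiocGenerics::end(gr)
  ann <- data.frame(
    feature_id = S4Vectors::mcols(gr)$feature_id,
    class = S4Vectors::mcols(gr)$class,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0, strand = strand,
    tss = ifelse(strand == "+", start0, end0 - 1))
  rownames(ann) <- NULL
  ann
}
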