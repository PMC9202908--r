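#' Binned Hi-C contact matrix
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp (the study default is 40 kb).
#' @param m Symmetric non-negative square matrix of contacts.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(chrom, bin_size, m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("contact_matrix: matrix must be square")
  if (any(m < 0)) stop("contact_matrix: negative entries")
  if (max(abs(m - t(m))) > 1e-9)
    stop("contact_matrix: matrix not symmetric")
  structure(list(chrom = chrom, bin_size = as.integer(bin_size), m = m,
                 n_bins = nrow(m)), class = "contact_matrix")
}

#' Read a contact matrix from dense TSV or COO triplets
#'
#' Dense input is a whitespace-separated square matrix without headers; COO
#' input has a header `bin_i bin_j count` with 0-based bin indices, missing
#' pairs are zero. Input is symmetrized by `max(m, t(m))`; a warning is
#' emitted when the relative asymmetry of a dense input exceeds 1e-6.
#'
#' @param path Input file.
#' @param format `"dense"` or `"coo"`.
#' @param bin_size Bin size in bp.
#' @param chrom Chromosome label to attach.
#' @param n_bins Number of bins (COO only; default: max index + 1).
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense", "coo"),
                                bin_size, chrom = "chr", n_bins = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    nf <- utils::count.fields(path)
    if (length(unique(nf)) != 1)
      stop("read_contact_matrix: ragged dense row at line ",
           which(nf != nf[1])[1])
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (any(m < 0)) stop("read_contact_matrix: negative entries")
    rel <- max(abs(m - t(m))) / max(1, max(abs(m)))
    if (rel > 1e-6)
      warning("read_contact_matrix: asymmetry ", signif(rel, 3),
              "; symmetrizing by max(m, t(m))")
    m <- pmax(m, t(m))
  } else {
    coo <- utils::read.table(path, header = TRUE)
    stopifnot(all(c("bin_i", "bin_j", "count") %in% names(coo)))
    if (any(coo$count < 0)) stop("read_contact_matrix: negative entries")
    nb <- if (is.null(n_bins)) max(coo$bin_i, coo$bin_j) + 1L
          else as.integer(n_bins)
    if (any(coo$bin_i >= nb | coo$bin_j >= nb | coo$bin_i < 0 |
            coo$bin_j < 0))
      stop("read_contact_matrix: COO triplet out of bounds")
    m <- matrix(0, nb, nb)
    m[cbind(coo$bin_i + 1L, coo$bin_j + 1L)] <- coo$count
    m <- pmax(m, t(m))
  }
  contact_matrix(chrom, bin_size, m)
}

#' Write a contact matrix as dense TSV and/or COO triplets
#'
#' @param cm A [contact_matrix()].
#' @param dense_path,coo_path Output paths (NULL to skip either). The COO
#'   file holds the nonzero upper triangle (including the diagonal) with
#'   0-based indices.
#' @return Invisibly, the written paths.
#' @export
write_contact_matrix <- function(cm, dense_path = NULL, coo_path = NULL) {
  if (!is.null(dense_path))
    utils::write.table(cm$m, dense_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(coo_path)) {
    up <- which(upper.tri(cm$m, diag = TRUE) & cm$m != 0, arr.ind = TRUE)
    coo <- data.frame(bin_i = up[, 1] - 1L, bin_j = up[, 2] - 1L,
                      count = cm$m[up])
    coo <- coo[order(coo$bin_i, coo$bin_j), ]
    utils::write.table(coo, coo_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(dense = dense_path, coo = coo_path))
}

#' Insulation score track
#'
#' Square-window insulation: for bin b (0-based), `raw(b)` is the mean
#' contact between the `w` bins upstream (b-w .. b-1) and the `w` bins
#' downstream (b+1 .. b+w); the score is `IS(b) = log2(raw(b) / mean raw)`
#' where the mean runs over all bins with a complete window. Bins within
#' `w` of either matrix edge are undefined (NA).
#'
#' @param cm A [contact_matrix()].
#' @param w Window half-width in bins (default 5, i.e. 200 kb at 40 kb
#'   resolution).
#' @return An `insulation_track`: list with `IS` (length n_bins, NA at
#'   undefined bins; index 1 is bin 0), `w`, `chrom`, `bin_size`.
#' @export
insulation <- function(cm, w = 5L) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$n_bins
  if (n <= 2L * w) stop("insulation: need n_bins > 2*w")
  raw <- rep(NA_real_, n)
  for (b in (w + 1L):(n - w))
    raw[b] <- mean(cm$m[(b - w):(b - 1L), (b + 1L):(b + w)])
  mu <- mean(raw, na.rm = TRUE)
  if (!is.finite(mu) || mu == 0) {
    warning("insulation: all-zero matrix, score undefined everywhere")
    IS <- rep(NA_real_, n)
  } else {
    IS <- log2(raw / mu)
  }
  structure(list(IS = IS, w = as.integer(w), chrom = cm$chrom,
                 bin_size = cm$bin_size), class = "insulation_track")
}

#' Write an insulation track as TSV (bin, start, end, IS)
#' @param track An [insulation()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_insulation <- function(track, path) {
  n <- length(track$IS)
  df <- data.frame(bin = 0:(n - 1),
                   start = (0:(n - 1)) * track$bin_size,
                   end = (1:n) * track$bin_size,
                   IS = track$IS)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# local minima of the defined IS segment with boundary strengths:
# strength = (lower of the two nearest flanking local maxima) - minimum,
# with segment-edge maxima standing in where no interior maximum exists.
# side = "max" scores the higher flank instead - used by the sub-TAD pass,
# where a nested high-contact domain makes boundaries step-like (only one
# flank rises).
boundary_candidates <- function(IS, side = c("min", "max")) {
  side <- match.arg(side)
  def <- which(!is.na(IS))
  x <- IS[def]
  n <- length(x)
  if (n < 3) return(data.frame(bin = integer(), delta = numeric()))
  d2 <- diff(sign(diff(x)))
  loc_min <- which(d2 > 0) + 1L
  loc_max <- which(d2 < 0) + 1L
  out <- lapply(loc_min, function(b) {
    lm <- loc_max[loc_max < b]
    rm <- loc_max[loc_max > b]
    lv <- if (length(lm)) x[max(lm)] else max(x[1:b])
    rv <- if (length(rm)) x[min(rm)] else max(x[b:n])
    flank <- if (side == "min") min(lv, rv) else max(lv, rv)
    c(bin = def[b] - 1L, delta = flank - x[b])  # 0-based bin
  })
  as.data.frame(do.call(rbind, out))
}

#' Call TADs from an insulation track
#'
#' Boundaries are local minima of the insulation score whose boundary
#' strength (drop below the lower of the two flanking local maxima) is at
#' least `delta_min`. Domains tile the chromosome between consecutive
#' boundaries; intervals shorter than `min_bins` are dropped. With
#' `sub_pass = TRUE` (and the contact matrix supplied) each called TAD is
#' re-scanned at half the window width and its internal partition is
#' emitted at `sub_tad` level.
#'
#' @param track An [insulation()] result.
#' @param delta_min Minimum boundary strength in log2 units (default 0.5).
#' @param min_bins Minimum domain span in bins (default 3).
#' @param sub_pass Logical; run the finer-scale second pass.
#' @param cm The [contact_matrix()] (required when `sub_pass = TRUE`).
#' @param delta_sub Boundary-strength threshold for the second pass; the
#'   half-width window is noisier, so the default doubles `delta_min`.
#' @return A `tad_set` data.frame: chrom, start_bp, end_bp, level; bp
#'   intervals are 0-based half-open and bin-aligned.
#' @export
call_tads <- function(track, delta_min = 0.5, min_bins = 3L,
                      sub_pass = FALSE, cm = NULL,
                      delta_sub = 2 * delta_min) {
  stopifnot(inherits(track, "insulation_track"))
  n <- length(track$IS)
  bc <- boundary_candidates(track$IS)
  bounds <- sort(bc$bin[bc$delta >= delta_min])
  cuts <- unique(c(0L, bounds, n))
  tads <- data.frame(chrom = track$chrom,
                     start_bp = utils::head(cuts, -1) * track$bin_size,
                     end_bp = utils::tail(cuts, -1) * track$bin_size,
                     level = "tad")
  tads <- tads[(tads$end_bp - tads$start_bp) >= min_bins * track$bin_size, ]
  rownames(tads) <- NULL
  if (sub_pass) {
    if (is.null(cm)) stop("call_tads: sub_pass requires the contact matrix")
    w2 <- max(1L, track$w %/% 2L)
    subs <- list()
    for (i in seq_len(nrow(tads))) {
      b0 <- tads$start_bp[i] / track$bin_size
      b1 <- tads$end_bp[i] / track$bin_size
      if ((b1 - b0) <= 2L * w2 + 2L) next
      sub_m <- cm$m[(b0 + 1):b1, (b0 + 1):b1, drop = FALSE]
      st <- insulation(contact_matrix(cm$chrom, cm$bin_size, sub_m), w2)
      sb <- boundary_candidates(st$IS, side = "max")
      sb <- sort(sb$bin[sb$delta >= delta_sub])
      if (!length(sb)) next
      cuts <- unique(c(0L, sb, b1 - b0))
      si <- data.frame(chrom = track$chrom,
                       start_bp = (b0 + utils::head(cuts, -1)) *
                         track$bin_size,
                       end_bp = (b0 + utils::tail(cuts, -1)) *
                         track$bin_size,
                       level = "sub_tad")
      si <- si[(si$end_bp - si$start_bp) >= min_bins * track$bin_size, ]
      subs[[length(subs) + 1]] <- si
    }
    if (length(subs)) tads <- rbind(tads, do.call(rbind, subs))
  }
  validate_tad_set(tads, track$bin_size)
  class(tads) <- c("tad_set", "data.frame")
  tads
}

validate_tad_set <- function(tads, bin_size = NULL) {
  if (nrow(tads) == 0) return(invisible(tads))
  if (any(tads$end_bp <= tads$start_bp))
    stop("tad_set: end_bp must exceed start_bp")
  for (lev in unique(tads$level)) {
    sub <- tads[tads$level == lev, ]
    for (ch in unique(sub$chrom)) {
      iv <- sub[sub$chrom == ch, c("start_bp", "end_bp")]
      iv <- iv[order(iv$start_bp), ]
      bad <- which(iv$start_bp[-1] < iv$end_bp[-nrow(iv)])
      if (length(bad))
        stop("tad_set: overlapping ", lev, " intervals on ", ch,
             " (rows ", paste(bad, collapse = ","), ")")
    }
  }
  invisible(tads)
}

#' Write a TAD set as BED (0-based half-open; name column = level)
#' @param tads A `tad_set` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tads_bed <- function(tads, path) {
  df <- data.frame(chrom = tads$chrom,
                   start = format(tads$start_bp, scientific = FALSE,
                                  trim = TRUE),
                   end = format(tads$end_bp, scientific = FALSE,
                                trim = TRUE),
                   name = tads$level)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a TAD set from BED
#'
#' BED3+ with 0-based half-open intervals; an optional 4th column equal to
#' `"sub_tad"` marks nested domains (anything else, or no column, is level
#' `"tad"`). Same-level overlaps are an error.
#'
#' @param path BED file path.
#' @return A `tad_set` data.frame.
#' @export
load_tads_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("load_tads_bed: need BED3+")
  tads <- data.frame(chrom = as.character(df[[1]]),
                     start_bp = as.numeric(df[[2]]),
                     end_bp = as.numeric(df[[3]]),
                     level = if (ncol(df) >= 4)
                       ifelse(df[[4]] == "sub_tad", "sub_tad", "tad")
                     else "tad")
  validate_tad_set(tads)
  class(tads) <- c("tad_set", "data.frame")
  tads
}

#' Find the TAD(s) containing a locus
#'
#' Returns every interval (both `tad` and `sub_tad` level) whose half-open
#' span `[start_bp, end_bp)` contains the SNP position.
#'
#' @param tads A `tad_set` data.frame.
#' @param locus A list with `name`, `chrom`, `snp_pos` (0-based bp).
#' @return The matching rows of `tads` (possibly zero rows).
#' @export
locate_tad <- function(tads, locus) {
  if (nrow(tads) == 0 || !locus$chrom %in% tads$chrom) {
    if (nrow(tads) > 0)
      warning("locate_tad: chromosome '", locus$chrom,
              "' absent from TAD set")
    return(tads[integer(0), ])
  }
  hit <- tads$chrom == locus$chrom & tads$start_bp <= locus$snp_pos &
    locus$snp_pos < tads$end_bp
  tads[hit, , drop = FALSE]
}
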