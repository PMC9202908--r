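#' Write / read a counts table (features x samples TSV)
#'
#' First column `feature_id`, remaining header fields are sample ids.
#'
#' @param counts Integer matrix with dimnames.
#' @param path File path.
#' @return Invisibly `path` (writer); named integer matrix (reader).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read the paired design sheet (sample, patient, condition)
#'
#' @param design data.frame with columns `sample`, `patient`, `condition`.
#' @param path File path.
#' @return Invisibly `path` (writer); data.frame (reader).
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a miRNA-target table (miRNA_id, target_id TSV)
#'
#' @param targets data.frame with columns `miRNA_id`, `target_id`.
#' @param path File path.
#' @return Invisibly `path` (writer); data.frame (reader).
#' @export
write_targets <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

write_tsv_quiet <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
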