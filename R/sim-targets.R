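#' Generate miRNA-target table, pathway sets and their ground truth
#'
#' Every miRNA receives a random set of mRNA targets with out-degree drawn
#' from `cfg$target_degree_range`; one designated hub miRNA gets the
#' maximal out-degree, so its degree is >= every other miRNA's by
#' construction. One pathway gene set is deliberately enriched for planted
#' DE mRNAs; the remaining sets are drawn at random from all mRNAs.
#'
#' @param cfg A [simulation_config()].
#' @param ann Annotation from [generate_annotation()].
#' @param de_truth DE truth table from [generate_counts()].
#' @return A list: `targets` (data.frame miRNA_id, target_id), `hub_mirna`,
#'   `pathways` (named list of member vectors), `enriched_pathway` (name of
#'   the DE-loaded set).
#' @export
generate_targets_and_pathways <- function(cfg, ann, de_truth) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(sim_seed(cfg, "targets"))
  mirnas <- ann$feature_id[ann$class == "miRNA"]
  mrnas <- ann$feature_id[ann$class == "mRNA"]
  deg_rng <- cfg$target_degree_range
  if (deg_rng[2] > length(mrnas))
    stop("configuration error: requested target degree exceeds n_mrna")

  targets <- NULL
  hub <- NA_character_
  if (length(mirnas) > 0 && length(mrnas) > 0) {
    hub <- mirnas[1]
    # the hub gets strictly the most targets (others stay below the max)
    lo <- deg_rng[1]
    hi <- max(lo, deg_rng[2] - 1L)
    degree <- stats::setNames(
      sample(seq(lo, hi), length(mirnas), replace = TRUE), mirnas)
    degree[hub] <- deg_rng[2]
    targets <- do.call(rbind, lapply(mirnas, function(m) data.frame(
      miRNA_id = m, target_id = sort(sample(mrnas, degree[[m]])))))
    rownames(targets) <- NULL
  } else {
    targets <- data.frame(miRNA_id = character(), target_id = character())
  }

  pathways <- list()
  enriched <- NA_character_
  if (cfg$n_pathways > 0 && length(mrnas) >= cfg$pathway_size) {
    de_mrna <- de_truth$feature_id[de_truth$is_de &
                                   de_truth$class == "mRNA"]
    names_pw <- sprintf("pathway_%02d", seq_len(cfg$n_pathways))
    pathways <- lapply(names_pw, function(nm) sort(sample(mrnas,
                                                          cfg$pathway_size)))
    names(pathways) <- names_pw
    if (length(de_mrna) > 0) {
      enriched <- names_pw[1]
      n_de_in <- min(length(de_mrna), ceiling(cfg$pathway_size / 2))
      extra <- sample(setdiff(mrnas, de_mrna),
                      cfg$pathway_size - n_de_in)
      pathways[[enriched]] <- sort(c(sample(de_mrna, n_de_in), extra))
    }
  }
  list(targets = targets, hub_mirna = hub, pathways = pathways,
       enriched_pathway = enriched)
}

#' Write a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>`
#' followed by tab-separated member ids.
#'
#' @param pathways Named list of member id vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "synthetic", pathways[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file.
#' @return Named list of member id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
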