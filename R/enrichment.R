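#' Gene-set collection with explicit universe
#'
#' @param sets Named list of member id vectors (deduplicated per set).
#' @param universe Character vector of background ids. By default the
#'   union of all set members; the conventional pipeline choice is all
#'   detected features carrying at least one set annotation.
#' @return A `gene_set_collection` list.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  sets <- lapply(sets, unique)
  if (is.null(universe)) universe <- unique(unlist(sets))
  if (!length(universe)) stop("gene_set_collection: empty universe")
  sets <- lapply(sets, intersect, universe)
  if (length(sets) && max(lengths(sets)) > length(universe))
    stop("gene_set_collection: set larger than universe")
  structure(list(sets = sets, universe = universe,
                 N = length(universe)), class = "gene_set_collection")
}

#' Fisher's exact over-representation test
#'
#' One-sided hypergeometric upper tail `P(X >= k)` for the overlap `k`
#' between the query and each set, over a universe of size `N`; BH
#' adjustment across sets. Query ids outside the universe are dropped
#' with a message.
#'
#' @param query Character vector of query ids.
#' @param gsc A [gene_set_collection()].
#' @param p_cut Significance flag threshold on the raw Fisher p (default
#'   0.01, the study's cut).
#' @return data.frame sorted by p: `set`, `k`, `K`, `n`, `N`, `p`,
#'   `odds_ratio`, `q`, `significant`.
#' @export
fisher_enrich <- function(query, gsc, p_cut = 0.01) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  query <- unique(query)
  outside <- setdiff(query, gsc$universe)
  if (length(outside))
    message("fisher_enrich: ", length(outside),
            " query id(s) outside universe dropped")
  q_in <- intersect(query, gsc$universe)
  n <- length(q_in); N <- gsc$N
  rows <- lapply(names(gsc$sets), function(nm) {
    set <- gsc$sets[[nm]]
    K <- length(set)
    k <- length(intersect(q_in, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    orr <- (k * (N - K - n + k)) / max(1e-300, (K - k) * (n - k))
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               odds_ratio = orr)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      odds_ratio = numeric())
  tab$q <- adjust_bh(tab$p)
  tab$significant <- tab$p < p_cut
  tab <- tab[order(tab$p, tab$set), ]
  rownames(tab) <- NULL
  tab
}

#' Per-module enrichment with top-k reporting
#'
#' Runs [fisher_enrich()] for each module's gene list and reports, per
#' module, the top `top_k` sets by p-value (default 8, following the
#' study's per-module display rule).
#'
#' @param module_genes Named list: module name -> member gene ids
#'   (nonempty).
#' @param gsc A [gene_set_collection()].
#' @param top_k Sets reported per module (default 8).
#' @param p_cut Significance flag threshold (default 0.01).
#' @return data.frame with a `module` column prepended to the
#'   [fisher_enrich()] columns, restricted to each module's top `top_k`.
#' @export
enrich_modules <- function(module_genes, gsc, top_k = 8, p_cut = 0.01) {
  stopifnot(length(module_genes) > 0, all(lengths(module_genes) > 0))
  out <- lapply(names(module_genes), function(m) {
    tab <- fisher_enrich(module_genes[[m]], gsc, p_cut = p_cut)
    cbind(module = m, utils::head(tab, top_k))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Substitute lncRNAs by their co-expressed mRNA partners
#'
#' lncRNA "target gene" enrichment is realized by replacing each DE lncRNA
#' with the mRNAs it pairs with at the PCC threshold before testing.
#'
#' @param lnc_ids DE lncRNA ids.
#' @param pairs [pcc_pairs()] output.
#' @return Character vector of partner mRNA ids (unique).
#' @export
lnc_target_genes <- function(lnc_ids, pairs) {
  unique(pairs$mrna_id[pairs$lnc_id %in% lnc_ids])
}
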