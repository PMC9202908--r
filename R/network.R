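#' Typed RNA regulation network
#'
#' Node set with class (`mRNA`/`lncRNA`/`miRNA`/`protein`) and DE direction
#' (`up`/`down`/`none`); edge set typed as `mirna_target` (directed,
#' miRNA to target), `lnc_coexpr` or `ppi` (both undirected). Undirected
#' edges are stored with lexicographically ordered endpoints; duplicates
#' collapse under set semantics; self-loops are rejected.
#'
#' @param nodes data.frame `id`, `class`, `de_direction`.
#' @param edges data.frame `src`, `dst`, `etype`.
#' @return A `reg_network` object.
#' @export
reg_network <- function(nodes, edges) {
  nodes <- unique(nodes[, c("id", "class", "de_direction")])
  if (anyDuplicated(nodes$id))
    stop("reg_network: namespace collision - conflicting class/direction ",
         "for id(s) ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (nrow(edges) > 0) {
    stopifnot(all(c("src", "dst", "etype") %in% names(edges)))
    if (any(edges$src == edges$dst)) stop("reg_network: self-loop")
    if (!all(edges$etype %in% c("mirna_target", "lnc_coexpr", "ppi")))
      stop("reg_network: unknown edge type")
    und <- edges$etype != "mirna_target"
    flip <- und & edges$src > edges$dst
    tmp <- edges$src[flip]; edges$src[flip] <- edges$dst[flip]
    edges$dst[flip] <- tmp
    edges <- unique(edges[, c("src", "dst", "etype")])
    miss <- setdiff(c(edges$src, edges$dst), nodes$id)
    if (length(miss))
      stop("reg_network: edge endpoint(s) missing from nodes: ",
           paste(utils::head(miss, 5), collapse = ", "))
    mt <- edges$etype == "mirna_target"
    bad <- mt & nodes$class[match(edges$src, nodes$id)] != "miRNA"
    if (any(bad))
      stop("reg_network: mirna_target edge with non-miRNA source")
    edges <- edges[order(edges$etype, edges$src, edges$dst), ]
  } else {
    edges <- data.frame(src = character(), dst = character(),
                        etype = character())
  }
  nodes <- nodes[order(nodes$id), ]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "reg_network")
}

#' miRNA-target edges restricted to the DE miRNAs
#'
#' Keeps a target-table row iff its miRNA is differentially expressed;
#' with `de_targets_only = TRUE` targets are additionally restricted to
#' the DE gene list (the study keeps all targets for the miRNA-target
#' network and then maps DE genes onto it, so both modes exist).
#'
#' @param de_mirnas Character vector of DE miRNA ids.
#' @param de_genes Character vector of DE gene ids (used when
#'   `de_targets_only`).
#' @param target_table data.frame with columns `miRNA_id`, `target_id`
#'   (malformed rows are skipped with a message).
#' @param de_targets_only Restrict targets to `de_genes`.
#' @return data.frame `src`, `dst`, `etype = "mirna_target"`.
#' @export
build_mirna_edges <- function(de_mirnas, de_genes, target_table,
                              de_targets_only = FALSE) {
  stopifnot(all(c("miRNA_id", "target_id") %in% names(target_table)))
  bad <- is.na(target_table$miRNA_id) | is.na(target_table$target_id) |
    target_table$miRNA_id == "" | target_table$target_id == ""
  if (any(bad))
    message("build_mirna_edges: skipped malformed row(s) ",
            paste(utils::head(which(bad), 5), collapse = ", "))
  tt <- target_table[!bad, , drop = FALSE]
  keep <- tt$miRNA_id %in% de_mirnas
  if (de_targets_only) keep <- keep & tt$target_id %in% de_genes
  ed <- unique(data.frame(src = tt$miRNA_id[keep],
                          dst = tt$target_id[keep],
                          etype = rep("mirna_target", sum(keep))))
  rownames(ed) <- NULL
  ed
}

#' Merge typed edge sets into a regulation network
#'
#' Union of miRNA-target, lncRNA-mRNA co-expression and optional PPI
#' edges; node classes and DE directions are attached from the DE result.
#' A pair connected by two different edge types keeps both typed edges.
#' Conflicting classes for one id raise a namespace-collision error.
#'
#' @param mirna_edges data.frame from [build_mirna_edges()] (or NULL).
#' @param coexpr_pairs data.frame from [pcc_pairs()] (or NULL).
#' @param ppi_edges Optional data.frame `src`, `dst`.
#' @param de A `de_result` used to type nodes and attach directions;
#'   features absent from it get class from `class_of` and direction
#'   `none`.
#' @param class_of Named class vector fallback for ids missing from `de`
#'   (PPI partners default to `protein`).
#' @return A [reg_network()].
#' @export
merge_network <- function(mirna_edges = NULL, coexpr_pairs = NULL,
                          ppi_edges = NULL, de = NULL, class_of = NULL) {
  parts <- list()
  if (!is.null(mirna_edges) && nrow(mirna_edges) > 0)
    parts$mir <- data.frame(src = mirna_edges$src, dst = mirna_edges$dst,
                            etype = "mirna_target")
  if (!is.null(coexpr_pairs) && nrow(coexpr_pairs) > 0)
    parts$coex <- data.frame(src = coexpr_pairs$lnc_id,
                             dst = coexpr_pairs$mrna_id,
                             etype = "lnc_coexpr")
  if (!is.null(ppi_edges) && nrow(ppi_edges) > 0)
    parts$ppi <- data.frame(src = ppi_edges$src, dst = ppi_edges$dst,
                            etype = "ppi")
  edges <- if (length(parts)) do.call(rbind, parts) else
    data.frame(src = character(), dst = character(), etype = character())
  ids <- unique(c(edges$src, edges$dst))
  cls <- rep(NA_character_, length(ids))
  dir <- rep("none", length(ids))
  if (!is.null(de)) {
    m <- match(ids, de$feature_id)
    cls <- ifelse(is.na(m), NA, de$class[m])
    lf <- de$log2fc[m]
    sig <- !is.na(m) & !is.na(de$q[m]) & de$q[m] < 0.05 & !is.na(lf)
    dir <- ifelse(sig & lf > 0, "up", ifelse(sig & lf < 0, "down", "none"))
  }
  if (!is.null(class_of)) {
    fill <- is.na(cls) & ids %in% names(class_of)
    cls[fill] <- class_of[ids[fill]]
  }
  cls[is.na(cls)] <- "protein"
  reg_network(data.frame(id = ids, class = cls, de_direction = dir),
              edges)
}

#' Degree table and top-n ranking
#'
#' Degree counts every incident edge; for directed miRNA-target edges
#' in/out degrees are reported separately and total degree is their sum.
#' Ranking is by degree descending with ties broken by node id, so the
#' top-n table is reproducible.
#'
#' @param net A [reg_network()].
#' @param top_n Rows to return (default 20); more nodes than available
#'   returns all.
#' @return data.frame `node_id`, `class`, `degree`, `in_degree`,
#'   `out_degree`.
#' @export
degree_ranking <- function(net, top_n = 20) {
  stopifnot(inherits(net, "reg_network"))
  ids <- net$nodes$id
  z <- stats::setNames(rep(0L, length(ids)), ids)
  dir <- net$edges$etype == "mirna_target"
  outd <- ind <- undd <- z
  if (any(dir)) {
    t1 <- table(net$edges$src[dir]); outd[names(t1)] <- as.integer(t1)
    t2 <- table(net$edges$dst[dir]); ind[names(t2)] <- as.integer(t2)
  }
  if (any(!dir)) {
    t3 <- table(c(net$edges$src[!dir], net$edges$dst[!dir]))
    undd[names(t3)] <- as.integer(t3)
  }
  tab <- data.frame(node_id = ids, class = net$nodes$class,
                    degree = outd + ind + undd,
                    in_degree = ind, out_degree = outd)
  tab <- tab[order(-tab$degree, tab$node_id), ]
  rownames(tab) <- NULL
  utils::head(tab, top_n)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = net$edges, directed = TRUE,
    vertices = net$nodes)
  g
}

#' Connected components of the network (edge direction ignored)
#'
#' @param net A [reg_network()].
#' @return List: `n_components`, `membership` (named integer vector).
#' @export
network_components <- function(net) {
  if (nrow(net$nodes) == 0)
    return(list(n_components = 0L, membership = integer(0)))
  comp <- igraph::components(
    igraph::as_undirected(as_igraph(net), mode = "collapse"))
  list(n_components = comp$no, membership = comp$membership)
}

#' Module-restricted subnetwork
#'
#' Keeps every edge with at least one endpoint assigned to a selected
#' module, plus the incident miRNAs (which carry no module label), and
#' reports the connected components of the result.
#'
#' @param net A [reg_network()].
#' @param labels Named module label vector covering the network's mRNA and
#'   lncRNA nodes.
#' @param selected Character vector of module names to keep.
#' @return List: `network` (the sub- [reg_network()]), `components`
#'   (see [network_components()]).
#' @export
extract_module_subnetwork <- function(net, labels, selected) {
  stopifnot(inherits(net, "reg_network"))
  known <- unique(labels)
  bad <- setdiff(selected, known)
  if (length(bad))
    stop("extract_module_subnetwork: unknown module name(s): ",
         paste(bad, collapse = ", "))
  in_mod <- function(id) !is.na(labels[id]) & labels[id] %in% selected
  keep <- in_mod(net$edges$src) | in_mod(net$edges$dst)
  edges <- net$edges[keep, , drop = FALSE]
  ids <- unique(c(edges$src, edges$dst))
  sub <- reg_network(net$nodes[net$nodes$id %in% ids, , drop = FALSE],
                     edges)
  list(network = sub, components = network_components(sub))
}

#' Export a regulation network (SIF, GraphML or edge TSV)
#'
#' GraphML (via igraph) is lossless for node classes, DE directions and
#' edge types; SIF uses the edge type as the relation token; TSV writes
#' the typed edge table.
#'
#' @param net A [reg_network()].
#' @param path Output path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", net$edges$src, net$edges$etype,
                       net$edges$dst), path)
  } else if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a regulation network back from GraphML
#'
#' @param path GraphML file written by [export_graph()].
#' @return A [reg_network()].
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      class = igraph::V(g)$class,
                      de_direction = igraph::V(g)$de_direction)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(src = el[, 1], dst = el[, 2],
                      etype = if (igraph::ecount(g))
                        igraph::E(g)$etype else character(0))
  reg_network(nodes, edges)
}
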