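#' Materialize a full synthetic study on disk
#'
#' Runs every generator under the configuration's seed and writes the
#' complete input bundle plus machine-readable ground truth: counts.tsv,
#' design.tsv, annotation.gtf/.bed, targets.tsv, pathways.gmt,
#' hic_<chrom>.tsv and hic_<chrom>.coo.tsv, loci.bed, and
#' truth_de/modules/tads/candidates tables. Identical configurations give
#' byte-identical files.
#'
#' @param cfg A [simulation_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, a list with all in-memory objects (`ann`, `counts`
#'   bundle, `hic` bundle, `tp` target/pathway bundle, `paths`).
#' @export
simulate_study <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  ann <- generate_annotation(cfg)
  gen <- generate_counts(cfg, ann)
  hic <- generate_hic(cfg)
  tp <- generate_targets_and_pathways(cfg, ann, gen$de_truth)

  write_annotation(ann, p("annotation.gtf"), p("annotation.bed"))
  write_counts(gen$cm$counts, p("counts.tsv"))
  write_design(gen$cm$design, p("design.tsv"))
  write_targets(tp$targets, p("targets.tsv"))
  write_gmt(tp$pathways, p("pathways.gmt"))
  for (chrom in names(hic$matrices))
    write_contact_matrix(hic$matrices[[chrom]],
                         p(sprintf("hic_%s.tsv", chrom)),
                         p(sprintf("hic_%s.coo.tsv", chrom)))
  write_loci_bed(cfg$loci_plan, p("loci.bed"))
  write_tsv_quiet(gen$de_truth, p("truth_de.tsv"))
  write_tsv_quiet(gen$module_truth, p("truth_modules.tsv"))
  write_tsv_quiet(hic$tad_truth, p("truth_tads.tsv"))
  cand_truth <- do.call(rbind, lapply(cfg$loci_plan, function(l)
    if (nrow(l$planted_candidates))
      data.frame(locus = l$name,
                 feature_id = l$planted_candidates$feature_id)))
  if (is.null(cand_truth))
    cand_truth <- data.frame(locus = character(),
                             feature_id = character())
  write_tsv_quiet(cand_truth, p("truth_candidates.tsv"))
  invisible(list(ann = ann, counts = gen, hic = hic, tp = tp,
                 candidate_truth = cand_truth, outdir = outdir))
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a synthetic configuration
#'
#' Executes simulate -> differential expression -> co-expression ->
#' regulatory network -> enrichment -> TAD calling -> locus
#' prioritization, writing every stage output under `outdir` together
#' with `run_manifest.json` (package version, seed, configuration hash,
#' per-stage row counts). Fully deterministic given the configuration;
#' stages named in `skip` are omitted (the TAD/prioritization arm is
#' independent of the co-expression arm).
#'
#' @param cfg A [simulation_config()].
#' @param outdir Output directory.
#' @param thresholds A [de_thresholds()] object.
#' @param skip Character vector among
#'   `c("coexpress", "network", "enrichment")`.
#' @param r_min,soft_powers,min_size,cut_frac,kme_min Co-expression
#'   options (see [pcc_pairs()], [pick_soft_power()], [detect_modules()]).
#' @param w,delta_min,min_bins TAD-calling options (see [insulation()],
#'   [call_tads()]).
#' @param p_cut,lfc_cut,p_field TAD-local filter (see [prioritize()]).
#' @param top_n Degree-table depth.
#' @return A results bundle (list) with every stage's objects and the
#'   manifest.
#' @export
run_pipeline <- function(cfg, outdir,
                         thresholds = de_thresholds(),
                         skip = character(0),
                         r_min = 0.9, soft_powers = 1:12, min_size = 30,
                         cut_frac = 0.9, kme_min = 0.9,
                         w = 5L, delta_min = 0.5, min_bins = 3L,
                         p_cut = 0.05, lfc_cut = 1, p_field = "raw",
                         top_n = 20) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  counts_of <- list()
  bundle <- list()

  sim <- stage_guard("simulate", simulate_study(cfg, p("inputs")))
  bundle$sim <- sim
  cm <- sim$counts$cm

  # differential expression
  de <- stage_guard("de", {
    sf <- size_factors_median_of_ratios(cm)
    paired_nb_test(cm, sf = sf)
  })
  write_de_results(de, p("de_results.tsv"))
  counts_of$de_results <- nrow(de)
  bundle$de <- de
  sf <- size_factors_median_of_ratios(cm)
  expr <- log_normalized(cm, sf)
  de_sets <- lapply(stats::setNames(nm = c("mRNA", "lncRNA", "miRNA")),
                    function(cl) filter_de(de, thresholds, cl))
  bundle$de_sets <- de_sets

  pairs <- NULL; ms <- NULL; sig <- NULL
  if (!"coexpress" %in% skip) {
    co <- stage_guard("coexpress", {
      de_g <- c(de_sets$mRNA$up, de_sets$mRNA$down)
      de_l <- c(de_sets$lncRNA$up, de_sets$lncRNA$down)
      pairs <- if (length(de_l) && length(de_g))
        pcc_pairs(expr[de_l, , drop = FALSE],
                  expr[de_g, , drop = FALSE], r_min = r_min)
      else data.frame(lnc_id = character(), mrna_id = character(),
                      r = numeric())
      feats <- c(de_g, de_l)
      ms <- NULL; sig <- NULL
      if (length(feats) >= 30) {
        sp <- pick_soft_power(expr[feats, , drop = FALSE],
                              powers = soft_powers)
        a <- adjacency_matrix(expr[feats, , drop = FALSE], sp$beta)
        tm <- tom_similarity(a)
        ms <- detect_modules(tm, expr[feats, , drop = FALSE],
                             min_size = min_size, cut_frac = cut_frac,
                             kme_min = kme_min)
        sig <- module_significance(ms, de)
      }
      list(pairs = pairs, ms = ms, sig = sig)
    })
    pairs <- co$pairs; ms <- co$ms; sig <- co$sig
    write_tsv_quiet(pairs, p("pcc_pairs.tsv"))
    counts_of$pcc_pairs <- nrow(pairs)
    if (!is.null(ms)) {
      write_tsv_quiet(data.frame(feature_id = names(ms$labels),
                                 module = unname(ms$labels)),
                      p("modules.tsv"))
      counts_of$modules <- length(ms$labels)
      write_tsv_quiet(sig$table, p("module_significance.tsv"))
      if (ncol(ms$eigengenes) > 0)
        write_tsv_quiet(data.frame(sample = colnames(cm$counts),
                                   ms$eigengenes, check.names = FALSE),
                        p("eigengenes.tsv"))
    }
    bundle$coexpress <- co
  }

  if (!"network" %in% skip) {
    net_out <- stage_guard("network", {
      de_mir <- c(de_sets$miRNA$up, de_sets$miRNA$down)
      de_gene <- c(de_sets$mRNA$up, de_sets$mRNA$down,
                   de_sets$lncRNA$up, de_sets$lncRNA$down)
      me <- build_mirna_edges(de_mir, de_gene, sim$tp$targets)
      net <- merge_network(me, pairs, de = de,
                           class_of = cm$class_of)
      list(net = net, degree = degree_ranking(net, top_n = top_n))
    })
    export_graph(net_out$net, p("network.graphml"), "graphml")
    export_graph(net_out$net, p("network.sif"), "sif")
    write_tsv_quiet(net_out$degree, p("degree_top.tsv"))
    counts_of$network_edges <- nrow(net_out$net$edges)
    counts_of$degree_top <- nrow(net_out$degree)
    bundle$network <- net_out
  }

  if (!"enrichment" %in% skip) {
    enr <- stage_guard("enrichment", {
      sets <- read_gmt(p("inputs/pathways.gmt"))
      detected <- names(which(detection_filter(cm)))
      gsc <- gene_set_collection(
        sets, universe = intersect(detected, unique(unlist(sets))))
      de_g <- c(de_sets$mRNA$up, de_sets$mRNA$down)
      tab <- fisher_enrich(de_g, gsc)
      list(gsc = gsc, table = tab)
    })
    write_tsv_quiet(enr$table, p("enrichment.tsv"))
    counts_of$enrichment <- nrow(enr$table)
    bundle$enrichment <- enr
  }

  tads_all <- stage_guard("tads", {
    out <- lapply(sim$hic$matrices, function(cmx) {
      tr <- insulation(cmx, w = w)
      call_tads(tr, delta_min = delta_min, min_bins = min_bins,
                sub_pass = TRUE, cm = cmx)
    })
    tads <- do.call(rbind, out)
    class(tads) <- c("tad_set", "data.frame")
    rownames(tads) <- NULL
    tads
  })
  write_tads_bed(tads_all, p("tads.bed"))
  counts_of$tads <- nrow(tads_all)
  bundle$tads <- tads_all

  pri <- stage_guard("prioritize", {
    loci <- read_loci(p("inputs/loci.bed"))
    prioritize_loci(loci, tads_all, sim$ann, de, p_cut = p_cut,
                    lfc_cut = lfc_cut, p_field = p_field)
  })
  write_tsv_quiet(pri$candidates, p("candidates.tsv"))
  write_tsv_quiet(pri$locus_status, p("locus_status.tsv"))
  for (lc in unique(pri$locus_status$locus))
    write_tsv_quiet(
      pri$candidates[pri$candidates$locus == lc, , drop = FALSE],
      p(sprintf("candidates_%s.tsv", lc)))
  counts_of$candidates <- nrow(pri$candidates)
  bundle$prioritize <- pri

  manifest <- list(
    package = "tadscope",
    version = as.character(utils::packageVersion("tadscope")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    row_counts = counts_of)
  jsonlite::write_json(manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  bundle$manifest <- manifest
  invisible(bundle)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
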