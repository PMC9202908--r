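#' Planted TAD specification
#'
#' Describes one topologically associating domain to plant in a synthetic
#' Hi-C contact matrix. Bin coordinates are 0-based half-open: a TAD
#' covering bins `start_bin .. end_bin - 1` spans
#' `[start_bin * bin_size, end_bin * bin_size)` bp.
#'
#' @param chrom Chromosome name.
#' @param start_bin,end_bin Half-open bin interval, `start_bin < end_bin`.
#' @param nested_sub Optional length-2 integer vector `(start_bin, end_bin)`
#'   of a sub-TAD strictly inside the parent; sub-TADs get an extra contact
#'   boost so a finer-scale caller can see them.
#' @return A `planted_tad` list.
#' @export
planted_tad <- function(chrom, start_bin, end_bin, nested_sub = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start_bin <- as.integer(start_bin); end_bin <- as.integer(end_bin)
  if (start_bin >= end_bin) stop("planted_tad: start_bin must be < end_bin")
  if (!is.null(nested_sub)) {
    nested_sub <- as.integer(nested_sub)
    stopifnot(length(nested_sub) == 2L)
    if (!(nested_sub[1] > start_bin && nested_sub[2] < end_bin &&
          nested_sub[1] < nested_sub[2]))
      stop("planted_tad: nested_sub must lie strictly inside the parent TAD")
  }
  structure(list(chrom = chrom, start_bin = start_bin, end_bin = end_bin,
                 nested_sub = nested_sub), class = "planted_tad")
}

#' Planted susceptibility locus specification
#'
#' A risk locus (a single SNP position carrying a cytoband-style label) tied
#' to one planted TAD, together with the differentially expressed features
#' deliberately placed inside that TAD. An empty `planted_candidates` list
#' plants a locus whose TAD contains no true DE feature, mirroring loci at
#' which no expression change is found.
#'
#' @param name Locus label (e.g. `"locus_A"`); labels are opaque, no
#'   cytoband-to-coordinate resolution is attempted.
#' @param chrom Chromosome name.
#' @param snp_pos 0-based bp position of the risk SNP; must fall inside the
#'   target TAD's bp span (validated once the TAD plan is known).
#' @param target_tad 1-based index into the configuration's `tad_plan`.
#' @param planted_candidates A data.frame with columns `feature_id`, `class`
#'   (`mRNA`/`lncRNA`/`miRNA`) and `log2fc` (signed planted effect), or NULL.
#' @param gene_desert When TRUE no random feature TSS is placed inside the
#'   target TAD (plus a one-bin margin): the locus's emptiness is planted
#'   structurally, so the pipeline's empty-candidate path is exercised
#'   deterministically.
#' @return A `planted_locus` list.
#' @export
planted_locus <- function(name, chrom, snp_pos, target_tad,
                          planted_candidates = NULL, gene_desert = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(planted_candidates)) {
    planted_candidates <- data.frame(feature_id = character(),
                                     class = character(),
                                     log2fc = numeric())
  }
  stopifnot(all(c("feature_id", "class", "log2fc") %in%
                names(planted_candidates)))
  if (is.null(planted_candidates$in_sub_tad))
    planted_candidates$in_sub_tad <- rep(FALSE, nrow(planted_candidates))
  if (isTRUE(gene_desert) && nrow(planted_candidates) > 0)
    stop("planted_locus: a gene-desert locus cannot carry candidates")
  if (any(!planted_candidates$class %in% c("mRNA", "lncRNA", "miRNA")))
    stop("planted_locus: candidate class must be mRNA, lncRNA or miRNA")
  if (any(!is.finite(planted_candidates$log2fc)) ||
      any(planted_candidates$log2fc == 0))
    stop("planted_locus: candidate log2fc must be finite and nonzero")
  structure(list(name = name, chrom = chrom, snp_pos = as.numeric(snp_pos),
                 target_tad = as.integer(target_tad),
                 planted_candidates = planted_candidates,
                 gene_desert = isTRUE(gene_desert)),
            class = "planted_locus")
}

default_tad_plan <- function() {
  # chromosomes are fully tiled: boundary ground truth is the set of
  # internal TAD-TAD transitions (chromosome edges sit inside the
  # insulation-window margin and are not recoverable by any caller)
  list(
    planted_tad("chrS1", 0, 20),
    planted_tad("chrS1", 20, 45),
    planted_tad("chrS1", 45, 70, nested_sub = c(50, 60)),
    planted_tad("chrS1", 70, 100),
    planted_tad("chrS2", 0, 30),
    planted_tad("chrS2", 30, 65),
    planted_tad("chrS2", 65, 100)
  )
}

default_loci_plan <- function() {
  list(
    # locus with upregulated candidates (1q41-like behaviour)
    planted_locus("locus_A", "chrS1", 1.30e6, 2, data.frame(
      feature_id = c("candA_m1", "candA_m2", "candA_l1", "candA_l2"),
      class = c("mRNA", "mRNA", "lncRNA", "lncRNA"),
      log2fc = c(2, 2, 2, 2))),
    # locus whose TAD carries no DE feature (3q22.3-like behaviour);
    # planted as a gene desert so its empty candidate table is structural
    planted_locus("locus_B", "chrS2", 1.80e6, 6, NULL,
                  gene_desert = TRUE),
    # locus with downregulated candidates plus upregulated ones in the
    # nested sub-TAD (15p21.3-like behaviour)
    planted_locus("locus_C", "chrS1", 2.30e6, 3, data.frame(
      feature_id = c("candC_m1", "candC_m2", "candC_l1",
                     "candC_sub_m1", "candC_sub_m2"),
      class = c("mRNA", "mRNA", "lncRNA", "mRNA", "mRNA"),
      log2fc = c(-2, -2, -2, 2, 2),
      in_sub_tad = c(FALSE, FALSE, FALSE, TRUE, TRUE)))
  )
}

#' Synthetic-study configuration
#'
#' Bundles every knob of the synthetic data generator: a paired
#' lesion/normal RNA-seq design (negative-binomial counts with patient
#' effects, planted differential expression and latent-factor co-expression
#' modules), miRNA-target and pathway files, and block-structured Hi-C
#' matrices with planted TADs and risk loci. Defaults emulate the study
#' design the pipeline targets: 3 patients, paired lesion/normal samples,
#' 40 kb Hi-C bins, class-specific planted log2 fold changes of 2 (mRNA,
#' lncRNA) and 1.5 (miRNA, comfortably above the 0.67 selection cut).
#'
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration including this seed.
#' @param n_patients Number of patients; each contributes one lesion and one
#'   normal sample.
#' @param n_mrna,n_lnc,n_mir Number of features per RNA class (planted locus
#'   candidates are additional).
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param bin_size Hi-C bin size in bp.
#' @param baseline_log_mean_range Range (natural-log scale) of per-feature
#'   baseline mean counts, drawn uniformly.
#' @param dispersion Negative-binomial dispersion alpha (> 0);
#'   `var = mu + alpha * mu^2`.
#' @param patient_effect_sd SD of the per-patient log-scale offset.
#' @param lib_size_sd SD of per-sample log-normal library size factors.
#' @param de_fraction_per_class Named fraction of features per class planted
#'   as differentially expressed.
#' @param de_log2fc_by_class Named signed-magnitude log2 fold change per
#'   class; planted features get this magnitude with random sign.
#' @param n_modules,module_size Number and size of planted co-expression
#'   modules (members drawn from non-DE mRNA/lncRNA features).
#' @param module_factor_sd SD (log2 scale) of the per-sample module factor
#'   scores; factor score vectors of distinct modules are orthogonalised so
#'   that the planted partition is identifiable at small sample sizes.
#' @param tad_plan List of [planted_tad()] objects.
#' @param loci_plan List of [planted_locus()] objects.
#' @param intra_tad_rate,inter_tad_rate Expected contact at bin distance 0
#'   inside/outside planted TADs (Poisson rates; must satisfy
#'   `intra_tad_rate > inter_tad_rate`); contacts decay as `1/(1+|i-j|)`.
#' @param sub_tad_boost Multiplier on `intra_tad_rate` inside nested
#'   sub-TADs.
#' @param n_pathways,pathway_size Gene-set collection shape; one pathway is
#'   deliberately enriched for planted DE genes.
#' @param target_degree_range Range of per-miRNA target out-degrees; one hub
#'   miRNA receives the maximum.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 3L,
                              n_mrna = 600L, n_lnc = 200L, n_mir = 80L,
                              genome = c(chrS1 = 4e6, chrS2 = 4e6),
                              bin_size = 40000L,
                              baseline_log_mean_range = c(3, 6),
                              dispersion = 0.1,
                              patient_effect_sd = 0.1,
                              lib_size_sd = 0.1,
                              de_fraction_per_class = c(mRNA = 0.1,
                                                        lncRNA = 0.1,
                                                        miRNA = 0.1),
                              de_log2fc_by_class = c(mRNA = 2,
                                                     lncRNA = 2,
                                                     miRNA = 1.5),
                              n_modules = 3L, module_size = 50L,
                              module_factor_sd = 2,
                              tad_plan = default_tad_plan(),
                              loci_plan = default_loci_plan(),
                              intra_tad_rate = 30,
                              inter_tad_rate = 10,
                              sub_tad_boost = 3,
                              n_pathways = 20L, pathway_size = 30L,
                              target_degree_range = c(5L, 40L)) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              n_mrna = as.integer(n_mrna), n_lnc = as.integer(n_lnc),
              n_mir = as.integer(n_mir), genome = genome,
              bin_size = as.integer(bin_size),
              baseline_log_mean_range = baseline_log_mean_range,
              dispersion = dispersion,
              patient_effect_sd = patient_effect_sd,
              lib_size_sd = lib_size_sd,
              de_fraction_per_class = de_fraction_per_class,
              de_log2fc_by_class = de_log2fc_by_class,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_factor_sd = module_factor_sd,
              tad_plan = tad_plan, loci_plan = loci_plan,
              intra_tad_rate = intra_tad_rate,
              inter_tad_rate = inter_tad_rate,
              sub_tad_boost = sub_tad_boost,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              target_degree_range = as.integer(target_degree_range))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$dispersion <= 0)
    stop("simulation_config: dispersion must be > 0", call. = FALSE)
  if (cfg$intra_tad_rate <= cfg$inter_tad_rate)
    stop("simulation_config: intra_tad_rate must exceed inter_tad_rate",
         call. = FALSE)
  if (is.null(names(cfg$genome)) || any(names(cfg$genome) == ""))
    stop("simulation_config: genome must be a named vector of lengths",
         call. = FALSE)
  if (any(cfg$genome %% cfg$bin_size != 0))
    stop("simulation_config: bin_size must divide each chromosome length",
         call. = FALSE)
  if (any(cfg$de_fraction_per_class < 0 | cfg$de_fraction_per_class > 1))
    stop("simulation_config: de fractions must be in [0,1]", call. = FALSE)
  if (any(!is.finite(cfg$de_log2fc_by_class)) ||
      any(cfg$de_log2fc_by_class == 0))
    stop("simulation_config: de_log2fc_by_class must be finite and nonzero",
         call. = FALSE)
  for (td in cfg$tad_plan) {
    if (!td$chrom %in% names(cfg$genome))
      stop("simulation_config: tad_plan chromosome '", td$chrom,
           "' absent from genome", call. = FALSE)
    if (td$end_bin * cfg$bin_size > cfg$genome[[td$chrom]])
      stop("simulation_config: TAD exceeds chromosome '", td$chrom, "'",
           call. = FALSE)
  }
  # same-chromosome planted TADs must not overlap (nesting is declared
  # separately through nested_sub)
  by_chrom <- split(cfg$tad_plan,
                    vapply(cfg$tad_plan, `[[`, "", "chrom"))
  for (tds in by_chrom) {
    if (length(tds) < 2) next
    iv <- t(vapply(tds, function(t) c(t$start_bin, t$end_bin), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("simulation_config: planted TADs overlap on one chromosome",
           call. = FALSE)
  }
  for (lc in cfg$loci_plan) {
    if (!lc$chrom %in% names(cfg$genome))
      stop("configuration error: locus '", lc$name,
           "' references chromosome '", lc$chrom, "' absent from genome",
           call. = FALSE)
    if (lc$target_tad < 1 || lc$target_tad > length(cfg$tad_plan))
      stop("simulation_config: locus '", lc$name,
           "' target_tad out of range", call. = FALSE)
    td <- cfg$tad_plan[[lc$target_tad]]
    if (td$chrom != lc$chrom)
      stop("simulation_config: locus '", lc$name,
           "' and its target TAD are on different chromosomes",
           call. = FALSE)
    span <- c(td$start_bin, td$end_bin) * cfg$bin_size
    if (lc$snp_pos < span[1] || lc$snp_pos >= span[2])
      stop("simulation_config: locus '", lc$name,
           "' snp_pos outside its target TAD span", call. = FALSE)
  }
  ids <- unlist(lapply(cfg$loci_plan,
                       function(l) l$planted_candidates$feature_id))
  if (anyDuplicated(ids))
    stop("simulation_config: duplicated planted candidate feature ids",
         call. = FALSE)
  if (cfg$target_degree_range[2] > cfg$n_mrna)
    stop("configuration error: requested target degree exceeds n_mrna",
         call. = FALSE)
  if (cfg$n_modules > 0 && cfg$module_size > 0 &&
      cfg$n_modules > 2L * cfg$n_patients - 2L)
    stop("simulation_config: n_modules must be <= 2*n_patients - 2 (the ",
         "factor scores are orthogonalised against intercept and condition)",
         call. = FALSE)
  invisible(cfg)
}

# Derived sub-seeds: one RNG stream forked per output, so adding an output
# never perturbs the draws of an earlier one. Kept below 2^31.
sim_seed <- function(cfg, stage) {
  offs <- c(annotation = 11L, counts = 29L, hic = 47L, targets = 83L)
  (cfg$seed * 1009L + offs[[stage]]) %% .Machine$integer.max
}
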