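small_cfg <- function(seed = 3, ...) {
  simulation_config(seed = seed, n_mrna = 120, n_lnc = 40, n_mir = 20,
                    n_modules = 0, n_pathways = 5, pathway_size = 10, ...)
}

test_that("identical configurations give byte-identical output bundles", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  expect_identical(sort(list.files(d1, recursive = TRUE)),
                   sort(list.files(d2, recursive = TRUE)))
  expect_identical(dir_md5(d1), dir_md5(d2))
})

test_that("planted candidate TSS containment and desert exclusion hold", {
  cfg <- simulation_config(seed = 11)
  ann <- generate_annotation(cfg)
  for (lc in cfg$loci_plan) {
    td <- cfg$tad_plan[[lc$target_tad]]
    span <- c(td$start_bin, td$end_bin) * cfg$bin_size
    for (i in seq_len(nrow(lc$planted_candidates))) {
      pc <- lc$planted_candidates[i, ]
      row <- ann[ann$feature_id == pc$feature_id, ]
      expect_equal(row$chrom, lc$chrom)
      expect_true(row$tss >= span[1] && row$tss < span[2])
      if (isTRUE(pc$in_sub_tad)) {
        sub <- td$nested_sub * cfg$bin_size
        expect_true(row$tss >= sub[1] && row$tss < sub[2])
      }
    }
    if (isTRUE(lc$gene_desert))
      expect_equal(sum(ann$chrom == lc$chrom & ann$tss >= span[1] &
                       ann$tss < span[2]), 0)
  }
  # SNP positions are inside their target TADs by config validation
  expect_error(planted_locus("x", "chrS1", 10, 1,
                             data.frame(feature_id = "f", class = "mRNA",
                                        log2fc = 0)),
               "finite and nonzero")
})

test_that("empty annotation and bad configurations are handled", {
  cfg <- simulation_config(seed = 1, n_mrna = 0, n_lnc = 0, n_mir = 0,
                           n_modules = 0, loci_plan = list(),
                           target_degree_range = c(0, 0))
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 0)
  d <- withr::local_tempdir()
  write_annotation(ann, file.path(d, "a.gtf"), file.path(d, "a.bed"))
  expect_true(file.exists(file.path(d, "a.gtf")))
  expect_error(simulation_config(seed = 1, dispersion = -1), "dispersion")
  expect_error(simulation_config(seed = 1, intra_tad_rate = 5,
                                 inter_tad_rate = 10), "exceed")
  expect_error(
    simulation_config(seed = 1, loci_plan = list(
      planted_locus("bad", "chrX", 100, 1))),
    "absent from genome")
})

test_that("annotation round-trips through the GTF writer", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  d <- withr::local_tempdir()
  write_annotation(ann, file.path(d, "a.gtf"), file.path(d, "a.bed"))
  back <- read_annotation_gtf(file.path(d, "a.gtf"))
  back <- back[match(ann$feature_id, back$feature_id), ]
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$strand, ann$strand)
  expect_equal(back$tss, ann$tss)
  expect_equal(back$class, ann$class)
})

test_that("count means follow the stated NB mean formula", {
  # near-Poisson noise, no patient effects, high baseline so the
  # Monte-Carlo error of a 6-sample mean resolves a 1% band
  cfg <- simulation_config(seed = 5, n_mrna = 2000, n_lnc = 0, n_mir = 0,
                           n_modules = 0, loci_plan = list(),
                           dispersion = 1e-6, patient_effect_sd = 0,
                           lib_size_sd = 0.1,
                           baseline_log_mean_range = c(9, 10),
                           de_fraction_per_class = c(mRNA = 0, lncRNA = 0,
                                                     miRNA = 0))
  ann <- generate_annotation(cfg)
  gen <- generate_counts(cfg, ann)
  # per-feature sample mean vs the stated mean formula: the mean of 6
  # Poisson draws at mu ~ 8-22k has relative sd 0.26-0.45%, so a 1% band
  # holds for (well over) 95% of features
  ratio <- rowMeans(gen$cm$counts) / rowMeans(gen$expected_mean)
  expect_gt(mean(abs(ratio - 1) < 0.01), 0.95)
  # condition-wise marginals agree with no DE and no patient effects
  norm <- sweep(gen$cm$counts, 2, gen$size_factors, `/`)
  lesion <- gen$cm$design$condition == "lesion"
  r2 <- rowMeans(norm[, lesion]) / rowMeans(norm[, !lesion])
  expect_lt(stats::median(abs(log2(r2))), 0.02)
})

test_that("DE truth honours fractions, classes and the paper's mRNA scale", {
  cfg <- simulation_config(seed = 9)
  ann <- generate_annotation(cfg)
  gen <- generate_counts(cfg, ann)
  tru <- gen$de_truth
  # planted mRNA effects sit at |log2FC| = 2, the scale of the mRNA filter
  mr <- tru[tru$class == "mRNA" & tru$is_de & !grepl("cand", tru$feature_id), ]
  expect_true(all(abs(mr$true_log2fc) == 2))
  mir <- tru[tru$class == "miRNA" & tru$is_de, ]
  expect_true(all(abs(mir$true_log2fc) == 1.5))
  # with no loci the eligible pool is the whole class: fraction exact
  cfg_nl <- simulation_config(seed = 9, loci_plan = list())
  tru_nl <- generate_counts(cfg_nl, generate_annotation(cfg_nl))$de_truth
  expect_equal(sum(tru_nl$is_de & tru_nl$class == "miRNA"),
               round(0.1 * sum(tru_nl$class == "miRNA")))
  # de_fraction 0 and no loci -> nothing DE
  cfg0 <- simulation_config(seed = 9, loci_plan = list(),
                            de_fraction_per_class = c(mRNA = 0, lncRNA = 0,
                                                      miRNA = 0))
  gen0 <- generate_counts(cfg0, generate_annotation(cfg0))
  expect_false(any(gen0$de_truth$is_de))
})

test_that("hic matrices are symmetric with planted contact contrast", {
  cfg <- simulation_config(seed = 13)
  hic <- generate_hic(cfg)
  m <- hic$matrices$chrS1$m
  expect_true(all(m == t(m)))
  expect_true(all(m >= 0))
  # distance-matched intra/inter contrast ~ rate ratio (3) within 10%
  n <- nrow(m)
  tad_of <- rep(0L, n)
  tds <- Filter(function(t) t$chrom == "chrS1", cfg$tad_plan)
  for (k in seq_along(tds))
    tad_of[(tds[[k]]$start_bin + 1):tds[[k]]$end_bin] <- k
  # decay-corrected contrast: dividing each count by its distance decay
  # leaves E[obs] = rate, so the intra/inter ratio estimates rate ratio 3
  contrast <- function(mm, dmax = 10) {
    num <- den <- c()
    sub <- tds[[3]]$nested_sub
    for (d in 1:dmax) {
      i <- seq_len(n - d); j <- i + d
      same <- tad_of[i] == tad_of[j] & tad_of[i] > 0
      insub <- i > sub[1] & j <= sub[2]
      v <- mm[cbind(i, j)] * (1 + d)
      num <- c(num, v[same & !insub])
      den <- c(den, v[!same])
    }
    mean(num) / mean(den)
  }
  expect_lt(abs(contrast(m) / 3 - 1), 0.1)
  # equal rates remove the block structure
  cfg_eq <- simulation_config(seed = 13, intra_tad_rate = 10.000001,
                              inter_tad_rate = 10)
  m_eq <- generate_hic(cfg_eq)$matrices$chrS1$m
  expect_lt(abs(contrast(m_eq) - 1), 0.1)
})

test_that("target table and pathway sets carry their planted structure", {
  cfg <- simulation_config(seed = 17)
  ann <- generate_annotation(cfg)
  gen <- generate_counts(cfg, ann)
  tp <- generate_targets_and_pathways(cfg, ann, gen$de_truth)
  deg <- table(tp$targets$miRNA_id)
  expect_true(all(deg[tp$hub_mirna] >= deg))
  de_mrna <- gen$de_truth$feature_id[gen$de_truth$is_de &
                                     gen$de_truth$class == "mRNA"]
  ov <- vapply(tp$pathways, function(s) length(intersect(s, de_mrna)), 0)
  expect_gt(ov[tp$enriched_pathway],
            mean(ov[names(ov) != tp$enriched_pathway]))
  # GMT round trip through the enrichment reader
  d <- withr::local_tempdir()
  write_gmt(tp$pathways, file.path(d, "p.gmt"))
  back <- read_gmt(file.path(d, "p.gmt"))
  expect_identical(lapply(back, sort), lapply(tp$pathways, sort))
  # degree demand beyond the mRNA pool is a configuration error
  expect_error(simulation_config(seed = 1, n_mrna = 5,
                                 target_degree_range = c(2, 50)),
               "configuration error")
})
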