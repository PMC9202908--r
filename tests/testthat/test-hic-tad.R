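test_that("contact matrices round-trip through dense and COO formats", {
  cfg <- simulation_config(seed = 41, genome = c(chrS1 = 1.2e6),
                           tad_plan = list(planted_tad("chrS1", 0, 15),
                                           planted_tad("chrS1", 15, 30)),
                           loci_plan = list())
  cm <- generate_hic(cfg)$matrices$chrS1
  d <- withr::local_tempdir()
  write_contact_matrix(cm, file.path(d, "m.tsv"), file.path(d, "m.coo"))
  dense <- read_contact_matrix(file.path(d, "m.tsv"), "dense", 40000,
                               "chrS1")
  coo <- read_contact_matrix(file.path(d, "m.coo"), "coo", 40000,
                             "chrS1", n_bins = cm$n_bins)
  expect_equal(dense$m, cm$m)
  expect_equal(coo$m, cm$m)
  # upper-triangle-only COO mirrors to a full symmetric matrix
  writeLines(c("bin_i\tbin_j\tcount", "0\t2\t7", "1\t1\t3"),
             file.path(d, "tri.coo"))
  tri <- read_contact_matrix(file.path(d, "tri.coo"), "coo", 40000)
  expect_equal(tri$m[3, 1], 7)
  expect_equal(tri$m, t(tri$m))
  # malformed inputs fail loudly
  writeLines(c("1\t2\t3", "4\t5"), file.path(d, "ragged.tsv"))
  expect_error(read_contact_matrix(file.path(d, "ragged.tsv"), "dense",
                                   40000), "ragged")
  writeLines(c("bin_i\tbin_j\tcount", "0\t1\t-4"), file.path(d, "neg.coo"))
  expect_error(read_contact_matrix(file.path(d, "neg.coo"), "coo", 40000),
               "negative")
})

test_that("insulation matches closed forms and the double-loop oracle", {
  # uniform matrix: IS identically 0 where defined
  u <- contact_matrix("c", 1e4, matrix(5, 20, 20))
  is_u <- insulation(u, w = 3)
  expect_true(all(abs(is_u$IS[!is.na(is_u$IS)]) < 1e-12))
  expect_true(all(is.na(is_u$IS[c(1:3, 18:20)])))
  # w = 1 degenerates to the single skew cell
  set.seed(2)
  m <- matrix(rpois(100, 9), 10); m <- m + t(m)
  cmx <- contact_matrix("c", 1e4, m)
  t1 <- insulation(cmx, w = 1)
  for (b in 2:9)
    expect_equal(2^t1$IS[b] * mean(sapply(2:9, function(x)
      m[x - 1, x + 1])), m[b - 1, b + 1])
  # random-matrix oracle equivalence
  for (i in 1:10) {
    m <- matrix(rpois(1600, 6), 40); m <- m + t(m)
    cmx <- contact_matrix("c", 4e4, m)
    tr <- insulation(cmx, w = 5)
    expect_lt(max(abs(tr$IS - insulation_oracle(m, 5)), na.rm = TRUE),
              1e-10)
  }
  # all-zero matrix: warning, everything undefined
  expect_warning(z <- insulation(contact_matrix("c", 1e4,
                                                matrix(0, 15, 15)), 3),
                 "all-zero")
  expect_true(all(is.na(z$IS)))
  expect_error(insulation(u, w = 10), "n_bins")
})

test_that("TAD calling recovers planted boundaries and honours guards", {
  # flat insulation -> no boundaries, one domain over the chromosome
  flat <- structure(list(IS = c(NA, NA, rep(0, 16), NA, NA), w = 2L,
                         chrom = "c", bin_size = 1e4L),
                    class = "insulation_track")
  tads <- call_tads(flat)
  expect_equal(nrow(tads), 1)
  expect_equal(tads$end_bp - tads$start_bp, 20 * 1e4)
  # infinite threshold silences every boundary
  cfg <- simulation_config(seed = 43)
  hic <- generate_hic(cfg)
  tr <- insulation(hic$matrices$chrS1, 5)
  expect_equal(nrow(call_tads(tr, delta_min = Inf)), 1)
  # planted boundaries recovered within +/- 1 bin at contrast 3
  called <- call_tads(tr, delta_min = 0.5)
  called_bins <- called$start_bp[-1] / 40000
  truth <- planted_boundaries(cfg)$chrS1
  expect_gte(boundary_f1(called_bins, truth), 0.9)
  # second pass recovers the planted nested sub-TAD within +/- 1 bin
  full <- call_tads(tr, sub_pass = TRUE, cm = hic$matrices$chrS1)
  sub <- full[full$level == "sub_tad", ]
  planted_sub <- cfg$tad_plan[[3]]$nested_sub * 40000
  # the half-window second pass localizes coarsely: +/- 2 bins
  hit <- any(abs(sub$start_bp - planted_sub[1]) <= 2 * 40000 &
             abs(sub$end_bp - planted_sub[2]) <= 2 * 40000)
  expect_true(hit)
  validate_sub <- sub[sub$chrom == "chrS1", ]
  expect_true(all(validate_sub$end_bp > validate_sub$start_bp))
})

test_that("TAD BED round trips exactly and rejects same-level overlap", {
  tads <- data.frame(chrom = c("c1", "c1", "c1"),
                     start_bp = c(0, 120000, 40000),
                     end_bp = c(120000, 360000, 100000),
                     level = c("tad", "tad", "sub_tad"))
  class(tads) <- c("tad_set", "data.frame")
  d <- withr::local_tempdir()
  write_tads_bed(tads, file.path(d, "t.bed"))
  back <- load_tads_bed(file.path(d, "t.bed"))
  expect_equal(back$start_bp, tads$start_bp)
  expect_equal(back$end_bp, tads$end_bp)
  expect_equal(back$level, tads$level)
  # a called set survives the round trip unchanged
  cfg <- simulation_config(seed = 47)
  tr <- insulation(generate_hic(cfg)$matrices$chrS2, 5)
  called <- call_tads(tr)
  write_tads_bed(called, file.path(d, "c.bed"))
  back2 <- load_tads_bed(file.path(d, "c.bed"))
  expect_equal(back2$start_bp, called$start_bp)
  expect_equal(back2$end_bp, called$end_bp)
  # overlapping same-level intervals are an error naming the rows
  bad <- data.frame(chrom = "c1", start_bp = c(0, 50000),
                    end_bp = c(100000, 150000), level = "tad")
  writeLines(sprintf("c1\t%d\t%d\ttad", bad$start_bp, bad$end_bp),
             file.path(d, "bad.bed"))
  expect_error(load_tads_bed(file.path(d, "bad.bed")), "overlapping")
})

test_that("locate_tad uses half-open containment and matches a scan oracle", {
  tads <- data.frame(chrom = c("c1", "c1", "c2"),
                     start_bp = c(0, 200, 0), end_bp = c(200, 500, 300),
                     level = "tad")
  class(tads) <- c("tad_set", "data.frame")
  # start inclusive, end exclusive
  expect_equal(locate_tad(tads, list(name = "x", chrom = "c1",
                                     snp_pos = 200))$start_bp, 200)
  expect_equal(nrow(locate_tad(tads, list(name = "x", chrom = "c1",
                                          snp_pos = 500))), 0)
  expect_warning(
    none <- locate_tad(tads, list(name = "x", chrom = "c9", snp_pos = 1)),
    "absent")
  expect_equal(nrow(none), 0)
  # random-case agreement with a linear scan
  set.seed(53)
  for (i in 1:40) {
    n <- sample(1:8, 1)
    starts <- sort(sample(seq(0, 900, 20), n))
    widths <- sample(seq(20, 100, 20), n, replace = TRUE)
    tt <- data.frame(chrom = sample(c("cA", "cB"), n, replace = TRUE),
                     start_bp = starts, end_bp = starts + widths,
                     level = "tad")
    tt <- tt[order(tt$chrom, tt$start_bp), ]
    class(tt) <- c("tad_set", "data.frame")
    for (j in 1:25) {
      ch <- sample(c("cA", "cB"), 1)
      pos <- sample(0:1100, 1)
      got <- suppressWarnings(
        locate_tad(tt, list(name = "q", chrom = ch, snp_pos = pos)))
      expect_equal(nrow(got), length(locate_oracle(tt, ch, pos)))
    }
  }
})
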