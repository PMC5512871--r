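test_that("an exact planted repeat is recovered at its coordinates", {
  erv <- simulate_erv_contig(ltr_len = 400, internal_len = 8000, tsd_len = 4,
                             ltr_divergence = 0, flank_len = 2000, seed = 1)
  pr <- find_ltr_pairs(erv)
  expect_equal(nrow(pr), 1L)
  expect_gte(pr$identity[1], 99)  # boundary columns may add a chance mismatch
  expect_lte(abs(pr$start5[1] - erv$truth$ltr5[1]), 5)
  expect_lte(abs(pr$end5[1] - erv$truth$ltr5[2]), 5)
  expect_lte(abs(pr$start3[1] - erv$truth$ltr3[1]), 5)
  expect_lte(abs(pr$end3[1] - erv$truth$ltr3[2]), 5)
})

test_that("a 95%-identity planted repeat is recovered with matching identity", {
  erv <- simulate_erv_contig(ltr_len = 400, internal_len = 8000, tsd_len = 5,
                             ltr_divergence = 0.052, flank_len = 2000, seed = 2)
  ## total divergence 0.052 gives ~95% observed identity between the copies
  pr <- find_ltr_pairs(erv)
  expect_equal(nrow(pr), 1L)
  expect_gte(pr$identity[1], 93)
  expect_lte(pr$identity[1], 97)
})

test_that("random sequences yield no LTR pair (null control)", {
  for (s in 1:20) {
    set.seed(s)
    contig <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                    collapse = "")
    pr <- find_ltr_pairs(contig, min_len = 200, min_identity = 80)
    expect_equal(nrow(pr), 0L, info = paste("seed", s))
  }
})

test_that("reported pairs never violate their thresholds", {
  for (s in 1:5) {
    erv <- simulate_erv_contig(ltr_len = 300, internal_len = 5000,
                               ltr_divergence = 0.03, flank_len = 1000,
                               seed = 300 + s)
    pr <- find_ltr_pairs(erv, min_len = 200, min_identity = 80, max_gap = 25000)
    for (i in seq_len(nrow(pr))) {
      expect_gte(pr$aln_length[i], 200)
      expect_gte(pr$identity[i], 80)
      expect_lte(pr$start3[i] - pr$end5[i], 25000)
      expect_lt(pr$end5[i], pr$start3[i])  # non-overlapping, 5' before 3'
    }
  }
})

test_that("find_ltr_pairs is strand-consistent under reverse complement", {
  erv <- simulate_erv_contig(ltr_len = 400, internal_len = 4000, tsd_len = 4,
                             ltr_divergence = 0, flank_len = 1500, seed = 8)
  pr <- find_ltr_pairs(erv)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(erv$contig)))
  pr_rc <- find_ltr_pairs(rc)
  expect_equal(nrow(pr_rc), 1L)
  L <- nchar(erv$contig)
  ## mirrored coordinates: the 5' copy of the reverse strand is the old 3'
  expect_equal(pr_rc$start5[1], L - pr$end3[1])
  expect_equal(pr_rc$end3[1], L - pr$start5[1])
})

test_that("planted TSDs are found and absent TSDs give NULL", {
  erv <- simulate_erv_contig(ltr_len = 400, internal_len = 4000, tsd_len = 4,
                             ltr_divergence = 0, flank_len = 1500, seed = 5)
  pr <- find_ltr_pairs(erv)
  tsd <- find_tsd(erv, pr[1, ])
  expect_s3_class(tsd, "tsd_call")
  ## the planted motif is contained in the call (boundary slack may extend it)
  expect_true(grepl(erv$truth$tsd, tsd$motif, fixed = TRUE) ||
                grepl(tsd$motif, erv$truth$tsd, fixed = TRUE))

  ## no shared boundary motif -> NULL
  contig <- paste0(paste(rep("A", 50), collapse = ""),
                   paste(rep("G", 300), collapse = ""),
                   paste(rep("C", 50), collapse = ""),
                   paste(rep("G", 300), collapse = ""),
                   paste(rep("T", 50), collapse = ""))
  fake_pair <- data.frame(start5 = 50, end5 = 350, start3 = 400, end3 = 700)
  expect_null(find_tsd(contig, fake_pair))
  expect_error(find_tsd("ACGT", data.frame(start5 = 1, end5 = 2,
                                           start3 = 3, end3 = 4)),
               "insufficient flank")
})

test_that("element boundaries round-trip within 2 nt over seeded contigs", {
  ## at the generator's default divergence the planted boundaries are fully
  ## determined by the sequence; diverged-element recovery rates are checked
  ## separately at the young-element operating point
  n_ok <- 0L
  n <- 30L
  for (s in seq_len(n)) {
    set.seed(6000 + s)
    tsd_len <- sample(4:6, 1)
    erv <- simulate_erv_contig(ltr_len = 350, internal_len = 3000,
                               tsd_len = tsd_len,
                               ltr_divergence = 0,
                               flank_len = 1200, seed = 6000 + s)
    pr <- find_ltr_pairs(erv)
    if (nrow(pr) < 1) next
    tsd <- tryCatch(find_tsd(erv, pr[1, ]), error = function(e) NULL)
    if (is.null(tsd)) next
    el_start <- tsd$left[2]
    el_end <- tsd$right[1]
    if (abs(el_start - erv$truth$element[1]) <= 2 &&
        abs(el_end - erv$truth$element[2]) <= 2) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("annotation writers emit BED and GFF3", {
  erv <- simulate_erv_contig(ltr_len = 300, internal_len = 2500, tsd_len = 4,
                             ltr_divergence = 0, flank_len = 1000, seed = 3)
  ann <- annotate_contig(erv)
  expect_equal(nrow(ann$ltr_pairs), 1L)
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_bed(ann, "ctg1", bed)
  write_annotation_gff3(ann, "ctg1", gff)
  bl <- readLines(bed)
  expect_true(any(grepl("LTR5_pair1", bl)))
  expect_true(any(grepl("TSD_left_pair1", bl)))
  gl <- readLines(gff)
  expect_equal(gl[1], "##gff-version 3")
  expect_true(any(grepl("long_terminal_repeat", gl)))
  ## GFF3 coordinates are 1-based inclusive: element start = BED start + 1
  ltr5_bed <- strsplit(bl[grepl("LTR5_pair1", bl)], "\t")[[1]]
  ltr5_gff <- strsplit(gl[grepl("ltr5", gl)], "\t")[[1]]
  expect_equal(as.integer(ltr5_gff[4]), as.integer(ltr5_bed[2]) + 1L)
  expect_equal(as.integer(ltr5_gff[5]), as.integer(ltr5_bed[3]))
})
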