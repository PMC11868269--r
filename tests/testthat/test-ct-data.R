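test_that("long-layout read round-trips a Ct matrix bit-exactly", {
  m <- fixture_f1()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(m, path)
  m2 <- read_ct_table(path, layout = "long")
  expect_identical(m2$ct, m$ct)
  expect_identical(m2$samples, m$samples)
  expect_identical(m2$genes, m$genes)
})

test_that("wide-layout read handles sentinels and preserves order", {
  dir <- withr::local_tempdir()
  ct_path <- file.path(dir, "ct.csv")
  meta_path <- file.path(dir, "meta.csv")
  writeLines(c("gene_id,w1,w2,w3,w4",
               "gA,20.0,21.0,22.0,23.0",
               "gB,18.5,Undetermined,19.5,19.0",
               "gC,25.0,25.5,NA,24.5"), ct_path)
  writeLines(c("well,sample_id,condition,timepoint,bio_rep,tech_rep",
               "w1,s1,ctrl,0,1,1", "w2,s2,ctrl,0,2,1",
               "w3,s3,cold,3,1,1", "w4,s4,cold,3,2,1"), meta_path)
  m <- read_ct_table(ct_path, layout = "wide", meta = meta_path)
  expect_equal(rownames(m$ct), c("gA", "gB", "gC"))
  expect_equal(sum(is.na(m$ct)), 2L)
  expect_true(is.na(m$ct["gB", 2]) && is.na(m$ct["gC", 3]))
  expect_equal(m$ct["gA", ], setNames(c(20, 21, 22, 23), colnames(m$ct)))
  expect_equal(m$samples$condition, c("ctrl", "ctrl", "cold", "cold"))
})

test_that("invalid cells are rejected with coordinates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  hdr <- "sample_id\tcondition\ttimepoint\tbio_rep\ttech_rep\tgene_id\tct"
  writeLines(c(hdr,
               "s1\tctrl\t0\t1\t1\tgA\t20.0",
               "s2\tctrl\t0\t2\t1\tgA\tabc"), path)
  expect_error(read_ct_table(path), "non-numeric.*gA@s2", ignore.case = TRUE)

  writeLines(c(hdr,
               "s1\tctrl\t0\t1\t1\tgA\t50.0",
               "s2\tctrl\t0\t2\t1\tgA\t20.0"), path)
  expect_error(read_ct_table(path), "outside \\[5, 45\\].*gA@s1")

  writeLines(c(hdr,
               "s1\tctrl\t0\t1\t1\tgA\t20.0",
               "s1\tctrl\t0\t1\t1\tgA\t20.2"), path)
  expect_error(read_ct_table(path), "duplicate.*gA, s1, tech_rep 1")
})

test_that("technical replicates collapse by mean, tolerate missing wells, and flag noisy triplicates", {
  ct <- rbind(gA = c(20.0, 20.2, 20.4),
              gB = c(20.0, NA, 20.4),
              gC = c(20.0, 21.5, 20.2))
  samples <- data.frame(sample_id = "s1", condition = "ctrl", timepoint = "0",
                        bio_rep = 1L, tech_rep = 1:3)
  m <- ct_matrix(ct, samples)
  expect_warning(cm <- collapse_technical_replicates(m), "SD 0\\.50")
  expect_equal(unname(cm$ct[, 1]),
               c(mean(c(20, 20.2, 20.4)), mean(c(20, 20.4)),
                 mean(c(20, 21.5, 20.2))))
  expect_equal(cm$ct["gC", 1], 20.5667, tolerance = 1e-4)
  qc <- attr(cm, "qc_log")
  expect_equal(qc$gene_id, "gC")
  expect_equal(qc$sd_ct, sd(c(20, 21.5, 20.2)))
  expect_gt(qc$sd_ct, 0.5)
  expect_equal(qc$sd_ct, 0.8145, tolerance = 1e-4)
})

test_that("collapse is idempotent on collapsed matrices and keeps all-missing wells missing", {
  ct <- rbind(gA = c(20, 20.4, NA, NA), gB = c(22, 22.4, NA, NA))
  samples <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                        condition = "ctrl", timepoint = "0",
                        bio_rep = rep(1:2, each = 2), tech_rep = rep(1:2, 2))
  cm <- collapse_technical_replicates(ct_matrix(ct, samples))
  expect_true(is.na(cm$ct["gA", 2]) && is.na(cm$ct["gB", 2]))
  cm2 <- collapse_technical_replicates(cm)
  expect_identical(cm2$ct, cm$ct)
  expect_identical(cm2$samples, cm$samples)
  expect_equal(nrow(attr(cm2, "qc_log")), 0L)
})

test_that("condition subsets filter samples and enforce completeness", {
  ct <- matrix(20 + seq_len(24) / 10, nrow = 3,
               dimnames = list(c("gA", "gB", "gC"), NULL))
  samples <- data.frame(sample_id = paste0("s", 1:8),
                        condition = rep(c("cold", "salt"), each = 4),
                        timepoint = "0", bio_rep = rep(1:4, 2), tech_rep = 1L)
  m <- ct_matrix(ct, samples, collapsed = TRUE)

  all_set <- subset_samples(m, condition_set("all"))
  expect_identical(all_set$ct, m$ct)

  cold <- subset_samples(m, condition_set("cold", "cold"))
  expect_equal(unique(cold$samples$condition), "cold")
  expect_equal(ncol(cold$ct), 4L)

  m$ct["gB", 2] <- NA
  expect_error(subset_samples(m, condition_set("cold", "cold")),
               "missing candidate-reference Ct.*gB@s2")
  dropped <- subset_samples(m, condition_set("all"),
                            on_missing = "drop_samples")
  expect_equal(ncol(dropped$ct), 7L)
  expect_equal(attr(dropped, "dropped_samples"), "s2")
  expect_false(anyNA(dropped$ct))
  # dropping below 4 samples is an error
  expect_error(subset_samples(m, condition_set("cold", "cold"),
                              on_missing = "drop_samples"),
               "at least 4")
})

test_that("ct_summary reports per-gene mean/min/max/range and is permutation invariant", {
  m <- make_ct(rbind(flat = rep(20, 3), var = c(18, 19, 21)))
  s <- ct_summary(m)
  expect_equal(s$range_ct, c(0, 3))
  expect_equal(s$mean_ct, c(20, 19.3333), tolerance = 1e-4)
  expect_equal(s$min_ct, c(20, 18))
  expect_equal(s$max_ct, c(20, 21))

  perm <- make_ct(rbind(flat = rep(20, 3), var = c(21, 18, 19)))
  s2 <- ct_summary(perm)
  expect_equal(s2, s)

  # a +c shift moves only the mean, never the range
  shifted <- make_ct(rbind(flat = rep(20, 3) + 2, var = c(18, 19, 21) + 2))
  s3 <- ct_summary(shifted)
  expect_equal(s3$range_ct, s$range_ct)
  expect_equal(s3$mean_ct, s$mean_ct + 2)

  empty <- ct_matrix(matrix(numeric(), 1, 0, dimnames = list("gA", NULL)),
                     data.frame(sample_id = character(),
                                condition = character(),
                                timepoint = character(),
                                bio_rep = integer(), tech_rep = integer()),
                     collapsed = TRUE)
  expect_error(ct_summary(empty), "empty")
})

test_that("candidate pre-selection applies abundance and fold-change filters", {
  expr <- rbind(keep = c(100, 120),
                too_variable = c(100, 150),
                too_low = c(2, 2.2),
                best = c(500, 510))
  got <- select_candidate_references(expr, min_expr = 50, max_fc = 1.4)
  expect_equal(got, c("best", "keep"))
  expect_error(select_candidate_references(rbind(a = c(-1, 2)), 0),
               "strictly positive")
})
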