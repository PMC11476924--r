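test_that("stage harmonization covers the publisher vocabulary", {
  healthy <- c("none", "control", "normal", "normal colonic mucosa")
  ibd <- c("IBD", "UC", "CD")
  tumor <- c("colorectal cancer", "primary tumor", "carcinoma")
  met <- c("metastatic cancer", "liver metastasis", "lung metastasis")
  expect_equal(harmonize_stage(healthy), rep("healthy_control", 4))
  expect_equal(harmonize_stage(ibd), rep("IBD", 3))
  expect_equal(harmonize_stage(c("colon adenoma", "adenoma")),
               rep("adenoma", 2))
  expect_equal(harmonize_stage(tumor), rep("primary_carcinoma", 3))
  expect_equal(harmonize_stage(met), rep("metastasis", 3))
  # case/whitespace normalization
  expect_equal(harmonize_stage(" Normal "), "healthy_control")
  expect_equal(harmonize_stage("uc"), "IBD")
  expect_error(harmonize_stage("polyp?"), "polyp?", fixed = TRUE)
})

test_that("user harmonization rules extend and override the built-ins", {
  expect_equal(harmonize_stage("polyp", rules = c(polyp = "adenoma")),
               "adenoma")
  # precedence: a user rule can re-route a built-in label
  expect_equal(harmonize_stage("adenoma",
                               rules = c(adenoma = "primary_carcinoma")),
               "primary_carcinoma")
  expect_error(harmonize_stage("x", rules = c(x = "not_a_stage")),
               "stage rules")
})

test_that("log2 standardization clamps, is idempotent and monotone", {
  mat <- matrix(c(8, 0, -3, 1024, 2, 0.5), nrow = 3,
                dimnames = list(paste0("P", 1:3), c("a", "b")))
  samples <- data.frame(sample_id = c("a", "b"),
                        raw_label = c("control", "UC"),
                        stage = c("healthy_control", "IBD"))
  ds <- expression_dataset("d", mat, samples,
                           setNames(c("G1", "G2", "G3"), paste0("P", 1:3)),
                           scale = "linear")
  out <- to_log2(ds)
  expect_equal(out$scale, "log2")
  expect_equal(out$matrix["P1", "a"], 3)        # log2(8)
  expect_equal(out$matrix["P2", "a"], 0)        # 0 clamped to eps = 1
  expect_equal(out$matrix["P3", "a"], 0)        # negative clamped
  expect_equal(out$matrix["P3", "b"], 0)        # 0.5 clamped up to 1
  expect_identical(to_log2(out), out)           # idempotent
  # monotone on positive values
  v <- sort(runif(20, 1, 100))
  m2 <- matrix(rep(v, 2), ncol = 2,
               dimnames = list(paste0("Q", 1:20), c("a", "b")))
  ds2 <- expression_dataset("d2", m2, samples,
                            setNames(paste0("g", 1:20), paste0("Q", 1:20)),
                            scale = "linear")
  expect_false(is.unsorted(to_log2(ds2)$matrix[, 1]))
})

test_that("probe collapse keeps the strongest probe per gene", {
  mat <- rbind(A = c(7.0, 7.4), B = c(9.0, 9.2),
               P2 = c(5, 5), P10 = c(5, 5), S1 = c(4, 6))
  colnames(mat) <- c("a", "b")
  samples <- data.frame(sample_id = c("a", "b"),
                        raw_label = c("control", "UC"),
                        stage = c("healthy_control", "IBD"))
  map <- c(A = "G1", B = "G1", P2 = "G2", P10 = "G2", S1 = "G3")
  ds <- expression_dataset("d", mat, samples, map, scale = "log2")
  tab <- collapse_probes(ds)
  # G1: probe B has the larger mean (9.1 > 7.2)
  expect_equal(tab$matrix["G1", ], c(a = 9.0, b = 9.2))
  # tie on mean: lexicographically smallest probe id wins ("P10" < "P2")
  expect_equal(unname(tab$matrix["G2", ]), c(5, 5))
  # singleton probe passes through
  expect_equal(unname(tab$matrix["G3", ]), c(4, 6))
  expect_false(anyDuplicated(rownames(tab$matrix)) > 0)
  # restriction omits unlisted genes, never zero-fills
  tab2 <- collapse_probes(ds, genes = c("G3", "G9"))
  expect_equal(rownames(tab2$matrix), "G3")
})

test_that("tie-break uses C-locale string order of probe ids", {
  # means tied at 5; "P10" sorts before "P2" byte-wise, so P10 must win
  mat <- rbind(P2 = c(1, 9), P10 = c(9, 1))
  colnames(mat) <- c("a", "b")
  samples <- data.frame(sample_id = c("a", "b"),
                        raw_label = c("control", "UC"),
                        stage = c("healthy_control", "IBD"))
  ds <- expression_dataset("d", mat, samples,
                           c(P2 = "G2", P10 = "G2"), scale = "log2")
  tab <- collapse_probes(ds)
  expect_equal(unname(tab$matrix["G2", ]), c(9, 1))
})

test_that("collapse on a one-probe-per-gene dataset is a relabeling", {
  mat <- matrix(rnorm(12), 3, 4,
                dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
  mat[2, 3] <- NA  # missing values propagate, not imputed
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        raw_label = c("control", "control", "UC", "UC"),
                        stage = rep(c("healthy_control", "IBD"), each = 2))
  map <- setNames(c("GA", "GB", "GC"), paste0("P", 1:3))
  ds <- expression_dataset("d", mat, samples, map, scale = "log2")
  tab <- collapse_probes(ds)
  expect_equal(unname(tab$matrix[unname(map[rownames(mat)]), ]),
               unname(mat))
  expect_true(is.na(tab$matrix["GB", "s3"]))
})

test_that("series-matrix reader parses fixtures and validates them", {
  dir <- withr::local_tempdir()
  mpath <- file.path(dir, "m.tsv")
  writeLines(c("#dataset_id=fix1",
               "#scale=linear",
               paste(c("probe_id", paste0("s", 1:5)), collapse = "\t"),
               paste(c("P1", 2, 4, 8, 16, 32), collapse = "\t"),
               paste(c("P2", 1, 1, 2, 2, 4), collapse = "\t")), mpath)
  apath <- file.path(dir, "a.tsv")
  writeLines(c("sample_id\traw_label",
               "s1\tnormal colonic mucosa", "s2\tnormal colonic mucosa",
               "s3\tUC", "s4\tUC", "s5\tUC"), apath)
  ppath <- file.path(dir, "p.tsv")
  writeLines(c("probe_id\tgene_symbol", "P1\tCXCL8", "P2\tCCL2"), ppath)

  ds <- read_series_matrix(mpath, apath, ppath)
  expect_s3_class(ds, "expression_dataset")
  expect_equal(ds$dataset_id, "fix1")
  expect_equal(ds$scale, "linear")  # declared in metadata, values untouched
  expect_equal(as.vector(table(ds$samples$stage)[c("healthy_control",
                                                   "IBD")]),
               c(2L, 3L))
  expect_equal(unname(ds$matrix["P1", "s5"]), 32)

  # unknown label without a rule is an error naming the label
  writeLines(c("sample_id\traw_label", "s1\tpolyp?", "s2\tnormal",
               "s3\tUC", "s4\tUC", "s5\tUC"), apath)
  expect_error(read_series_matrix(mpath, apath, ppath), "polyp?",
               fixed = TRUE)

  # malformed row reports its line number
  writeLines(c(paste(c("probe_id", paste0("s", 1:5)), collapse = "\t"),
               paste(c("P1", 1, 2, 3, 4, 5), collapse = "\t"),
               paste(c("P2", 1, 2), collapse = "\t")), mpath)
  expect_error(read_series_matrix(mpath, apath, ppath), "line 3")

  # empty sample set
  writeLines(c("probe_id", "P1"), mpath)
  expect_error(read_series_matrix(mpath, apath, ppath), "no sample")
})

test_that("scale auto-detection flags large-valued matrices as linear", {
  dir <- withr::local_tempdir()
  mpath <- file.path(dir, "m.tsv")
  apath <- file.path(dir, "a.tsv")
  ppath <- file.path(dir, "p.tsv")
  writeLines(c("sample_id\traw_label", "s1\tnormal", "s2\tUC"), apath)
  writeLines(c("probe_id\tgene_symbol", "P1\tCCL2"), ppath)
  writeLines(c("probe_id\ts1\ts2", "P1\t200\t400"), mpath)
  expect_equal(read_series_matrix(mpath, apath, ppath)$scale, "linear")
  writeLines(c("probe_id\ts1\ts2", "P1\t7.5\t8.5"), mpath)
  expect_equal(read_series_matrix(mpath, apath, ppath)$scale, "log2")
})
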