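test_that("cohort generation is reproducible and validates its spec", {
  spec <- cohort_spec(seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_length(a, 9L)  # 4 IBD + 2 adenoma + 3 carcinoma
  expect_identical(lapply(a, `[[`, "matrix"), lapply(b, `[[`, "matrix"))
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  # a different seed changes the draws
  c <- generate_cohort(cohort_spec(seed = 10))
  expect_false(identical(a[[1]]$matrix, c[[1]]$matrix))
  # invalid specs are rejected
  expect_error(cohort_spec(list(list(id = "x", stages = "IBD",
                                     n_per_arm = 1, noise_sd = 0.5))),
               "n_per_arm")
  expect_error(cohort_spec(list(list(id = "x", stages = "IBD",
                                     n_per_arm = 5, noise_sd = 0))),
               "noise_sd")
  expect_error(cohort_spec(list(list(id = "x", stages = "polyp",
                                     n_per_arm = 5, noise_sd = 1))),
               "stage")
})

test_that("generated datasets satisfy the container invariants", {
  cohort <- generate_cohort(cohort_spec(seed = 13))
  for (ds in cohort) {
    expect_s3_class(ds, "expression_dataset")
    expect_equal(ds$scale, "log2")
    expect_true(all(is.finite(ds$matrix)))
    expect_setequal(colnames(ds$matrix), ds$samples$sample_id)
    # raw labels round-trip through harmonization to the stored stage
    expect_equal(harmonize_stage(ds$samples$raw_label), ds$samples$stage)
  }
})

test_that("noise-free limit recovers the archetype effects exactly", {
  arch <- c(CCL20 = "neoplasm_up", CXCL9 = "inflammation_specific",
            CXCL12 = "neoplasm_down", CCL1 = "unchanged")
  spec <- cohort_spec(list(list(id = "d1", stages = "IBD", n_per_arm = 4,
                                paired = FALSE, genes = NULL,
                                noise_sd = 1e-9)),
                      gene_archetypes = arch, baseline = 8, seed = 2)
  tab <- collapse_probes(generate_cohort(spec)[[1]])
  res <- run_contrast(tab, contrast("IBD"))$results
  fc <- setNames(res$log2fc, res$gene)
  eff <- archetype_effects()
  expect_equal(fc[["CCL20"]], eff$neoplasm_up[["IBD"]], tolerance = 1e-6)
  expect_equal(fc[["CXCL9"]],
               eff$inflammation_specific[["IBD"]], tolerance = 1e-6)
  expect_equal(fc[["CXCL12"]], eff$neoplasm_down[["IBD"]],
               tolerance = 1e-6)
  expect_equal(fc[["CCL1"]], 0, tolerance = 1e-6)
})

test_that("platform subsets and per-dataset null genes are honored", {
  arch <- c(CCL20 = "neoplasm_up", CCL2 = "inflammation_specific")
  spec <- cohort_spec(list(
    list(id = "d1", stages = "IBD", n_per_arm = 3, paired = FALSE,
         genes = "CCL20", noise_sd = 0.5),
    list(id = "d2", stages = "IBD", n_per_arm = 3, paired = FALSE,
         genes = NULL, noise_sd = 1e-9, null_genes = "CCL20")),
    gene_archetypes = arch, baseline = 8, seed = 3)
  cohort <- generate_cohort(spec)
  expect_equal(unname(sort(cohort[[1]]$probe_gene_map)), "CCL20")
  res <- run_contrast(collapse_probes(cohort[[2]]),
                      contrast("IBD"))$results
  fc <- setNames(res$log2fc, res$gene)
  expect_equal(fc[["CCL20"]], 0, tolerance = 1e-6)   # nulled here
  expect_equal(fc[["CCL2"]], 3, tolerance = 1e-6)    # untouched
})

test_that("paired cohorts carry a shared pair intercept", {
  arch <- setNames(rep("unchanged", 60), paste0("CCL", 1:60))
  spec <- cohort_spec(list(list(id = "p1", stages = "IBD", n_per_arm = 10,
                                paired = TRUE, genes = NULL,
                                noise_sd = 0.5)),
                      gene_archetypes = arch, baseline = 8, seed = 4)
  ds <- generate_cohort(spec)[[1]]
  expect_true(ds$paired)
  # every pair id occurs in two samples of different stages
  tab <- table(ds$samples$pair_id, ds$samples$stage)
  expect_true(all(tab == 1))
  # the intercept is a per-pair location shift shared by both members:
  # per-sample means (across genes) of the two members of a pair track
  # each other, which is what makes the paired test more powerful
  ctrl <- ds$samples$sample_id[ds$samples$stage == "healthy_control"]
  dis <- ds$samples$sample_id[ds$samples$stage == "IBD"]
  pid <- setNames(ds$samples$pair_id, ds$samples$sample_id)
  partner <- vapply(ctrl, function(s) dis[pid[dis] == pid[s]], "")
  expect_gt(cor(colMeans(ds$matrix[, ctrl]),
                colMeans(ds$matrix[, partner])), 0.5)
})

test_that("empirical fold changes concentrate around the planted effect", {
  arch <- c(CCL20 = "neoplasm_up")
  reps <- vapply(1:40, function(i) {
    spec <- cohort_spec(list(list(id = "d", stages = "IBD", n_per_arm = 10,
                                  paired = FALSE, genes = NULL,
                                  noise_sd = 0.8)),
                        gene_archetypes = arch, baseline = 8, seed = 100 + i)
    res <- run_contrast(collapse_probes(generate_cohort(spec)[[1]]),
                        contrast("IBD"))$results
    res$log2fc
  }, 0)
  expect_equal(mean(reps), 2.5, tolerance = 0.2)
  # spread ~ noise_sd * sqrt(2 / n) = 0.358
  expect_lt(sd(reps), 2 * 0.8 * sqrt(2 / 10))
})

test_that("mouse model generator hits the correlation limits", {
  reg <- build_default_registry()
  spec <- cohort_spec(seed = 5)
  # rho = 1, near-noise-free: measured r approaches 1
  m1 <- generate_mouse_model(spec, 1, seed = 6, registry = reg,
                             noise_sd = 1e-6)
  comp <- run_contrast(collapse_probes(m1), contrast("IBD"))
  truth <- attr(m1, "true_effects")
  fc <- setNames(comp$results$log2fc, comp$results$gene)
  expect_equal(unname(cor(fc[names(truth)], truth)), 1, tolerance = 1e-6)
  # determinism
  m2 <- generate_mouse_model(spec, 0.7, seed = 7, registry = reg)
  m3 <- generate_mouse_model(spec, 0.7, seed = 7, registry = reg)
  expect_identical(m2$matrix, m3$matrix)
  expect_error(generate_mouse_model(spec, 1.4, seed = 1), "correlation")
})

test_that("cohorts written to disk round-trip through the reader", {
  dir <- withr::local_tempdir()
  arch <- c(CCL20 = "neoplasm_up", CCL2 = "inflammation_specific",
            CXCL12 = "neoplasm_down")
  spec <- cohort_spec(list(list(id = "rt", stages = "IBD", n_per_arm = 3,
                                paired = FALSE, genes = NULL,
                                noise_sd = 0.5)),
                      gene_archetypes = arch, baseline = 8, seed = 8)
  cohort <- generate_cohort(spec)
  paths <- write_cohort(cohort, dir)
  ds <- read_series_matrix(paths[["rt"]],
                           file.path(dir, "rt_annotation.tsv"),
                           file.path(dir, "rt_probes.tsv"))
  expect_equal(ds$dataset_id, "rt")
  expect_equal(ds$scale, "log2")   # declared in file metadata
  expect_equal(ds$matrix, cohort[[1]]$matrix, tolerance = 1e-12)
  expect_equal(ds$samples$stage, cohort[[1]]$samples$stage)
})
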