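#' Expression archetypes for the synthetic cohorts
#'
#' The generator plants four gene-level expression patterns mirroring the
#' clusters seen along the colitis-to-cancer axis: neoplasm-upregulated
#' (up in IBD and expression stays high through adenoma/carcinoma),
#' inflammation-specific (up only in IBD), unchanged, and
#' neoplasm-downregulated (down in adenoma/carcinoma only). Effects are true
#' Log2FC values versus healthy control; metastasis effects are versus
#' primary carcinoma and default to 0.
#'
#' @return named list of stage -> Log2FC vectors, one per archetype.
#' @export
archetype_effects <- function() {
  zero <- stats::setNames(rep(0, 4), .STAGES[-1])
  list(
    neoplasm_up = stats::setNames(c(2.5, 2, 2, 0), .STAGES[-1]),
    inflammation_specific = stats::setNames(c(3, 0, 0, 0), .STAGES[-1]),
    unchanged = zero,
    neoplasm_down = stats::setNames(c(0, -2, -2.5, 0), .STAGES[-1])
  )
}

#' Default gene -> archetype assignment
#'
#' Assigns the registry genes to archetypes following the membership of the
#' four published expression clusters (ELR+ ligands and CCL20/24 behave as
#' neoplasm-upregulated; interferon-induced CXCL9/10 and monocyte
#' chemoattractants as inflammation-specific; homeostatic ligands such as
#' CXCL12/13/14 as neoplasm-downregulated); everything else, including most
#' receptors, is unchanged.
#'
#' @param registry a [build_default_registry()] registry.
#' @return named character vector gene -> archetype name.
#' @export
default_gene_archetypes <- function(registry = build_default_registry()) {
  up <- c("CXCL1", "CXCL2", "CXCL3", "PF4", "CXCL5", "CXCL6", "PPBP",
          "CXCL8", "CXCL11", "CCL20", "CCL24", "CXCR2")
  infl <- c("CXCL9", "CXCL10", "CXCL16", "CCL2", "CCL3", "CCL4", "CCL11",
            "CCL18", "CCL22", "CCR1")
  down <- c("CXCL12", "CXCL13", "CXCL14", "CCL5", "CCL8", "CCL13", "CCL14",
            "CCL15", "CCL19", "CCL21", "CCL23", "XCL1", "XCL2", "CCR2",
            "CXCR5")
  genes <- registry$genes$symbol
  arch <- stats::setNames(rep("unchanged", length(genes)), genes)
  arch[up] <- "neoplasm_up"
  arch[infl] <- "inflammation_specific"
  arch[down] <- "neoplasm_down"
  arch
}

#' Specify a synthetic multi-dataset cohort
#'
#' The default cohort mirrors the structure of published multi-center
#' compendia: several small-to-moderate independent datasets per stage
#' (4 IBD, 2 adenoma, 3 carcinoma), 10 samples per arm, additive Gaussian
#' noise of SD 0.8 on the log2 scale, unpaired designs, and every registry
#' gene on every platform.
#'
#' @param datasets list of per-dataset specs; each a list with `id`,
#'   `stages` (stages beyond the reference present in the dataset),
#'   `n_per_arm` (>= 2), `paired` flag, `genes` (platform subset, NULL =
#'   all), `noise_sd` (> 0), and optionally `null_genes` (genes whose stage
#'   effects are zeroed in this dataset, emulating cohort heterogeneity).
#' @param gene_archetypes named character vector gene -> archetype.
#' @param baseline baseline mean log2 expression: a single number, a named
#'   per-gene vector, or NULL to draw per-gene baselines uniformly from
#'   \[6, 10\].
#' @param seed integer seed making generation reproducible.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(datasets = NULL,
                        gene_archetypes = default_gene_archetypes(),
                        baseline = NULL, seed = 1L) {
  if (is.null(datasets)) {
    mk <- function(id, stage) {
      list(id = id, stages = stage, n_per_arm = 10L, paired = FALSE,
           genes = NULL, noise_sd = 0.8, null_genes = character())
    }
    datasets <- c(
      lapply(paste0("IBD", 1:4), mk, stage = "IBD"),
      lapply(paste0("ADE", 1:2), mk, stage = "adenoma"),
      lapply(paste0("CRC", 1:3), mk, stage = "primary_carcinoma"))
  }
  for (d in datasets) {
    if (is.null(d$id) || is.null(d$stages)) {
      stop("each dataset spec needs 'id' and 'stages'")
    }
    if (is.null(d$n_per_arm) || d$n_per_arm < 2L) {
      stop("dataset ", d$id, ": n_per_arm must be >= 2")
    }
    if (is.null(d$noise_sd) || d$noise_sd <= 0) {
      stop("dataset ", d$id, ": noise_sd must be > 0")
    }
    if (!all(d$stages %in% .STAGES)) {
      stop("dataset ", d$id, ": unknown stage")
    }
  }
  if (is.null(names(gene_archetypes)) ||
      !all(gene_archetypes %in% names(archetype_effects()))) {
    stop("gene_archetypes must be a named vector of archetype names")
  }
  structure(list(datasets = datasets, gene_archetypes = gene_archetypes,
                 baseline = baseline, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Raw annotation strings per stage, sampled to exercise harmonization.
.RAW_LABELS <- list(
  healthy_control = c("none", "control", "Normal", "normal colonic mucosa"),
  IBD = c("IBD", "UC", "CD"),
  adenoma = c("colon adenoma", "Adenoma"),
  primary_carcinoma = c("colorectal cancer", "primary tumor", "carcinoma"),
  metastasis = c("metastatic cancer", "liver metastasis",
                 "lung metastasis"))

#' Generate a synthetic multi-dataset cohort
#'
#' For every dataset in the spec, per-gene per-sample log2 values are drawn
#' as gene baseline + archetype stage effect + Normal(0, noise_sd) noise;
#' paired datasets additionally share a per-pair Normal(0, noise_sd / 2)
#' intercept across stages, making the paired test strictly more powerful.
#' Each dataset contains a healthy-control reference arm (metastasis-only
#' datasets use a primary-carcinoma reference arm) plus one arm per listed
#' stage. Sample labels are drawn from the heterogeneous publisher
#' vocabulary so the harmonization path is exercised end-to-end.
#'
#' @param spec a [cohort_spec()].
#' @return list of [expression_dataset()] objects (log2 scale, human).
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' length(cohort)  # 9 datasets
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  genes <- names(spec$gene_archetypes)
  baseline <- spec$baseline
  if (is.null(baseline)) {
    baseline <- stats::setNames(stats::runif(length(genes), 6, 10), genes)
  } else if (length(baseline) == 1L) {
    baseline <- stats::setNames(rep(baseline, length(genes)), genes)
  }
  effects <- archetype_effects()
  lapply(spec$datasets, function(d) {
    g <- if (is.null(d$genes)) genes else intersect(genes, d$genes)
    ref_stage <- if (identical(d$stages, "metastasis"))
      "primary_carcinoma" else "healthy_control"
    stages <- c(ref_stage, setdiff(d$stages, ref_stage))
    n <- d$n_per_arm
    eff <- lapply(stages, function(st) {
      if (st == ref_stage) return(stats::setNames(rep(0, length(g)), g))
      e <- vapply(g, function(gg)
        effects[[spec$gene_archetypes[gg]]][[st]], 0)
      e[g %in% d$null_genes] <- 0
      e
    })
    names(eff) <- stages
    nsamp <- n * length(stages)
    ids <- sprintf("%s_s%02d", d$id, seq_len(nsamp))
    stage_of <- rep(stages, each = n)
    mat <- matrix(NA_real_, length(g), nsamp,
                  dimnames = list(paste0(g, "_at"), ids))
    pair_off <- if (isTRUE(d$paired)) {
      stats::rnorm(n, 0, d$noise_sd / 2)
    } else NULL
    for (j in seq_len(nsamp)) {
      st <- stage_of[j]
      mu <- baseline[g] + eff[[st]]
      if (!is.null(pair_off)) mu <- mu + pair_off[(j - 1L) %% n + 1L]
      mat[, j] <- mu + stats::rnorm(length(g), 0, d$noise_sd)
    }
    raw <- vapply(stage_of, function(st)
      sample(.RAW_LABELS[[st]], 1L), "")
    samples <- data.frame(
      sample_id = ids, raw_label = raw,
      stage = harmonize_stage(raw),
      pair_id = if (isTRUE(d$paired))
        sprintf("%s_p%02d", d$id, (seq_len(nsamp) - 1L) %% n + 1L)
      else NA_character_,
      stringsAsFactors = FALSE)
    expression_dataset(d$id, mat, samples,
                       probe_gene_map = stats::setNames(g, rownames(mat)),
                       species = "human", scale = "log2",
                       paired = isTRUE(d$paired))
  })
}

#' Generate a mouse disease-model dataset with a target correlation
#'
#' Constructs true mouse per-gene effects correlated with the human true
#' effects of the cohort spec at the chosen disease stage: the standardized
#' human effects z are mixed as rho * z + sqrt(1 - rho^2) * independent
#' noise and rescaled back to Log2FC units (human effect mean and SD). A
#' two-arm (healthy vs disease) mouse expression dataset is then simulated
#' around those effects, with genes renamed to their mouse orthologs; human
#' genes without an ortholog are dropped.
#'
#' @param human_spec a [cohort_spec()] supplying the human true effects.
#' @param target_correlation rho in \[-1, 1\].
#' @param seed integer seed.
#' @param registry registry providing the ortholog map.
#' @param stage disease stage whose human effects are mirrored ("IBD" for
#'   colitis models, "primary_carcinoma" for colon-cancer models).
#' @param n_per_arm mouse samples per arm (models are small; default 5).
#' @param noise_sd residual SD on log2 scale (default 0.8, matching the
#'   human cohort generator).
#' @param genes human genes to include; defaults to all spec genes with a
#'   mouse ortholog.
#' @return an [expression_dataset()] (mouse, log2) with attributes
#'   `true_effects` (named by mouse symbol) and `human_genes`.
#' @export
generate_mouse_model <- function(human_spec, target_correlation, seed,
                                 registry = build_default_registry(),
                                 stage = "IBD", n_per_arm = 5L,
                                 noise_sd = 0.8, genes = NULL) {
  stopifnot(inherits(human_spec, "cohort_spec"),
            abs(target_correlation) <= 1)
  set.seed(as.integer(seed))
  if (is.null(genes)) genes <- names(human_spec$gene_archetypes)
  hm <- map_to_mouse(registry, genes)
  genes <- names(hm$mapped)
  if (length(genes) < 3L) stop("fewer than 3 genes with mouse orthologs")
  eff <- archetype_effects()
  e_h <- vapply(genes, function(g)
    eff[[human_spec$gene_archetypes[g]]][[stage]], 0)
  s <- stats::sd(e_h)
  if (s == 0) stop("human effects are constant at stage ", stage,
                   "; target correlation is undefined")
  z <- (e_h - mean(e_h)) / s
  rho <- target_correlation
  e_m <- mean(e_h) + s * (rho * z + sqrt(1 - rho^2) *
                            stats::rnorm(length(z)))
  mouse_sym <- unname(hm$mapped)
  n <- n_per_arm
  ids <- sprintf("m_s%02d", seq_len(2L * n))
  stage_of <- rep(c("healthy_control", stage), each = n)
  mat <- matrix(NA_real_, length(genes), 2L * n,
                dimnames = list(paste0(mouse_sym, "_at"), ids))
  for (j in seq_len(2L * n)) {
    mu <- 8 + if (stage_of[j] == stage) e_m else 0
    mat[, j] <- mu + stats::rnorm(length(genes), 0, noise_sd)
  }
  raw <- vapply(stage_of, function(st) sample(.RAW_LABELS[[st]], 1L), "")
  samples <- data.frame(sample_id = ids, raw_label = raw,
                        stage = stage_of, pair_id = NA_character_,
                        stringsAsFactors = FALSE)
  ds <- expression_dataset("mouse_model", mat, samples,
                           probe_gene_map = stats::setNames(mouse_sym,
                                                            rownames(mat)),
                           species = "mouse", scale = "log2")
  attr(ds, "true_effects") <- stats::setNames(e_m, mouse_sym)
  attr(ds, "human_genes") <- genes
  ds
}

#' Write a synthetic cohort in the TSV dialect the ingest module reads
#'
#' For each dataset, writes `<id>_matrix.tsv` (with `#` metadata lines),
#' `<id>_annotation.tsv` and `<id>_probes.tsv` into `dir`.
#'
#' @param cohort list of [expression_dataset()] objects.
#' @param dir output directory (created if needed).
#' @return named character vector of matrix file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vapply(cohort, function(ds) {
    base <- file.path(dir, ds$dataset_id)
    mpath <- paste0(base, "_matrix.tsv")
    con <- file(mpath, "w")
    writeLines(c(paste0("#dataset_id=", ds$dataset_id),
                 paste0("#species=", ds$species),
                 paste0("#scale=", ds$scale)), con)
    utils::write.table(
      data.frame(probe_id = rownames(ds$matrix), ds$matrix,
                 check.names = FALSE),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    utils::write.table(ds$samples, paste0(base, "_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(probe_id = names(ds$probe_gene_map),
                 gene_symbol = unname(ds$probe_gene_map)),
      paste0(base, "_probes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    mpath
  }, "")
  names(out) <- vapply(cohort, `[[`, "", "dataset_id")
  out
}
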