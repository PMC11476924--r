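#' Fit the multi-cohort chemokine expression profile
#'
#' The central fit of the package: given a list of per-cohort expression
#' datasets, standardizes each to log2, collapses probes to genes, runs the
#' per-dataset stage contrasts (paired or unpaired equal-variance t-tests
#' with BH correction over the gene panel), and aggregates them into the
#' three integration structures: the ratio-of-significant-difference score
#' matrix, the four-group fold-change classification, and the k-cluster
#' grouping of score profiles. Metastasis arms are contrasted against
#' primary carcinoma; all other stages against healthy control.
#'
#' @param datasets list of [expression_dataset()] objects (any scale).
#' @param registry a [build_default_registry()] registry.
#' @param panel `"both"` (default), `"ligands"` or `"receptors"`; the gene
#'   panel analyzed, and the BH family within each dataset.
#' @param fc_threshold,q_threshold significance gates for scoring
#'   (defaults |Log2FC| > 1, Q < 0.05).
#' @param k number of clusters for the score-profile clustering.
#' @return object of class `chemokine_profile`: list with `comparisons`
#'   (per dataset/stage), `metastasis_comparisons`, `score_matrix`,
#'   `groups`, `clusters`, `panel_genes`, `thresholds`, `registry`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 3))
#' fit <- profile_chemokines(cohort, panel = "ligands")
#' fit
#' @export
profile_chemokines <- function(datasets,
                               registry = build_default_registry(),
                               panel = c("both", "ligands", "receptors"),
                               fc_threshold = 1, q_threshold = 0.05,
                               k = 4) {
  panel <- match.arg(panel)
  stopifnot(length(datasets) > 0,
            all(vapply(datasets, inherits, TRUE, "expression_dataset")))
  genes <- switch(panel,
                  both = registry$genes$symbol,
                  ligands = chemokine_ligands(registry),
                  receptors = chemokine_receptors(registry))
  comparisons <- list()
  met_comparisons <- list()
  for (ds in datasets) {
    tab <- collapse_probes(to_log2(ds), genes = genes)
    stages <- unique(tab$samples$stage)
    design <- if (ds$paired) "paired" else "unpaired"
    if ("healthy_control" %in% stages) {
      for (st in intersect(.STAGES[2:4], stages)) {
        cc <- run_contrast(tab, contrast(st, design = design),
                           genes = genes)
        comparisons[[paste(ds$dataset_id, st, sep = ".")]] <- cc
      }
    }
    if (all(c("metastasis", "primary_carcinoma") %in% stages)) {
      cc <- run_contrast(
        tab, contrast("metastasis", "primary_carcinoma", design = design),
        genes = genes)
      met_comparisons[[ds$dataset_id]] <- cc
    }
  }
  if (length(comparisons) == 0L) {
    stop("no dataset provides a healthy-control contrast")
  }
  by_stage <- function(st) {
    Filter(function(cc) cc$contrast$test_stage == st, comparisons)
  }
  score <- build_score_matrix(comparisons, genes = NULL,
                              fc_threshold = fc_threshold,
                              q_threshold = q_threshold)
  groups <- classify_groups(by_stage("IBD"), by_stage("adenoma"),
                            by_stage("primary_carcinoma"),
                            fc_threshold = fc_threshold)
  clusters <- if (nrow(score) >= k) cluster_genes(score, k = k) else NULL
  structure(list(comparisons = comparisons,
                 metastasis_comparisons = met_comparisons,
                 score_matrix = score, groups = groups,
                 clusters = clusters, panel = panel, panel_genes = genes,
                 thresholds = c(fc = fc_threshold, q = q_threshold),
                 registry = registry, call = match.call()),
            class = "chemokine_profile")
}

#' @export
print.chemokine_profile <- function(x, ...) {
  cat("Multi-cohort chemokine expression profile\n")
  cat(" ", length(x$comparisons), "stage comparisons (",
      length(x$metastasis_comparisons), "metastasis-vs-primary )\n")
  cat("  score matrix:", nrow(x$score_matrix), "genes x",
      ncol(x$score_matrix), "stages; gates |Log2FC| >",
      x$thresholds[["fc"]], ", Q <", x$thresholds[["q"]], "\n")
  if (any(x$groups$classifiable)) {
    cat("  groups:",
        paste(levels(x$groups$group),
              table(x$groups$group[x$groups$classifiable]),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.chemokine_profile <- function(object, ...) {
  g <- object$groups
  top <- function(grp) {
    gg <- g[!is.na(g$group) & g$group == grp, , drop = FALSE]
    gg$gene[order(-abs(gg$x + gg$y))][seq_len(min(5, nrow(gg)))]
  }
  out <- list(
    n_comparisons = length(object$comparisons),
    score_matrix = object$score_matrix,
    group_counts = table(g$group[g$classifiable]),
    unclassifiable = g$gene[!g$classifiable],
    top_genes = list(neoplasm_upregulated = top("i"),
                     inflammation_specific = top("ii"),
                     neoplasm_downregulated = top("iv")),
    clusters = object$clusters)
  class(out) <- "summary.chemokine_profile"
  out
}

#' @export
print.summary.chemokine_profile <- function(x, ...) {
  cat("Chemokine profile across", x$n_comparisons, "stage comparisons\n\n")
  cat("Group counts (i = neoplasm-up, ii = inflammation-specific,",
      "iii = unrelated, iv = neoplasm-down):\n")
  print(x$group_counts)
  cat("\nRepresentative genes:\n")
  for (nm in names(x$top_genes)) {
    cat(" ", nm, ":", paste(x$top_genes[[nm]], collapse = ", "), "\n")
  }
  if (length(x$unclassifiable)) {
    cat("Unclassifiable (missing stage coverage):",
        paste(x$unclassifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @param x a `chemokine_profile`.
#' @param type which figure to draw: quadrant `"scatter"` (default), score
#'   `"heatmap"`, per-cluster `"lines"`, or `"volcano"` for one comparison.
#' @param which for `type = "volcano"`, name or index of the comparison.
#' @param path optional output file; NULL draws on the current device.
#' @param ... unused.
#' @rdname profile_chemokines
#' @export
plot.chemokine_profile <- function(x, type = c("scatter", "heatmap",
                                               "lines", "volcano"),
                                   which = 1L, path = NULL, ...) {
  type <- match.arg(type)
  switch(type,
         scatter = plot_scatter(x$groups, path = path,
                                fc_threshold = x$thresholds[["fc"]]),
         heatmap = plot_heatmap(x$score_matrix, x$clusters, path = path),
         lines = {
           lab <- stats::setNames(as.character(x$groups$group),
                                  x$groups$gene)
           plot_lines(x$comparisons, lab[!is.na(lab)], path = path)
         },
         volcano = plot_volcano(x$comparisons[[which]], path = path,
                                fc_threshold = x$thresholds[["fc"]],
                                q_threshold = x$thresholds[["q"]]))
}

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.spec_from_config <- function(config, seed) {
  sim <- config$simulate %||% list()
  datasets <- sim$datasets
  if (is.null(datasets)) {
    # default cohort layout: 4 IBD + 2 adenoma + 3 carcinoma datasets
    datasets <- c(
      lapply(paste0("IBD", 1:4), function(id) list(id = id, stages = "IBD")),
      lapply(paste0("ADE", 1:2),
             function(id) list(id = id, stages = "adenoma")),
      lapply(paste0("CRC", 1:3),
             function(id) list(id = id, stages = "primary_carcinoma")))
  }
  datasets <- lapply(datasets, function(d) {
    list(id = d$id, stages = unlist(d$stages),
         n_per_arm = d$n_per_arm %||% sim$n_per_arm %||% 10L,
         paired = isTRUE(d$paired),
         genes = if (!is.null(d$genes)) unlist(d$genes),
         noise_sd = d$noise_sd %||% sim$noise_sd %||% 0.8,
         null_genes = unlist(d$null_genes) %||% character())
  })
  cohort_spec(datasets = datasets, seed = seed)
}

#' Run the full pipeline from a configuration
#'
#' Config-driven orchestration: loads datasets (series-matrix TSV triples
#' listed under `datasets:`) or generates a synthetic cohort (under
#' `simulate:`), fits [profile_chemokines()], optionally correlates
#' synthetic mouse models (`simulate: mouse_models:`), and writes
#' `comparisons.tsv`, `score_matrix.tsv`, `groups.tsv`,
#' `correlations.json`, figures, and a machine-readable `run_manifest.json`
#' into the output directory. All randomness flows from the seed, so a
#' rerun with the same config and seed reproduces the tables byte for byte.
#'
#' @param config path to a YAML file or an equivalent named list.
#'   Recognized top-level keys: `datasets` (list of `matrix`, `annotation`,
#'   `probe_map`, optional `id`, `species`, `scale`, `paired`), `simulate`
#'   (`n_per_arm`, `noise_sd`, optional `datasets`, `mouse_models`),
#'   `panel`, `fc_threshold`, `q_threshold`, `clusters`, `exclude`,
#'   `seed`, `out_dir`.
#' @param out_dir output directory; overrides the config.
#' @param seed integer seed; overrides the config.
#' @return invisibly, a list with the fitted `profile`, `correlations`,
#'   and the output directory.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- .read_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    stop("no output directory given")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- build_default_registry()

  if (!is.null(config$datasets)) {
    datasets <- lapply(config$datasets, function(d) {
      for (p in c(d$matrix, d$annotation, d$probe_map)) {
        if (!file.exists(p)) stop("dataset file not found: ", p)
      }
      read_series_matrix(d$matrix, d$annotation, d$probe_map,
                         dataset_id = d$id,
                         species = d$species %||% "human",
                         scale = d$scale %||% "auto",
                         rules = unlist(config$stage_rules),
                         paired = isTRUE(d$paired))
    })
    spec <- NULL
  } else {
    spec <- .spec_from_config(config, seed)
    datasets <- generate_cohort(spec)
  }

  fit <- profile_chemokines(
    datasets, registry = registry,
    panel = config$panel %||% "both",
    fc_threshold = config$fc_threshold %||% 1,
    q_threshold = config$q_threshold %||% 0.05,
    k = config$clusters %||% 4)

  comp_df <- do.call(rbind, lapply(
    c(fit$comparisons, fit$metastasis_comparisons), function(cc) {
      r <- cc$results
      r$dataset_id <- cc$dataset_id
      r$contrast <- format(cc$contrast)
      r
    }))
  utils::write.table(comp_df, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_score_matrix(fit$score_matrix,
                     file.path(out_dir, "score_matrix.tsv"), fit$clusters)
  write_groups(fit$groups, file.path(out_dir, "groups.tsv"))

  correlations <- list()
  for (mm in (config$simulate %||% list())$mouse_models %||% list()) {
    if (is.null(spec)) break
    stage <- mm$stage %||% "IBD"
    model <- generate_mouse_model(
      spec, target_correlation = mm$target_correlation %||% 0.7,
      seed = seed + (mm$seed_offset %||% 1L), registry = registry,
      stage = stage, n_per_arm = mm$n_per_arm %||% 5L,
      noise_sd = mm$noise_sd %||% 0.8)
    model$dataset_id <- mm$id %||% model$dataset_id
    mtab <- collapse_probes(model)
    mcomp <- run_contrast(mtab, contrast(stage))
    human <- Filter(function(cc) cc$contrast$test_stage == stage,
                    fit$comparisons)
    corr <- model_vs_human(mcomp, human, registry,
                           exclusions = unlist(config$exclude) %||%
                             character())
    correlations[[model$dataset_id]] <- corr
  }
  if (length(correlations)) {
    jsonlite::write_json(
      lapply(correlations, function(co)
        list(model_id = co$model_id, r = co$r, p = co$p_value, n = co$n,
             exclusions = co$excluded_genes$gene)),
      file.path(out_dir, "correlations.json"),
      auto_unbox = TRUE, digits = NA)
  }

  plot.chemokine_profile(fit, "heatmap",
                         path = file.path(out_dir, "heatmap.png"))
  plot.chemokine_profile(fit, "scatter",
                         path = file.path(out_dir, "scatter.png"))
  plot.chemokine_profile(fit, "lines",
                         path = file.path(out_dir, "lines.png"))
  plot.chemokine_profile(fit, "volcano", which = 1L,
                         path = file.path(out_dir, "volcano.png"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("chemoatlas")),
    seed = seed,
    panel = fit$panel,
    thresholds = as.list(fit$thresholds),
    clusters = config$clusters %||% 4,
    inputs = if (is.null(spec)) {
      lapply(config$datasets, function(d) d$matrix)
    } else "synthetic cohort",
    n_datasets = length(datasets),
    outputs = c("comparisons.tsv", "score_matrix.tsv", "groups.tsv",
                if (length(correlations)) "correlations.json",
                "heatmap.png", "scatter.png", "lines.png", "volcano.png"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profile = fit, correlations = correlations,
                 out_dir = out_dir))
}

#' Generate a synthetic cohort and write it to disk
#'
#' Wraps [generate_cohort()] + [write_cohort()]: accepts a [cohort_spec()],
#' a YAML file, or a config list with a `simulate` section, and writes the
#' cohort in the TSV dialect [read_series_matrix()] reads.
#'
#' @param spec a `cohort_spec`, YAML path, or config list.
#' @param out_dir output directory.
#' @param seed optional seed override.
#' @return named character vector of written matrix files.
#' @export
simulate_to_dir <- function(spec, out_dir, seed = NULL) {
  if (!inherits(spec, "cohort_spec")) {
    config <- .read_config(spec)
    spec <- .spec_from_config(config, as.integer(seed %||% config$seed
                                                 %||% 1L))
  } else if (!is.null(seed)) {
    spec$seed <- as.integer(seed)
  }
  write_cohort(generate_cohort(spec), out_dir)
}
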