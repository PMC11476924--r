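#' @keywords internal
.STAGES <- c("healthy_control", "IBD", "adenoma", "primary_carcinoma",
             "metastasis")

#' Built-in stage harmonization vocabulary
#'
#' Cohort publishers annotate histologically equivalent samples with widely
#' different free-text labels. The analysis harmonizes them into five stages:
#' healthy control, IBD (ulcerative colitis and Crohn's disease pooled),
#' adenoma, primary carcinoma, and metastasis (liver and lung pooled).
#'
#' @return named character vector: lower-cased raw label -> stage.
#' @export
default_stage_rules <- function() {
  c("none" = "healthy_control",
    "control" = "healthy_control",
    "normal" = "healthy_control",
    "normal colonic mucosa" = "healthy_control",
    "ibd" = "IBD",
    "uc" = "IBD",
    "cd" = "IBD",
    "colon adenoma" = "adenoma",
    "adenoma" = "adenoma",
    "colorectal cancer" = "primary_carcinoma",
    "primary tumor" = "primary_carcinoma",
    "carcinoma" = "primary_carcinoma",
    "metastatic cancer" = "metastasis",
    "liver metastasis" = "metastasis",
    "lung metastasis" = "metastasis")
}

#' Harmonize a raw sample annotation into one of the five disease stages
#'
#' Matching is case-insensitive and whitespace-trimmed. User-supplied rules
#' take precedence over the built-in vocabulary; an unmatched label is an
#' error, never silently dropped.
#'
#' @param raw_label character vector of free-text sample annotations.
#' @param rules optional named character vector (label -> stage) extending
#'   or overriding [default_stage_rules()].
#' @return character vector of stages.
#' @examples
#' harmonize_stage("UC")            # "IBD"
#' harmonize_stage("Normal ")       # "healthy_control"
#' @export
harmonize_stage <- function(raw_label, rules = NULL) {
  vocab <- default_stage_rules()
  if (!is.null(rules)) {
    if (is.null(names(rules)) || any(!nzchar(names(rules)))) {
      stop("stage rules must be a named character vector")
    }
    if (!all(rules %in% .STAGES)) {
      stop("stage rules must map to one of: ",
           paste(.STAGES, collapse = ", "))
    }
    user <- stats::setNames(as.character(rules),
                            tolower(trimws(names(rules))))
    vocab <- c(user, vocab[!names(vocab) %in% names(user)])
  }
  key <- tolower(trimws(raw_label))
  out <- unname(vocab[key])
  if (anyNA(out)) {
    stop("unrecognized sample label(s): ",
         paste(unique(raw_label[is.na(out)]), collapse = ", "),
         "; supply a harmonization rule")
  }
  out
}

#' Construct an expression dataset for one cohort
#'
#' @param dataset_id identifier string.
#' @param matrix numeric probe x sample matrix with row and column names;
#'   missing values allowed.
#' @param samples data frame with columns `sample_id`, `raw_label`, `stage`,
#'   and optionally `pair_id` (NA for unpaired samples).
#' @param probe_gene_map named character vector, probe id -> gene symbol.
#' @param species `"human"` or `"mouse"`.
#' @param scale `"linear"` or `"log2"`.
#' @param paired logical; whether the cohort design is paired.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, matrix, samples, probe_gene_map,
                               species = c("human", "mouse"),
                               scale = c("log2", "linear"),
                               paired = FALSE) {
  species <- match.arg(species)
  scale <- match.arg(scale)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("matrix must be a numeric matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix needs probe rownames and sample colnames")
  }
  if (ncol(matrix) == 0L || nrow(samples) == 0L) {
    stop("dataset '", dataset_id, "' has no samples")
  }
  if (!all(c("sample_id", "raw_label", "stage") %in% names(samples))) {
    stop("samples needs columns sample_id, raw_label, stage")
  }
  if (is.null(samples$pair_id)) samples$pair_id <- NA_character_
  if (!setequal(colnames(matrix), samples$sample_id) ||
      ncol(matrix) != nrow(samples)) {
    stop("matrix columns and sample annotations must match one-to-one")
  }
  samples <- samples[match(colnames(matrix), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$stage %in% .STAGES)) {
    stop("sample stages must be one of: ", paste(.STAGES, collapse = ", "))
  }
  miss <- setdiff(rownames(matrix), names(probe_gene_map))
  if (length(miss)) {
    stop("probes without gene mapping: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  structure(list(dataset_id = dataset_id, species = species, scale = scale,
                 matrix = matrix,
                 probe_gene_map = probe_gene_map[rownames(matrix)],
                 samples = samples, paired = isTRUE(paired)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset", x$dataset_id, sprintf("(%s, %s scale%s)\n",
      x$species, x$scale, if (x$paired) ", paired" else ""))
  cat(" ", nrow(x$matrix), "probes x", ncol(x$matrix), "samples\n")
  print(table(x$samples$stage))
  invisible(x)
}

#' Read a series-matrix style expression file
#'
#' Expects a tab-separated matrix whose first column is the probe id and
#' whose header row carries sample ids, with two companion tables: a sample
#' annotation TSV (`sample_id`, `raw_label`, optional `pair_id`) and a probe
#' map TSV (`probe_id`, `gene_symbol`). Lines starting with `#` before the
#' header may declare metadata as `#key=value` (recognized: `scale`,
#' `species`, `dataset_id`).
#'
#' Scale handling: an explicit declaration (argument or file metadata) wins;
#' under `scale = "auto"` a matrix whose maximum exceeds 50 is treated as
#' linear intensity, otherwise as already log2 (log2 microarray intensities
#' rarely exceed ~20). Values are never modified here; see [to_log2()].
#'
#' @param path expression matrix file.
#' @param annotation_path sample annotation TSV.
#' @param probe_map_path probe -> gene TSV.
#' @param dataset_id identifier; defaults to file metadata or the file name.
#' @param species dataset species, unless declared in file metadata.
#' @param scale `"auto"`, `"linear"` or `"log2"`.
#' @param rules extra stage-harmonization rules, see [harmonize_stage()].
#' @param paired whether the design is paired (pair ids must then be present
#'   in the annotation table).
#' @return an [expression_dataset()].
#' @export
read_series_matrix <- function(path, annotation_path, probe_map_path,
                               dataset_id = NULL, species = "human",
                               scale = c("auto", "linear", "log2"),
                               rules = NULL, paired = FALSE) {
  scale <- match.arg(scale)
  for (p in c(path, annotation_path, probe_map_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  meta <- list()
  for (l in lines[meta_idx]) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (length(body) < 2L) stop("malformed matrix in ", path, ": no data rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop("malformed matrix in ", path, ": line ",
         length(meta_idx) + bad, " has ", ncols[bad],
         " fields, expected ", ncols[1])
  }
  header <- fields[[1]]
  sample_ids <- header[-1]
  if (length(sample_ids) == 0L) stop("no sample columns in ", path)
  probe_ids <- vapply(fields[-1], `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(fields[-1], function(f) as.numeric(f[-1]),
           numeric(length(sample_ids))))
  mat <- matrix(vals, nrow = length(probe_ids), ncol = length(sample_ids),
                byrow = TRUE, dimnames = list(probe_ids, sample_ids))

  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!all(c("sample_id", "raw_label") %in% names(ann))) {
    stop("annotation file needs columns sample_id, raw_label")
  }
  extra <- setdiff(sample_ids, ann$sample_id)
  if (length(extra)) stop("samples missing annotation: ",
                          paste(extra, collapse = ", "))
  ann <- ann[match(sample_ids, ann$sample_id), , drop = FALSE]
  ann$stage <- harmonize_stage(ann$raw_label, rules)

  pm <- utils::read.delim(probe_map_path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(pm))) {
    stop("probe map needs columns probe_id, gene_symbol")
  }
  probe_gene_map <- stats::setNames(pm$gene_symbol, pm$probe_id)

  if (!is.null(meta$scale)) scale <- match.arg(meta$scale,
                                               c("linear", "log2"))
  if (scale == "auto") {
    scale <- if (max(mat, na.rm = TRUE) > 50) "linear" else "log2"
  }
  expression_dataset(
    dataset_id = dataset_id %||% meta$dataset_id %||%
      tools::file_path_sans_ext(basename(path)),
    matrix = mat, samples = ann, probe_gene_map = probe_gene_map,
    species = meta$species %||% species, scale = scale, paired = paired)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize an expression dataset to log2 scale
#'
#' Linear intensities v are replaced by `log2(max(v, eps))`; background-
#' subtracted microarray values can be zero or negative, and clamping at
#' `eps = 1` maps them to 0 on the log2 scale. Datasets already on log2
#' scale are returned unchanged (idempotent).
#'
#' @param dataset an [expression_dataset()].
#' @param eps positive clamp applied before the logarithm.
#' @return the dataset with `scale == "log2"`.
#' @export
to_log2 <- function(dataset, eps = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale == "log2") return(dataset)
  m <- dataset$matrix
  m[] <- log2(pmax(m, eps))
  dataset$matrix <- m
  dataset$scale <- "log2"
  dataset
}

#' Collapse probes to genes by strongest mean signal
#'
#' For each gene with at least one probe on the platform, the single probe
#' with the highest mean log2 intensity across all samples of the dataset is
#' retained; ties are broken by the lexicographically smallest probe id
#' (C-locale ordering). Genes absent from the platform are simply absent
#' from the result, never zero-filled. Missing values are ignored in the
#' probe means and propagate into the gene table.
#'
#' @param dataset an [expression_dataset()] on log2 scale.
#' @param genes optional gene symbols to restrict to.
#' @return object of class `gene_expression_table`: list with `dataset_id`,
#'   gene x sample `matrix`, `samples`, `species`, `paired`.
#' @export
collapse_probes <- function(dataset, genes = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "log2") {
    stop("standardize to log2 first (to_log2)")
  }
  map <- dataset$probe_gene_map
  if (!is.null(genes)) map <- map[map %in% genes]
  if (length(map) == 0L) {
    keep <- character()
  } else {
    means <- rowMeans(dataset$matrix[names(map), , drop = FALSE],
                      na.rm = TRUE)
    id_rank <- match(names(map), sort(names(map), method = "radix"))
    ord <- order(unname(map), -means, id_rank, method = "radix")
    keep <- names(map)[ord][!duplicated(unname(map)[ord])]
  }
  mat <- dataset$matrix[keep, , drop = FALSE]
  rownames(mat) <- unname(map[keep])
  structure(list(dataset_id = dataset$dataset_id, matrix = mat,
                 samples = dataset$samples, species = dataset$species,
                 paired = dataset$paired),
            class = "gene_expression_table")
}

#' @export
print.gene_expression_table <- function(x, ...) {
  cat("Gene expression table", x$dataset_id, ":", nrow(x$matrix),
      "genes x", ncol(x$matrix), "samples\n")
  invisible(x)
}

#' Write a gene expression table as TSV
#'
#' @param table a `gene_expression_table`.
#' @param path output file.
#' @export
write_expression_table <- function(table, path) {
  df <- data.frame(gene = rownames(table$matrix), table$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
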