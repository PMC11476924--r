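#' Significance score for one gene in one dataset
#'
#' A gene is called significantly changed in a dataset when its Q-value is
#' below `q_threshold` and its |Log2FC| exceeds `fc_threshold` (defaults:
#' Q < 0.05, i.e. -Log10Q > 1.3, and |Log2FC| > 1). Significant increases
#' score +1, significant decreases -1, everything else 0.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param q_value numeric vector of BH Q-values.
#' @param fc_threshold positive |Log2FC| cut-off (default 1).
#' @param q_threshold Q-value cut-off (default 0.05).
#' @return integer vector in \{-1, 0, +1\}; NA inputs give NA.
#' @examples
#' score_gene(c(2.1, 0.5, -1.5), c(0.01, 0.001, 0.2))  # 1 0 0
#' @export
score_gene <- function(log2fc, q_value, fc_threshold = 1,
                       q_threshold = 0.05) {
  stopifnot(fc_threshold > 0)
  out <- ifelse(q_value < q_threshold & log2fc > fc_threshold, 1L,
                ifelse(q_value < q_threshold & log2fc < -fc_threshold,
                       -1L, 0L))
  out[is.na(log2fc) | is.na(q_value)] <- NA_integer_
  as.integer(out)
}

#' Ratio of significant difference
#'
#' The vote-counting statistic: the arithmetic mean of per-dataset
#' significance scores (+1/0/-1) for one gene at one stage. A gene
#' significantly up in 3 of 4 datasets scores (1+1+1+0)/4 = 0.75.
#'
#' @param scores integer scores from [score_gene()], one per dataset
#'   measuring the gene at this stage.
#' @return mean score in \[-1, 1\].
#' @examples
#' ratio_of_significant_difference(c(1, 1, 1, 0))  # 0.75
#' @export
ratio_of_significant_difference <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) {
    stop("no datasets measure this gene at this stage; cell is missing")
  }
  if (!all(scores %in% c(-1L, 0L, 1L))) {
    stop("scores must be -1, 0 or +1")
  }
  mean(scores)
}

#' Build the gene x stage score matrix
#'
#' Each cell is the ratio of significant difference for a gene at a stage:
#' the signed mean of +1/0/-1 calls over the datasets that both cover that
#' stage and measure that gene. Cells with no measuring dataset are NA.
#'
#' @param comparisons list of `stage_comparison` objects sharing one
#'   reference stage (healthy control for the disease-course matrix;
#'   metastasis-vs-primary is built separately).
#' @param genes gene roster for the rows; defaults to the union of genes
#'   seen in the comparisons.
#' @param fc_threshold,q_threshold passed to [score_gene()].
#' @return object of class `score_matrix`: numeric gene x stage matrix in
#'   \[-1, 1\] with attribute `n_datasets` (per-cell denominators).
#' @export
build_score_matrix <- function(comparisons, genes = NULL, fc_threshold = 1,
                               q_threshold = 0.05) {
  stopifnot(length(comparisons) > 0,
            all(vapply(comparisons, inherits, TRUE, "stage_comparison")))
  refs <- unique(vapply(comparisons,
                        function(cc) cc$contrast$reference_stage, ""))
  if (length(refs) != 1L) {
    stop("comparisons must share one reference stage, got: ",
         paste(refs, collapse = ", "))
  }
  stages <- unique(vapply(comparisons,
                          function(cc) cc$contrast$test_stage, ""))
  stages <- .STAGES[.STAGES %in% stages]
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(comparisons,
                                       function(cc) cc$results$gene))),
                  method = "radix")
  }
  score_sum <- n <- matrix(0, length(genes), length(stages),
                           dimnames = list(genes, stages))
  for (cc in comparisons) {
    st <- cc$contrast$test_stage
    r <- cc$results[cc$results$gene %in% genes, , drop = FALSE]
    s <- score_gene(r$log2fc, r$q_value, fc_threshold, q_threshold)
    ok <- !is.na(s)
    idx <- cbind(match(r$gene[ok], genes), match(st, stages))
    score_sum[idx] <- score_sum[idx] + s[ok]
    n[idx] <- n[idx] + 1L
  }
  out <- ifelse(n > 0, score_sum / n, NA_real_)
  structure(out, n_datasets = n, class = c("score_matrix", "matrix"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Ratio-of-significant-difference matrix:", nrow(x), "genes x",
      ncol(x), "stages\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Classify genes into the four expression-pattern groups
#'
#' Places each gene on the plane x = mean Log2FC across IBD datasets,
#' y = arithmetic mean of (mean adenoma Log2FC, mean carcinoma Log2FC), and
#' assigns the four groups with a two-fold-change criterion:
#' \describe{
#'   \item{i}{neoplasm-upregulated: x > 1 and y > 1 — up in colitis and
#'     expression stays high in tumors.}
#'   \item{ii}{inflammation-specific: x > 1 and |y| <= 1 — up only during
#'     the inflammatory stage.}
#'   \item{iii}{unrelated: no two-fold change on either axis (and any
#'     remaining cells of the plane the four named patterns do not cover).}
#'   \item{iv}{neoplasm-downregulated: y < -1 and |x| <= 1 — down in tumors
#'     with no IBD change.}
#' }
#' The unnamed cell x > 1, y < -1 is resolved by the nearest archetype
#' (larger absolute coordinate wins; exact tie falls to iii). Genes exactly
#' at a threshold fall on the |value| <= 1 side.
#'
#' @param ibd_comparisons,adenoma_comparisons,carcinoma_comparisons lists of
#'   `stage_comparison` objects for the three stages (vs healthy control).
#' @param genes gene roster; defaults to union of genes measured.
#' @param fc_threshold quadrant cut-off on both axes (default 1).
#' @return data frame of class `group_assignment` with columns `gene`, `x`,
#'   `y`, `group` (factor i/ii/iii/iv, NA when unclassifiable) and
#'   `classifiable`.
#' @export
classify_groups <- function(ibd_comparisons, adenoma_comparisons,
                            carcinoma_comparisons, genes = NULL,
                            fc_threshold = 1) {
  mean_fc <- function(comps) {
    tabs <- lapply(comps, function(cc) {
      r <- cc$results
      stats::setNames(r$log2fc, r$gene)
    })
    all_genes <- unique(unlist(lapply(tabs, names)))
    vapply(all_genes, function(g) {
      v <- unlist(lapply(tabs, function(t) t[g]))
      mean(v, na.rm = TRUE)
    }, 0)
  }
  x_fc <- mean_fc(ibd_comparisons)
  aden_fc <- mean_fc(adenoma_comparisons)
  carc_fc <- mean_fc(carcinoma_comparisons)
  if (is.null(genes)) {
    genes <- sort(unique(c(names(x_fc), names(aden_fc), names(carc_fc))),
                  method = "radix")
  }
  t <- fc_threshold
  out <- data.frame(gene = genes, x = NA_real_, y = NA_real_,
                    group = NA_character_, classifiable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    x <- if (g %in% names(x_fc) && is.finite(x_fc[g])) x_fc[[g]] else NA
    tumor <- c(aden_fc[g][is.finite(aden_fc[g])],
               carc_fc[g][is.finite(carc_fc[g])])
    y <- if (length(tumor)) mean(tumor) else NA
    out$x[i] <- x
    out$y[i] <- y
    if (is.na(x) || is.na(y)) next
    out$classifiable[i] <- TRUE
    out$group[i] <-
      if (x > t && y > t) "i"
      else if (x > t && abs(y) <= t) "ii"
      else if (y < -t && abs(x) <= t) "iv"
      else if (x > t && y < -t) {
        if (abs(x) > abs(y)) "ii" else if (abs(y) > abs(x)) "iv" else "iii"
      } else "iii"
  }
  out$group <- factor(out$group, levels = c("i", "ii", "iii", "iv"))
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Cluster genes on their score-matrix profiles
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of the score-matrix rows, cut at `k` clusters. Missing cells
#' are imputed as 0 ("no evidence of change") for clustering only. Rows are
#' processed in gene-symbol order so the result is deterministic.
#'
#' @param matrix a [build_score_matrix()] result.
#' @param k number of clusters (default 4, matching the four expression
#'   patterns).
#' @return object of class `cluster_result`: list with `labels` (named
#'   integer vector in 1..k), `hclust` (the merge tree), and `k`.
#' @export
cluster_genes <- function(matrix, k = 4) {
  stopifnot(inherits(matrix, "score_matrix") || is.matrix(matrix))
  m <- unclass(matrix)
  if (nrow(m) < k) {
    stop("fewer genes (", nrow(m), ") than clusters (", k, ")")
  }
  m <- m[sort(rownames(m), method = "radix"), , drop = FALSE]
  m[is.na(m)] <- 0
  hc <- stats::hclust(stats::dist(m), method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, hclust = hc, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Gene clustering: k =", x$k, "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Write the score matrix (with optional cluster labels) as TSV
#'
#' @param matrix a `score_matrix`.
#' @param path output file.
#' @param clusters optional `cluster_result`; labels appended as a column.
#' @export
write_score_matrix <- function(matrix, path, clusters = NULL) {
  df <- data.frame(gene = rownames(matrix), unclass(matrix)[, , drop = FALSE],
                   check.names = FALSE)
  if (!is.null(clusters)) {
    df$cluster <- clusters$labels[df$gene]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write group assignments as TSV
#'
#' @param assignments a `group_assignment` data frame.
#' @param path output file.
#' @export
write_groups <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
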