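#' Correlate a mouse disease model against human cohorts
#'
#' Pairs each human gene's mean Log2FC (unweighted mean across the human
#' datasets measuring it) with the Log2FC of its mouse ortholog in a mouse
#' model dataset, then computes the Pearson correlation and its two-tailed
#' p-value (t distribution, n - 2 degrees of freedom). Genes can be excluded
#' explicitly (the published analyses drop, e.g., interferon-driven CXCL10
#' and CXCL11 from the TNBS colitis comparison); genes without a mouse
#' ortholog, or with one that the model platform does not measure, are
#' reported rather than silently lost.
#'
#' @param model_comparison `stage_comparison` from a mouse model dataset
#'   (genes named with mouse symbols).
#' @param human_comparisons list of human `stage_comparison` objects sharing
#'   one contrast (e.g. IBD vs healthy control).
#' @param registry a [build_default_registry()] registry providing the
#'   ortholog map.
#' @param exclusions human gene symbols to drop before correlating.
#' @param method `"pearson"` (default, parametric p-value) or `"spearman"`.
#' @return object of class `model_correlation`: list with `model_id`,
#'   `points` (data frame gene, mouse_log2fc, human_mean_log2fc), `r`,
#'   `p_value`, `n`, `method`, and `excluded_genes` (data frame gene,
#'   reason).
#' @export
model_vs_human <- function(model_comparison, human_comparisons, registry,
                           exclusions = character(),
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(model_comparison, "stage_comparison"),
            inherits(registry, "chemokine_registry"))
  human_contrasts <- unique(vapply(human_comparisons,
                                   function(cc) format(cc$contrast), ""))
  if (length(human_contrasts) != 1L) {
    stop("human comparisons must share one contrast, got: ",
         paste(human_contrasts, collapse = "; "))
  }
  tabs <- lapply(human_comparisons, function(cc) {
    stats::setNames(cc$results$log2fc, cc$results$gene)
  })
  human_genes <- sort(unique(unlist(lapply(tabs, names))), method = "radix")
  human_fc <- vapply(human_genes, function(g) {
    v <- unlist(lapply(tabs, function(tt) tt[g]))
    mean(v, na.rm = TRUE)
  }, 0)

  mouse_fc <- stats::setNames(model_comparison$results$log2fc,
                              model_comparison$results$gene)
  excl <- data.frame(gene = character(), reason = character(),
                     stringsAsFactors = FALSE)
  add_excl <- function(genes, reason) {
    if (length(genes)) {
      rbind(excl, data.frame(gene = genes, reason = reason,
                             stringsAsFactors = FALSE))
    } else excl
  }
  if (length(exclusions)) {
    exclusions <- resolve_symbol(registry, exclusions)
    excl <- add_excl(intersect(human_genes, exclusions), "excluded")
    human_genes <- setdiff(human_genes, exclusions)
  }
  hm <- map_to_mouse(registry, human_genes)
  excl <- add_excl(hm$unmapped, "no mouse ortholog")
  pairs <- hm$mapped
  measured <- names(pairs)[pairs %in% names(mouse_fc) &
                             !is.na(mouse_fc[pairs])]
  excl <- add_excl(setdiff(names(pairs), measured),
                   "not measured in model")
  measured <- measured[is.finite(human_fc[measured])]
  points <- data.frame(gene = measured,
                       mouse_log2fc = unname(mouse_fc[pairs[measured]]),
                       human_mean_log2fc = unname(human_fc[measured]),
                       stringsAsFactors = FALSE)
  if (nrow(points) < 3L) {
    stop("need at least 3 paired genes to correlate, got ", nrow(points))
  }
  ct <- suppressWarnings(
    stats::cor.test(points$mouse_log2fc, points$human_mean_log2fc,
                    method = method, exact = FALSE))
  structure(list(model_id = model_comparison$dataset_id, points = points,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(points), method = method, excluded_genes = excl),
            class = "model_correlation")
}

#' @export
print.model_correlation <- function(x, ...) {
  cat(sprintf("Model %s vs human cohorts: %s r = %.3f (p = %.3g, n = %d)\n",
              x$model_id, x$method, x$r, x$p_value, x$n))
  if (nrow(x$excluded_genes)) {
    cat("  excluded:", paste(x$excluded_genes$gene, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Leave-one-out influence on the model correlation
#'
#' Recomputes the correlation with each gene removed in turn — a diagnostic
#' for genes (such as divergent interferon-induced chemokines) whose removal
#' changes r materially.
#'
#' @param correlation a [model_vs_human()] result with at least 4 points.
#' @return named numeric vector of leave-one-out r values, sorted by
#'   decreasing |r_without - r|; the change itself is in attribute
#'   `delta_r`.
#' @export
leave_one_out_influence <- function(correlation) {
  stopifnot(inherits(correlation, "model_correlation"))
  p <- correlation$points
  if (nrow(p) < 4L) stop("need at least 4 points for leave-one-out")
  loo <- vapply(seq_len(nrow(p)), function(i) {
    stats::cor(p$mouse_log2fc[-i], p$human_mean_log2fc[-i],
               method = correlation$method)
  }, 0)
  names(loo) <- p$gene
  delta <- loo - correlation$r
  ord <- order(-abs(delta), names(loo), method = "radix")
  structure(loo[ord], delta_r = delta[ord])
}

#' Write a model correlation as TSV + JSON summary
#'
#' @param correlation a `model_correlation`.
#' @param tsv_path per-gene point table output path (NULL to skip).
#' @param json_path summary JSON output path (NULL to skip).
#' @export
write_correlation <- function(correlation, tsv_path = NULL,
                              json_path = NULL) {
  if (!is.null(tsv_path)) {
    pts <- correlation$points
    pts$included <- TRUE
    ex <- correlation$excluded_genes
    if (nrow(ex)) {
      pts <- rbind(pts, data.frame(gene = ex$gene, mouse_log2fc = NA,
                                   human_mean_log2fc = NA,
                                   included = FALSE))
    }
    utils::write.table(pts, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(model_id = correlation$model_id, method = correlation$method,
           r = correlation$r, p = correlation$p_value, n = correlation$n,
           exclusions = correlation$excluded_genes$gene),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(correlation)
}
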