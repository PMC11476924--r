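#' Significance stars for p-values
#'
#' @param p numeric p-values.
#' @return character vector: "****" p < 1e-4, "***" p < 1e-3, "**" p < 0.01,
#'   "*" p < 0.05, "" otherwise.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", ""), right = FALSE) |>
    as.character()
}

.open_device <- function(path, width = 7, height = 7) {
  if (is.null(path)) return(FALSE)
  if (grepl("\\.svg$", path)) {
    grDevices::svg(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width * 100, height = height * 100,
                   res = 100)
  }
  TRUE
}

#' Heatmap of the score matrix
#'
#' Renders the gene x stage ratio-of-significant-difference matrix with
#' the field's polarity convention: red for upregulation, green for
#' downregulation, black for no change; missing cells (no measuring
#' dataset) in grey. Genes are ordered by cluster and, within cluster, by
#' dendrogram order when a clustering is supplied.
#'
#' @param matrix a [build_score_matrix()] result.
#' @param clusters optional [cluster_genes()] result ordering the rows.
#' @param path output PNG/SVG path, or NULL to draw on the current device.
#' @return invisibly, the row order used.
#' @export
plot_heatmap <- function(matrix, clusters = NULL, path = NULL) {
  m <- unclass(matrix)
  if (nrow(m) == 0L) stop("empty score matrix")
  if (!is.null(clusters)) {
    dend_order <- clusters$hclust$labels[clusters$hclust$order]
    lab <- clusters$labels[dend_order]
    ord <- dend_order[order(match(lab, unique(lab)))]
    m <- m[ord[ord %in% rownames(m)], , drop = FALSE]
  }
  dev <- .open_device(path, 6, max(4, 0.18 * nrow(m)))
  if (dev) on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("green3", "black", "red2"))(101)
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  op <- graphics::par(mar = c(2, 6, 3, 6))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "",
                  ylab = "", main = "Ratio of significant difference")
  if (anyNA(z)) {
    na_idx <- which(is.na(z), arr.ind = TRUE)
    graphics::rect(na_idx[, 1] - 0.5, na_idx[, 2] - 0.5,
                   na_idx[, 1] + 0.5, na_idx[, 2] + 0.5,
                   col = "grey70", border = NA)
  }
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                 tick = FALSE, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, tick = FALSE, cex.axis = 0.55)
  invisible(rownames(m))
}

#' Fold-change quadrant scatter plot
#'
#' x = mean IBD Log2FC, y = mean tumor Log2FC, guide lines at the two-fold
#' cut-offs (+1/-1) on both axes, points colored by group i-iv.
#'
#' @param assignments a [classify_groups()] result.
#' @param path output path or NULL.
#' @param fc_threshold guide-line position (default 1).
#' @return invisibly, the table of group counts drawn.
#' @export
plot_scatter <- function(assignments, path = NULL, fc_threshold = 1) {
  a <- assignments[assignments$classifiable, , drop = FALSE]
  dev <- .open_device(path)
  if (dev) on.exit(grDevices::dev.off())
  cols <- c(i = "red2", ii = "orange2", iii = "grey50", iv = "green4")
  graphics::plot(a$x, a$y, col = cols[as.character(a$group)], pch = 19,
                 xlab = "mean Log2FC (IBD vs healthy)",
                 ylab = "mean Log2FC (adenoma/carcinoma vs healthy)",
                 main = "Expression-pattern groups")
  graphics::abline(v = c(-1, 1) * fc_threshold,
                   h = c(-1, 1) * fc_threshold, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(table(a$group))
}

#' Line chart of mean fold change per group across stages
#'
#' For each expression-pattern group (or cluster), plots the mean Log2FC of
#' its genes at each disease stage of one dataset (or cohort aggregate),
#' connected in stage order.
#'
#' @param comparisons list of `stage_comparison` objects (one per stage,
#'   shared reference) from which per-gene Log2FCs are taken.
#' @param groups named vector gene -> group/cluster label.
#' @param path output path or NULL.
#' @return invisibly, the group x stage matrix of means drawn.
#' @export
plot_lines <- function(comparisons, groups, path = NULL) {
  stages <- vapply(comparisons, function(cc) cc$contrast$test_stage, "")
  ord <- order(match(stages, .STAGES))
  comparisons <- comparisons[ord]
  stages <- stages[ord]
  labs <- sort(unique(as.character(groups)), method = "radix")
  m <- matrix(NA_real_, length(labs), length(stages),
              dimnames = list(labs, stages))
  for (k in seq_along(comparisons)) {
    r <- comparisons[[k]]$results
    g <- intersect(r$gene, names(groups))
    fc <- stats::setNames(r$log2fc, r$gene)[g]
    for (l in labs) {
      v <- fc[names(fc)[as.character(groups[names(fc)]) == l]]
      if (length(v)) m[l, k] <- mean(v, na.rm = TRUE)
    }
  }
  dev <- .open_device(path, 7, 5)
  if (dev) on.exit(grDevices::dev.off())
  graphics::matplot(t(m), type = "b", pch = 19, lty = 1, xaxt = "n",
                    xlab = "stage", ylab = "mean Log2FC vs healthy",
                    main = "Expression trends by group")
  graphics::axis(1, at = seq_along(stages), labels = stages,
                 cex.axis = 0.8)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = labs,
                   col = seq_along(labs), lty = 1, pch = 19, bty = "n")
  invisible(m)
}

#' Volcano plot for one stage comparison
#'
#' x = Log2FC, y = -Log10 Q, guide lines at |Log2FC| = fc_threshold and
#' -Log10Q = 1.3 (Q = 0.05). Points beyond both gates — exactly the genes
#' [score_gene()] marks nonzero — are highlighted.
#'
#' @param comparison a `stage_comparison`.
#' @param path output path or NULL.
#' @param fc_threshold,q_threshold significance gates.
#' @return invisibly, the character vector of flagged gene symbols.
#' @export
plot_volcano <- function(comparison, path = NULL, fc_threshold = 1,
                         q_threshold = 0.05) {
  r <- comparison$results
  s <- score_gene(r$log2fc, r$q_value, fc_threshold, q_threshold)
  flagged <- r$gene[!is.na(s) & s != 0L]
  dev <- .open_device(path)
  if (dev) on.exit(grDevices::dev.off())
  y <- -log10(pmax(r$q_value, 1e-300))
  col <- ifelse(is.na(s) | s == 0L, "grey60",
                ifelse(s > 0L, "red2", "green4"))
  graphics::plot(r$log2fc, y, pch = 19, col = col, xlab = "Log2FC",
                 ylab = "-Log10 Q",
                 main = paste(comparison$dataset_id,
                              format(comparison$contrast)))
  graphics::abline(v = c(-1, 1) * fc_threshold, lty = 2, col = "grey40")
  graphics::abline(h = -log10(q_threshold), lty = 2, col = "grey40")
  if (length(flagged)) {
    idx <- match(flagged, r$gene)
    graphics::text(r$log2fc[idx], y[idx], flagged, pos = 3, cex = 0.6)
  }
  invisible(flagged)
}
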