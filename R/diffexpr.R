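#' Define a stage contrast
#'
#' @param test_stage stage whose expression is tested.
#' @param reference_stage baseline stage; healthy control by default, and
#'   primary carcinoma for metastasis analyses.
#' @param design `"unpaired"` (pooled-variance Student t-test) or `"paired"`.
#' @return object of class `stage_contrast`.
#' @export
contrast <- function(test_stage,
                     reference_stage = "healthy_control",
                     design = c("unpaired", "paired")) {
  design <- match.arg(design)
  stopifnot(test_stage %in% .STAGES, reference_stage %in% .STAGES)
  if (test_stage == reference_stage) {
    stop("test and reference stage must differ")
  }
  structure(list(test_stage = test_stage,
                 reference_stage = reference_stage,
                 design = design),
            class = "stage_contrast")
}

#' @export
format.stage_contrast <- function(x, ...) {
  paste0(x$test_stage, "_vs_", x$reference_stage,
         if (x$design == "paired") " (paired)" else "")
}

#' @export
print.stage_contrast <- function(x, ...) {
  cat("Contrast:", format(x), "\n")
  invisible(x)
}

# Two-tailed equal-variance t-tests in closed form. A closed form is used
# (rather than stats::t.test) so that zero-variance inputs can be handled
# deterministically: identical groups give p = 1, and otherwise the variance
# is floored at .VAR_FLOOR instead of producing an infinite statistic.
# stats::t.test serves as the independent check in the test suite.
.VAR_FLOOR <- 1e-12

.pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (s2 < .VAR_FLOOR) {
    if (d == 0) return(list(estimate = 0, statistic = 0, p = 1, df = df))
    s2 <- .VAR_FLOOR
  }
  tstat <- d / sqrt(s2 * (1 / n1 + 1 / n2))
  list(estimate = d, statistic = tstat,
       p = 2 * stats::pt(-abs(tstat), df), df = df)
}

.paired_t <- function(d) {
  n <- length(d)
  m <- mean(d)
  v <- stats::var(d)
  if (v < .VAR_FLOOR) {
    if (m == 0) return(list(estimate = 0, statistic = 0, p = 1, df = n - 1))
    v <- .VAR_FLOOR
  }
  tstat <- m / sqrt(v / n)
  list(estimate = m, statistic = tstat,
       p = 2 * stats::pt(-abs(tstat), n - 1), df = n - 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Converts p-values to Q-values by the step-up false-discovery-rate
#' procedure, preserving input order. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector in \[0, 1\] (NA allowed, propagated).
#' @return Q-values in \[0, 1\], same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric")
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) {
    stop("p-values outside [0, 1]: ",
         paste(signif(p_values[bad], 3), collapse = ", "))
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-dataset differential expression for one stage contrast
#'
#' Computes, for every gene of the panel present in the table, the log2 fold
#' change (difference of group means on log2 scale), a two-tailed
#' equal-variance t-test p-value (pooled-variance Student test for unpaired
#' designs, paired t-test over pair-matched samples otherwise), and the
#' Benjamini-Hochberg Q-value adjusted across exactly the genes reported.
#'
#' Pairs with a missing member are dropped (complete-case); genes for which
#' fewer than two observations (or complete pairs) remain in an arm get NA
#' statistics and do not enter the BH family.
#'
#' @param table a [collapse_probes()] gene expression table.
#' @param contrast a [contrast()].
#' @param genes gene panel to test; defaults to all genes in the table. The
#'   BH family is this panel restricted to genes measured on the platform.
#' @return object of class `stage_comparison`: list with `dataset_id`,
#'   `contrast`, and `results` data frame (gene, log2fc, p_value, q_value,
#'   n_test, n_ref).
#' @examples
#' # two arms of three samples each
#' m <- rbind(GENE1 = c(5, 6, 7, 2, 3, 4))
#' s <- data.frame(sample_id = paste0("s", 1:6),
#'                 raw_label = rep(c("UC", "control"), each = 3),
#'                 stage = rep(c("IBD", "healthy_control"), each = 3))
#' colnames(m) <- s$sample_id
#' tab <- structure(list(dataset_id = "demo", matrix = m, samples = s,
#'                       species = "human", paired = FALSE),
#'                  class = "gene_expression_table")
#' run_contrast(tab, contrast("IBD"))$results
#' @export
run_contrast <- function(table, contrast, genes = NULL) {
  stopifnot(inherits(table, "gene_expression_table"),
            inherits(contrast, "stage_contrast"))
  samples <- table$samples
  test_ids <- samples$sample_id[samples$stage == contrast$test_stage]
  ref_ids <- samples$sample_id[samples$stage == contrast$reference_stage]
  if (length(test_ids) < 2L) {
    stop("insufficient samples in test arm '", contrast$test_stage,
         "' of ", table$dataset_id, " (", length(test_ids), " < 2)")
  }
  if (length(ref_ids) < 2L) {
    stop("insufficient samples in reference arm '",
         contrast$reference_stage, "' of ", table$dataset_id,
         " (", length(ref_ids), " < 2)")
  }
  panel <- if (is.null(genes)) rownames(table$matrix) else
    intersect(genes, rownames(table$matrix))
  paired <- contrast$design == "paired"
  if (paired) {
    pr <- samples$pair_id
    names(pr) <- samples$sample_id
    shared <- intersect(stats::na.omit(pr[test_ids]),
                        stats::na.omit(pr[ref_ids]))
    if (length(shared) == 0L) {
      stop("paired design but no shared pairs between arms in ",
           table$dataset_id)
    }
    test_ids <- test_ids[match(shared, pr[test_ids])]
    ref_ids <- ref_ids[match(shared, pr[ref_ids])]
  }

  res <- data.frame(gene = panel, log2fc = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, n_test = NA_integer_,
                    n_ref = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(panel)) {
    x <- table$matrix[panel[i], test_ids]
    y <- table$matrix[panel[i], ref_ids]
    if (paired) {
      ok <- !is.na(x) & !is.na(y)
      d <- x[ok] - y[ok]
      res$n_test[i] <- res$n_ref[i] <- length(d)
      if (length(d) >= 1L) res$log2fc[i] <- mean(d)
      if (length(d) >= 2L) {
        tt <- .paired_t(d)
        res$p_value[i] <- tt$p
      }
    } else {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      res$n_test[i] <- length(x); res$n_ref[i] <- length(y)
      if (length(x) >= 1L && length(y) >= 1L) {
        res$log2fc[i] <- mean(x) - mean(y)
      }
      if (length(x) >= 2L && length(y) >= 2L) {
        tt <- .pooled_t(x, y)
        res$p_value[i] <- tt$p
      }
    }
  }
  res$q_value <- bh_adjust(res$p_value)
  structure(list(dataset_id = table$dataset_id, contrast = contrast,
                 results = res),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat("Stage comparison", x$dataset_id, "-", format(x$contrast), "\n")
  sig <- with(x$results, !is.na(q_value) & q_value < 0.05 &
                abs(log2fc) > 1)
  cat(" ", nrow(x$results), "genes tested;", sum(sig),
      "significant (Q < 0.05, |Log2FC| > 1)\n")
  invisible(x)
}

#' Write a stage comparison as TSV
#'
#' @param comparison a `stage_comparison`.
#' @param path output file.
#' @export
write_comparison <- function(comparison, path) {
  df <- comparison$results
  df$dataset_id <- comparison$dataset_id
  df$contrast <- format(comparison$contrast)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
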