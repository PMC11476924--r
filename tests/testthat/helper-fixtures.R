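# Independent brute-force BH step-up, straight from the definition:
# q_i = min over sorted positions j with p_(j) >= p_i of m * p_(j) / j,
# clipped at 1. Kept deliberately naive as the oracle for bh_adjust().
bh_brute <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi)
    min(1, min(m * sp[js] / js))
  }, 0)
}

# Build a gene_expression_table directly from a gene x sample matrix.
make_table <- function(mat, stages, pair_id = NULL, id = "t1",
                       paired = !is.null(pair_id)) {
  colnames(mat) <- colnames(mat) %||% paste0("s", seq_len(ncol(mat)))
  samples <- data.frame(
    sample_id = colnames(mat),
    raw_label = stages,
    stage = stages,
    pair_id = pair_id %||% NA_character_,
    stringsAsFactors = FALSE)
  structure(list(dataset_id = id, matrix = mat, samples = samples,
                 species = "human", paired = paired),
            class = "gene_expression_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a stage_comparison from per-gene summary values.
make_comp <- function(genes, log2fc, q, stage = "IBD", id = "d1",
                      ref = "healthy_control") {
  structure(list(
    dataset_id = id,
    contrast = contrast(stage, ref),
    results = data.frame(gene = genes, log2fc = log2fc,
                         p_value = q, q_value = q,
                         n_test = 10L, n_ref = 10L,
                         stringsAsFactors = FALSE)),
    class = "stage_comparison")
}

# Archetype name -> expected quadrant group under the default effects.
archetype_group_map <- c(neoplasm_up = "i", inflammation_specific = "ii",
                         unchanged = "iii", neoplasm_down = "iv")
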