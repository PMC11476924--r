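#' Chemokine nomenclature registry
#'
#' The human chemokine system comprises four subfamilies defined by the
#' spacing of conserved N-terminal cysteines: CXC, CC, CX3C and XC. The
#' registry bundled with this package holds the 39 ligands and 22 receptors
#' used throughout the analysis, together with common aliases (e.g. CXCL7 for
#' PPBP), the ELR-motif flag for the seven ELR+ CXC ligands, receptor-ligand
#' pairings, and a one-to-one human-to-mouse ortholog map.
#'
#' @return An object of class `chemokine_registry`: a list with components
#'   \describe{
#'     \item{genes}{data frame with columns `symbol`, `family`, `role`,
#'       `elr_positive`, `aliases`, `mouse_homolog`.}
#'     \item{receptor_ligand_map}{named list mapping each receptor symbol to
#'       the character vector of its ligands present in the registry.}
#'     \item{homolog_map}{named character vector, human symbol -> mouse
#'       symbol; genes without a mouse ortholog are absent.}
#'     \item{alias_map}{named character vector, alias -> canonical symbol.}
#'   }
#' @examples
#' reg <- build_default_registry()
#' sum(reg$genes$role == "ligand")          # 39
#' chemokine_info(reg, "CXCL7")$symbol      # resolves alias to PPBP
#' @export
build_default_registry <- function() {
  path <- system.file("extdata", "chemokine_registry.tsv",
                      package = "chemoatlas", mustWork = TRUE)
  genes <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = character())
  genes$elr_positive <- as.logical(genes$elr_positive)

  alias_map <- character()
  has_alias <- nzchar(genes$aliases)
  for (i in which(has_alias)) {
    for (a in strsplit(genes$aliases[i], ",", fixed = TRUE)[[1]]) {
      alias_map[toupper(trimws(a))] <- genes$symbol[i]
    }
  }

  homolog <- genes$mouse_homolog
  names(homolog) <- genes$symbol
  homolog_map <- homolog[nzchar(homolog)]

  reg <- structure(
    list(genes = genes,
         receptor_ligand_map = .default_receptor_ligand_map(),
         homolog_map = homolog_map,
         alias_map = alias_map),
    class = "chemokine_registry")
  validate_registry(reg)
  reg
}

# Receptor pairings restricted to ligands on the 39-member roster.
.default_receptor_ligand_map <- function() {
  elr <- c("CXCL1", "CXCL2", "CXCL3", "CXCL5", "CXCL6", "PPBP", "CXCL8")
  list(
    CXCR1 = elr,
    CXCR2 = elr,
    CXCR3 = c("CXCL9", "CXCL10", "CXCL11"),
    CXCR4 = "CXCL12",
    CXCR5 = "CXCL13",
    CXCR6 = "CXCL16",
    CCR1  = c("CCL3", "CCL5", "CCL7", "CCL8", "CCL13", "CCL14", "CCL15",
              "CCL16", "CCL23"),
    CCR2  = "CCL2",
    CCR3  = c("CCL11", "CCL24", "CCL26"),
    CCR4  = "CCL22",
    CCR5  = c("CCL3", "CCL4", "CCL5"),
    CCR6  = "CCL20",
    CCR7  = c("CCL19", "CCL21"),
    CCR8  = "CCL1",
    CCR10 = "CCL28",
    XCR1  = c("XCL1", "XCL2"),
    CX3CR1 = "CX3CL1",
    ACKR3 = "CXCL12"
  )
}

#' @keywords internal
validate_registry <- function(reg) {
  genes <- reg$genes
  n_lig <- sum(genes$role == "ligand")
  n_rec <- sum(genes$role == "receptor")
  if (n_lig != 39L || n_rec != 22L) {
    stop("registry must hold 39 ligands and 22 receptors, got ",
         n_lig, "/", n_rec)
  }
  if (anyDuplicated(genes$symbol)) stop("duplicate symbols in registry")
  if (!all(genes$family %in% c("CXC", "CC", "CX3C", "XC"))) {
    stop("unknown subfamily in registry")
  }
  # Subfamily must be derivable from the symbol prefix (via alias for the
  # genes whose HGNC symbol predates chemokine nomenclature, PF4/PPBP).
  for (i in seq_len(nrow(genes))) {
    syms <- c(genes$symbol[i],
              strsplit(genes$aliases[i], ",", fixed = TRUE)[[1]])
    derived <- .family_from_symbol(syms)
    if (!is.na(derived) && derived != genes$family[i]) {
      stop("family of ", genes$symbol[i], " inconsistent with its prefix")
    }
  }
  elr_set <- sort(genes$symbol[genes$elr_positive])
  expected <- sort(c("CXCL1", "CXCL2", "CXCL3", "CXCL5", "CXCL6", "PPBP",
                     "CXCL8"))
  if (!identical(elr_set, expected)) stop("ELR+ set mismatch")
  if (anyDuplicated(reg$homolog_map)) {
    stop("homolog map is not injective")
  }
  unknown <- setdiff(unlist(reg$receptor_ligand_map),
                     genes$symbol[genes$role == "ligand"])
  if (length(unknown)) {
    stop("receptor_ligand_map names unknown ligands: ",
         paste(unknown, collapse = ", "))
  }
  invisible(reg)
}

# CX3C before CXC: "CX3CL1" also matches the CXC pattern loosely if tested
# naively, so test the longer motif first.
.family_from_symbol <- function(symbols) {
  for (s in symbols) {
    if (grepl("^CX3C[LR]", s)) return("CX3C")
    if (grepl("^CXC[LR]", s)) return("CXC")
    if (grepl("^CC[LR]", s)) return("CC")
    if (grepl("^XC[LR]", s)) return("XC")
  }
  NA_character_
}

#' Resolve a gene symbol or alias to its canonical registry symbol
#'
#' @param registry a `chemokine_registry`.
#' @param symbol character vector of symbols or aliases (case-insensitive).
#' @return canonical symbols; error on symbols unknown to the registry.
#' @export
resolve_symbol <- function(registry, symbol) {
  stopifnot(inherits(registry, "chemokine_registry"))
  up <- toupper(trimws(symbol))
  out <- ifelse(up %in% registry$genes$symbol, up,
                unname(registry$alias_map[up]))
  if (anyNA(out)) {
    stop("unknown gene symbol(s): ",
         paste(symbol[is.na(out)], collapse = ", "))
  }
  out
}

#' Look up one gene record
#'
#' @inheritParams resolve_symbol
#' @return one-row data frame from the registry gene table.
#' @export
chemokine_info <- function(registry, symbol) {
  sym <- resolve_symbol(registry, symbol)
  registry$genes[match(sym, registry$genes$symbol), , drop = FALSE]
}

#' Registry gene rosters
#'
#' @inheritParams resolve_symbol
#' @return character vector of ligand or receptor symbols, in registry order.
#' @export
chemokine_ligands <- function(registry) {
  registry$genes$symbol[registry$genes$role == "ligand"]
}

#' @rdname chemokine_ligands
#' @export
chemokine_receptors <- function(registry) {
  registry$genes$symbol[registry$genes$role == "receptor"]
}

#' Map human symbols to mouse orthologs
#'
#' Uses the bundled static homology table. Symbols without a clean
#' one-to-one mouse ortholog (e.g. CXCL8, which mice lack) are reported in
#' the `unmapped` component rather than mapped to a placeholder.
#'
#' @inheritParams resolve_symbol
#' @param symbols character vector of human symbols (aliases allowed); all
#'   must be present in the registry.
#' @return list with `mapped` (named character vector, human -> mouse, in
#'   input order) and `unmapped` (human symbols with no ortholog).
#' @examples
#' reg <- build_default_registry()
#' map_to_mouse(reg, c("CCL2", "CXCL8"))
#' @export
map_to_mouse <- function(registry, symbols) {
  if (length(symbols) == 0L) {
    return(list(mapped = character(), unmapped = character()))
  }
  sym <- resolve_symbol(registry, symbols)
  mouse <- registry$homolog_map[sym]
  ok <- !is.na(mouse)
  mapped <- unname(mouse[ok])
  names(mapped) <- sym[ok]
  list(mapped = mapped, unmapped = sym[!ok])
}

#' @export
print.chemokine_registry <- function(x, ...) {
  cat("Chemokine registry:", sum(x$genes$role == "ligand"), "ligands,",
      sum(x$genes$role == "receptor"), "receptors\n")
  cat("Subfamilies:",
      paste(names(table(x$genes$family)), table(x$genes$family),
            sep = "=", collapse = ", "), "\n")
  cat("Human->mouse orthologs:", length(x$homolog_map), "\n")
  invisible(x)
}
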