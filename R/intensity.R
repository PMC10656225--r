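#' Construct an intensity table
#'
#' Protein-by-sample raw intensity matrix with explicit missingness (`NA`,
#' never 0: intensity is a sum of peptide peak areas, so an absent
#' quantification means "below detection", not zero). Carries per-genotype
#' razor+unique peptide counts for quality filtering and the sample design.
#'
#' @param values Numeric matrix, proteins x samples; missing values `NA`;
#'   present values must be strictly positive.
#' @param protein_ids Character vector of unique accessions (rownames).
#' @param gene_names Character vector; entries may hold several
#'   semicolon-separated symbols, the first being canonical.
#' @param razor_unique Integer matrix with columns `WT` and `KO`:
#'   per-protein max razor+unique peptide counts per genotype.
#' @param design A [sample_design()] describing every column of `values`.
#' @return An `intensity_table`.
#' @export
intensity_table <- function(values, protein_ids, gene_names, razor_unique,
                            design) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyDuplicated(protein_ids))
    stop("duplicate protein accessions: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  stopifnot(nrow(values) == length(protein_ids),
            length(gene_names) == length(protein_ids))
  razor_unique <- as.matrix(razor_unique)
  if (!all(c("WT", "KO") %in% colnames(razor_unique)))
    stop("razor_unique must have 'WT' and 'KO' columns")
  stopifnot(nrow(razor_unique) == length(protein_ids))
  if (any(razor_unique < 0, na.rm = TRUE))
    stop("razor+unique peptide counts must be nonnegative")
  validate_sample_design(design)
  miss <- setdiff(design$sample, colnames(values))
  if (length(miss))
    stop("design sample(s) absent from value matrix: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(colnames(values), design$sample)
  if (length(extra))
    stop("value column(s) not described by the design: ",
         paste(extra, collapse = ", "))
  values <- values[, design$sample, drop = FALSE]
  if (any(values <= 0, na.rm = TRUE))
    stop("present intensities must be > 0 (zeros must be converted to NA on read)")
  rownames(values) <- protein_ids
  structure(list(values = values,
                 protein_ids = as.character(protein_ids),
                 gene_names = as.character(gene_names),
                 razor_unique = razor_unique,
                 design = design),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table:", nrow(x$values), "proteins x", ncol(x$values),
      "samples;", sum(is.na(x$values)), "missing cells\n")
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

subset_proteins <- function(x, keep) {
  x$values <- x$values[keep, , drop = FALSE]
  x$protein_ids <- x$protein_ids[keep]
  x$gene_names <- x$gene_names[keep]
  x$razor_unique <- x$razor_unique[keep, , drop = FALSE]
  if (!is.null(x$imputed)) x$imputed <- x$imputed[keep, , drop = FALSE]
  x
}

#' First-listed (canonical) gene symbol
#'
#' Protein groups can carry several semicolon-separated gene symbols
#' (e.g. `"Prrx2; Prrx1"`); the first listed symbol is used when counting
#' distinct proteins.
#'
#' @param gene_names Character vector.
#' @return Character vector of first-listed symbols.
#' @export
first_gene <- function(gene_names) {
  trimws(sub(";.*$", "", gene_names))
}
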