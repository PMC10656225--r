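# Small builders used across test files. Everything is generated in code;
# no stored binary fixtures.

# A minimal 3-column design intensity table with hand-chosen values.
# `values` may contain NA for missing cells.
toy_table <- function(values, razor_wt = NULL, razor_ko = NULL,
                      n_columns = 3) {
  design <- default_design(n_columns)
  n <- nrow(values)
  colnames(values) <- design$sample
  if (is.null(razor_wt)) razor_wt <- rep(5L, n)
  if (is.null(razor_ko)) razor_ko <- rep(5L, n)
  intensity_table(values,
                  protein_ids = sprintf("P%02d", seq_len(n)),
                  gene_names = sprintf("G%02d", seq_len(n)),
                  razor_unique = cbind(WT = razor_wt, KO = razor_ko),
                  design = design)
}

# Constant-abundance table: every cell `base`, then per-sample log2 shifts
# applied by name, e.g. shifts = c(WT_eluate_c1 = 1).
shifted_table <- function(n = 4, base = 1000, shifts = numeric(0), ...) {
  design <- default_design(3)
  v <- matrix(base, n, nrow(design),
              dimnames = list(NULL, design$sample))
  for (s in names(shifts)) v[, s] <- v[, s] * 2^shifts[[s]]
  toy_table(v, ...)
}

# Evidence record builder (one row, one or more mods).
toy_evidence <- function(peptide_seq, leading_protein, offsets,
                         mod_types = rep("R", length(offsets)),
                         loc = 0.99, pep = 0.001, genotype = "WT",
                         column_id = "c1", gene = leading_protein) {
  d <- data.frame(peptide_seq = peptide_seq,
                  leading_protein = leading_protein, gene_names = gene,
                  localization_probability = loc, pep = pep,
                  genotype = genotype, column_id = column_id,
                  stringsAsFactors = FALSE)
  d$mods <- list(data.frame(
    offset = offsets,
    residue = vapply(offsets, function(o) substr(peptide_seq, o, o), ""),
    mod_type = mod_types, stringsAsFactors = FALSE))
  class(d) <- c("peptide_evidence", "data.frame")
  d
}

bind_evidence <- function(...) {
  parts <- list(...)
  d <- do.call(rbind, parts)
  class(d) <- c("peptide_evidence", "data.frame")
  d
}

# Canonical form of a partition for label-free comparison.
canonical_partition <- function(membership) {
  membership <- membership[order(names(membership))]
  match(membership, unique(membership))
}
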