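#' Construct and validate a sample design
#'
#' Describes each quantified sample of a pulldown experiment: its genotype
#' (`WT` wildtype or `KO` arginyltransferase knockout), the antibody column
#' it came from, and its role (`input` lysate or antibody-column `eluate`).
#' The layout mirrors the experiment: one input lysate per genotype and one
#' eluate per (genotype, antibody column).
#'
#' @param sample Character vector of sample (intensity column) names.
#' @param genotype Character vector, each `"WT"` or `"KO"`.
#' @param column_id Antibody-column identifier per sample (`NA` for inputs
#'   is allowed and normalized to `""`).
#' @param role Character vector, each `"input"` or `"eluate"`.
#' @return A `sample_design` data.frame.
#' @examples
#' default_design()
#' @export
sample_design <- function(sample, genotype, column_id, role) {
  d <- data.frame(sample = as.character(sample),
                  genotype = as.character(genotype),
                  column_id = as.character(column_id),
                  role = as.character(role),
                  stringsAsFactors = FALSE)
  d$column_id[is.na(d$column_id)] <- ""
  validate_sample_design(d)
  class(d) <- c("sample_design", "data.frame")
  d
}

validate_sample_design <- function(d) {
  req <- c("sample", "genotype", "column_id", "role")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("sample design lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample))
    stop("duplicate sample names in design")
  if (!all(d$genotype %in% c("WT", "KO")))
    stop("genotype must be 'WT' or 'KO'")
  if (!all(d$role %in% c("input", "eluate")))
    stop("role must be 'input' or 'eluate'")
  el <- d[d$role == "eluate", ]
  if (anyDuplicated(paste(el$genotype, el$column_id)))
    stop("each (genotype, column_id) eluate combination may appear at most once")
  for (g in c("WT", "KO")) {
    n_in <- sum(d$genotype == g & d$role == "input")
    if (n_in != 1L)
      stop("design must contain exactly one input sample for genotype ", g,
           " (found ", n_in, ")")
  }
  invisible(d)
}

#' Default three-antibody-column design
#'
#' One input per genotype plus WT/KO eluates for each of `n_columns`
#' antibody columns, matching the three independent polyclonal
#' pan-arginylation columns of the experimental layout.
#'
#' @param n_columns Number of antibody columns (default 3).
#' @return A `sample_design`.
#' @export
default_design <- function(n_columns = 3) {
  cols <- paste0("c", seq_len(n_columns))
  sample_design(
    sample = c("WT_input", "KO_input",
               paste0("WT_eluate_", cols), paste0("KO_eluate_", cols)),
    genotype = c("WT", "KO", rep("WT", n_columns), rep("KO", n_columns)),
    column_id = c("", "", cols, cols),
    role = c("input", "input", rep("eluate", 2 * n_columns)))
}

#' Read / write a sample design TSV
#'
#' Tab-separated with header columns `sample`, `genotype`, `column_id`,
#' `role`.
#'
#' @param path File path.
#' @return `read_sample_design()` returns a `sample_design`.
#' @export
read_sample_design <- function(path) {
  d <- read_tsv_checked(path, c("sample", "genotype", "column_id", "role"))
  d$column_id[is.na(d$column_id)] <- ""
  sample_design(d$sample, d$genotype, d$column_id, d$role)
}

#' @rdname read_sample_design
#' @param design A `sample_design`.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

design_samples <- function(design, genotype, role, column_id = NULL) {
  keep <- design$genotype == genotype & design$role == role
  if (!is.null(column_id)) keep <- keep & design$column_id == column_id
  design$sample[keep]
}

eluate_columns <- function(design) {
  sort(unique(design$column_id[design$role == "eluate"]))
}
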