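# Readers/writers for the on-disk artifacts. All tables are UTF-8,
# tab-separated with a mandatory header; decimal point ".", scientific
# notation accepted; no binary formats.

read_tsv_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "", comment.char = "", encoding = "UTF-8")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("file '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  d
}

#' Read a protein-group quantification table
#'
#' Tab-separated, MaxQuant proteinGroups-like: one row per protein group
#' with accession, gene names, per-genotype max razor+unique peptide counts,
#' and one raw intensity column per sample of the design. Intensities of 0
#' or empty cells are converted to missing (`NA`): an absent quantification
#' means the protein fell below the detection limit, and the downstream
#' imputation must be able to distinguish that from a measured value.
#'
#' @param path File path. Required columns: `protein_id`, `gene_names`,
#'   `razor_unique_wt`, `razor_unique_ko`, plus every `design$sample`.
#' @param design A [sample_design()] mapping intensity column names to
#'   (genotype, antibody column, role).
#' @return An [intensity_table()]. The number of zero/empty cells converted
#'   to missing is reported in attribute `"n_zero_to_missing"`.
#' @export
read_protein_groups <- function(path, design) {
  validate_sample_design(design)
  d <- read_tsv_checked(path, c("protein_id", "gene_names",
                                "razor_unique_wt", "razor_unique_ko",
                                design$sample))
  if (anyDuplicated(d$protein_id))
    stop("duplicate protein accession(s) in '", path, "': ",
         paste(unique(d$protein_id[duplicated(d$protein_id)]),
               collapse = ", "))
  vals <- matrix(NA_real_, nrow(d), length(design$sample),
                 dimnames = list(d$protein_id, design$sample))
  n_zero <- 0L
  for (s in design$sample) {
    raw <- d[[s]]
    if (is.character(raw)) {
      raw_trim <- trimws(raw)
      empty <- raw_trim == "" | is.na(raw_trim)
      num <- suppressWarnings(as.numeric(raw_trim))
      bad <- which(!empty & is.na(num))
      if (length(bad))
        stop("non-numeric intensity in column '", s, "', row ", bad[1],
             " of '", path, "'")
    } else {
      num <- as.numeric(raw)
    }
    neg <- which(!is.na(num) & num < 0)
    if (length(neg))
      stop("negative intensity in column '", s, "', row ", neg[1],
           " of '", path, "'")
    zero <- !is.na(num) & num == 0
    n_zero <- n_zero + sum(zero)
    num[zero] <- NA_real_
    vals[, s] <- num
  }
  ru <- cbind(WT = as.integer(d$razor_unique_wt),
              KO = as.integer(d$razor_unique_ko))
  out <- intensity_table(vals, d$protein_id, d$gene_names, ru, design)
  attr(out, "n_zero_to_missing") <- n_zero
  out
}

#' @rdname read_protein_groups
#' @param x An `intensity_table`.
#' @export
write_protein_groups <- function(x, path) {
  stopifnot(inherits(x, "intensity_table"))
  vals <- x$values
  vals[is.na(vals)] <- 0  # MaxQuant convention: absent quantification is 0
  d <- data.frame(protein_id = x$protein_ids, gene_names = x$gene_names,
                  razor_unique_wt = x$razor_unique[, "WT"],
                  razor_unique_ko = x$razor_unique[, "KO"],
                  stringsAsFactors = FALSE, check.names = FALSE)
  d <- cbind(d, as.data.frame(vals, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a modified-peptide / site evidence table
#'
#' Accepts two equivalent encodings of the modification positions:
#' \describe{
#'   \item{inline}{a `peptide` column with parenthesized markers, e.g.
#'     `"DTSLYRPALE(R)ELR"` (see [parse_modified_peptide()]);}
#'   \item{positional}{a plain `peptide` column plus per-type peptide-offset
#'     columns `r_offsets`, `rme_offsets`, `rme2_offsets` holding
#'     semicolon-separated 1-based offsets.}
#' }
#' Both encodings parse to identical evidence records. Optional columns
#' `leading_protein`, `gene_names`, `localization_probability`, `pep`,
#' `genotype` (default `"WT"`), `column_id`.
#'
#' @param path File path.
#' @return A `peptide_evidence` data.frame: one row per evidence record with
#'   columns `peptide_seq`, `leading_protein`, `gene_names`,
#'   `localization_probability`, `pep`, `genotype`, `column_id`, and a
#'   list-column `mods` of per-record data.frames
#'   (`offset`, `residue`, `mod_type`).
#' @export
read_site_table <- function(path) {
  d <- read_tsv_checked(path, "peptide")
  n <- nrow(d)
  positional <- any(c("r_offsets", "rme_offsets", "rme2_offsets") %in% names(d))
  seqs <- character(n)
  mods <- vector("list", n)
  for (i in seq_len(n)) {
    if (positional) {
      seqs[i] <- toupper(d$peptide[i])
      mods[[i]] <- parse_offset_columns(d, i, seqs[i])
    } else {
      p <- parse_modified_peptide(d$peptide[i])
      seqs[i] <- p$seq
      mods[[i]] <- p$mods
    }
    validate_evidence_mods(seqs[i], mods[[i]])
  }
  geno <- if ("genotype" %in% names(d)) as.character(d$genotype) else
    rep("WT", n)
  if (!all(geno %in% c("WT", "KO")))
    stop("genotype column must contain only 'WT'/'KO'")
  ev <- data.frame(
    peptide_seq = seqs,
    leading_protein = if ("leading_protein" %in% names(d))
      as.character(d$leading_protein) else rep(NA_character_, n),
    gene_names = if ("gene_names" %in% names(d))
      as.character(d$gene_names) else rep(NA_character_, n),
    localization_probability = if ("localization_probability" %in% names(d))
      as.numeric(d$localization_probability) else rep(NA_real_, n),
    pep = if ("pep" %in% names(d)) as.numeric(d$pep) else rep(NA_real_, n),
    genotype = geno,
    column_id = if ("column_id" %in% names(d))
      as.character(d$column_id) else rep(NA_character_, n),
    stringsAsFactors = FALSE)
  lp <- ev$localization_probability
  if (any(!is.na(lp) & (lp < 0 | lp > 1)))
    stop("localization_probability outside [0,1] in '", path, "'")
  if (any(!is.na(ev$pep) & (ev$pep < 0 | ev$pep > 1)))
    stop("pep outside [0,1] in '", path, "'")
  ev$mods <- mods
  class(ev) <- c("peptide_evidence", "data.frame")
  ev
}

parse_offset_columns <- function(d, i, seq) {
  cols <- c(r_offsets = "R", rme_offsets = "R-me", rme2_offsets = "R-me2")
  offs <- integer(0); typ <- character(0)
  for (cn in names(cols)) {
    if (!cn %in% names(d)) next
    v <- d[[cn]][i]
    if (is.na(v) || trimws(as.character(v)) == "") next
    o <- as.integer(trimws(strsplit(as.character(v), ";", fixed = TRUE)[[1]]))
    if (any(is.na(o)))
      stop("malformed offsets '", v, "' in column ", cn, ", row ", i)
    offs <- c(offs, o); typ <- c(typ, rep(cols[[cn]], length(o)))
  }
  ord <- order(offs)
  data.frame(offset = offs[ord],
             residue = vapply(offs[ord], function(o) substr(seq, o, o), ""),
             mod_type = typ[ord], stringsAsFactors = FALSE)
}

validate_evidence_mods <- function(seq, mods) {
  if (nrow(mods) == 0L) return(invisible(TRUE))
  if (any(mods$offset < 1L | mods$offset > nchar(seq)))
    stop("modification offset outside peptide '", seq, "'")
  at <- vapply(mods$offset, function(o) substr(seq, o, o), "")
  if (!identical(at, mods$residue))
    stop("modification residue mismatch in peptide '", seq, "'")
  # Glu/Asp side chains, or the peptide N-terminal residue
  bad <- !(mods$residue %in% c("E", "D")) & mods$offset != 1L
  if (any(bad))
    stop("modified residue must be E/D or the peptide N terminus ",
         "(peptide '", seq, "', offset ", mods$offset[bad][1], ")")
  invisible(TRUE)
}

#' @rdname read_site_table
#' @param evidence A `peptide_evidence` data.frame.
#' @param encoding `"inline"` (parenthesized markers) or `"positional"`
#'   (per-type offset columns).
#' @export
write_site_table <- function(evidence, path, encoding = c("inline",
                                                          "positional")) {
  encoding <- match.arg(encoding)
  n <- nrow(evidence)
  d <- data.frame(
    peptide = character(n),
    leading_protein = evidence$leading_protein,
    gene_names = evidence$gene_names,
    localization_probability = evidence$localization_probability,
    pep = evidence$pep,
    genotype = evidence$genotype,
    column_id = evidence$column_id,
    stringsAsFactors = FALSE)
  if (encoding == "inline") {
    d$peptide <- vapply(seq_len(n), function(i)
      encode_modified_peptide(evidence$peptide_seq[i], evidence$mods[[i]]),
      "")
  } else {
    d$peptide <- evidence$peptide_seq
    for (cn in c("r_offsets", "rme_offsets", "rme2_offsets")) d[[cn]] <- ""
    key <- c("R" = "r_offsets", "R-me" = "rme_offsets",
             "R-me2" = "rme2_offsets")
    for (i in seq_len(n)) {
      m <- evidence$mods[[i]]
      if (nrow(m) == 0L) next
      for (tp in unique(m$mod_type))
        d[[key[[tp]]]][i] <- paste(m$offset[m$mod_type == tp], collapse = ";")
    }
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein sequence database from FASTA
#'
#' Accession is the first whitespace-delimited header token; UniProt
#' `sp|ACC|NAME` (or `tr|...`) headers yield `ACC`. Sequences are uppercased
#' and `*` terminators stripped.
#'
#' @param path FASTA file path.
#' @return Named character vector mapping accession to sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  accs <- vapply(strsplit(names(aa), "[ \t]"), `[[`, "", 1L)
  piped <- grepl("^(sp|tr)\\|", accs)
  accs[piped] <- vapply(strsplit(accs[piped], "|", fixed = TRUE), `[[`, "",
                        2L)
  if (anyDuplicated(accs))
    stop("duplicate accession(s) in FASTA '", path, "': ",
         paste(unique(accs[duplicated(accs)]), collapse = ", "))
  seqs <- gsub("*", "", toupper(as.character(aa)), fixed = TRUE)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA '", path, "'")
  names(seqs) <- accs
  seqs
}

#' @rdname read_fasta
#' @param db Named character vector (accession -> sequence).
#' @export
write_fasta <- function(db, path) {
  stopifnot(is.character(db), !is.null(names(db)))
  aa <- Biostrings::AAStringSet(db)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read / write a weighted interaction edge list
#'
#' Tab-separated with header columns `node_a`, `node_b`, `score`. Edges are
#' undirected; self-edges and duplicate unordered pairs are rejected; scores
#' must lie in [0,1] (STRING-style combined confidence).
#'
#' @param path File path.
#' @return A data.frame with columns `node_a`, `node_b`, `score`.
#' @export
read_edge_list <- function(path) {
  d <- read_tsv_checked(path, c("node_a", "node_b", "score"))
  d$node_a <- as.character(d$node_a)
  d$node_b <- as.character(d$node_b)
  d$score <- as.numeric(d$score)
  validate_edge_list(d)
  d[c("node_a", "node_b", "score")]
}

validate_edge_list <- function(d) {
  if (any(is.na(d$score) | d$score < 0 | d$score > 1))
    stop("edge score outside [0,1]")
  if (any(d$node_a == d$node_b))
    stop("self-edge not allowed: ", d$node_a[d$node_a == d$node_b][1])
  key <- ifelse(d$node_a < d$node_b, paste(d$node_a, d$node_b),
                paste(d$node_b, d$node_a))
  if (anyDuplicated(key))
    stop("duplicate unordered edge pair: ", key[duplicated(key)][1])
  invisible(d)
}

#' @rdname read_edge_list
#' @param edges Edge-list data.frame.
#' @export
write_edge_list <- function(edges, path) {
  validate_edge_list(edges)
  utils::write.table(edges[c("node_a", "node_b", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write result tables
#'
#' Generic TSV round-trip for result records (enrichment records, classified
#' sites, cluster assignments). `write_results()` emits a stable column
#' order; `read_results()` restores types from the header.
#'
#' @param records A data.frame (list-columns are not serialized).
#' @param path File path.
#' @return `read_results()` returns a data.frame.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  keep <- !vapply(records, is.list, TRUE)
  utils::write.table(records[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read_tsv_checked(path)
}
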