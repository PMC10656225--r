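# Mapping of modified-peptide evidence onto protein coordinates, the
# preceded-by-Arg artifact filter, and confidence classification of
# arginylation sites.

#' Map peptide evidence onto protein sequences
#'
#' Locates each evidence peptide in its leading protein (first exact match)
#' and converts modification offsets to 1-based protein coordinates
#' (counting from the initiator Met). Evidence rows describing the same
#' site set on the same protein across samples are merged, keeping the best
#' (highest) localization probability and lowest PEP and taking the union
#' of genotypes observed. A record whose first modified residue sits at the
#' peptide start directly after an Arg in the protein is flagged: such a
#' site is indistinguishable from a missed tryptic cleavage.
#'
#' Rows with several modified residues are kept as one record per evidence
#' row (all positions listed inside the record) so that record counts match
#' published site tables; `site_granularity = "residue"` explodes them to
#' one record per modified residue instead.
#'
#' @param evidence A `peptide_evidence` data.frame (see
#'   [read_site_table()]).
#' @param db Named character vector from [read_fasta()], or `NULL` to skip
#'   coordinate mapping (positions become `NA`; merging then keys on the
#'   peptide itself).
#' @param site_granularity `"row"` (default) or `"residue"`.
#' @return An `arg_sites` data.frame with columns `protein_id`, `gene`,
#'   `positions`, `residues`, `mod_types` (semicolon-joined within a
#'   record), `peptide_seq`, `localization_probability`, `pep`,
#'   `genotypes_observed`, `preceded_by_arg_at_peptide_start`, `ambiguous`,
#'   `confidence` (`NA` until classified). Evidence whose peptide is not
#'   found in its protein is returned in attribute `"unmapped"` with a
#'   warning, never silently dropped.
#' @export
map_sites <- function(evidence, db = NULL,
                      site_granularity = c("row", "residue")) {
  site_granularity <- match.arg(site_granularity)
  n <- nrow(evidence)
  recs <- vector("list", n)
  unmapped <- integer(0)
  for (i in seq_len(n)) {
    m <- evidence$mods[[i]]
    if (nrow(m) == 0L) next
    pid <- evidence$leading_protein[i]
    pep <- evidence$peptide_seq[i]
    start <- NA_integer_
    ambiguous <- FALSE
    if (!is.null(db)) {
      if (is.na(pid) || !pid %in% names(db)) {
        unmapped <- c(unmapped, i)
        next
      }
      prot <- db[[pid]]
      hits <- gregexpr(pep, prot, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) {
        unmapped <- c(unmapped, i)
        next
      }
      start <- hits[1L]
      ambiguous <- length(hits) > 1L
    }
    pos <- if (is.na(start)) rep(NA_integer_, nrow(m)) else
      start + m$offset - 1L
    preceded <- !is.na(start) && any(m$offset == 1L) && start > 1L &&
      substr(db[[pid]], start - 1L, start - 1L) == "R"
    if (site_granularity == "row") {
      recs[[i]] <- data.frame(
        protein_id = pid,
        gene = evidence$gene_names[i],
        positions = paste(pos, collapse = ";"),
        residues = paste(m$residue, collapse = ";"),
        mod_types = paste(m$mod_type, collapse = ";"),
        peptide_seq = pep,
        localization_probability = evidence$localization_probability[i],
        pep = evidence$pep[i],
        genotypes_observed = evidence$genotype[i],
        preceded_by_arg_at_peptide_start = preceded,
        ambiguous = ambiguous, stringsAsFactors = FALSE)
    } else {
      recs[[i]] <- data.frame(
        protein_id = pid,
        gene = evidence$gene_names[i],
        positions = as.character(pos),
        residues = m$residue,
        mod_types = m$mod_type,
        peptide_seq = pep,
        localization_probability = evidence$localization_probability[i],
        pep = evidence$pep[i],
        genotypes_observed = evidence$genotype[i],
        preceded_by_arg_at_peptide_start = preceded & m$offset == 1L,
        ambiguous = ambiguous, stringsAsFactors = FALSE)
    }
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  out <- if (length(recs)) do.call(rbind, recs) else empty_arg_sites()
  out <- merge_site_records(out)
  out$confidence <- rep(NA_character_, nrow(out))
  class(out) <- c("arg_sites", "data.frame")
  if (length(unmapped)) {
    warning(length(unmapped), " evidence record(s) could not be mapped ",
            "onto their leading protein")
    attr(out, "unmapped") <- as.data.frame(
      evidence[unmapped, setdiff(names(evidence), "mods"), drop = FALSE])
  }
  out
}

empty_arg_sites <- function() {
  data.frame(protein_id = character(0), gene = character(0),
             positions = character(0), residues = character(0),
             mod_types = character(0), peptide_seq = character(0),
             localization_probability = numeric(0), pep = numeric(0),
             genotypes_observed = character(0),
             preceded_by_arg_at_peptide_start = logical(0),
             ambiguous = logical(0), stringsAsFactors = FALSE)
}

merge_site_records <- function(s) {
  if (nrow(s) == 0L) return(s)
  key <- paste(s$protein_id, s$positions, s$mod_types, s$peptide_seq,
               sep = "\r")
  out <- lapply(split(seq_len(nrow(s)), key), function(idx) {
    r <- s[idx[1L], , drop = FALSE]
    r$localization_probability <-
      suppressWarnings(max(s$localization_probability[idx], na.rm = TRUE))
    r$pep <- suppressWarnings(min(s$pep[idx], na.rm = TRUE))
    geno <- unique(unlist(strsplit(s$genotypes_observed[idx], ";")))
    r$genotypes_observed <- paste(sort(geno, decreasing = TRUE),
                                  collapse = ";")  # WT before KO
    r$ambiguous <- any(s$ambiguous[idx])
    r
  })
  out <- do.call(rbind, out)
  out <- out[order(out$protein_id, out$positions), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove preceded-by-Arg artifact sites
#'
#' A modification on the first residue of a peptide directly preceded by
#' Arg in the protein sequence cannot be distinguished from a missed
#' tryptic cleavage; such records get `confidence = "removed"`. Internal
#' modifications (offset > 1) are never removed by this rule.
#'
#' @param sites An `arg_sites` data.frame from [map_sites()].
#' @param keep Character vector of protein accessions exempt from the rule
#'   (a per-site override for curated exceptions).
#' @return The sites with artifact records marked `removed`; the removed
#'   subset is also recorded in attribute `"removed"`.
#' @export
apply_preceding_arg_filter <- function(sites, keep = character(0)) {
  hit <- sites$preceded_by_arg_at_peptide_start %in% TRUE &
    !(sites$protein_id %in% keep)
  sites$confidence[hit] <- "removed"
  attr(sites, "removed") <- sites[hit, , drop = FALSE]
  sites
}

#' Classify site confidence
#'
#' Knockout exclusivity first: a site observed in any KO sample is
#' `nonspecific` (it cannot be ATE1-dependent). WT-exclusive sites with
#' localization probability above `loc_threshold` and PEP at most
#' `pep_threshold` are `high` confidence; other WT-exclusive sites are
#' `medium`. Records already `removed` by the artifact filter are left
#' untouched. Records whose modifications are all non-side-chain (an
#' N-terminal arginylation on a residue other than Glu/Asp) are capped at
#' `medium`: the high tier is reserved for side-chain arginylation.
#'
#' @param sites An `arg_sites` data.frame.
#' @param loc_threshold Localization probability threshold (default 0.75,
#'   strict `>`).
#' @param pep_threshold Posterior error probability threshold (default
#'   0.01, `<=`).
#' @return The sites with `confidence` filled in.
#' @export
classify_confidence <- function(sites, loc_threshold = 0.75,
                                pep_threshold = 0.01) {
  open <- is.na(sites$confidence)
  ko_seen <- grepl("\\bKO\\b", sites$genotypes_observed)
  side_chain <- vapply(strsplit(sites$residues, ";"), function(r)
    any(r %in% c("E", "D")), TRUE)
  high <- open & !ko_seen & side_chain &
    !is.na(sites$localization_probability) & !is.na(sites$pep) &
    sites$localization_probability > loc_threshold &
    sites$pep <= pep_threshold
  sites$confidence[open & ko_seen] <- "nonspecific"
  sites$confidence[high] <- "high"
  sites$confidence[open & !ko_seen & !high] <- "medium"
  sites
}

#' Summarize classified sites per confidence tier
#'
#' @param sites A classified `arg_sites` data.frame.
#' @return A data.frame with one row per tier (`high`, `medium`,
#'   `nonspecific`, `removed`): number of site records and number of
#'   distinct first-listed gene symbols.
#' @export
summarize_sites <- function(sites) {
  tiers <- c("high", "medium", "nonspecific", "removed")
  do.call(rbind, lapply(tiers, function(tier) {
    sel <- sites$confidence %in% tier
    data.frame(confidence = tier, n_sites = sum(sel),
               n_proteins = length(unique(first_gene(sites$gene[sel]))),
               stringsAsFactors = FALSE)
  }))
}
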