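# Synthetic pulldown experiments with truth labels. The generator emulates
# the statistical structure the analysis assumes -- log-normal intensities,
# genotype-dependent eluate enrichment for a spiked subset, per-sample
# detection-limit left-censoring (MNAR), three antibody columns per
# genotype, and site evidence with localization probabilities, PEPs,
# knockout contaminant sites and preceded-by-Arg artifact sites -- so every
# downstream stage is testable without external data.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' Defaults describe a modest pulldown: 500 proteins of which 10% are true
#' arginylation targets, a 3 log2-unit wildtype-eluate enrichment of true
#' targets over knockout, 0.5 log2 units of measurement noise, and
#' left-censoring of the bottom quarter of each sample (missingness rates
#' of 20-30% are typical of label-free single-shot experiments).
#'
#' @param n_proteins Number of simulated protein groups.
#' @param frac_arginylated Fraction that are true arginylation targets.
#' @param log2_effect Mean WT-eluate enrichment of true targets over
#'   KO-eluate, log2 units.
#' @param background_capture Mean log2 eluate-vs-input level for
#'   non-targets, both genotypes (nonspecific antibody capture).
#' @param noise_sd Log2 measurement noise SD.
#' @param censor_quantile Per-sample left-censoring quantile in [0,1).
#' @param n_columns Antibody columns per genotype (>= 2; default 3).
#' @param frac_preceded_by_arg Fraction of true sites placed immediately
#'   after an Arg at a peptide start, to exercise the artifact-removal rule.
#' @param frac_ko_contaminant_sites Number of knockout contaminant sites as
#'   a fraction of true-site count.
#' @param seq_length Simulated protein length (residues).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 500, frac_arginylated = 0.1,
                       log2_effect = 3, background_capture = 0,
                       noise_sd = 0.5, censor_quantile = 0.25,
                       n_columns = 3, frac_preceded_by_arg = 0.1,
                       frac_ko_contaminant_sites = 0.1, seq_length = 200,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              frac_arginylated = frac_arginylated,
              log2_effect = log2_effect,
              background_capture = background_capture,
              noise_sd = noise_sd,
              censor_quantile = censor_quantile,
              n_columns = as.integer(n_columns),
              frac_preceded_by_arg = frac_preceded_by_arg,
              frac_ko_contaminant_sites = frac_ko_contaminant_sites,
              seq_length = as.integer(seq_length),
              seed = as.integer(seed))
  fracs <- c("frac_arginylated", "frac_preceded_by_arg",
             "frac_ko_contaminant_sites")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0,1]")
  if (cfg$censor_quantile < 0 || cfg$censor_quantile >= 1)
    stop("censor_quantile must lie in [0,1)")
  if (cfg$n_proteins < 1L) stop("n_proteins must be positive")
  if (cfg$n_columns < 2L)
    stop("n_columns must be >= 2 (the paired test needs >= 2 pairs)")
  if (cfg$log2_effect < 0) stop("log2_effect must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$seq_length < 50L) stop("seq_length must be >= 50")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a full pulldown experiment
#'
#' Generates an intensity table over `{WT,KO} x input` plus
#' `{WT,KO} x eluate x columns`, peptide evidence, a protein sequence
#' database, and truth labels. Base log2 abundances are Normal(25, 2); true
#' targets get `log2_effect` added in every WT eluate; Gaussian measurement
#' noise is added per sample; each sample's values below its own
#' `censor_quantile` are set missing (missing-not-at-random). True sites
#' appear only in WT evidence with high localization probability
#' (Beta(20,1)) and low PEP (Exponential, mean 0.002, truncated to [0,1]);
#' knockout contaminant sites appear only in KO evidence with flat
#' localization (Beta(2,2)) and larger PEP (Uniform(0, 0.05)). A fraction
#' of true sites is placed at a peptide start directly preceded by Arg.
#' Each artifact consumes its own RNG substream derived from `seed`, so
#' outputs are byte-reproducible.
#'
#' @param config A [sim_config()].
#' @return A list with elements `intensities` ([intensity_table()]),
#'   `evidence` (`peptide_evidence`), `db` (named character vector), and
#'   `truth` (list of `proteins` and `sites` truth data.frames).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_proteins
  ids <- sprintf("SIM%04d", seq_len(n))
  genes <- sprintf("Gene%04d", seq_len(n))
  design <- default_design(config$n_columns)

  # substream 1: protein-level truth and intensities
  set.seed(config$seed)
  is_arg <- rep(FALSE, n)
  n_arg <- round(config$frac_arginylated * n)
  if (n_arg > 0) is_arg[sample.int(n, n_arg)] <- TRUE
  base <- stats::rnorm(n, 25, 2)
  x <- matrix(NA_real_, n, nrow(design),
              dimnames = list(ids, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- base
    if (design$role[j] == "eluate") {
      mu <- mu + config$background_capture
      if (design$genotype[j] == "WT")
        mu <- mu + ifelse(is_arg, config$log2_effect, 0)
    }
    x[, j] <- mu + stats::rnorm(n, 0, config$noise_sd)
  }
  x_precensor <- x
  if (config$censor_quantile > 0) {
    for (j in seq_len(ncol(x))) {
      thr <- stats::quantile(x[, j], config$censor_quantile, names = FALSE)
      x[x[, j] < thr, j] <- NA_real_
    }
  }
  razor <- cbind(WT = 1L + stats::rpois(n, 7), KO = 1L + stats::rpois(n, 7))
  tab <- intensity_table(2^x, ids, genes, razor, design)

  # substream 2: sequences
  set.seed(derive_seed(config$seed, 1L))
  L <- config$seq_length
  seq_mat <- matrix(sample(AA20, n * L, replace = TRUE), n, L)

  # substream 3: sites and evidence
  set.seed(derive_seed(config$seed, 2L))
  ev_rows <- list()
  site_rows <- list()
  place_site <- function(i, artifact) {
    pos <- sample(30:(L - 30), 1L)
    seq_mat[i, pos] <<- sample(c("E", "D"), 1L)
    if (artifact) {
      seq_mat[i, pos - 1L] <<- "R"
      start <- pos
      end <- pos + sample(8:14, 1L)
    } else {
      # internal offset >= 4 so the artifact rule can never fire
      start <- pos - sample(3:8, 1L)
      end <- pos + sample(3:8, 1L)
    }
    list(pos = pos, start = start, end = end,
         offset = pos - start + 1L)
  }
  for (i in which(is_arg)) {
    artifact <- stats::runif(1) < config$frac_preceded_by_arg
    s <- place_site(i, artifact)
    loc <- stats::rbeta(1, 20, 1)
    pep <- min(stats::rexp(1, rate = 500), 1)
    n_obs <- 1L + stats::rbinom(1L, config$n_columns - 1L, 0.5)
    obs_cols <- sample(paste0("c", seq_len(config$n_columns)), n_obs)
    pepseq <- paste(seq_mat[i, s$start:s$end], collapse = "")
    for (cc in obs_cols) {
      ev_rows[[length(ev_rows) + 1L]] <- list(
        peptide_seq = pepseq, leading_protein = ids[i],
        gene_names = genes[i], localization_probability = loc, pep = pep,
        genotype = "WT", column_id = cc, offset = s$offset,
        residue = seq_mat[i, s$pos], mod_type = "R")
    }
    site_rows[[length(site_rows) + 1L]] <- list(
      protein_id = ids[i], position = s$pos, residue = seq_mat[i, s$pos],
      mod_type = "R", is_true_site = TRUE,
      is_preceded_by_arg_artifact = artifact, is_ko_contaminant = FALSE)
  }
  n_true <- length(site_rows)
  n_ko <- round(config$frac_ko_contaminant_sites * n_true)
  if (n_ko > 0) {
    host <- sample(which(!is_arg), n_ko)
    for (i in host) {
      s <- place_site(i, artifact = FALSE)
      pepseq <- paste(seq_mat[i, s$start:s$end], collapse = "")
      ev_rows[[length(ev_rows) + 1L]] <- list(
        peptide_seq = pepseq, leading_protein = ids[i],
        gene_names = genes[i],
        localization_probability = stats::rbeta(1, 2, 2),
        pep = stats::runif(1, 0, 0.05),
        genotype = "KO", column_id = sample(paste0("c",
          seq_len(config$n_columns)), 1L), offset = s$offset,
        residue = seq_mat[i, s$pos], mod_type = "R")
      site_rows[[length(site_rows) + 1L]] <- list(
        protein_id = ids[i], position = s$pos, residue = seq_mat[i, s$pos],
        mod_type = "R", is_true_site = FALSE,
        is_preceded_by_arg_artifact = FALSE, is_ko_contaminant = TRUE)
    }
  }
  db <- apply(seq_mat, 1L, paste, collapse = "")
  names(db) <- ids

  evidence <- if (length(ev_rows)) {
    d <- do.call(rbind, lapply(ev_rows, function(r)
      data.frame(r[setdiff(names(r), c("offset", "residue", "mod_type"))],
                 stringsAsFactors = FALSE)))
    d$mods <- lapply(ev_rows, function(r)
      data.frame(offset = r$offset, residue = r$residue,
                 mod_type = r$mod_type, stringsAsFactors = FALSE))
    rownames(d) <- NULL
    class(d) <- c("peptide_evidence", "data.frame")
    d
  } else {
    empty_evidence()
  }
  truth_sites <- if (length(site_rows))
    do.call(rbind, lapply(site_rows, as.data.frame)) else
    data.frame(protein_id = character(0), position = integer(0),
               residue = character(0), mod_type = character(0),
               is_true_site = logical(0),
               is_preceded_by_arg_artifact = logical(0),
               is_ko_contaminant = logical(0))
  list(intensities = tab,
       evidence = evidence,
       db = db,
       truth = list(
         proteins = data.frame(protein_id = ids, gene = genes,
                               is_arginylated = is_arg,
                               stringsAsFactors = FALSE),
         sites = truth_sites,
         precensor_log2 = x_precensor))
}

empty_evidence <- function() {
  d <- data.frame(peptide_seq = character(0),
                  leading_protein = character(0),
                  gene_names = character(0),
                  localization_probability = numeric(0), pep = numeric(0),
                  genotype = character(0), column_id = character(0),
                  stringsAsFactors = FALSE)
  d$mods <- list()
  class(d) <- c("peptide_evidence", "data.frame")
  d
}

# Deterministic substream seeds, kept well below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 100000000L) * 13L + 7L * as.integer(k)
}

#' Simulate a weighted interaction edge list with planted communities
#'
#' Nodes are split into `n_communities` blocks; intra-block edges appear
#' with probability `p_intra` and scores in [0.6, 1], inter-block edges
#' with probability `p_inter` and scores in [0.15, 0.7], emulating a
#' STRING-style confidence-scored network with modular structure.
#'
#' @param nodes Character vector of node identifiers.
#' @param n_communities Number of planted blocks.
#' @param p_intra,p_inter Edge probabilities within/between blocks.
#' @param seed Integer seed.
#' @return A list with `edges` (edge-list data.frame) and `membership`
#'   (named integer vector of planted block ids).
#' @export
simulate_interactions <- function(nodes, n_communities = 4, p_intra = 0.7,
                                  p_inter = 0.02, seed = 1L) {
  stopifnot(length(nodes) >= 2L, !anyDuplicated(nodes))
  set.seed(derive_seed(seed, 3L))
  member <- sort(rep_len(seq_len(n_communities), length(nodes)))
  names(member) <- nodes
  pairs <- utils::combn(nodes, 2L)
  same <- member[pairs[1L, ]] == member[pairs[2L, ]]
  p <- ifelse(same, p_intra, p_inter)
  keep <- stats::runif(length(p)) < p
  score <- ifelse(same, stats::runif(length(p), 0.6, 1),
                  stats::runif(length(p), 0.15, 0.7))
  edges <- data.frame(node_a = pairs[1L, keep], node_b = pairs[2L, keep],
                      score = round(score[keep], 3L),
                      stringsAsFactors = FALSE)
  list(edges = edges, membership = member)
}

#' In-text fixture tables
#'
#' `make_table1_fixture()` returns the transcribed table of the 108
#' proteins significantly enriched in wildtype samples (gene symbols, fold
#' changes, p-values); `make_table2_fixture()` returns the transcribed
#' table of the 17 high-confidence arginylation sites as a
#' `peptide_evidence` table with inline-marker peptides, localization
#' probabilities and PEPs. Both are read from the TSVs shipped under
#' `inst/extdata` through the package's own readers.
#'
#' @return A data.frame (`make_table1_fixture`) or `peptide_evidence`
#'   (`make_table2_fixture`).
#' @export
make_table1_fixture <- function() {
  path <- system.file("extdata", "table1_enriched.tsv",
                      package = "argenrich", mustWork = TRUE)
  d <- read_results(path)
  stopifnot(all(c("protein_name", "gene_names", "fold_change",
                  "p_value") %in% names(d)))
  d
}

#' @rdname make_table1_fixture
#' @export
make_table2_fixture <- function() {
  path <- system.file("extdata", "table2_sites.tsv",
                      package = "argenrich", mustWork = TRUE)
  read_site_table(path)
}
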