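# Enrichment statistics for knockout-controlled immunoaffinity pulldowns:
# QC filter, log2 transform + per-sample mean centering, MNAR downshift
# imputation, input-normalized fold change, paired t-test across antibody
# columns, and the three-criterion enrichment call.

#' Quality-control filter on razor+unique peptide counts
#'
#' Retains proteins identified by more than one razor+unique peptide in
#' wildtype OR knockout samples (`>1`, i.e. at least `min_razor_unique`).
#'
#' @param x An [intensity_table()].
#' @param min_razor_unique Minimum count (default 2, the `>1` rule).
#' @return Filtered `intensity_table`; dropped accessions are recorded in
#'   attribute `"dropped"`.
#' @export
qc_filter <- function(x, min_razor_unique = 2) {
  stopifnot(inherits(x, "intensity_table"))
  keep <- x$razor_unique[, "WT"] >= min_razor_unique |
    x$razor_unique[, "KO"] >= min_razor_unique
  keep[is.na(keep)] <- FALSE
  out <- subset_proteins(x, keep)
  attr(out, "dropped") <- x$protein_ids[!keep]
  out
}

#' Log2 transform and per-sample normalization
#'
#' Intensities are log2-transformed and each sample column is centered by
#' subtracting its own mean over present (measured) values — scaling each
#' value against the average of all proteins in the sample, which on the
#' log scale is division by the sample's geometric mean. Missing cells stay
#' missing.
#'
#' @param x An [intensity_table()].
#' @return A `normalized_table`: the `intensity_table` structure with log2
#'   centered `values` and a logical `imputed` matrix (all `FALSE` here).
#' @export
log_transform_normalize <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  if (any(x$values <= 0, na.rm = TRUE))
    stop("nonpositive present intensity: zeros must be missing before log transform")
  lv <- log2(x$values)
  mu <- colMeans(lv, na.rm = TRUE)
  x$values <- sweep(lv, 2L, mu, `-`)
  x$imputed <- matrix(FALSE, nrow(lv), ncol(lv), dimnames = dimnames(lv))
  class(x) <- c("normalized_table", "intensity_table")
  x
}

#' Downshift imputation of missing values
#'
#' Missing values are assumed missing-not-at-random (below the detection
#' limit) and are imputed per sample as `Uniform(0, jitter_max)` minus
#' `shift_sd_mult` times that sample's standard deviation of present
#' normalized values — i.e. a draw from a narrow band well below the
#' observed distribution.
#'
#' @param x A `normalized_table` from [log_transform_normalize()].
#' @param shift_sd_mult Downshift in sample SD units (default 2.5).
#' @param jitter_max Upper bound of the uniform jitter in log2 units
#'   (default 0.3).
#' @param seed Integer seed; imputation is reproducible given the seed.
#' @return The table with missing cells filled in and flagged in `imputed`.
#' @export
impute_missing <- function(x, shift_sd_mult = 2.5, jitter_max = 0.3, seed) {
  stopifnot(inherits(x, "normalized_table"))
  if (missing(seed)) stop("impute_missing() requires an explicit seed")
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(x$values))) {
    v <- x$values[, j]
    present <- !is.na(v) & !x$imputed[, j]
    if (sum(present) < 2L)
      stop("sample '", colnames(x$values)[j],
           "' has fewer than 2 present values; SD undefined")
    idx <- which(is.na(v))
    if (length(idx) == 0L) next
    sigma <- stats::sd(v[present])
    x$values[idx, j] <- stats::runif(length(idx), 0, jitter_max) -
      shift_sd_mult * sigma
    x$imputed[idx, j] <- TRUE
  }
  x
}

#' Input-normalized fold change per antibody column
#'
#' For antibody column c, on the log2 scale,
#' `delta_c = (WT_eluate_c - WT_input) - (KO_eluate_c - KO_input)`:
#' the wildtype-over-knockout eluate ratio after normalizing each eluate to
#' its genotype's input lysate. The average fold change is the arithmetic
#' mean of the per-column linear fold changes `2^delta_c`
#' (`fc_average = "linear"`), or `2^mean(delta_c)` (`"geometric"`).
#'
#' @param x An imputed `normalized_table`.
#' @param fc_average `"linear"` (default) or `"geometric"`.
#' @return A list with `delta` (proteins x columns matrix of per-column
#'   log2 fold changes) and `avg_fold_change` (linear scale).
#' @export
fold_change_vs_input <- function(x, fc_average = c("linear", "geometric")) {
  stopifnot(inherits(x, "normalized_table"))
  fc_average <- match.arg(fc_average)
  if (any(is.na(x$values)))
    stop("fold_change_vs_input() requires imputed values (no NAs)")
  design <- x$design
  cols <- eluate_columns(design)
  wt_in <- x$values[, design_samples(design, "WT", "input")]
  ko_in <- x$values[, design_samples(design, "KO", "input")]
  delta <- sapply(cols, function(cc) {
    (x$values[, design_samples(design, "WT", "eluate", cc)] - wt_in) -
      (x$values[, design_samples(design, "KO", "eluate", cc)] - ko_in)
  })
  delta <- matrix(delta, nrow = nrow(x$values),
                  dimnames = list(x$protein_ids, cols))
  avg <- if (fc_average == "linear") rowMeans(2^delta) else
    2^rowMeans(delta)
  list(delta = delta, avg_fold_change = avg)
}

#' Paired t-test across antibody columns
#'
#' Two-sided paired Student t-test of per-column wildtype versus knockout
#' values: `d_c = wt_c - ko_c`, `t = mean(d) / (sd(d)/sqrt(n))` with the
#' n-1 sample SD and n-1 degrees of freedom. Degenerate case `sd(d) = 0`:
#' p = 1 if `mean(d) = 0`, else p = 0.
#'
#' @param wt_vals,ko_vals Numeric vectors of equal length (>= 2), one value
#'   per antibody column.
#' @return A list with `t` and `p`.
#' @export
paired_t_test <- function(wt_vals, ko_vals) {
  stopifnot(length(wt_vals) == length(ko_vals), length(wt_vals) >= 2L,
            !any(is.na(wt_vals)), !any(is.na(ko_vals)))
  d <- wt_vals - ko_vals
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0))
  }
  tt <- m / (s / sqrt(n))
  list(t = tt, p = 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE))
}

#' Three-criterion enrichment call
#'
#' A protein is called enriched when (1) its average wildtype-over-knockout
#' fold change after input normalization exceeds `fc_threshold`, (2) the
#' paired t-test p-value is at most `alpha`, and (3) it was measured (not
#' imputed) in at least `min_wt_detected` wildtype eluate samples — and it
#' passed the razor+unique QC filter. A Benjamini-Hochberg adjusted p-value
#' is reported for information only and never enters the call.
#'
#' @param protein_id,gene Character vectors.
#' @param delta Proteins x columns matrix of per-column log2 fold changes.
#' @param avg_fold_change,p_value Numeric vectors.
#' @param n_wt_detected Integer vector: non-imputed WT eluate measurements.
#' @param passes_qc Logical vector.
#' @param fc_threshold,alpha,min_wt_detected Call thresholds
#'   (defaults 1.5, 0.05, 2).
#' @return An enrichment-record data.frame sorted by descending
#'   `avg_fold_change`, ties broken by ascending p then accession.
#' @export
call_enrichment <- function(protein_id, gene, delta, avg_fold_change,
                            p_value, n_wt_detected, passes_qc,
                            fc_threshold = 1.5, alpha = 0.05,
                            min_wt_detected = 2) {
  rec <- data.frame(protein_id = protein_id, gene = gene,
                    stringsAsFactors = FALSE)
  colnames(delta) <- paste0("log2fc_", colnames(delta))
  rec <- cbind(rec, as.data.frame(delta, check.names = FALSE))
  rec$avg_fold_change <- avg_fold_change
  rec$p_value <- p_value
  rec$p_adj <- stats::p.adjust(p_value, method = "BH")
  rec$n_wt_detected <- as.integer(n_wt_detected)
  rec$passes_qc <- as.logical(passes_qc)
  rec$enriched <- rec$passes_qc &
    rec$avg_fold_change > fc_threshold &
    rec$p_value <= alpha &
    rec$n_wt_detected >= min_wt_detected
  ord <- order(-rec$avg_fold_change, rec$p_value, rec$protein_id)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Run the full enrichment analysis on an intensity table
#'
#' QC filter, log2 transform + normalization, downshift imputation,
#' input-normalized fold changes, paired t-tests, and the enrichment call.
#'
#' The paired t-test compares, by default, the normalized log2 eluate
#' values of the two genotypes paired by antibody column
#' (`t_test_on = "eluate"`). Because each genotype contributes a single
#' shared input lysate, normalizing the t-test values to input would add
#' one constant to every pair, inflating `|mean(d)|` without entering
#' `sd(d)` and making the test strongly anticonservative; input
#' normalization is therefore applied to the fold-change criterion only.
#' The alternative is available as `t_test_on = "input_normalized"`.
#'
#' @param x An [intensity_table()].
#' @param min_razor_unique,fc_threshold,alpha,min_wt_detected Thresholds
#'   (defaults 2, 1.5, 0.05, 2).
#' @param shift_sd_mult,jitter_max Imputation parameters (2.5, 0.3).
#' @param fc_average Fold-change averaging, `"linear"` or `"geometric"`.
#' @param t_test_on `"eluate"` (default) or `"input_normalized"`.
#' @param seed Integer seed for the imputation draws.
#' @return An enrichment-record data.frame (see [call_enrichment()]), with
#'   the QC-dropped accessions in attribute `"qc_dropped"`.
#' @export
enrich_proteins <- function(x, min_razor_unique = 2, fc_threshold = 1.5,
                            alpha = 0.05, min_wt_detected = 2,
                            shift_sd_mult = 2.5, jitter_max = 0.3,
                            fc_average = "linear",
                            t_test_on = c("eluate", "input_normalized"),
                            seed = 1L) {
  t_test_on <- match.arg(t_test_on)
  xq <- qc_filter(x, min_razor_unique)
  if (nrow(xq$values) == 0L)
    stop("no proteins pass the razor+unique QC filter")
  nt <- log_transform_normalize(xq)
  nt <- impute_missing(nt, shift_sd_mult, jitter_max, seed = seed)
  fc <- fold_change_vs_input(nt, fc_average)
  design <- nt$design
  cols <- eluate_columns(design)
  wt_el <- vapply(cols, function(cc)
    design_samples(design, "WT", "eluate", cc), "")
  ko_el <- vapply(cols, function(cc)
    design_samples(design, "KO", "eluate", cc), "")
  wt_mat <- nt$values[, wt_el, drop = FALSE]
  ko_mat <- nt$values[, ko_el, drop = FALSE]
  if (t_test_on == "input_normalized") {
    wt_mat <- wt_mat - nt$values[, design_samples(design, "WT", "input")]
    ko_mat <- ko_mat - nt$values[, design_samples(design, "KO", "input")]
  }
  tests <- vapply(seq_len(nrow(wt_mat)), function(i) {
    r <- paired_t_test(wt_mat[i, ], ko_mat[i, ])
    c(r$t, r$p)
  }, numeric(2))
  n_wt_det <- rowSums(!nt$imputed[, wt_el, drop = FALSE])
  rec <- call_enrichment(nt$protein_ids, nt$gene_names, fc$delta,
                         fc$avg_fold_change, tests[2, ], n_wt_det,
                         passes_qc = rep(TRUE, length(nt$protein_ids)),
                         fc_threshold = fc_threshold, alpha = alpha,
                         min_wt_detected = min_wt_detected)
  attr(rec, "qc_dropped") <- attr(xq, "dropped")
  rec
}
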