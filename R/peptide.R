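#' Modification types recognized in modified-peptide strings
#'
#' Side-chain arginylation (`R`), methyl-arginylation (`R-me`) and
#' dimethyl-arginylation (`R-me2`), the three variable arginylation
#' modifications considered by the upstream database search.
#'
#' @export
ARG_MOD_TYPES <- c("R", "R-me", "R-me2")

#' Parse a peptide string with inline modification markers
#'
#' Parses strings such as `"DTSLYRPALE(R)ELR"` or
#' `"NEGE(R-me2)GD(R-me2)SE(R-me)EVK"`. A parenthesized marker attaches to
#' the residue immediately preceding it, so `"DTSLYRPALE(R)ELR"` carries one
#' arginylation at peptide offset 10 (the `E`).
#'
#' @param x Single character string, an uppercase peptide with optional
#'   `(R)`, `(R-me)`, `(R-me2)` markers.
#' @return A list with `seq` (the plain peptide string) and `mods`, a
#'   data.frame with columns `offset` (1-based position in `seq`),
#'   `residue`, and `mod_type`. Unmodified peptides yield a zero-row `mods`.
#' @examples
#' parse_modified_peptide("DTSLYRPALE(R)ELR")
#' @export
parse_modified_peptide <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  n <- nchar(x)
  seq_chars <- character(0)
  offs <- integer(0); res <- character(0); typ <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "(") {
      close_rel <- regexpr(")", substr(x, i, n), fixed = TRUE)
      if (close_rel < 0L)
        stop("unterminated modification marker in peptide '", x, "'")
      marker <- substr(x, i + 1L, i + close_rel - 2L)
      if (!marker %in% ARG_MOD_TYPES)
        stop("unknown modification marker '(", marker, ")' in peptide '",
             x, "'")
      if (length(seq_chars) == 0L)
        stop("modification marker not preceded by a residue in peptide '",
             x, "'")
      offs <- c(offs, length(seq_chars))
      res <- c(res, seq_chars[length(seq_chars)])
      typ <- c(typ, marker)
      i <- i + close_rel
    } else {
      if (!grepl("^[A-Za-z]$", ch))
        stop("invalid character '", ch, "' in peptide '", x, "'")
      seq_chars <- c(seq_chars, toupper(ch))
      i <- i + 1L
    }
  }
  list(seq = paste(seq_chars, collapse = ""),
       mods = data.frame(offset = offs, residue = res, mod_type = typ,
                         stringsAsFactors = FALSE))
}

#' Encode a peptide and its modifications as an inline-marker string
#'
#' Inverse of [parse_modified_peptide()].
#'
#' @param seq Plain peptide string.
#' @param mods Data.frame with columns `offset` and `mod_type`.
#' @return Single character string with parenthesized markers.
#' @export
encode_modified_peptide <- function(seq, mods) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.null(mods) || nrow(mods) == 0L) return(seq)
  stopifnot(all(mods$offset >= 1L), all(mods$offset <= nchar(seq)),
            all(mods$mod_type %in% ARG_MOD_TYPES))
  ord <- order(mods$offset, decreasing = TRUE)
  out <- seq
  for (k in ord) {
    o <- mods$offset[k]
    out <- paste0(substr(out, 1L, o), "(", mods$mod_type[k], ")",
                  substr(out, o + 1L, nchar(out)))
  }
  out
}
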