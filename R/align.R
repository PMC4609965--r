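#' Global alignment and residue-index mapping of two chains
#'
#' Needleman--Wunsch global alignment with affine gap penalties (BLOSUM62
#' substitution scores), used to place homologous chains on a common
#' residue axis, e.g. the C-terminal residues of alpha- and beta-synuclein
#' after alignment. Returns the partial 1-based index map between the two
#' sequences: residues aligned to a gap are unmapped.
#'
#' @param seq_a,seq_b amino-acid strings (non-empty).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return tibble with columns `pos_a`, `res_a`, `pos_b`, `res_b` (matched
#'   columns only); attributes `aligned_a`, `aligned_b` (gapped strings)
#'   and `score`.
#' @export
#' @examples
#' align_sequences("ACDE", "ACE")
align_sequences <- function(seq_a, seq_b, gap_opening = 10,
                            gap_extension = 0.5) {
  stopifnot(nchar(seq_a) >= 1L, nchar(seq_b) >= 1L)
  mat <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  pos_a <- cumsum(a != "-")
  pos_b <- cumsum(b != "-")
  keep <- a != "-" & b != "-"
  out <- tibble::tibble(pos_a = as.integer(pos_a[keep]), res_a = a[keep],
                        pos_b = as.integer(pos_b[keep]), res_b = b[keep])
  attr(out, "aligned_a") <- paste(a, collapse = "")
  attr(out, "aligned_b") <- paste(b, collapse = "")
  attr(out, "score") <- Biostrings::score(pa)
  out
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Gap runs of an aligned (gapped) string
#'
#' @param aligned gapped string as stored in the attributes of
#'   [align_sequences()].
#' @return tibble with `start` (column index), `length` of each gap run.
#' @export
gap_runs <- function(aligned) {
  ch <- strsplit(aligned, "")[[1L]]
  r <- rle(ch == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], length = r$lengths[r$values])
}

#' Bundled synuclein sequences
#'
#' Canonical human alpha-synuclein (140 aa) and beta-synuclein (134 aa),
#' shipped as plain-text FASTA.
#'
#' @param which `"alpha"` or `"beta"`.
#' @return amino-acid string.
#' @export
synuclein_sequence <- function(which = c("alpha", "beta")) {
  which <- match.arg(which)
  fa <- Biostrings::readAAStringSet(
    system.file("extdata", "synucleins.fasta", package = "prekd",
                mustWork = TRUE))
  nm <- if (which == "alpha") "alpha_synuclein" else "beta_synuclein"
  idx <- grep(nm, names(fa))
  as.character(fa[[idx[1L]]])
}
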