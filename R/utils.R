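# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

# integer codes 1..4 for A/C/G/T, NA for anything else (N etc.)
encode_bases <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], DNA_BASES)
}

#' Reverse complement of a DNA string
#'
#' @param sequence single character string over the IUPAC alphabet
#'   (only A/C/G/T/N are mapped; case is preserved).
#' @return the reverse-complemented string.
#' @export
revcomp <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  flipped <- chartr("ACGTacgtNn", "TGCAtgcaNn", sequence)
  paste(rev(strsplit(flipped, "", fixed = TRUE)[[1]]), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
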