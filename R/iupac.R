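## IUPAC nucleotide alphabet as 4-bit masks (A=1, C=2, G=4, T=8).
## N in a *genome* is encoded as 0 so it never satisfies any motif position,
## including N-in-motif; N in a *motif* is the full mask 15.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.check_iupac <- function(motif) {
  if (length(motif) != 1L || is.na(motif)) {
    stop("motif must be a single non-NA character string")
  }
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), names(.IUPAC_BITS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  }
  chars
}

#' Reverse complement of an IUPAC motif
#'
#' Applies the standard IUPAC complement base-wise and reverses the string.
#' The operation is an involution: applying it twice returns the input.
#'
#' @param motif Character scalar over the IUPAC nucleotide alphabet.
#' @return The reverse-complemented motif (uppercase).
#' @examples
#' reverse_complement_iupac("GANTC")  # palindromic: returns "GANTC"
#' reverse_complement_iupac("ACGGAG") # "CTCCGT"
#' @export
reverse_complement_iupac <- function(motif) {
  chars <- .check_iupac(motif)
  if (length(chars) == 0L) return("")
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Is a motif palindromic?
#'
#' A motif is palindromic when it equals its own IUPAC reverse complement
#' character-for-character (e.g. GANTC, CTCGAG).
#'
#' @param motif Character scalar over the IUPAC alphabet.
#' @return Logical scalar.
#' @export
is_palindromic <- function(motif) {
  identical(toupper(motif), reverse_complement_iupac(motif))
}

## bitmask vector for a motif string
.motif_masks <- function(motif) {
  chars <- .check_iupac(motif)
  unname(.IUPAC_BITS[chars])
}

## encode a genome sequence: A/C/G/T -> bit, anything else (incl. N) -> 0
.encode_sequence <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  code <- .IUPAC_BITS[chars]
  code[is.na(code) | !(chars %in% c("A", "C", "G", "T"))] <- 0L
  as.integer(code)
}

## all concrete A/C/G/T words matching an IUPAC motif (used for planting;
## tests carry their own expansion oracle)
.expand_iupac <- function(motif) {
  chars <- .check_iupac(motif)
  bases <- c("A", "C", "G", "T")
  sets <- lapply(chars, function(ch) {
    bases[bitwAnd(.IUPAC_BITS[[ch]], c(1L, 2L, 4L, 8L)) > 0L]
  })
  if (length(sets) == 0L) return(character(0))
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}
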