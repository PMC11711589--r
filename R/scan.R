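## starts (1-based) of all windows of `seq_code` matching bitmask vector
## `masks`; a window matches when every position shares at least one base
## with the motif set. N in the genome is encoded 0, so it never matches.
.scan_masks <- function(seq_code, masks) {
  n <- length(seq_code)
  L <- length(masks)
  if (L == 0L || L > n) return(integer(0))
  ok <- bitwAnd(seq_code[seq_len(n - L + 1L)], masks[1L]) > 0L
  if (L > 1L) {
    for (j in 2:L) {
      idx <- which(ok)
      if (length(idx) == 0L) return(integer(0))
      ok[idx] <- bitwAnd(seq_code[idx + j - 1L], masks[j]) > 0L
    }
  }
  which(ok)
}

#' Scan one replicon for occurrences of an IUPAC motif on both strands
#'
#' Exhaustive (naive-match) scanning: every window of the plus strand
#' matching the IUPAC pattern yields a `+` occurrence; every window whose
#' reverse complement matches yields a `-` occurrence, reported by its
#' leftmost plus-strand coordinate. Palindromic motifs therefore yield
#' paired +/- occurrences at the same start; overlapping occurrences are all
#' retained. Windows containing N never match.
#'
#' The modified genome position is `start + modified_index - 1` on `+` and
#' `start + length(motif) - modified_index` on `-`.
#'
#' @param genome One-row genome data frame (or a list with `strain_id`,
#'   `replicon_id`, `sequence`, `replicon_class`).
#' @param motif A [motif_spec()].
#' @return Data frame sorted by (start, strand): `motif_label`, `strain_id`,
#'   `replicon_id`, `replicon_class`, `start`, `strand`,
#'   `modified_genome_position`, `methylated` (initialized FALSE).
#' @export
scan_motif <- function(genome, motif) {
  stopifnot(inherits(motif, "motif_spec"))
  seq_code <- .encode_sequence(genome$sequence[[1L]])
  masks <- .motif_masks(motif$iupac)
  L <- length(masks)
  fwd <- .scan_masks(seq_code, masks)
  rev_masks <- .motif_masks(reverse_complement_iupac(motif$iupac))
  rev <- .scan_masks(seq_code, rev_masks)
  starts <- c(fwd, rev)
  strands <- c(rep("+", length(fwd)), rep("-", length(rev)))
  modpos <- c(fwd + motif$modified_index - 1L,
              rev + L - motif$modified_index)
  ord <- order(starts, strands)
  data.frame(
    motif_label = rep(motif$label, length(starts)),
    strain_id = rep(genome$strain_id[[1L]], length(starts)),
    replicon_id = rep(genome$replicon_id[[1L]], length(starts)),
    replicon_class = rep(genome$replicon_class[[1L]], length(starts)),
    start = starts[ord],
    strand = strands[ord],
    modified_genome_position = modpos[ord],
    methylated = rep(FALSE, length(starts)),
    stringsAsFactors = FALSE
  )
}

#' Scan a whole genome (all replicons) for a set of motifs
#'
#' @param genome Genome data frame (one row per replicon).
#' @param motifs List of [motif_spec()] objects.
#' @return Row-bound occurrence data frame (see [scan_motif()]).
#' @export
scan_genome <- function(genome, motifs) {
  out <- vector("list", nrow(genome) * length(motifs))
  k <- 0L
  for (i in seq_len(nrow(genome))) {
    for (m in motifs) {
      k <- k + 1L
      out[[k]] <- scan_motif(genome[i, , drop = FALSE], m)
    }
  }
  do.call(rbind, out)
}

#' Flag motif occurrences as methylated from base-modification calls
#'
#' An occurrence is methylated when a call exists on the same replicon and
#' strand at exactly its modified genome position, with a compatible
#' modification type. A generic "modified_base" call is compatible with any
#' motif type when `allow_generic = TRUE` (default); with strict typing the
#' call type must equal the motif's. One call may flag several overlapping
#' occurrences. Unmatched calls (no occurrence at their position) are
#' tallied in the `unmatched_calls` attribute.
#'
#' @param occurrences Occurrence data frame from [scan_motif()]/[scan_genome()].
#' @param calls Methylation-call data frame from [read_methylation_gff3()].
#' @param motifs List of [motif_spec()] giving each motif's modification
#'   type (looked up by label).
#' @param allow_generic Accept "modified_base" calls for any motif type.
#' @return The occurrence data frame with `methylated` filled; attribute
#'   `unmatched_calls` holds the number of calls matching no occurrence.
#' @export
assign_methylation <- function(occurrences, calls, motifs,
                               allow_generic = TRUE) {
  if (nrow(occurrences) == 0L) {
    attr(occurrences, "unmatched_calls") <- nrow(calls)
    return(occurrences)
  }
  types <- vapply(motifs, `[[`, "", "modification_type")
  names(types) <- vapply(motifs, `[[`, "", "label")
  occ_type <- types[occurrences$motif_label]
  if (anyNA(occ_type)) {
    stop("occurrences reference motif label(s) absent from `motifs`: ",
         paste(unique(occurrences$motif_label[is.na(occ_type)]),
               collapse = ", "))
  }
  call_key <- paste(calls$replicon_id, calls$strand, calls$position,
                    calls$modification_type, sep = "\r")
  occ_key <- paste(occurrences$replicon_id, occurrences$strand,
                   occurrences$modified_genome_position, occ_type,
                   sep = "\r")
  methylated <- occ_key %in% call_key
  matched_call <- call_key %in% occ_key
  if (allow_generic) {
    generic <- calls$modification_type == "modified_base"
    if (any(generic)) {
      gen_key <- paste(calls$replicon_id, calls$strand,
                       calls$position, sep = "\r")[generic]
      occ_pos_key <- paste(occurrences$replicon_id, occurrences$strand,
                           occurrences$modified_genome_position, sep = "\r")
      methylated <- methylated | (occ_pos_key %in% gen_key)
      matched_call[generic] <- gen_key %in% occ_pos_key
    }
  }
  occurrences$methylated <- methylated
  attr(occurrences, "unmatched_calls") <- sum(!matched_call)
  occurrences
}
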