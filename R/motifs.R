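.MOD_TYPES <- c("6mA", "4mC", "5mC")

## which base must sit at the modified position for each modification type
.MOD_BASE_BIT <- c("6mA" = 1L, "4mC" = 2L, "5mC" = 2L)

#' Construct a motif specification
#'
#' A motif specification couples an IUPAC recognition sequence with its
#' modification type (6mA, 4mC or 5mC) and the 1-based position of the
#' methylated base within the motif. When `modified_index` is omitted, the
#' first position whose IUPAC set is compatible with the modification type
#' (contains A for 6mA, C for 4mC/5mC) is used and a warning is emitted,
#' since published motif tables often omit the offset.
#'
#' @param iupac Character scalar over the IUPAC alphabet.
#' @param modification_type One of "6mA", "4mC", "5mC".
#' @param modified_index Integer, 1-based position of the methylated base
#'   within the motif; defaults to the first compatible position.
#' @param label Motif label; defaults to the IUPAC string.
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(iupac, modification_type,
                       modified_index = NULL, label = iupac) {
  chars <- .check_iupac(iupac)
  if (length(chars) == 0L) stop("motif must be non-empty")
  modification_type <- match.arg(modification_type, .MOD_TYPES)
  iupac <- paste(chars, collapse = "")
  bit <- .MOD_BASE_BIT[[modification_type]]
  compatible <- which(bitwAnd(.IUPAC_BITS[chars], bit) > 0L)
  if (is.null(modified_index) || is.na(modified_index)) {
    if (length(compatible) == 0L) {
      stop("motif ", iupac, " has no position compatible with ",
           modification_type)
    }
    modified_index <- compatible[1L]
    warning("modified_index missing for ", iupac,
            "; defaulting to first compatible position ", modified_index)
  }
  modified_index <- as.integer(modified_index)
  if (modified_index < 1L || modified_index > length(chars)) {
    stop("modified_index out of range for motif ", iupac)
  }
  if (!(modified_index %in% compatible)) {
    stop("base set at position ", modified_index, " of ", iupac,
         " is incompatible with ", modification_type)
  }
  structure(
    list(iupac = iupac, modification_type = modification_type,
         modified_index = modified_index, label = label),
    class = "motif_spec"
  )
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> %s  %s at position %d  (label: %s)\n",
              x$iupac, x$modification_type, x$modified_index, x$label))
  invisible(x)
}

#' Read a motif list from TSV
#'
#' Expected columns: `motif`, `modification_type`, optionally
#' `modified_index` and `label`. Additional columns (e.g. a core/shell
#' `distribution` or an average-frequency column) are preserved as
#' attributes on the returned list for summary purposes.
#'
#' @param path Path to a tab-separated motif table with a header line.
#' @return A list of `motif_spec` objects; extra columns are attached as the
#'   attribute `table` (the full data frame as read).
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("motif", "modification_type")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("motif table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  idx <- if ("modified_index" %in% names(tab)) tab$modified_index else
    rep(NA_integer_, nrow(tab))
  labs <- if ("label" %in% names(tab)) tab$label else tab$motif
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    motif_spec(tab$motif[i], tab$modification_type[i],
               modified_index = idx[i], label = labs[i])
  })
  names(specs) <- labs
  attr(specs, "table") <- tab
  specs
}

#' Write a motif list to TSV
#'
#' @param motifs List of `motif_spec` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  tab <- data.frame(
    motif = vapply(motifs, `[[`, "", "iupac"),
    modification_type = vapply(motifs, `[[`, "", "modification_type"),
    modified_index = vapply(motifs, `[[`, 0L, "modified_index"),
    label = vapply(motifs, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## does `inner` occur as a contiguous sub-motif of `outer` such that every
## outer IUPAC set at the aligned positions is a subset of inner's set, with
## the modified bases aligned?  Returns TRUE/FALSE.
.contains_submotif <- function(outer, inner) {
  mo <- .motif_masks(outer$iupac)
  mi <- .motif_masks(inner$iupac)
  Lo <- length(mo); Li <- length(mi)
  if (Li > Lo) return(FALSE)
  for (off in 0:(Lo - Li)) {
    window <- mo[(off + 1L):(off + Li)]
    if (all(bitwAnd(window, bitwNot(mi)) == 0L) &&
        outer$modified_index == off + inner$modified_index) {
      return(TRUE)
    }
  }
  ## reverse-complement orientation: inner read on the opposite strand;
  ## the modified base of inner maps to outer position off + L - idx + 1
  rc <- reverse_complement_iupac(inner$iupac)
  mi_rc <- .motif_masks(rc)
  for (off in 0:(Lo - Li)) {
    window <- mo[(off + 1L):(off + Li)]
    if (all(bitwAnd(window, bitwNot(mi_rc)) == 0L) &&
        outer$modified_index == off + (Li - inner$modified_index + 1L)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Collapse a motif list by shared core sequence
#'
#' Motif A is collapsed onto motif B when B (or its reverse complement)
#' occurs as a contiguous sub-motif of A such that each of A's IUPAC sets at
#' the aligned positions is a subset of B's set and the modified base
#' aligns. The retained representative is the shorter (more general) motif.
#' Motif-prediction software often reports both a core recognition sequence
#' and extended variants of it; this reduces such lists to the core set.
#'
#' Motifs that would collapse but carry conflicting modification types are
#' both retained, with a warning.
#'
#' @param motifs List of `motif_spec` objects.
#' @return A list with elements `collapsed` (the retained `motif_spec`s) and
#'   `mapping` (named character vector: input label -> representative label;
#'   identity for retained motifs).
#' @export
collapse_motifs <- function(motifs) {
  if (length(motifs) == 0L) stop("empty motif list")
  labels <- vapply(motifs, `[[`, "", "label")
  names(motifs) <- labels
  n <- length(motifs)
  ## representative[i]: index of the motif i collapses onto (possibly itself)
  rep_idx <- seq_len(n)
  lens <- vapply(motifs, function(m) nchar(m$iupac), 0L)
  for (i in seq_len(n)) {
    ## candidate representatives: strictly shorter motifs containing motif i
    cand <- which(lens < lens[i])
    cand <- cand[order(lens[cand])]
    for (j in cand) {
      if (motifs[[i]]$modification_type != motifs[[j]]$modification_type) {
        if (.same_type_ignored(motifs[[i]], motifs[[j]])) {
          warning("motifs ", labels[i], " and ", labels[j],
                  " share a core sequence but differ in modification type;",
                  " both retained")
        }
        next
      }
      if (.contains_submotif(motifs[[i]], motifs[[j]])) {
        rep_idx[i] <- j
        break
      }
    }
  }
  ## resolve chains so the mapping is idempotent
  for (i in seq_len(n)) {
    while (rep_idx[rep_idx[i]] != rep_idx[i]) rep_idx[i] <- rep_idx[rep_idx[i]]
  }
  keep <- sort(unique(rep_idx))
  mapping <- labels[rep_idx]
  names(mapping) <- labels
  list(collapsed = motifs[keep], mapping = mapping)
}

## would the pair collapse if types matched? (drives the conflict warning)
.same_type_ignored <- function(a, b) {
  a2 <- a; b2 <- b
  a2$modification_type <- b$modification_type
  ## modified-base compatibility may fail under the swapped type; guard
  ok <- tryCatch(.contains_submotif(a2, b2), error = function(e) FALSE)
  isTRUE(ok)
}
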