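.REGION_CATEGORIES <- c("CDS", "nCDS", "US", "tIG")

## per-position category codes, in increasing precedence order of assignment
.REGION_CODE <- c(tIG = 1L, US = 2L, nCDS = 3L, CDS = 4L)

#' Build the strand-aware region partition of one replicon
#'
#' Partitions every position of the replicon, separately per strand, into
#' four classes: CDS (inside a gene on the accordant strand), nCDS (inside a
#' gene on the discordant strand), US (within `us_length` bp upstream,
#' 5'-ward and strand-aware, of a gene start on the accordant strand) and
#' tIG (true intergenic: everything else). Precedence CDS > nCDS > US > tIG
#' is applied per strand so the four classes form a true partition; a base
#' inside a gene is never US even when it also lies upstream of a neighbor.
#' US windows are truncated at the replicon boundary unless
#' `circular = TRUE`, in which case they wrap across the origin.
#'
#' @param genes Gene data frame (one replicon) from [read_annotation_gff3()].
#' @param replicon_length Replicon length in bp.
#' @param us_length Upstream window size in bp (default 300, a conventional
#'   bacterial promoter-proximal window).
#' @param circular Treat the replicon as circular (default FALSE).
#' @return A list of class `region_index` with `replicon_id`, `length`,
#'   `us_length`, and `segments`: a data frame (`strand`, `start`, `end`,
#'   `category`) of maximal runs covering [1, length] on each strand.
#' @export
build_region_index <- function(genes, replicon_length, us_length = 300L,
                               circular = FALSE) {
  replicon_length <- as.integer(replicon_length)
  us_length <- as.integer(us_length)
  stopifnot(replicon_length >= 1L, us_length >= 0L)
  if (nrow(genes) > 0L) {
    if (length(unique(genes$replicon_id)) > 1L) {
      stop("genes span multiple replicons; index one replicon at a time")
    }
    if (any(genes$start < 1L) || any(genes$end > replicon_length)) {
      stop("gene coordinates exceed replicon length on ",
           genes$replicon_id[1L])
    }
  }
  segs <- vector("list", 2L)
  for (si in 1:2) {
    s <- c("+", "-")[si]
    code <- rep(.REGION_CODE[["tIG"]], replicon_length)
    same <- genes[genes$strand == s, , drop = FALSE]
    other <- genes[genes$strand != s, , drop = FALSE]
    ## US windows of accordant-strand genes (assigned first, lowest precedence)
    if (us_length > 0L && nrow(same) > 0L) {
      for (i in seq_len(nrow(same))) {
        if (s == "+") {
          from <- same$start[i] - us_length
          to <- same$start[i] - 1L
        } else {
          from <- same$end[i] + 1L
          to <- same$end[i] + us_length
        }
        pos <- seq.int(from, to)
        if (circular) {
          pos <- ((pos - 1L) %% replicon_length) + 1L
        } else {
          pos <- pos[pos >= 1L & pos <= replicon_length]
        }
        code[pos] <- pmax(code[pos], .REGION_CODE[["US"]])
      }
    }
    for (i in seq_len(nrow(other))) {
      rng <- other$start[i]:other$end[i]
      code[rng] <- pmax(code[rng], .REGION_CODE[["nCDS"]])
    }
    for (i in seq_len(nrow(same))) {
      rng <- same$start[i]:same$end[i]
      code[rng] <- .REGION_CODE[["CDS"]]
    }
    r <- rle(code)
    ends <- cumsum(r$lengths)
    segs[[si]] <- data.frame(
      strand = s,
      start = ends - r$lengths + 1L,
      end = ends,
      category = names(.REGION_CODE)[r$values],
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(replicon_id = if (nrow(genes) > 0L) genes$replicon_id[1L] else NA_character_,
         length = replicon_length, us_length = us_length,
         segments = rbind(segs[[1L]], segs[[2L]])),
    class = "region_index"
  )
}

#' @export
print.region_index <- function(x, ...) {
  tab <- tapply(x$segments$end - x$segments$start + 1L,
                list(x$segments$strand, x$segments$category), sum)
  cat(sprintf("<region_index> %s, %d bp, us_length=%d\n",
              x$replicon_id, x$length, x$us_length))
  print(tab)
  invisible(x)
}

#' Look up the region category of positions on a strand
#'
#' @param index A `region_index`.
#' @param position Integer vector of 1-based positions.
#' @param strand Character vector ("+"/"-"), recycled against `position`.
#' @return Character vector of categories (CDS/nCDS/US/tIG).
#' @export
region_category <- function(index, position, strand) {
  n <- max(length(position), length(strand))
  position <- rep_len(as.integer(position), n)
  strand <- rep_len(strand, n)
  if (any(position < 1L | position > index$length)) {
    stop("position outside [1, ", index$length, "]")
  }
  out <- character(n)
  for (s in c("+", "-")) {
    seg <- index$segments[index$segments$strand == s, , drop = FALSE]
    sel <- strand == s
    if (!any(sel)) next
    i <- findInterval(position[sel], seg$start)
    out[sel] <- seg$category[i]
  }
  out
}

#' Classify motif occurrences by the region of their modified base
#'
#' @param index A `region_index` for the occurrences' replicon.
#' @param occurrences Occurrence data frame (same replicon).
#' @return The occurrence data frame with a `region` column appended.
#' @export
classify_occurrences <- function(index, occurrences) {
  if (nrow(occurrences) == 0L) {
    occurrences$region <- character(0)
    return(occurrences)
  }
  occurrences$region <- region_category(
    index, occurrences$modified_genome_position, occurrences$strand)
  occurrences
}

#' Export a region index as BED
#'
#' BED is 0-based half-open; this is the only place half-open coordinates
#' appear. One line per segment, with name `<category>` and the strand
#' column filled.
#'
#' @param index A `region_index`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_region_bed <- function(index, path) {
  seg <- index$segments
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   index$replicon_id, seg$start - 1L, seg$end,
                   seg$category, seg$strand)
  writeLines(lines, path)
  invisible(path)
}
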