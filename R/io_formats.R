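.REPLICON_CLASSES <- c("chromosome", "pSymA", "pSymB", "plasmid", "unassigned")

#' Read a multi-replicon genome FASTA
#'
#' Sequences are uppercased. Characters outside {A,C,G,T,N} are rejected by
#' default, or silently mapped to N with `nonstandard = "to_n"` (ambiguity
#' codes in draft assemblies are then treated like unsequenced gaps).
#'
#' @param path Path to a FASTA file.
#' @param strain_id Strain identifier attached to each record; defaults to
#'   the file name without extension.
#' @param nonstandard Either "error" (default) or "to_n".
#' @return A data frame with one row per replicon: `strain_id`,
#'   `replicon_id`, `sequence`, `length`, `replicon_class` (initially
#'   "unassigned"; see [assign_replicon_classes()]).
#' @export
read_fasta <- function(path, strain_id = NULL,
                       nonstandard = c("error", "to_n")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a valid FASTA file: ", path, " (",
                             conditionMessage(e), ")")
  )
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate replicon_id in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (nonstandard == "to_n") {
    seqs <- gsub("[^ACGTN]", "N", seqs)
  } else {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("sequence(s) with characters outside {A,C,G,T,N}: ",
           paste(ids[bad], collapse = ", "),
           " (use nonstandard = \"to_n\" to mask them)")
    }
  }
  if (is.null(strain_id)) {
    strain_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  }
  data.frame(
    strain_id = strain_id,
    replicon_id = unname(ids),
    sequence = unname(seqs),
    length = nchar(seqs),
    replicon_class = "unassigned",
    stringsAsFactors = FALSE
  )
}

#' Write genome records to FASTA
#'
#' @param genome Data frame as returned by [read_fasta()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$replicon_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a strain manifest (replicon class assignments)
#'
#' Tab-separated with header `strain_id`, `replicon_id`, `replicon_class`;
#' classes must be one of chromosome, pSymA, pSymB, plasmid, unassigned.
#' Replicon classes come from an explicit manifest rather than any
#' alignment-based assignment.
#'
#' @param path Path to the manifest TSV.
#' @return Data frame with the three columns.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain_id", "replicon_id", "replicon_class")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(tab$replicon_class), .REPLICON_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown replicon_class value(s): ", paste(bad, collapse = ", "))
  }
  tab[, req]
}

#' Apply manifest replicon classes to genome records
#'
#' @param genome Data frame from [read_fasta()].
#' @param manifest Data frame from [read_manifest()].
#' @return The genome data frame with `replicon_class` filled; replicons
#'   absent from the manifest stay "unassigned".
#' @export
assign_replicon_classes <- function(genome, manifest) {
  key <- paste(manifest$strain_id, manifest$replicon_id, sep = "\r")
  idx <- match(paste(genome$strain_id, genome$replicon_id, sep = "\r"), key)
  hit <- !is.na(idx)
  genome$replicon_class[hit] <- manifest$replicon_class[idx[hit]]
  genome
}

## parse a GFF3 body into a data frame of the 9 standard columns; skips
## comment/pragma lines, keeps original line numbers for error reporting
.read_gff3_body <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), score = character(0),
                      strand = character(0), phase = character(0),
                      attributes = character(0), line = integer(0)))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  lineno <- which(keep)
  if (any(nfield != 9L)) {
    stop("malformed GFF3 (expected 9 tab-separated columns) at line ",
         lineno[which(nfield != 9L)[1L]], " of ", path)
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  data.frame(
    seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
    start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
    score = m[, 6L], strand = m[, 7L], phase = m[, 8L],
    attributes = m[, 9L], line = lineno,
    stringsAsFactors = FALSE
  )
}

## extract one key from a GFF3 column-9 attribute string (key=value;...)
.gff3_attr <- function(attributes, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attributes, regexec(pat, attributes))
  vapply(m, function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
}

#' Read gene features from an annotation GFF3
#'
#' Coordinates are 1-based inclusive (GFF3-native) and kept that way
#' throughout the package. Only features of the configured types are
#' returned; gene features with strand "." are rejected because the
#' region partition is strand-aware.
#'
#' @param path Path to a GFF3 annotation.
#' @param feature_types Character vector of feature types to keep
#'   (default: CDS plus common RNA gene types).
#' @return Data frame: `replicon_id`, `start`, `end`, `strand`,
#'   `feature_type`, `gene_id`.
#' @export
read_annotation_gff3 <- function(path,
                                 feature_types = c("CDS", "tRNA", "rRNA",
                                                   "tmRNA", "ncRNA")) {
  gff <- .read_gff3_body(path)
  gff <- gff[gff$type %in% feature_types, , drop = FALSE]
  bad <- gff$start > gff$end
  if (any(bad)) {
    stop("start > end at line ", gff$line[which(bad)[1L]], " of ", path)
  }
  nostrand <- !(gff$strand %in% c("+", "-"))
  if (any(nostrand)) {
    stop("gene feature without +/- strand at line ",
         gff$line[which(nostrand)[1L]], " of ", path)
  }
  ids <- .gff3_attr(gff$attributes, "ID")
  ids[is.na(ids)] <- paste0("feature_", gff$line[is.na(ids)])
  data.frame(
    replicon_id = gff$seqid, start = gff$start, end = gff$end,
    strand = gff$strand, feature_type = gff$type, gene_id = ids,
    stringsAsFactors = FALSE
  )
}

#' Write gene features to GFF3
#'
#' @param genes Data frame as returned by [read_annotation_gff3()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return The path, invisibly.
#' @export
write_annotation_gff3 <- function(genes, path, source = "panepi") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$replicon_id, source, genes$feature_type,
                     genes$start, genes$end, genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Default methylation GFF3 dialect
#'
#' Describes how base-modification calls are encoded: which feature-type
#' tokens are accepted and how they map onto modification types. The default
#' follows the PacBio base-modification GFF3 convention (`m6A`, `m4C`,
#' `m5C`, `modified_base`), with the call coordinate being the modified base
#' itself.
#'
#' @param type_map Named character vector mapping GFF3 type tokens to
#'   modification types.
#' @return A list of class `methylation_dialect`.
#' @export
methylation_dialect <- function(type_map = c(m6A = "6mA", m4C = "4mC",
                                             m5C = "5mC",
                                             modified_base = "modified_base")) {
  structure(list(type_map = type_map), class = "methylation_dialect")
}

#' Read strand-specific methylation calls from GFF3
#'
#' Parses base-modification calls in the PacBio-like dialect: one row per
#' modified base, with the position column naming the modified base itself
#' and strand +/-. Optional `coverage` attribute and the score column are
#' retained when present.
#'
#' @param path Path to the methylation GFF3.
#' @param dialect A [methylation_dialect()] object.
#' @param genome Optional genome data frame; when given, calls on replicons
#'   absent from the genome, or with positions beyond the replicon length,
#'   are rejected.
#' @return Data frame: `replicon_id`, `position`, `strand`,
#'   `modification_type`, `score`, `coverage`.
#' @export
read_methylation_gff3 <- function(path, dialect = methylation_dialect(),
                                  genome = NULL) {
  gff <- .read_gff3_body(path)
  unknown <- setdiff(unique(gff$type), names(dialect$type_map))
  if (length(unknown) > 0L) {
    stop("unknown modification type token(s): ",
         paste(unknown, collapse = ", "), " in ", path)
  }
  nostrand <- !(gff$strand %in% c("+", "-"))
  if (any(nostrand)) {
    stop("methylation call without +/- strand at line ",
         gff$line[which(nostrand)[1L]], " of ", path)
  }
  calls <- data.frame(
    replicon_id = gff$seqid,
    position = gff$start,
    strand = gff$strand,
    modification_type = unname(dialect$type_map[gff$type]),
    score = suppressWarnings(as.numeric(gff$score)),
    coverage = suppressWarnings(
      as.integer(.gff3_attr(gff$attributes, "coverage"))),
    stringsAsFactors = FALSE
  )
  if (any(calls$position < 1L, na.rm = TRUE)) {
    stop("methylation call with position < 1 in ", path)
  }
  if (!is.null(genome)) {
    idx <- match(calls$replicon_id, genome$replicon_id)
    if (anyNA(idx)) {
      stop("methylation call(s) on replicon(s) absent from the genome: ",
           paste(unique(calls$replicon_id[is.na(idx)]), collapse = ", "))
    }
    out <- calls$position > genome$length[idx]
    if (any(out)) {
      stop("methylation call position beyond replicon length: ",
           calls$replicon_id[which(out)[1L]], ":",
           calls$position[which(out)[1L]])
    }
  }
  calls
}

#' Write methylation calls to GFF3
#'
#' Inverse of [read_methylation_gff3()] under the same dialect.
#'
#' @param calls Data frame of methylation calls.
#' @param path Output path.
#' @param dialect A [methylation_dialect()] object.
#' @return The path, invisibly.
#' @export
write_methylation_gff3 <- function(calls, path,
                                   dialect = methylation_dialect()) {
  rev_map <- stats::setNames(names(dialect$type_map), dialect$type_map)
  bad <- setdiff(unique(calls$modification_type), names(rev_map))
  if (length(bad) > 0L) {
    stop("modification type(s) not expressible in dialect: ",
         paste(bad, collapse = ", "))
  }
  score <- ifelse(is.na(calls$score), ".", format(calls$score))
  attrs <- ifelse(is.na(calls$coverage), ".",
                  paste0("coverage=", calls$coverage))
  lines <- c("##gff-version 3",
             sprintf("%s\tkinModCall\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                     calls$replicon_id, rev_map[calls$modification_type],
                     calls$position, calls$position, score, calls$strand,
                     attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data frame as headered TSV
#'
#' Convenience wrapper used for all tabular outputs; -Inf is serialized as
#' the literal token "-Inf".
#'
#' @param x Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
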