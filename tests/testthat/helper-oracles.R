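## Independent oracles and fixture builders shared across the suite.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

## brute-force motif expansion to concrete words (independent of the
## package's internals)
oracle_expand <- function(motif) {
  sets <- IUPAC_SETS[strsplit(motif, "")[[1]]]
  words <- ""
  for (s in sets) words <- as.vector(outer(words, s, paste0))
  words
}

## brute-force double-strand scan via Biostrings exact matching of every
## concrete word; windows containing N cannot match because words are ACGT
oracle_scan <- function(sequence, motif_iupac, modified_index) {
  L <- nchar(motif_iupac)
  subj <- Biostrings::BString(sequence)
  find_all <- function(words) {
    sort(unique(unlist(lapply(words, function(w)
      Biostrings::start(Biostrings::matchPattern(w, subj))))))
  }
  fwd <- find_all(oracle_expand(motif_iupac))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(oracle_expand(motif_iupac))))
  rev <- find_all(rc)
  data.frame(
    start = c(fwd, rev),
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    modified = c(fwd + modified_index - 1L, rev + L - modified_index),
    stringsAsFactors = FALSE
  )[order(c(fwd, rev), c(rep("+", length(fwd)), rep("-", length(rev)))), ]
}

## per-position brute-force region classification for one strand
oracle_regions <- function(genes, len, us_length, strand) {
  out <- rep("tIG", len)
  same <- genes[genes$strand == strand, , drop = FALSE]
  if (us_length > 0 && nrow(same) > 0) {
    for (i in seq_len(nrow(same))) {
      w <- if (strand == "+") {
        (same$start[i] - us_length):(same$start[i] - 1L)
      } else {
        (same$end[i] + 1L):(same$end[i] + us_length)
      }
      w <- w[w >= 1 & w <= len]
      out[w] <- "US"
    }
  }
  other <- genes[genes$strand != strand, , drop = FALSE]
  for (i in seq_len(nrow(other))) out[other$start[i]:other$end[i]] <- "nCDS"
  for (i in seq_len(nrow(same))) out[same$start[i]:same$end[i]] <- "CDS"
  out
}

## exhaustive complete-linkage agglomeration: at each step merge the cluster
## pair with the smallest maximum pairwise leaf distance
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

## small cached panel so several test files can share one generation
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- panel_config(
        n_strains = 6L, seed = 11L, n_min = 4L,
        replicon_plan = data.frame(
          replicon_class = c("chromosome", "pSymB", "pSymA"),
          length = c(30000L, 20000L, 15000L), stringsAsFactors = FALSE))
      cache <<- generate_panel(cfg)
    }
    cache
  }
})
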