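#' Curated motif set of the S. meliloti pan-epigenome
#'
#' Reads the packaged reference table of the 16 methylated motifs observed
#' across a 21-strain Sinorhizobium meliloti panel (motif, modification
#' type, core/shell distribution, REBASE presence, average methylation
#' frequency). Modified-base offsets are curated defaults chosen as the
#' canonical methylated base where known (e.g. the A of GANTC targeted by
#' CcrM) and the first compatible base otherwise.
#'
#' @return A list of `motif_spec` objects with the full table attached as
#'   attribute `table` (see [read_motif_table()]).
#' @export
sm_motifs <- function() {
  read_motif_table(system.file("extdata", "sm_motifs.tsv",
                               package = "panepi", mustWork = TRUE))
}

#' Default methylation-probability design
#'
#' One Bernoulli probability per motif x region category x replicon class.
#' GANTC is nearly fully methylated everywhere (0.99), emulating a
#' cell-cycle MTase acting genome-wide in late exponential phase. Other
#' motifs get a motif-specific baseline (0.3-0.9), modulated by region
#' (regulatory regions slightly higher than antisense-gene positions) and
#' replicon (plasmids markedly hypomethylated, secondary replicons mildly
#' so), so that region- and replicon-wise contrasts exist by construction.
#'
#' @param motifs List of `motif_spec` objects.
#' @return Data frame: `motif_label`, `region`, `replicon_class`, `p`.
#' @export
default_probability_design <- function(motifs) {
  labels <- vapply(motifs, `[[`, "", "label")
  base_p <- 0.3 + 0.6 * (seq_along(labels) - 1) / max(1, length(labels) - 1)
  names(base_p) <- labels
  if ("GANTC" %in% labels) base_p["GANTC"] <- 0.99
  region_mult <- c(CDS = 1.0, nCDS = 0.8, US = 1.15, tIG = 1.3)
  replicon_mult <- c(chromosome = 1.0, pSymB = 0.9, pSymA = 0.85,
                     plasmid = 0.55, unassigned = 1.0)
  grid <- expand.grid(motif_label = labels,
                      region = names(region_mult),
                      replicon_class = names(replicon_mult),
                      stringsAsFactors = FALSE)
  p <- base_p[grid$motif_label] * region_mult[grid$region] *
    replicon_mult[grid$replicon_class]
  grid$p <- pmin(0.995, p)
  grid$p[grid$motif_label == "GANTC"] <- 0.99
  grid
}

#' Configuration for a synthetic multi-strain methylome panel
#'
#' Defines the panel the generator emits: strain count, per-strain replicon
#' plan, gene geometry, motif set, which strains carry an active MTase for
#' each motif (the presence design), and the Bernoulli methylation
#' probabilities per motif x region x replicon class.
#'
#' Defaults emulate a 21-strain panel of a multipartite-genome bacterium at
#' desk scale: three replicon classes per strain (chromosome 100 kb, pSymB
#' chromid 50 kb, pSymA megaplasmid 40 kb; roughly 35x smaller than real
#' S. meliloti replicons), every third strain carrying an additional 15 kb
#' plasmid; 10 core motifs present in all strains and 6 shell motifs in
#' nested subsets of 2 to 19 strains (the shell occupancy range observed in
#' the real panel).
#'
#' @param n_strains Number of strains.
#' @param motifs List of `motif_spec` (default [sm_motifs()]).
#' @param replicon_plan Data frame `replicon_class`, `length`.
#' @param plasmid_every Give every k-th strain the plasmid replicon (0 = no
#'   plasmids).
#' @param gene_length,gene_gap Integer ranges (length-2 vectors) for gene
#'   sizes and intergenic gaps, bp.
#' @param us_length Upstream window used both for planting and analysis, bp.
#' @param presence Named list: motif label -> character vector of strains
#'   carrying the motif's MTase. Default: core motifs (per the attached
#'   table's `distribution`, else all motifs) in all strains; shell motifs
#'   in nested leading subsets of sizes spread over 2..(n_strains - 2).
#' @param probability_design Data frame as from
#'   [default_probability_design()].
#' @param n_min Guaranteed minimum planted occurrences per motif x region x
#'   replicon (per strain).
#' @param gc GC content of the background sequence.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_strains = 21L,
                         motifs = sm_motifs(),
                         replicon_plan = data.frame(
                           replicon_class = c("chromosome", "pSymB", "pSymA"),
                           length = c(100000L, 50000L, 40000L),
                           stringsAsFactors = FALSE),
                         plasmid_every = 3L,
                         gene_length = c(300L, 900L),
                         gene_gap = c(200L, 700L),
                         us_length = 300L,
                         presence = NULL,
                         probability_design = default_probability_design(motifs),
                         n_min = 8L,
                         gc = 0.5,
                         seed = 1L) {
  stopifnot(n_strains >= 2L, all(replicon_plan$length > 0L),
            gc > 0, gc < 1, n_min >= 0L)
  strains <- sprintf("S%02d", seq_len(n_strains))
  labels <- vapply(motifs, `[[`, "", "label")
  if (is.null(presence)) {
    tab <- attr(motifs, "table")
    is_shell <- if (!is.null(tab) && "distribution" %in% names(tab)) {
      tolower(tab$distribution) == "shell"
    } else {
      rep(FALSE, length(labels))
    }
    presence <- stats::setNames(vector("list", length(labels)), labels)
    shell_idx <- which(is_shell)
    sizes <- if (length(shell_idx) > 0L) {
      pmax(2L, pmin(n_strains - 2L,
                    round(seq(2L, max(2L, n_strains - 2L),
                              length.out = length(shell_idx)))))
    } else integer(0)
    for (i in seq_along(labels)) {
      presence[[i]] <- if (is_shell[i]) {
        strains[seq_len(sizes[match(i, shell_idx)])]
      } else {
        strains
      }
    }
  }
  missing_pres <- setdiff(labels, names(presence))
  if (length(missing_pres) > 0L) {
    stop("presence design missing motif(s): ",
         paste(missing_pres, collapse = ", "))
  }
  if (any(probability_design$p < 0 | probability_design$p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(
    list(n_strains = n_strains, strains = strains, motifs = motifs,
         replicon_plan = replicon_plan, plasmid_every = plasmid_every,
         gene_length = gene_length, gene_gap = gene_gap,
         us_length = us_length, presence = presence,
         probability_design = probability_design, n_min = n_min,
         gc = gc, seed = as.integer(seed)),
    class = "panel_config"
  )
}

## probability lookup table keyed by motif\rregion\rreplicon_class
.design_lookup <- function(design) {
  stats::setNames(design$p, paste(design$motif_label, design$region,
                                  design$replicon_class, sep = "\r"))
}

## sample a background sequence as a character vector of single bases
.sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## random non-overlapping gene layout along one replicon
.place_genes <- function(replicon_id, len, gene_length, gene_gap, prefix) {
  starts <- integer(0); ends <- integer(0); strands <- character(0)
  pos <- sample(gene_gap[1L]:gene_gap[2L], 1L)
  while (TRUE) {
    glen <- sample(gene_length[1L]:gene_length[2L], 1L)
    if (pos + glen - 1L > len - 50L) break
    starts <- c(starts, pos)
    ends <- c(ends, pos + glen - 1L)
    strands <- c(strands, sample(c("+", "-"), 1L))
    pos <- pos + glen + sample(gene_gap[1L]:gene_gap[2L], 1L)
  }
  data.frame(
    replicon_id = rep(replicon_id, length(starts)),
    start = starts, end = ends, strand = strands,
    feature_type = rep("CDS", length(starts)),
    gene_id = sprintf("%s_g%04d", prefix, seq_along(starts)),
    stringsAsFactors = FALSE
  )
}

## plant >= n_min occurrences of each motif into each region category of one
## replicon; mutates the base vector in place (returns it)
.plant_motifs <- function(bases, index, motifs, n_min, max_tries = 300L) {
  if (n_min <= 0L) return(bases)
  occupied <- rep(FALSE, length(bases))
  segs <- index$segments
  ## candidate segments per strand x category, precomputed once
  cand_tab <- list()
  for (strand in c("+", "-")) {
    for (cat in .REGION_CATEGORIES) {
      sel <- segs$strand == strand & segs$category == cat
      cand_tab[[paste0(strand, cat)]] <- list(
        start = segs$start[sel], end = segs$end[sel],
        len = segs$end[sel] - segs$start[sel] + 1L)
    }
  }
  for (m in motifs) {
    words <- .expand_iupac(m$iupac)
    rc_words <- vapply(words, reverse_complement_iupac, "")
    L <- nchar(m$iupac)
    for (cat in .REGION_CATEGORIES) {
      has_room <- any(vapply(c("+", "-"), function(s)
        any(cand_tab[[paste0(s, cat)]]$len >= L), TRUE))
      if (!has_room) next  # this category cannot hold the motif at all
      for (k in seq_len(n_min)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          strand <- if (stats::runif(1) < 0.5) "+" else "-"
          cand <- cand_tab[[paste0(strand, cat)]]
          fit <- which(cand$len >= L)
          if (length(fit) == 0L) next
          ci <- fit[sample.int(length(fit), 1L, prob = cand$len[fit])]
          s <- cand$start[ci] + sample.int(cand$len[ci] - L + 1L, 1L) - 1L
          win <- s:(s + L - 1L)
          if (any(occupied[win])) next
          wi <- sample.int(length(words), 1L)
          word <- if (strand == "-") rc_words[wi] else words[wi]
          bases[win] <- strsplit(word, "", fixed = TRUE)[[1L]]
          occupied[win] <- TRUE
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not plant ", m$label, " in region ", cat,
               ": demanded more occurrences than fit")
        }
      }
    }
  }
  bases
}

#' Generate a synthetic multi-strain methylome panel
#'
#' Emits, per strain, a multi-replicon genome (i.i.d. background sequence at
#' the configured GC content), a gene annotation (non-overlapping genes on
#' both strands), planted motif occurrences guaranteeing minimum counts per
#' motif x region x replicon, and strand-specific methylation calls drawn as
#' independent Bernoulli trials with the design probabilities. Strains
#' outside a motif's presence subset emit no calls for it. Deterministic
#' given the seed.
#'
#' The returned ground truth records every motif occurrence in the final
#' sequences (planted and background alike), its true region category and
#' whether a call was emitted at its modified position, so downstream
#' recovery can be checked exactly.
#'
#' @param config A [panel_config()].
#' @param out_dir Optional directory; when given, writes per-strain FASTA
#'   (`<strain>.fna`), annotation (`<strain>.genes.gff3`) and methylation
#'   calls (`<strain>.meth.gff3`), plus `manifest.tsv` and `motifs.tsv`.
#' @return A list of class `panel`: `genomes`, `genes`, `calls` (with
#'   `strain_id`), `truth` (flagged occurrences with `region`), `manifest`,
#'   `config`, and `files` (named paths when `out_dir` was given).
#' @export
generate_panel <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "panel_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  plookup <- .design_lookup(config$probability_design)
  genomes <- list(); genes <- list(); calls <- list(); truth <- list()
  for (si in seq_along(config$strains)) {
    strain <- config$strains[si]
    plan <- config$replicon_plan
    if (config$plasmid_every > 0L && si %% config$plasmid_every == 0L) {
      plan <- rbind(plan, data.frame(replicon_class = "plasmid",
                                     length = 15000L,
                                     stringsAsFactors = FALSE))
    }
    for (ri in seq_len(nrow(plan))) {
      rid <- sprintf("%s_r%d", strain, ri)
      len <- plan$length[ri]
      g <- .place_genes(rid, len, config$gene_length, config$gene_gap,
                        prefix = rid)
      idx <- build_region_index(g, len, us_length = config$us_length)
      idx$replicon_id <- rid
      bases <- .sample_bases(len, config$gc)
      bases <- .plant_motifs(bases, idx, config$motifs, config$n_min)
      grec <- data.frame(strain_id = strain, replicon_id = rid,
                         sequence = paste(bases, collapse = ""),
                         length = len,
                         replicon_class = plan$replicon_class[ri],
                         stringsAsFactors = FALSE)
      occ <- scan_genome(grec, config$motifs)
      occ <- classify_occurrences(idx, occ)
      ## Bernoulli methylation per occurrence, independent across occurrences
      pres <- vapply(config$presence[occ$motif_label],
                     function(v) strain %in% v, TRUE)
      p <- plookup[paste(occ$motif_label, occ$region, occ$replicon_class,
                         sep = "\r")]
      if (anyNA(p)) {
        stop("probability design missing combination(s), e.g. ",
             paste(occ$motif_label[is.na(p)][1L], occ$region[is.na(p)][1L],
                   occ$replicon_class[is.na(p)][1L]))
      }
      draw <- pres & (stats::runif(nrow(occ)) < p)
      types <- vapply(config$motifs, `[[`, "", "modification_type")
      names(types) <- vapply(config$motifs, `[[`, "", "label")
      cl <- occ[draw, , drop = FALSE]
      call_df <- unique(data.frame(
        replicon_id = cl$replicon_id,
        position = cl$modified_genome_position,
        strand = cl$strand,
        modification_type = unname(types[cl$motif_label]),
        score = NA_real_, coverage = NA_integer_,
        stringsAsFactors = FALSE))
      ## true flags: match against the emitted calls, so overlapping
      ## occurrences sharing a modified base are flagged consistently
      occ <- assign_methylation(occ, call_df, config$motifs,
                                allow_generic = FALSE)
      occ$design_p <- ifelse(pres, unname(p), 0)
      ## exact per-occurrence methylation probability: occurrences of
      ## same-type motifs sharing a modified base are flagged together, so
      ## P(methylated) = 1 - prod(1 - p) over co-located occurrences
      site <- paste(occ$replicon_id, occ$strand,
                    occ$modified_genome_position,
                    types[occ$motif_label], sep = "\r")
      log_unmeth <- tapply(log1p(-occ$design_p), site, sum)
      occ$expected_p <- 1 - exp(log_unmeth[site])
      occ$site_id <- paste0(rid, ":", match(site, names(log_unmeth)))
      call_df$strain_id <- strain
      g$strain_id <- rep(strain, nrow(g))
      genomes[[rid]] <- grec
      genes[[rid]] <- g
      calls[[rid]] <- call_df
      truth[[rid]] <- occ
    }
  }
  genomes <- do.call(rbind, genomes)
  genes <- do.call(rbind, genes)
  calls <- do.call(rbind, calls)
  truth <- do.call(rbind, truth)
  rownames(genomes) <- rownames(genes) <- rownames(calls) <-
    rownames(truth) <- NULL
  manifest <- genomes[, c("strain_id", "replicon_id", "replicon_class")]
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (strain in config$strains) {
      gsub_ <- genomes[genomes$strain_id == strain, , drop = FALSE]
      fa <- file.path(out_dir, paste0(strain, ".fna"))
      write_fasta(gsub_, fa)
      gf <- file.path(out_dir, paste0(strain, ".genes.gff3"))
      write_annotation_gff3(genes[genes$strain_id == strain, , drop = FALSE],
                            gf)
      mf <- file.path(out_dir, paste0(strain, ".meth.gff3"))
      write_methylation_gff3(calls[calls$strain_id == strain, , drop = FALSE],
                             mf)
      files[[strain]] <- c(fasta = fa, genes = gf, methylation = mf)
    }
    files$manifest <- file.path(out_dir, "manifest.tsv")
    write_tsv(manifest, files$manifest)
    files$motifs <- file.path(out_dir, "motifs.tsv")
    write_motif_table(config$motifs, files$motifs)
  }
  structure(list(genomes = genomes, genes = genes, calls = calls,
                 truth = truth, manifest = manifest, config = config,
                 files = files),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf(
    "<panel> %d strains, %d replicons, %d genes, %d occurrences, %d calls\n",
    length(unique(x$genomes$strain_id)), nrow(x$genomes), nrow(x$genes),
    nrow(x$truth), nrow(x$calls)))
  invisible(x)
}

#' Design-implied expected frequencies for a synthetic panel
#'
#' Computes, per group, the exact expectation and standard deviation of the
#' observed methylation frequency under the generator's design: each
#' occurrence is methylated with its `expected_p` (which accounts for
#' same-type motifs sharing a modified base), and occurrences sharing a
#' site are perfectly correlated while distinct sites are independent.
#'
#' @param panel A `panel` from [generate_panel()].
#' @param by Grouping keys over the truth table (e.g.
#'   `c("motif_label", "region")`).
#' @return Data frame: grouping keys, `n` (occurrences), `expected`
#'   (expected frequency) and `sd` (standard deviation of the observed
#'   frequency).
#' @export
expected_frequency <- function(panel, by = c("motif_label", "region")) {
  tr <- panel$truth
  key <- do.call(paste, c(tr[by], sep = "\r"))
  lev <- sort(unique(key))
  n <- as.integer(table(factor(key, levels = lev)))
  expd <- as.numeric(tapply(tr$expected_p, factor(key, levels = lev), mean))
  ## within-group variance: sum over sites of m^2 p (1-p), m = multiplicity
  site_key <- paste(key, tr$site_id, sep = "\r")
  tab <- table(site_key)
  first <- !duplicated(site_key)
  p_site <- tr$expected_p[first]
  g_site <- key[first]
  m_site <- as.integer(tab[site_key[first]])
  v <- tapply(m_site^2 * p_site * (1 - p_site),
              factor(g_site, levels = lev), sum)
  v[is.na(v)] <- 0
  out <- stats::setNames(as.data.frame(
    do.call(rbind, strsplit(lev, "\r", fixed = TRUE)),
    stringsAsFactors = FALSE), by)
  out$n <- n
  out$expected <- expd
  out$sd <- sqrt(as.numeric(v)) / n
  out
}

#' Generate a donor x recipient transformation-ratio table with known truth
#'
#' Plants log10 fold changes (including -Inf cells, i.e. zero
#' transformants) on top of per-recipient self-ratios, so the fold-change
#' computation can be checked for exact recovery.
#'
#' @param n_strains Number of strains (square matrix).
#' @param planted_fc Optional donor x recipient matrix of log10 fold changes
#'   (diagonal must be 0; -Inf allowed off-diagonal). Default: random in
#'   [-3, 3] with a couple of -Inf cells.
#' @param self_ratio_scale Range of the uniform log10 self-ratio draw.
#' @param seed Integer seed.
#' @return List: `table` (donor, recipient, ratio data frame), `truth`
#'   (the planted fold-change matrix).
#' @export
generate_transfer_table <- function(n_strains = 5L, planted_fc = NULL,
                                    self_ratio_scale = c(-6, -3),
                                    seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  strains <- sprintf("D%02d", seq_len(n_strains))
  if (is.null(planted_fc)) {
    planted_fc <- matrix(round(stats::runif(n_strains^2, -3, 3), 3),
                         n_strains, n_strains,
                         dimnames = list(strains, strains))
    diag(planted_fc) <- 0
    off <- which(row(planted_fc) != col(planted_fc))
    planted_fc[sample(off, min(2L, length(off)))] <- -Inf
  } else {
    dimnames(planted_fc) <- list(strains, strains)
    if (any(diag(planted_fc) != 0)) stop("diagonal fold changes must be 0")
  }
  self <- 10^stats::runif(n_strains, self_ratio_scale[1L],
                          self_ratio_scale[2L])
  ratio <- sweep(10^planted_fc, 2L, self, "*")
  ratio[is.infinite(planted_fc) & planted_fc < 0] <- 0
  tab <- data.frame(
    donor = rep(strains, times = n_strains),
    recipient = rep(strains, each = n_strains),
    ratio = as.vector(ratio),
    stringsAsFactors = FALSE
  )
  list(table = tab, truth = planted_fc)
}
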