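#' End-to-end pan-epigenome analysis of a strain panel
#'
#' Runs the full analysis in memory: scans every replicon of every strain
#' for the motif set on both strands, flags occurrences from the strain's
#' methylation calls, classifies each occurrence's modified base into
#' CDS/nCDS/US/tIG, and computes the comparative layer: frequency tables at
#' several granularities, the core/shell pan-epigenome classification,
#' NRMSD matrices (raw and scaled), PCA region contributions, Dunn tests
#' across regions and replicon classes, strain dendrograms for the core and
#' shell epigenome with their cophenetic correlations, and a motif
#' dendrogram on intergenic frequencies.
#'
#' @param genomes Genome data frame (all strains) with `replicon_class`
#'   assigned; see [read_fasta()] and [assign_replicon_classes()].
#' @param genes Gene data frame with a `strain_id` column.
#' @param calls Methylation-call data frame with a `strain_id` column.
#' @param motifs List of [motif_spec()] objects.
#' @param us_length Upstream window in bp (default 300).
#' @param circular Treat replicons as circular (default FALSE).
#' @param min_frequency Presence threshold for the core/shell rule.
#' @param nrmsd_normalizer "mean" or "range" (see [nrmsd()]).
#' @param p_adjust Multiple-testing adjustment for the Dunn tables.
#' @param allow_generic Accept generic modified_base calls for any motif.
#' @param verbose Narrate per-strain occurrence/call reconciliation counts.
#' @return An object of class `pan_epigenome`; see Details.
#' @details The returned list contains `occurrences` (flagged, with
#'   `region`), `frequency` (long table at strain x motif x region x
#'   replicon-class granularity plus marginal "ALL" aggregates),
#'   `classification`, `nrmsd` (raw/row-scaled/column-scaled region
#'   matrices and a replicon-class matrix), `pca`, `dunn_region`,
#'   `dunn_replicon`, `trees` (hclust objects), `cophenetic` (pairwise
#'   correlation table), and `settings`.
#' @export
analyze_panel <- function(genomes, genes, calls, motifs,
                          us_length = 300L, circular = FALSE,
                          min_frequency = 0,
                          nrmsd_normalizer = c("mean", "range"),
                          p_adjust = "holm", allow_generic = TRUE,
                          verbose = FALSE) {
  nrmsd_normalizer <- match.arg(nrmsd_normalizer)
  strains <- sort(unique(genomes$strain_id))
  occ_all <- vector("list", nrow(genomes))
  unmatched <- 0L
  for (i in seq_len(nrow(genomes))) {
    grec <- genomes[i, , drop = FALSE]
    g <- genes[genes$strain_id == grec$strain_id &
                 genes$replicon_id == grec$replicon_id, , drop = FALSE]
    idx <- build_region_index(g, grec$length, us_length = us_length,
                              circular = circular)
    idx$replicon_id <- grec$replicon_id
    occ <- scan_genome(grec, motifs)
    occ <- classify_occurrences(idx, occ)
    cl <- calls[calls$strain_id == grec$strain_id &
                  calls$replicon_id == grec$replicon_id, , drop = FALSE]
    occ <- assign_methylation(occ, cl, motifs, allow_generic = allow_generic)
    unmatched <- unmatched + attr(occ, "unmatched_calls")
    if (verbose) {
      message(sprintf("%s/%s: %d occurrences, %d calls, %d unmatched",
                      grec$strain_id, grec$replicon_id, nrow(occ), nrow(cl),
                      attr(occ, "unmatched_calls")))
    }
    occ_all[[i]] <- occ
  }
  occurrences <- do.call(rbind, occ_all)
  rownames(occurrences) <- NULL

  freq_full <- methylation_frequency(
    occurrences, by = c("strain_id", "motif_label", "region",
                        "replicon_class"))
  freq_gw <- methylation_frequency(
    occurrences, by = c("strain_id", "motif_label"), complete = TRUE)
  freq_region <- methylation_frequency(
    occurrences, by = c("strain_id", "motif_label", "region"),
    complete = TRUE)
  freq_replicon <- methylation_frequency(
    occurrences, by = c("strain_id", "motif_label", "replicon_class"),
    complete = TRUE)
  frequency <- rbind(freq_full, freq_gw, freq_region, freq_replicon)

  classification <- classify_pan_epigenome(freq_gw, strains = strains,
                                           min_frequency = min_frequency)

  nr_raw <- nrmsd_matrix(freq_region, group = "region",
                         normalizer = nrmsd_normalizer)
  nr <- list(
    region_raw = nr_raw,
    region_row_scaled = if (ncol(nr_raw) >= 2L)
      scale_matrix(nr_raw, "row") else nr_raw,
    region_column_scaled = if (nrow(nr_raw) >= 2L)
      scale_matrix(nr_raw, "column") else nr_raw,
    replicon_raw = nrmsd_matrix(freq_replicon, group = "replicon_class",
                                normalizer = nrmsd_normalizer)
  )

  ## PCA: observations are strain x motif profiles, variables the regions
  pca_mat <- .freq_matrix(freq_region,
                          rows = c("strain_id", "motif_label"),
                          cols = "region")
  pca <- if (nrow(pca_mat) >= 2L && ncol(pca_mat) >= 2L) {
    suppressMessages(pca_contributions(pca_mat))
  } else NULL

  dunn_region <- .dunn_by_motif(freq_region, "region", p_adjust)
  dunn_replicon <- .dunn_by_motif(freq_replicon, "replicon_class", p_adjust)

  trees <- .panel_trees(freq_gw, classification)
  coph <- .cophenetic_table(trees)

  structure(
    list(occurrences = occurrences, frequency = frequency,
         classification = classification, nrmsd = nr, pca = pca,
         dunn_region = dunn_region, dunn_replicon = dunn_replicon,
         trees = trees, cophenetic = coph,
         unmatched_calls = unmatched,
         settings = list(us_length = us_length, circular = circular,
                         min_frequency = min_frequency,
                         nrmsd_normalizer = nrmsd_normalizer,
                         p_adjust = p_adjust,
                         allow_generic = allow_generic)),
    class = "pan_epigenome"
  )
}

## long frequency table -> wide matrix (missing stays NA)
.freq_matrix <- function(freq, rows, cols) {
  sub <- freq[freq[[cols]] != "ALL", , drop = FALSE]
  rkey <- do.call(paste, c(sub[rows], sep = ":"))
  rlev <- sort(unique(rkey))
  clev <- sort(unique(sub[[cols]]))
  m <- matrix(NA_real_, length(rlev), length(clev),
              dimnames = list(rlev, clev))
  m[cbind(match(rkey, rlev), match(sub[[cols]], clev))] <- sub$frequency
  m
}

## one Dunn table per motif: groups are the region/replicon classes,
## observations the per-strain frequencies
.dunn_by_motif <- function(freq, group, p_adjust) {
  sub <- freq[freq[[group]] != "ALL" & !is.na(freq$frequency), , drop = FALSE]
  out <- list()
  for (m in sort(unique(sub$motif_label))) {
    d <- sub[sub$motif_label == m, , drop = FALSE]
    if (length(unique(d[[group]])) < 2L) next
    if (min(table(d[[group]])) < 1L) next
    kd <- kruskal_dunn(d$frequency, d[[group]], p_adjust = p_adjust)
    tab <- kd$comparisons
    tab$motif_label <- m
    tab$kw_p <- kd$kw_p
    out[[m]] <- tab
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("motif_label", "group_i", "group_j", "z", "p", "p_adjusted",
          "significant", "kw_p")]
}

## strain dendrograms on genome-wide frequencies: full, core-only, shell-only
.panel_trees <- function(freq_gw, classification) {
  lab <- classification$summary
  sets <- list(
    all = lab$motif_label[lab$label != "absent"],
    core = lab$motif_label[lab$label == "core"],
    shell = lab$motif_label[lab$label %in% c("shell", "exclusive")]
  )
  trees <- list()
  for (nm in names(sets)) {
    if (length(sets[[nm]]) < 1L) next
    m <- .freq_matrix(freq_gw[freq_gw$motif_label %in% sets[[nm]], ,
                              drop = FALSE],
                      rows = "strain_id", cols = "motif_label")
    m[is.na(m)] <- 0
    if (nrow(m) >= 2L && ncol(m) >= 1L) {
      trees[[nm]] <- hcluster_complete(euclidean_distance_matrix(m))
    }
  }
  trees
}

.cophenetic_table <- function(trees) {
  nms <- names(trees)
  if (length(nms) < 2L) return(NULL)
  pairs <- utils::combn(nms, 2L)
  data.frame(
    tree_i = pairs[1L, ], tree_j = pairs[2L, ],
    r = apply(pairs, 2L, function(p)
      cophenetic_correlation(trees[[p[1L]]], trees[[p[2L]]])),
    stringsAsFactors = FALSE
  )
}

#' @export
print.pan_epigenome <- function(x, ...) {
  cat(sprintf("<pan_epigenome> %d strains, %d motifs, %d occurrences\n",
              length(unique(x$occurrences$strain_id)),
              nrow(x$classification$summary), nrow(x$occurrences)))
  print(x$classification)
  invisible(x)
}

#' @export
summary.pan_epigenome <- function(object, ...) {
  cls <- object$classification$summary
  gw <- object$frequency[object$frequency$region == "ALL" &
                           object$frequency$replicon_class == "ALL" &
                           object$frequency$total > 0, ]
  mean_freq <- tapply(gw$frequency, gw$motif_label, mean, na.rm = TRUE)
  out <- cls
  out$mean_frequency <- round(as.numeric(mean_freq[cls$motif_label]), 4)
  print(out)
  invisible(out)
}

#' Run the pipeline from a configuration file or list
#'
#' Reads per-strain FASTA/GFF3 inputs listed in a YAML configuration,
#' executes [analyze_panel()] and writes the report bundle (TSV tables,
#' Newick dendrograms and a run manifest recording every setting) into the
#' output directory.
#'
#' Config keys: `strains` (list of `id`, `fasta`, `annotation`,
#' `methylation`), `manifest` (replicon-class TSV), `motifs` (motif TSV),
#' `out_dir`, and optionally `us_length`, `circular`, `min_frequency`,
#' `nrmsd_normalizer`, `p_adjust`, `allow_generic`, `transfer_table`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param verbose Narrate per-strain reconciliation counts.
#' @return The `pan_epigenome` object, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("strains", "manifest", "motifs", "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0L) {
    stop("config missing key(s): ", paste(miss, collapse = ", "))
  }
  for (s in config$strains) {
    for (f in c("fasta", "annotation", "methylation")) {
      if (is.null(s[[f]]) || !file.exists(s[[f]])) {
        stop("strain ", s$id, ": missing or nonexistent ", f, " file")
      }
    }
  }
  if (!file.exists(config$manifest)) stop("manifest file not found")
  if (!file.exists(config$motifs)) stop("motif file not found")
  motifs <- read_motif_table(config$motifs)
  manifest <- read_manifest(config$manifest)
  genomes <- list(); genes <- list(); calls <- list()
  for (s in config$strains) {
    g <- read_fasta(s$fasta, strain_id = s$id)
    g <- assign_replicon_classes(g, manifest)
    a <- read_annotation_gff3(s$annotation)
    a$strain_id <- rep(s$id, nrow(a))
    m <- read_methylation_gff3(s$methylation, genome = g)
    m$strain_id <- rep(s$id, nrow(m))
    genomes[[s$id]] <- g; genes[[s$id]] <- a; calls[[s$id]] <- m
  }
  genomes <- do.call(rbind, genomes)
  genes <- do.call(rbind, genes)
  calls <- do.call(rbind, calls)
  opt <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  res <- analyze_panel(
    genomes, genes, calls, motifs,
    us_length = opt("us_length", 300L),
    circular = opt("circular", FALSE),
    min_frequency = opt("min_frequency", 0),
    nrmsd_normalizer = opt("nrmsd_normalizer", "mean"),
    p_adjust = opt("p_adjust", "holm"),
    allow_generic = opt("allow_generic", TRUE),
    verbose = verbose
  )
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$occurrences, file.path(out, "occurrences.tsv"))
  write_tsv(res$frequency, file.path(out, "frequency.tsv"))
  write_tsv(res$classification$summary, file.path(out, "classification.tsv"))
  for (nm in names(res$nrmsd)) {
    m <- res$nrmsd[[nm]]
    write_tsv(data.frame(motif_label = rownames(m), m, check.names = FALSE),
              file.path(out, paste0("nrmsd_", nm, ".tsv")))
  }
  if (!is.null(res$pca)) {
    write_tsv(data.frame(variable = rownames(res$pca$contributions),
                         res$pca$contributions, check.names = FALSE),
              file.path(out, "pca_contributions.tsv"))
  }
  if (!is.null(res$dunn_region)) {
    write_tsv(res$dunn_region, file.path(out, "dunn_region.tsv"))
  }
  if (!is.null(res$dunn_replicon)) {
    write_tsv(res$dunn_replicon, file.path(out, "dunn_replicon.tsv"))
  }
  for (nm in names(res$trees)) {
    write_dendrogram_newick(res$trees[[nm]],
                            file.path(out, paste0("dendrogram_", nm, ".nwk")))
  }
  if (!is.null(res$cophenetic)) {
    write_tsv(res$cophenetic, file.path(out, "cophenetic_correlations.tsv"))
  }
  if (!is.null(config$transfer_table)) {
    fc <- log10_fold_change(read_transfer_table(config$transfer_table))
    write_transfer_matrix(fc, file.path(out, "transfer_log10fc.tsv"))
  }
  run_manifest <- c(res$settings,
                    list(n_strains = length(unique(genomes$strain_id)),
                         n_motifs = length(motifs),
                         motif_file = config$motifs,
                         manifest_file = config$manifest))
  yaml::write_yaml(run_manifest, file.path(out, "run_manifest.yaml"))
  invisible(res)
}
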