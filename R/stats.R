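#' Methylation frequency table
#'
#' Aggregates flagged motif occurrences into methylated/total counts and
#' frequencies. The frequency of a motif in a group is the number of times
#' it was found methylated over the total number of times it was found
#' there. Groups are defined by `by`: any subset of
#' `c("strain_id", "motif_label", "region", "replicon_class")`; dimensions
#' not grouped on are aggregated over (reported as "ALL").
#'
#' When `complete = TRUE` the table is completed over the full grid of
#' observed key levels; grid cells with no occurrences are emitted with
#' `total = 0` and `frequency = NA` (missing, never 0).
#'
#' @param occurrences Flagged occurrence data frame (with `methylated`, and
#'   `region` if grouping on it).
#' @param by Character vector of grouping keys.
#' @param complete Complete the key grid with zero-total missing records.
#' @return Data frame: the grouping keys (with "ALL" for aggregated
#'   dimensions), `methylated`, `total`, `frequency`.
#' @export
methylation_frequency <- function(occurrences,
                                  by = c("strain_id", "motif_label"),
                                  complete = FALSE) {
  all_keys <- c("strain_id", "motif_label", "region", "replicon_class")
  by <- match.arg(by, all_keys, several.ok = TRUE)
  miss <- setdiff(by, names(occurrences))
  if (length(miss) > 0L) {
    stop("occurrences lack grouping column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(occurrences) == 0L) {
    out <- stats::setNames(
      as.data.frame(matrix(character(0), 0L, length(all_keys))), all_keys)
    out$methylated <- integer(0); out$total <- integer(0)
    out$frequency <- numeric(0)
    return(out)
  }
  keys <- occurrences[by]
  if (complete) {
    grid <- do.call(expand.grid,
                    c(lapply(keys, function(x) sort(unique(x))),
                      list(stringsAsFactors = FALSE)))
    agg_key <- do.call(paste, c(keys, sep = "\r"))
    grid_key <- do.call(paste, c(grid, sep = "\r"))
    total <- as.integer(table(factor(agg_key, levels = grid_key)))
    meth <- as.integer(tapply(occurrences$methylated,
                              factor(agg_key, levels = grid_key), sum))
    meth[is.na(meth)] <- 0L
    out <- grid
  } else {
    agg_key <- do.call(paste, c(keys, sep = "\r"))
    lev <- sort(unique(agg_key))
    total <- as.integer(table(factor(agg_key, levels = lev)))
    meth <- as.integer(tapply(occurrences$methylated,
                              factor(agg_key, levels = lev), sum))
    out <- stats::setNames(as.data.frame(
      do.call(rbind, strsplit(lev, "\r", fixed = TRUE)),
      stringsAsFactors = FALSE), by)
  }
  for (k in setdiff(all_keys, by)) out[[k]] <- "ALL"
  out <- out[all_keys]
  out$methylated <- meth
  out$total <- total
  out$frequency <- ifelse(total > 0L, meth / total, NA_real_)
  rownames(out) <- NULL
  out
}

#' Core/shell classification of the pan-epigenome
#'
#' Classifies each motif by its methylation presence pattern across strains:
#' core when methylated in every strain of the panel, exclusive when
#' methylated in exactly one, shell otherwise (two or more but not all). A
#' motif methylated in no strain is labeled absent and excluded from the
#' core/shell counts. Presence in a strain defaults to at least one
#' methylated occurrence genome-wide; `min_frequency` sets a stricter rule
#' (frequency >= threshold), since near-zero frequencies may still count as
#' present.
#'
#' @param freq Genome-wide frequency table: one record per strain x motif
#'   (region and replicon_class "ALL"), from [methylation_frequency()].
#' @param strains Optional full strain panel; defaults to strains in `freq`.
#'   Needed when some strains have no occurrences of some motif.
#' @param min_frequency Presence threshold on frequency (default 0: any
#'   methylated occurrence).
#' @return A list of class `pan_epigenome_classification`: `presence`
#'   (motif x strain logical matrix), `summary` data frame (`motif_label`,
#'   `n_present`, `n_strains`, `label`).
#' @export
classify_pan_epigenome <- function(freq, strains = NULL, min_frequency = 0) {
  gw <- freq[freq$region == "ALL" & freq$replicon_class == "ALL", ,
             drop = FALSE]
  if (nrow(gw) == 0L) stop("no genome-wide (ALL/ALL) records in `freq`")
  if (is.null(strains)) strains <- sort(unique(gw$strain_id))
  motifs <- sort(unique(gw$motif_label))
  present <- matrix(FALSE, length(motifs), length(strains),
                    dimnames = list(motifs, strains))
  pres_rec <- if (min_frequency > 0) {
    !is.na(gw$frequency) & gw$frequency >= min_frequency
  } else {
    gw$methylated > 0L
  }
  present[cbind(match(gw$motif_label, motifs),
                match(gw$strain_id, strains))] <- pres_rec
  n_present <- rowSums(present)
  n <- length(strains)
  label <- ifelse(n_present == 0L, "absent",
                  ifelse(n_present == n, "core",
                         ifelse(n_present == 1L, "exclusive", "shell")))
  structure(
    list(presence = present,
         summary = data.frame(motif_label = motifs,
                              n_present = as.integer(n_present),
                              n_strains = n, label = label,
                              stringsAsFactors = FALSE)),
    class = "pan_epigenome_classification"
  )
}

#' @export
print.pan_epigenome_classification <- function(x, ...) {
  counts <- table(factor(x$summary$label,
                         levels = c("core", "shell", "exclusive", "absent")))
  cat(sprintf(
    "<pan_epigenome_classification> %d motifs across %d strains:\n",
    nrow(x$summary), x$summary$n_strains[1L]))
  cat(sprintf("  core: %d  shell: %d  exclusive: %d  absent: %d\n",
              counts["core"], counts["shell"], counts["exclusive"],
              counts["absent"]))
  if (counts["exclusive"] == 0L) {
    cat("  No strain-exclusive methylated motif was found.\n")
  }
  invisible(x)
}

#' Normalized root-mean-square deviation (coefficient-of-variation form)
#'
#' `sqrt(mean((x - mean(x))^2)) / mean(x)`: the root-mean-square deviation
#' about the mean, normalized by the mean. Low values indicate low
#' strain-to-strain variability. Scale-invariant: `nrmsd(c*x) == nrmsd(x)`
#' for c > 0. With `normalizer = "range"` the RMSD is divided by
#' `max(x) - min(x)` instead.
#'
#' @param x Numeric vector, length >= 2, no missing values.
#' @param normalizer "mean" (default) or "range".
#' @return Non-negative scalar; `NA` when the normalizer is 0 (undefined).
#' @export
nrmsd <- function(x, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  if (length(x) < 2L) stop("nrmsd needs at least 2 values")
  if (anyNA(x)) stop("nrmsd: missing values not allowed")
  rmsd <- sqrt(mean((x - mean(x))^2))
  denom <- switch(normalizer, mean = mean(x), range = diff(range(x)))
  if (denom == 0) {
    if (rmsd == 0) return(0) else return(NA_real_)
  }
  rmsd / denom
}

#' NRMSD matrix of frequencies across strains
#'
#' For each motif x group cell (group = region category or replicon class),
#' computes the NRMSD of the per-strain methylation frequencies: the
#' strain-to-strain variability of that motif in that genomic context.
#'
#' @param freq Frequency table grouped by strain, motif and one of `region`
#'   or `replicon_class`.
#' @param group Column to spread over: "region" or "replicon_class".
#' @param normalizer Passed to [nrmsd()].
#' @return Numeric matrix, motifs x groups; cells with fewer than 2 strain
#'   values are NA. Attribute `normalizer` records the choice.
#' @export
nrmsd_matrix <- function(freq, group = c("region", "replicon_class"),
                         normalizer = c("mean", "range")) {
  group <- match.arg(group)
  normalizer <- match.arg(normalizer)
  sub <- freq[!is.na(freq$frequency) & freq[[group]] != "ALL", , drop = FALSE]
  motifs <- sort(unique(sub$motif_label))
  groups <- sort(unique(sub[[group]]))
  m <- matrix(NA_real_, length(motifs), length(groups),
              dimnames = list(motifs, groups))
  for (i in seq_along(motifs)) {
    for (j in seq_along(groups)) {
      v <- sub$frequency[sub$motif_label == motifs[i] &
                           sub[[group]] == groups[j]]
      if (length(v) >= 2L) m[i, j] <- nrmsd(v, normalizer)
    }
  }
  attr(m, "normalizer") <- normalizer
  m
}

#' Z-score scaling of a matrix along rows or columns
#'
#' Centers and scales by the sample standard deviation. Zero-variance rows
#' or columns map to all zeros, with a warning, rather than NaN.
#'
#' @param m Numeric matrix.
#' @param axis "row" or "column".
#' @return The scaled matrix.
#' @export
scale_matrix <- function(m, axis = c("row", "column")) {
  axis <- match.arg(axis)
  if (axis == "row") {
    if (ncol(m) < 2L) stop("need >= 2 entries along the scaled axis")
    t(apply(m, 1L, .zscore))
  } else {
    if (nrow(m) < 2L) stop("need >= 2 entries along the scaled axis")
    apply(m, 2L, .zscore)
  }
}

.zscore <- function(v) {
  s <- stats::sd(v, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    warning("zero-variance vector scaled to all zeros")
    return(ifelse(is.na(v), NA_real_, 0))
  }
  (v - mean(v, na.rm = TRUE)) / s
}

#' PCA explained variance and variable contributions
#'
#' Principal component analysis of an entity x variable matrix (e.g. strain
#' x region-frequency), with the percentage contribution of each variable to
#' each component: `100 * loading^2 / sum(loadings^2)`, which sums to 100
#' per PC. Missing cells are imputed to the column mean (with a message)
#' before decomposition.
#'
#' @param m Numeric matrix, >= 2 rows and columns.
#' @param center,scale Passed to [stats::prcomp()]; scaling is the default
#'   because frequencies differ in magnitude across motifs/regions.
#' @return List: `explained_variance` (percent per PC), `contributions`
#'   (variable x PC matrix, percent), `loadings`, `sdev`.
#' @export
pca_contributions <- function(m, center = TRUE, scale = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need a matrix of at least 2 x 2")
  if (anyNA(m)) {
    message("imputing ", sum(is.na(m)), " missing cell(s) to column means")
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      m[is.na(v), j] <- mean(v, na.rm = TRUE)
    }
  }
  if (scale) {
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant column(s) cannot be scaled: ",
           paste(colnames(m)[sds == 0], collapse = ", "))
    }
  }
  p <- stats::prcomp(m, center = center, scale. = scale)
  ev <- 100 * p$sdev^2 / sum(p$sdev^2)
  contrib <- 100 * sweep(p$rotation^2, 2L, colSums(p$rotation^2), "/")
  list(explained_variance = ev, contributions = contrib,
       loadings = p$rotation, sdev = p$sdev)
}

#' Kruskal-Wallis test with Dunn's post hoc pairwise comparisons
#'
#' Computes the Kruskal-Wallis rank-sum statistic (via
#' [stats::kruskal.test()]) and then Dunn's z for every group pair:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))`
#' with tie correction `T = sum(t^3 - t) / (12 (N - 1))` over tied groups of
#' size t. Two-sided p-values from the standard normal, adjusted for
#' multiple comparisons (Holm by default).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coerced to factor).
#' @param p_adjust Adjustment method for [stats::p.adjust()].
#' @return List of class `kruskal_dunn`: `kw_statistic`, `kw_p`,
#'   `comparisons` data frame (`group_i`, `group_j`, `z`, `p`, `p_adjusted`,
#'   `significant` at p_adjusted < 0.001).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (anyNA(values)) {
    groups <- groups[!is.na(values)]
    values <- values[!is.na(values)]
    groups <- droplevels(groups)
    if (nlevels(groups) < 2L) stop("need at least 2 groups")
  }
  if (length(unique(values)) == 1L) {
    ## degenerate: every observation tied; H is 0 by convention
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0), p.value = 1)
  } else {
    kw <- stats::kruskal.test(values, groups)
  }
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  tie_sizes <- table(values)
  Tcorr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(seq_along(lev), 2L)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[i] + 1 / n[j]))
    z[k] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  }
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = p_adjust)
  structure(
    list(kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
         p_adjust = p_adjust,
         comparisons = data.frame(
           group_i = lev[pairs[1L, ]], group_j = lev[pairs[2L, ]],
           z = z, p = p, p_adjusted = padj,
           significant = padj < 0.001,
           stringsAsFactors = FALSE)),
    class = "kruskal_dunn"
  )
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, p = %.4g (%s-adjusted Dunn pairs)\n",
              x$kw_statistic, x$kw_p, x$p_adjust))
  print(x$comparisons, digits = 4)
  invisible(x)
}
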