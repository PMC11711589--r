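#' Read a donor x recipient transformation-ratio table
#'
#' Tab-separated with header `donor`, `recipient`, `ratio` (plasmid
#' acquisition ratio, e.g. transformants per input DNA, in any unit that is
#' consistent within a recipient).
#'
#' @param path Path to the TSV.
#' @return Data frame with the three columns.
#' @export
read_transfer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("donor", "recipient", "ratio")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("transfer table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(tab$ratio < 0, na.rm = TRUE)) stop("negative acquisition ratio")
  tab[, req]
}

#' log10 fold change of plasmid acquisition ratios against self-DNA
#'
#' For donor d and recipient r, `log10(ratio(d, r) / ratio(r, r))`: how much
#' better or worse DNA methylated by strain d transforms into strain r than
#' r's own DNA. The diagonal is 0 by construction. A zero nonself ratio
#' (no transformants obtained) yields -Inf, serialized as the literal token
#' "-Inf" in TSV output. Rows are donors, columns recipients.
#'
#' @param transfers Data frame from [read_transfer_table()].
#' @return Numeric donor x recipient matrix of log10 fold changes.
#' @export
log10_fold_change <- function(transfers) {
  donors <- sort(unique(transfers$donor))
  recipients <- sort(unique(transfers$recipient))
  ratio <- matrix(NA_real_, length(donors), length(recipients),
                  dimnames = list(donors, recipients))
  ratio[cbind(match(transfers$donor, donors),
              match(transfers$recipient, recipients))] <- transfers$ratio
  for (r in recipients) {
    self <- if (r %in% donors) ratio[r, r] else NA_real_
    if (is.na(self) || self <= 0) {
      stop("missing or zero self-ratio for recipient ", r)
    }
  }
  fc <- log10(sweep(ratio, 2L, ratio[cbind(recipients, recipients)], "/"))
  fc
}

#' Write a fold-change matrix as TSV with "-Inf" tokens
#'
#' @param fc Matrix from [log10_fold_change()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_transfer_matrix <- function(fc, path) {
  df <- data.frame(donor = rownames(fc),
                   apply(fc, 2L, function(v)
                     ifelse(is.infinite(v) & v < 0, "-Inf",
                            format(v, trim = TRUE))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
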