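# Tab-separated readers/writers for the tables exchanged between stages.

#' Write decay series to a tab-separated peak-list table
#'
#' One row per (residue, delay) observation with columns `experiment`
#' (`r1` or `r1rho`), `residue`, `delay_ms`, `volume`, `sigma`.
#'
#' @param dataset a `"relax_dataset"` (see [generate_dataset()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_decay_table <- function(dataset, file) {
  flat <- function(decays, label) {
    do.call(rbind, lapply(decays, function(d)
      data.frame(experiment = label, residue = d$residue_index,
                 delay_ms = d$delays * 1000, volume = d$volumes,
                 sigma = d$sigma)))
  }
  tab <- rbind(flat(dataset$decays_r1, "r1"),
               flat(dataset$decays_r1rho, "r1rho"))
  utils::write.table(tab, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read a decay table written by [write_decay_table()]
#'
#' @param file path to the tab-separated table.
#' @return list with `decays_r1` and `decays_r1rho`: lists of
#'   [decay_series()] keyed by residue.
#' @export
read_decay_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t")
  split_one <- function(lab) {
    sub <- tab[tab$experiment == lab, ]
    out <- lapply(split(sub, sub$residue), function(d)
      decay_series(d$residue[1], d$delay_ms / 1000, d$volume,
                   d$sigma[1]))
    out[order(as.integer(names(out)))]
  }
  list(decays_r1 = split_one("r1"), decays_r1rho = split_one("r1rho"))
}

#' Write a NOE saturation-pair table
#'
#' @param dataset a `"relax_dataset"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_noe_table <- function(dataset, file) {
  utils::write.table(dataset$noe_pairs, file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write / read a rates table
#'
#' Plain TSV with the `"rates_table"` columns (see [extract_rates()]).
#'
#' @param rates a `"rates_table"`.
#' @param file path.
#' @return `file` (writer) or a `"rates_table"` (reader).
#' @export
write_rates_table <- function(rates, file) {
  utils::write.table(rates, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_rates_table
#' @export
read_rates_table <- function(file) {
  out <- utils::read.table(file, header = TRUE, sep = "\t")
  class(out) <- c("rates_table", "data.frame")
  out
}

#' Write ground truth as a plain-text key-value table
#'
#' @param truth a `"truth_profile"` (see [generate_profile()]).
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_truth_table <- function(truth, file) {
  utils::write.table(truth, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Write model-free results as TSV
#'
#' @param fit a `"model_free"` object.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_modelfree_table <- function(fit, file) {
  utils::write.table(fit$results, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
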