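# Small text-format writers/readers rounding out the module interfaces.

#' Read intein site annotations from TSV
#'
#' Columns `site`, `start`, `end` (0-based, half-open alignment-column
#' intervals of the intein blocks).
#'
#' @param file Path to a tab-separated file.
#' @return A data frame suitable for [annotated_alignment()].
#' @export
read_sites <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("site", "start", "end") %in% names(df)))
    stop2("site annotation TSV needs columns site, start, end")
  df
}

#' Write a flank count matrix to TSV
#'
#' Rows are residues, columns flank positions (`-w..-1`, `+1..+w`), plus a
#' final `coverage` row.
#'
#' @param fm A `"flank_matrix"` from [extract_flanks()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_flank_matrix <- function(fm, file) {
  stopifnot(inherits(fm, "flank_matrix"))
  out <- rbind(fm$counts, coverage = fm$coverage)
  utils::write.table(data.frame(residue = rownames(out), out,
                                check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write logo data to a long-format TSV
#'
#' One row per (position, residue) with the residue frequency and the
#' column's information content, consumable by standard logo plotters.
#'
#' @param ld A `"logo_data"` object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_logo_data <- function(ld, file) {
  stopifnot(inherits(ld, "logo_data"))
  long <- do.call(rbind, lapply(seq_len(ncol(ld$freq)), function(j) {
    pos <- colnames(ld$freq)[j]
    data.frame(position = pos, residue = rownames(ld$freq),
               freq = ld$freq[, j],
               ic = ld$columns$ic[ld$columns$position == pos])
  }))
  utils::write.table(long, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a pattern distribution to JSON
#'
#' @param pd A `"pattern_distribution"` (ideally from
#'   [expected_independent()] so both observed and expected are present).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_pattern_distribution <- function(pd, file) {
  stopifnot(inherits(pd, "pattern_distribution"))
  jsonlite::write_json(list(n = pd$n, marginal = as.list(pd$marginal),
                            patterns = pd$patterns),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Write a fitted model to JSON
#'
#' Serializes an `intein_fit` (rates keyed by transition label, lnL, k, n,
#' AICc, per-restart optima, root prior, bounds, seed).
#'
#' @param fit An `"intein_fit"` from [fit_model()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  stopifnot(inherits(fit, "intein_fit"))
  jsonlite::write_json(list(
    model = fit$model, rates = as.list(fit$rates), lnL = fit$lnL,
    k = fit$k, n = fit$n, AICc = fit$AICc,
    restart_lnL = fit$restarts$lnL, converged = fit$converged,
    root_prior = if (is.character(fit$pi)) fit$pi else "user",
    bounds = as.list(fit$bounds), seed = fit$seed),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Dump a rate matrix to TSV
#'
#' @param Q A rate matrix (e.g. rebuilt from a fit's rates with
#'   [build_rate_matrix()]).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_rate_matrix <- function(Q, file) {
  utils::write.table(data.frame(from = rownames(Q), Q, check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
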