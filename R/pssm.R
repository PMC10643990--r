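#' Build a position-specific scoring matrix from an aligned block
#'
#' Log-odds scores in bits:
#' `s(p, aa) = log2((c(p, aa) + alpha * b(aa)) / ((n_p + alpha) * b(aa)))`,
#' where `c(p, aa)` are the ungapped residue counts in column `p`, `n_p`
#' the ungapped count of the column, `b` the background frequencies, and
#' `alpha` the total pseudocount mass (distributed proportionally to the
#' background).
#'
#' @param block Character vector of >= 2 equal-length aligned sequences
#'   (the conserved block; gaps allowed and excluded from counts).
#' @param background Named numeric vector of background frequencies over
#'   the 20 amino acids (default uniform 1/20).
#' @param alpha Pseudocount mass, > 0 (default 1).
#' @param name Optional block name stored in the PSSM metadata.
#' @return An object of class `"pssm"`: `scores` (L x 20 matrix, bits),
#'   `length`, `name`, `alpha`, `background`, and `consensus_score` (the
#'   maximum attainable window score).
#' @export
build_pssm <- function(block, background = NULL, alpha = 1, name = "block") {
  block <- toupper(as.character(block))
  if (length(block) < 2L) stop2("need at least 2 sequences in the block")
  L <- unique(nchar(block))
  if (length(L) != 1L || L < 1L) stop2("block sequences must share a length >= 1")
  if (alpha <= 0) stop2("pseudocount alpha must be > 0")
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20]
  if (anyNA(background) || any(background <= 0))
    stop2("background must give a positive frequency for all 20 amino acids")
  background <- background / sum(background)

  mat <- do.call(rbind, strsplit(block, ""))
  scores <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  for (p in seq_len(L)) {
    col <- mat[, p]
    col <- col[col %in% AA20]
    np <- length(col)
    cnt <- table(factor(col, levels = AA20))
    scores[p, ] <- log2((as.numeric(cnt) + alpha * background) /
                          ((np + alpha) * background))
  }
  structure(list(scores = scores, length = L, name = name, alpha = alpha,
                 background = background,
                 consensus_score = sum(apply(scores, 1L, max))),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cons <- AA20[apply(x$scores, 1L, which.max)]
  cat(sprintf("PSSM \"%s\": length %d, alpha = %g, consensus score %.2f bits\n",
              x$name, x$length, x$alpha, x$consensus_score))
  cat("  consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

# Score every window of `seq` (integer-encoded; NA = ambiguous, scores 0).
score_windows <- function(pssm, seq_idx) {
  L <- pssm$length
  n <- length(seq_idx) - L + 1L
  if (n < 1L) return(numeric(0))
  total <- numeric(n)
  for (p in seq_len(L)) {
    sc <- pssm$scores[p, seq_idx[p:(p + n - 1L)]]
    sc[is.na(sc)] <- 0
    total <- total + sc
  }
  total
}

encode_aa <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1L]], AA20)
  idx  # NA for X and other ambiguity codes -> neutral score 0
}

#' Scan a protein sequence with a PSSM
#'
#' Scores every window of the sequence and reports those at or above the
#' threshold. Overlapping reportable windows of the same PSSM are merged to
#' the best-scoring offset. Ambiguity codes (e.g. `X`) score 0.
#'
#' @param pssm A [build_pssm()] object.
#' @param seq A protein sequence (single string).
#' @param threshold Score threshold in bits; default 60% of the PSSM's
#'   consensus (maximum attainable) score.
#' @param id Sequence identifier carried into the hit table.
#' @return Data frame of hits: `seq`, `pssm`, `start` (1-based), `end`,
#'   `score`, sorted by `start`. Zero rows if nothing scores above
#'   threshold or the sequence is shorter than the PSSM (with a warning).
#' @export
scan_sequence <- function(pssm, seq, threshold = NULL, id = "seq") {
  stopifnot(inherits(pssm, "pssm"))
  if (is.null(threshold)) threshold <- 0.6 * pssm$consensus_score
  empty <- data.frame(seq = character(0), pssm = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0))
  idx <- encode_aa(seq)
  if (length(idx) < pssm$length) {
    warning("sequence \"", id, "\" shorter than PSSM \"", pssm$name, "\"")
    return(empty)
  }
  sc <- score_windows(pssm, idx)
  hit <- which(sc >= threshold)
  if (!length(hit)) return(empty)
  # merge chains of mutually overlapping windows to the best-scoring offset
  keep <- integer(0)
  run_best <- hit[1L]; prev <- hit[1L]
  for (h in hit[-1L]) {
    if (h <= prev + pssm$length - 1L) {
      if (sc[h] > sc[run_best]) run_best <- h
    } else {
      keep <- c(keep, run_best)
      run_best <- h
    }
    prev <- h
  }
  keep <- c(keep, run_best)
  out <- data.frame(seq = id, pssm = pssm$name, start = keep,
                    end = keep + pssm$length - 1L, score = sc[keep])
  out[order(out$start), , drop = FALSE]
}

#' Scan a proteome with a set of PSSMs
#'
#' @param pssms List of [build_pssm()] objects.
#' @param seqs Named character vector of protein sequences.
#' @param threshold Either `NULL` (per-PSSM default, 60% of consensus
#'   score) or a single threshold in bits applied to all PSSMs.
#' @return Combined hit data frame (see [scan_sequence()]).
#' @export
scan_proteome <- function(pssms, seqs, threshold = NULL) {
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  out <- list()
  for (i in seq_along(seqs)) {
    for (ps in pssms) {
      out[[length(out) + 1L]] <-
        scan_sequence(ps, seqs[[i]], threshold = threshold,
                      id = names(seqs)[i])
    }
  }
  do.call(rbind, out)
}

#' Collapse PSSM hits into intein calls
#'
#' Hits on the same sequence (from any intein PSSM) whose windows lie
#' within `merge_gap` residues of one another collapse into a single
#' intein region; an intein spans far more residues than any one conserved
#' block, so nearby blocks belong to one element.
#'
#' @param hits Hit data frame from [scan_proteome()]/[scan_sequence()].
#' @param merge_gap Maximum residue gap between hits merged into one
#'   region (default 150).
#' @return Data frame of calls: `seq`, `intein` (index within sequence),
#'   `start`, `end`, `n_hits`, `best_score`.
#' @export
call_inteins <- function(hits, merge_gap = 150L) {
  cols <- c("seq", "intein", "start", "end", "n_hits", "best_score")
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- data.frame(seq = character(0), intein = integer(0),
                      start = integer(0), end = integer(0),
                      n_hits = integer(0), best_score = numeric(0))
    return(out)
  }
  out <- list()
  for (sq in unique(hits$seq)) {
    h <- hits[hits$seq == sq, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(h$start[-1L] - cummax_end(h)[-nrow(h)] >
                                     merge_gap)))
    for (g in unique(grp)) {
      hg <- h[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        seq = sq, intein = g, start = min(hg$start), end = max(hg$end),
        n_hits = nrow(hg), best_score = max(hg$score))
    }
  }
  do.call(rbind, out)
}

cummax_end <- function(h) cummax(h$end)

#' Classify intein calls as full or mini by HEN detection
#'
#' A call is a full intein if at least one of the homing-endonuclease
#' (HEN) block PSSMs scores at or above threshold within the call region
#' (padded by `pad` residues); otherwise it is a mini-intein (splicing
#' domain only).
#'
#' @param calls Call data frame from [call_inteins()].
#' @param seqs Named character vector of the scanned protein sequences.
#' @param hen_pssms List of HEN block PSSMs.
#' @param threshold `NULL` for the per-PSSM default, or a single value in
#'   bits.
#' @param pad Residues of context added around each call when searching
#'   for HEN blocks (default 50).
#' @return The call data frame with added columns `category`
#'   (`"full"`/`"mini"`) and `hen_blocks` (comma-separated names of the
#'   HEN blocks detected).
#' @export
classify_hen <- function(calls, seqs, hen_pssms, threshold = NULL,
                         pad = 50L) {
  if (nrow(calls) == 0L) {
    calls$category <- character(0)
    calls$hen_blocks <- character(0)
    return(calls)
  }
  if (inherits(hen_pssms, "pssm")) hen_pssms <- list(hen_pssms)
  calls$category <- "mini"
  calls$hen_blocks <- ""
  for (i in seq_len(nrow(calls))) {
    s <- seqs[[calls$seq[i]]]
    a <- max(1L, calls$start[i] - pad)
    b <- min(nchar(s), calls$end[i] + pad)
    region <- substr(s, a, b)
    found <- character(0)
    for (ps in hen_pssms) {
      hh <- suppressWarnings(
        scan_sequence(ps, region, threshold = threshold, id = calls$seq[i]))
      if (nrow(hh)) found <- c(found, ps$name)
    }
    if (length(found)) {
      calls$category[i] <- "full"
      calls$hen_blocks[i] <- paste(found, collapse = ",")
    }
  }
  calls
}

#' Group summary of intein calls
#'
#' Summarizes classified calls per taxon group in the style of a survey
#' table: genes carrying more than one intein versus exactly one, and the
#' percentage of inteins with a detectable HEN in each class (denominators
#' are intein counts, not gene counts).
#'
#' @param calls Classified call data frame ([classify_hen()]); one row per
#'   intein with columns `seq` (gene id) and `category`.
#' @param groups Named character vector mapping each gene id to its group.
#' @return Data frame per group: `group`, `multi_genes`,
#'   `multi_inteins`, `pct_multi_hen`, `single_genes`, `pct_single_hen`
#'   (percentages are `NA` when the denominator is zero).
#' @export
group_summary <- function(calls, groups) {
  if (is.null(names(groups))) stop2("groups must be named by gene id")
  miss <- setdiff(unique(calls$seq), names(groups))
  if (length(miss))
    stop2("no group label for gene(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (g in unique(groups)) {
    genes <- names(groups)[groups == g]
    cg <- calls[calls$seq %in% genes, , drop = FALSE]
    per_gene <- table(cg$seq)
    multi_genes <- names(per_gene)[per_gene >= 2L]
    single_genes <- names(per_gene)[per_gene == 1L]
    cm <- cg[cg$seq %in% multi_genes, , drop = FALSE]
    cs <- cg[cg$seq %in% single_genes, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      group = g,
      multi_genes = length(multi_genes),
      multi_inteins = nrow(cm),
      pct_multi_hen = if (nrow(cm)) 100 * mean(cm$category == "full")
                      else NA_real_,
      single_genes = length(single_genes),
      pct_single_hen = if (nrow(cs)) 100 * mean(cs$category == "full")
                       else NA_real_)
  }
  do.call(rbind, out)
}
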