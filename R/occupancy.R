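#' Construct a taxon-by-site intein occupancy table
#'
#' @param presence Logical matrix (or data frame of 0/1), rows = taxa with
#'   unique row names, columns = insertion sites (conventionally
#'   `a`, `b`, `c`, `d`).
#' @param mini Optional logical matrix of the same shape flagging
#'   mini-inteins (intein present but no detectable homing endonuclease).
#'   A mini-intein counts as present for all occupancy purposes; the flag
#'   is carried separately.
#' @param genus Optional character vector of per-taxon genus labels.
#' @return An object of class `"occupancy_table"`.
#' @export
occupancy_table <- function(presence, mini = NULL, genus = NULL) {
  presence <- as.matrix(presence)
  if (is.numeric(presence)) {
    if (!all(presence %in% c(0, 1))) stop2("presence cells must be 0/1")
    presence <- presence == 1
  }
  if (!is.logical(presence)) stop2("presence must be logical or 0/1")
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop2("presence needs taxon row names and site column names")
  if (anyDuplicated(rownames(presence)))
    stop2("duplicate taxon labels: ",
          paste(unique(rownames(presence)[duplicated(rownames(presence))]),
                collapse = ", "))
  if (anyNA(presence)) stop2("every cell must be present/absent (no NA)")
  if (nrow(presence) < 1L) stop2("table must have at least one taxon")
  if (!is.null(mini)) {
    mini <- as.matrix(mini) == TRUE
    if (!identical(dim(mini), dim(presence)))
      stop2("mini flag matrix must match the presence matrix shape")
    if (any(mini & !presence))
      stop2("mini-intein flagged at a site marked absent")
  }
  if (!is.null(genus)) {
    if (length(genus) != nrow(presence))
      stop2("genus labels must match the taxon count")
    genus <- stats::setNames(as.character(genus), rownames(presence))
  }
  structure(list(presence = presence, mini = mini, genus = genus),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("occupancy table: %d taxa x %d sites (%s)\n",
              nrow(x$presence), ncol(x$presence),
              paste(colnames(x$presence), collapse = ", ")))
  cat("  per-site presence:",
      paste(sprintf("%s=%d", colnames(x$presence), colSums(x$presence)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read an occupancy table from TSV
#'
#' Expects a header row. The first column (or a column named `taxon`) holds
#' taxon labels; a column named `genus` (if any) holds genus labels; all
#' remaining columns are insertion sites. Cells may be `0`/`1`,
#' `absent`/`present`, or `-`/`full`/`mini` (a `mini` cell is present with
#' the mini-intein flag set).
#'
#' @param file Path to a tab-separated file.
#' @return An [occupancy_table()].
#' @export
read_occupancy <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop2("empty occupancy table: ", file)
  taxcol <- if ("taxon" %in% names(df)) "taxon" else names(df)[1L]
  taxa <- df[[taxcol]]
  genus <- if ("genus" %in% names(df)) df[["genus"]] else NULL
  sites <- setdiff(names(df), c(taxcol, "genus"))
  if (!length(sites)) stop2("no site columns found")
  parse_cell <- function(v) {
    v <- tolower(trimws(v))
    pres <- v %in% c("1", "present", "full", "mini")
    abs_ <- v %in% c("0", "absent", "-")
    if (any(!pres & !abs_))
      stop2("unparseable cell value(s): ",
            paste(unique(v[!pres & !abs_]), collapse = ", "))
    list(present = pres, mini = v == "mini")
  }
  parsed <- lapply(df[sites], parse_cell)
  presence <- do.call(cbind, lapply(parsed, `[[`, "present"))
  mini <- do.call(cbind, lapply(parsed, `[[`, "mini"))
  dimnames(presence) <- dimnames(mini) <- list(taxa, sites)
  occupancy_table(presence, mini = if (any(mini)) mini else NULL,
                  genus = genus)
}

#' Write an occupancy table to TSV
#'
#' @param table An [occupancy_table()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_occupancy <- function(table, file) {
  stopifnot(inherits(table, "occupancy_table"))
  m <- ifelse(table$presence, "1", "0")
  if (!is.null(table$mini)) m[table$mini] <- "mini"
  df <- data.frame(taxon = rownames(table$presence), m,
                   check.names = FALSE)
  if (!is.null(table$genus)) df$genus <- table$genus
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

site_patterns <- function(sites) {
  ns <- length(sites)
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), ns)))[, ns:1, drop = FALSE]
  colnames(grid) <- sites
  grid
}

pattern_label <- function(grid) {
  apply(grid, 1L, function(r)
    paste(ifelse(r == 1L, toupper(colnames(grid)), "-"), collapse = ""))
}

#' Observed distribution of joint occupancy patterns
#'
#' Counts, over all taxa, each of the `2^S` presence/absence patterns
#' across the table's `S` sites, together with the per-site marginal
#' frequencies.
#'
#' @param table An [occupancy_table()].
#' @return A list of class `"pattern_distribution"`: data frame `patterns`
#'   (`pattern`, one indicator column per site, `observed`), vector
#'   `marginal` of per-site presence frequencies, and `n` (taxon count).
#' @export
count_patterns <- function(table) {
  stopifnot(inherits(table, "occupancy_table"))
  pres <- table$presence
  sites <- colnames(pres)
  grid <- site_patterns(sites)
  key <- apply(grid, 1L, paste, collapse = "")
  obs_key <- apply(pres * 1L, 1L, paste, collapse = "")
  counts <- table(factor(obs_key, levels = key))
  out <- data.frame(pattern = pattern_label(grid), grid,
                    observed = as.integer(counts), check.names = FALSE)
  structure(list(patterns = out,
                 marginal = colMeans(pres),
                 n = nrow(pres)),
            class = "pattern_distribution")
}

#' Expected pattern distribution under independent invasion
#'
#' Under the null that each site is invaded independently at its marginal
#' frequency `f_s`, the expected count of pattern `p` in `N` taxa is
#' `E_p = N * prod_s f_s^{p_s} (1 - f_s)^{1 - p_s}`. Expected counts are
#' reals and are never rounded.
#'
#' @param table An [occupancy_table()], or a `pattern_distribution` from
#'   [count_patterns()].
#' @return A `pattern_distribution` whose `patterns` data frame carries
#'   both `observed` and `expected` columns.
#' @export
expected_independent <- function(table) {
  pd <- if (inherits(table, "pattern_distribution")) table
        else count_patterns(table)
  sites <- names(pd$marginal)
  grid <- as.matrix(pd$patterns[, sites, drop = FALSE])
  f <- pd$marginal
  prob <- apply(grid, 1L, function(p) prod(ifelse(p == 1L, f, 1 - f)))
  pd$patterns$expected <- pd$n * prob
  pd
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("pattern distribution over %d taxa, sites: %s\n", x$n,
              paste(names(x$marginal), collapse = ", ")))
  print(x$patterns[x$patterns$observed > 0 |
                     (!is.null(x$patterns$expected) &
                        x$patterns$expected > 0.5), ],
        row.names = FALSE)
  invisible(x)
}

#' Exploratory chi-square comparison of observed and expected patterns
#'
#' Compares the observed pattern counts with the independence expectation
#' by Pearson's X^2 with `2^S - 1 - S` degrees of freedom (S marginal
#' frequencies estimated). This is exploratory: it ignores phylogenetic
#' non-independence of taxa, which the Markov model addresses properly.
#'
#' @param table An [occupancy_table()].
#' @return A list with `statistic`, `df`, and `p_value`.
#' @export
pattern_chisq <- function(table) {
  pd <- expected_independent(table)
  o <- pd$patterns$observed
  e <- pd$patterns$expected
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  s <- length(pd$marginal)
  df <- 2^s - 1L - s
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Project an occupancy table onto the four joint a/d states
#'
#' Sites other than `a` and `d` are ignored by the paired-trait Markov
#' model; mini-inteins count as present.
#'
#' @param table An [occupancy_table()] with sites `a` and `d`.
#' @return Named character vector over `"--"`, `"-D"`, `"A-"`, `"AD"`.
#' @export
to_ctmc_states <- function(table) {
  stopifnot(inherits(table, "occupancy_table"))
  pres <- table$presence
  if (!all(c("a", "d") %in% colnames(pres)))
    stop2("occupancy table must contain sites \"a\" and \"d\"")
  idx <- 1L + pres[, "d"] * 1L + pres[, "a"] * 2L
  stats::setNames(OCC_STATES[idx], rownames(pres))
}

#' Per-genus summary of a/d occupancy
#'
#' @param table An [occupancy_table()] with genus labels.
#' @return Data frame with one row per genus: counts of taxa carrying only
#'   the site-a intein, only the site-d intein, both, or neither, plus the
#'   genus total.
#' @export
genus_summary <- function(table) {
  stopifnot(inherits(table, "occupancy_table"))
  if (is.null(table$genus)) stop2("occupancy table has no genus labels")
  st <- to_ctmc_states(table)
  g <- table$genus[names(st)]
  tab <- table(genus = g, state = factor(st, levels = OCC_STATES))
  out <- data.frame(genus = rownames(tab),
                    a_only = as.integer(tab[, "A-"]),
                    d_only = as.integer(tab[, "-D"]),
                    both = as.integer(tab[, "AD"]),
                    neither = as.integer(tab[, "--"]))
  out$n <- out$a_only + out$d_only + out$both + out$neither
  out
}
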