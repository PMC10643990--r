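#' Read a protein multiple alignment
#'
#' Reads FASTA (via Biostrings when available, otherwise a minimal reader)
#' or NEXUS data blocks (via [ape::read.nexus.data]). Sequences are
#' returned as a named character vector of equal-length aligned rows.
#'
#' @param file Path to the alignment.
#' @param format `"auto"` (by extension/sniffing), `"fasta"`, or `"nexus"`.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L, warn = FALSE)
    format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus"
              else "fasta"
  }
  if (format == "nexus") {
    lst <- ape::read.nexus.data(file)
    seqs <- vapply(lst, function(s) paste(toupper(s), collapse = ""),
                   character(1))
  } else if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(file)
    ids <- sub("\\s.*$", "", names(aa))  # id = first header token
    seqs <- stats::setNames(toupper(as.character(aa)), ids)
  } else {
    seqs <- read_fasta_plain(file)
  }
  if (length(unique(nchar(seqs))) != 1L)
    stop2("alignment rows differ in length")
  seqs
}

read_fasta_plain <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop2("no FASTA records in ", file)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(toupper(lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, character(1))
  stats::setNames(gsub("\\s", "", seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param file Output path.
#' @param width Line wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, file, width = 70L) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}

#' An intein-annotated alignment
#'
#' Bundles an aligned set of protein sequences with the alignment-column
#' intervals occupied by each intein block. Intervals use 0-based,
#' half-open coordinates: the block occupies columns `[start, end)`; the
#' insertion point sits between the residue before `start` and the residue
#' at/after `end`. A sequence counts as invaded at a site when at least
#' `occupancy_threshold` of the block's columns are non-gap (robust to
#' ragged block ends).
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @param sites Data frame with columns `site`, `start`, `end` (0-based,
#'   half-open alignment-column interval of each intein block).
#' @param occupancy_threshold Fraction of non-gap block columns required to
#'   call a sequence invaded (default 0.5).
#' @return An object of class `"annotated_alignment"`.
#' @export
annotated_alignment <- function(seqs, sites, occupancy_threshold = 0.5) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop2("sequences must have unique names")
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop2("alignment rows differ in length")
  sites <- as.data.frame(sites)
  if (!all(c("site", "start", "end") %in% names(sites)))
    stop2("sites needs columns site, start, end")
  sites$start <- as.integer(sites$start)
  sites$end <- as.integer(sites$end)
  if (any(sites$start < 0L) || any(sites$end > len) ||
      any(sites$end <= sites$start))
    stop2("site intervals must satisfy 0 <= start < end <= alignment length")
  o <- order(sites$start)
  if (any(sites$end[o][-length(o)] > sites$start[o][-1L]))
    stop2("intein block intervals overlap")
  structure(list(seqs = seqs, sites = sites, length = len,
                 occupancy_threshold = occupancy_threshold),
            class = "annotated_alignment")
}

site_interval <- function(aln, site) {
  i <- match(site, aln$sites$site)
  if (is.na(i)) stop2("site \"", site, "\" is not annotated")
  c(start = aln$sites$start[i], end = aln$sites$end[i])
}

#' Invasion status of every sequence at a site
#'
#' @param aln An [annotated_alignment()].
#' @param site Site name.
#' @return Named logical vector: `TRUE` where the intein block is occupied.
#' @export
invasion_status <- function(aln, site) {
  stopifnot(inherits(aln, "annotated_alignment"))
  iv <- site_interval(aln, site)
  block <- substring(aln$seqs, iv["start"] + 1L, iv["end"])
  frac <- 1 - nchar(gsub("[^-]", "", block)) / (iv["end"] - iv["start"])
  stats::setNames(frac >= aln$occupancy_threshold, names(aln$seqs))
}

# Walk outward from an insertion point, skipping gaps, collecting up to w
# residues on each side. Returns list(up, down) of residue vectors ordered
# away from the junction (up[1] is the -1 residue, down[1] the +1 residue).
walk_flanks <- function(seq, start0, end0, w) {
  chars <- strsplit(seq, "")[[1L]]
  up <- chars[seq_len(start0)]
  up <- rev(up[up != "-"])
  down <- if (end0 < length(chars)) chars[(end0 + 1L):length(chars)]
          else character(0)
  down <- down[down != "-"]
  list(up = up[seq_len(min(w, length(up)))],
       down = down[seq_len(min(w, length(down)))])
}

new_flank_matrix <- function(w, partition, site) {
  pos <- c(paste0("-", w:1), paste0("+", 1:w))
  counts <- matrix(0L, nrow = length(AA20), ncol = length(pos),
                   dimnames = list(AA20, pos))
  structure(list(counts = counts,
                 coverage = stats::setNames(integer(length(pos)), pos),
                 n_seq = 0L, partition = partition, site = site, w = w),
            class = "flank_matrix")
}

#' Extract insertion-site flank composition
#'
#' For each sequence, walks outward from the insertion point of `site`,
#' skipping alignment gaps, and collects up to `w` residues on each side
#' ("residues, not columns"). Sequences are partitioned by invasion status
#' at the site, and per-position residue counts are accumulated for each
#' partition. Sequences with fewer than `w` available residues on a side
#' contribute reduced coverage at the outer positions (with a warning).
#'
#' @param aln An [annotated_alignment()].
#' @param site Site name.
#' @param w Flank width in residues (default 20).
#' @return List with elements `invaded` and `uninvaded`, each a
#'   `"flank_matrix"`: a 20-residue by `2w`-position count matrix (positions
#'   `-w..-1`, `+1..+w`), per-position coverage, and the partition size.
#' @export
extract_flanks <- function(aln, site, w = 20L) {
  stopifnot(inherits(aln, "annotated_alignment"))
  if (w < 1L) stop2("flank width w must be >= 1")
  iv <- site_interval(aln, site)
  inv <- invasion_status(aln, site)
  fms <- list(invaded = new_flank_matrix(w, "invaded", site),
              uninvaded = new_flank_matrix(w, "uninvaded", site))
  short <- character(0)
  for (nm in names(aln$seqs)) {
    fl <- walk_flanks(aln$seqs[[nm]], iv["start"], iv["end"], w)
    if (length(fl$up) < w || length(fl$down) < w) short <- c(short, nm)
    part <- if (inv[[nm]]) "invaded" else "uninvaded"
    fm <- fms[[part]]
    fm$n_seq <- fm$n_seq + 1L
    for (i in seq_along(fl$up)) {
      p <- paste0("-", i)
      if (fl$up[i] %in% AA20) {
        fm$counts[fl$up[i], p] <- fm$counts[fl$up[i], p] + 1L
        fm$coverage[p] <- fm$coverage[p] + 1L
      }
    }
    for (i in seq_along(fl$down)) {
      p <- paste0("+", i)
      if (fl$down[i] %in% AA20) {
        fm$counts[fl$down[i], p] <- fm$counts[fl$down[i], p] + 1L
        fm$coverage[p] <- fm$coverage[p] + 1L
      }
    }
    fms[[part]] <- fm
  }
  if (length(short))
    warning("sequences with fewer than w = ", w, " flank residues: ",
            paste(short, collapse = ", "))
  fms
}

#' @export
print.flank_matrix <- function(x, ...) {
  cat(sprintf("flank matrix, site \"%s\", partition %s: %d sequences, w = %d\n",
              x$site, x$partition, x$n_seq, x$w))
  invisible(x)
}

#' Sequence-logo data for a flank matrix
#'
#' Per-position residue frequencies and information content
#' `IC = log2(20) - H - e_n`, with Shannon entropy `H` in bits and the
#' small-sample correction `e_n = 19 / (2 ln(2) n)`; negative corrected IC
#' clamps to zero. Positions with zero coverage are omitted with a warning.
#'
#' @param fm A `"flank_matrix"` from [extract_flanks()].
#' @return A list of class `"logo_data"`: data frame `columns` (`position`,
#'   `coverage`, `entropy`, `ic`) and matrix `freq` (residues x positions).
#' @export
logo_data <- function(fm) {
  stopifnot(inherits(fm, "flank_matrix"))
  keep <- fm$coverage > 0L
  if (any(!keep))
    warning("positions with zero coverage omitted: ",
            paste(names(fm$coverage)[!keep], collapse = ", "))
  counts <- fm$counts[, keep, drop = FALSE]
  n <- fm$coverage[keep]
  freq <- sweep(counts, 2L, n, "/")
  H <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  en <- 19 / (2 * log(2) * n)
  ic <- pmax(log2(20) - H - en, 0)
  structure(list(columns = data.frame(position = colnames(counts),
                                      coverage = as.integer(n),
                                      entropy = as.numeric(H),
                                      ic = as.numeric(ic)),
                 freq = freq),
            class = "logo_data")
}

#' @export
print.logo_data <- function(x, ...) {
  print(x$columns, row.names = FALSE)
  invisible(x)
}

#' Residues immediately flanking an insertion point
#'
#' @param aln An [annotated_alignment()].
#' @param site Site name.
#' @param sequence Sequence name.
#' @return Character vector `c(minus1, plus1)`: the nearest ungapped
#'   residues before and after the insertion point.
#' @export
junction_residues <- function(aln, site, sequence) {
  stopifnot(inherits(aln, "annotated_alignment"))
  if (!sequence %in% names(aln$seqs))
    stop2("no sequence named \"", sequence, "\"")
  iv <- site_interval(aln, site)
  fl <- walk_flanks(aln$seqs[[sequence]], iv["start"], iv["end"], 1L)
  if (!length(fl$up)) stop2("sequence \"", sequence,
                            "\" is entirely gapped upstream of ", site)
  if (!length(fl$down)) stop2("sequence \"", sequence,
                              "\" is entirely gapped downstream of ", site)
  c(minus1 = fl$up[1L], plus1 = fl$down[1L])
}

#' Contingency table of +1 residues by invasion status
#'
#' The +1 residue (the first C-terminal extein residue) must be a
#' nucleophile (S, C, or T) for protein splicing; a proline blocks it. This
#' summary exposes the invaded/uninvaded dichotomy at a site without
#' attaching a test.
#'
#' @param invaded,uninvaded `"flank_matrix"` objects for the two partitions
#'   (as returned by [extract_flanks()]).
#' @return An integer matrix, residues (rows with any count) by partition.
#' @export
plus1_summary <- function(invaded, uninvaded) {
  stopifnot(inherits(invaded, "flank_matrix"),
            inherits(uninvaded, "flank_matrix"))
  if (invaded$n_seq == 0L || uninvaded$n_seq == 0L)
    stop2("both partitions must be nonempty")
  m <- cbind(invaded = invaded$counts[, "+1"],
             uninvaded = uninvaded$counts[, "+1"])
  m[rowSums(m) > 0, , drop = FALSE]
}
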