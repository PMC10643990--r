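#' Read a phylogenetic tree
#'
#' Reads a tree in Newick format, or extracts the embedded Newick tree(s)
#' from a NEXUS `trees` block. Branch lengths are required: downstream
#' likelihood computations are defined per unit branch length, so a tree
#' without lengths is rejected rather than silently assigned zeros.
#'
#' @param file Path to a Newick or NEXUS file, or `NULL` if `text` is given.
#' @param text A Newick string (alternative to `file`).
#' @return An [ape::phylo] object with branch lengths. Internal node labels
#'   (e.g. support values) are preserved verbatim in `node.label`.
#' @examples
#' tr <- read_tree(text = "((A:1,B:1):0.5,C:2);")
#' @export
read_tree <- function(file = NULL, text = NULL) {
  if (is.null(file) && is.null(text)) stop2("supply `file` or `text`")
  if (is.null(text)) {
    raw <- paste(readLines(file, warn = FALSE), collapse = "\n")
    if (grepl("^\\s*#NEXUS", raw, ignore.case = TRUE)) {
      tr <- ape::read.nexus(file)
      if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
      return(validate_tree(tr))
    }
    text <- raw
  }
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop2("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop2("Newick parse error: unparseable input")
  validate_tree(tr)
}

# Balanced-parenthesis pre-check so malformed input fails with a position.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop2("Newick parse error: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop2("Newick parse error: ", depth, " unclosed '(' at end of input")
  if (!grepl(";", text)) stop2("Newick parse error: missing terminal ';'")
  invisible(TRUE)
}

#' Validate a phylogeny for use in this package
#'
#' Checks tip-label uniqueness, presence and non-negativity of branch
#' lengths, and a minimum of two tips.
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop2("not a \"phylo\" object")
  if (ape::Ntip(tree) < 2L) stop2("tree must have at least 2 tips")
  lab <- tree$tip.label
  if (anyNA(lab) || any(!nzchar(lab))) stop2("empty tip labels are not allowed")
  dup <- unique(lab[duplicated(lab)])
  if (length(dup))
    stop2("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop2("tree has no branch lengths; lengths are required")
  if (anyNA(tree$edge.length)) stop2("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop2("negative branch lengths are not allowed")
  tree
}

#' Write a tree to Newick
#'
#' @param tree An [ape::phylo] object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths (default 12, ample
#'   for 1e-9 round-trip fidelity on trees of ordinary scale).
#' @return The Newick string (invisibly if written to `file`).
#' @export
write_tree <- function(tree, file = NULL, digits = 12L) {
  validate_tree(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths on the path between two tips.
#'
#' @param tree An [ape::phylo] object.
#' @param i,j Tip labels.
#' @return A single non-negative number; zero iff `i == j`.
#' @export
tip_distance <- function(tree, i, j) {
  validate_tree(tree)
  ii <- match(i, tree$tip.label)
  jj <- match(j, tree$tip.label)
  if (is.na(ii)) stop2("unknown tip label: ", i)
  if (is.na(jj)) stop2("unknown tip label: ", j)
  if (ii == jj) return(0)
  d <- ape::dist.nodes(tree)
  unname(d[ii, jj])
}
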