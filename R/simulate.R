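#' Simulate a birth-death (or Yule) tree
#'
#' Thin, seeded wrapper around [ape::rphylo()] producing a rooted tree with
#' the requested number of extant tips and branch lengths in time units.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate `lambda` (> `death`).
#' @param death Extinction rate `mu` (>= 0); 0 gives a Yule tree.
#' @param seed Integer seed; the same seed yields the identical tree.
#' @return A rooted [ape::phylo].
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = 1L) {
  if (n_tips < 2L) stop2("need at least 2 tips")
  if (!(birth > death) || death < 0)
    stop2("need birth > death >= 0")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = death,
                                    fossils = FALSE))
  validate_tree(tr)
}

#' Simulate an occupancy history along a tree (Gillespie)
#'
#' Evolves the four-state occupancy character from the root towards the
#' tips. Along each branch, waiting times to the next event are
#' exponential with rate `-Q[s, s]` and the next state is chosen with
#' probability proportional to `Q[s, .]`; every event is recorded.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param model A [transition_model()] or its name.
#' @param rates Per-transition rates in the model's declared order.
#' @param root_state Root state name (default `"--"`), or a probability
#'   vector over the four states to draw it from.
#' @param seed Integer seed.
#' @return A list of class `"sim_history"`: `tree`, `root_state`, `events`
#'   (data frame: `edge`, `time` along the branch, `from`, `to`),
#'   `tip_states` (named character), `node_states`, `model`, `rates`,
#'   `seed`.
#' @export
simulate_history <- function(tree, model = "no_cohoming", rates,
                             root_state = "--", seed = 1L) {
  if (is.character(model)) model <- transition_model(model)
  validate_tree(tree)
  # the display root is the simulation's ancestor; a basal polytomy (e.g.
  # a star tree) is acceptable here even though ape calls it unrooted
  Q <- build_rate_matrix(model, rates)
  states <- model$states
  nt <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  # preorder = reversed postorder: parents always precede children
  edges_pre <- rev(seq_len(nrow(tr$edge)))

  with_seed(seed, {
    if (is.numeric(root_state)) {
      root_idx <- sample.int(length(states), 1L, prob = root_state)
    } else {
      root_idx <- match(root_state, states)
      if (is.na(root_idx)) stop2("unknown root state: ", root_state)
    }
    node_states <- integer(nt + tr$Nnode)
    node_states[nt + 1L] <- root_idx
    ev <- list()
    for (e in edges_pre) {
      s <- node_states[tr$edge[e, 1L]]
      bl <- tr$edge.length[e]
      t <- 0
      times <- numeric(0); froms <- integer(0); tos <- integer(0)
      repeat {
        out_rate <- -Q[s, s]
        if (out_rate <= 0) break
        t <- t + stats::rexp(1L, out_rate)
        if (t > bl) break
        probs <- Q[s, ]
        probs[s] <- 0
        s_new <- sample.int(length(states), 1L, prob = probs)
        times <- c(times, t); froms <- c(froms, s); tos <- c(tos, s_new)
        s <- s_new
      }
      if (length(times))
        ev[[length(ev) + 1L]] <- data.frame(
          edge = e, time = times, from = states[froms], to = states[tos])
      node_states[tr$edge[e, 2L]] <- s
    }
    events <- if (length(ev)) do.call(rbind, ev)
              else data.frame(edge = integer(0), time = numeric(0),
                              from = character(0), to = character(0))
    structure(list(
      tree = tr, root_state = states[root_idx], events = events,
      tip_states = stats::setNames(states[node_states[seq_len(nt)]],
                                   tr$tip.label),
      node_states = states[node_states],
      model = model, rates = rates, seed = seed
    ), class = "sim_history")
  })
}

#' Replay a simulated history from the root
#'
#' Recomputes all node and tip states by applying the recorded events in
#' chronological order along each branch; by construction this must agree
#' exactly with the states stored in the history.
#'
#' @param history A `"sim_history"` from [simulate_history()].
#' @return Named character vector of tip states.
#' @export
replay_history <- function(history) {
  stopifnot(inherits(history, "sim_history"))
  tr <- history$tree
  states <- history$model$states
  nt <- ape::Ntip(tr)
  node_states <- integer(nt + tr$Nnode)
  node_states[nt + 1L] <- match(history$root_state, states)
  for (e in rev(seq_len(nrow(tr$edge)))) {
    s <- node_states[tr$edge[e, 1L]]
    ev <- history$events[history$events$edge == e, , drop = FALSE]
    if (nrow(ev)) {
      ev <- ev[order(ev$time), , drop = FALSE]
      if (any(diff(ev$time) < 0) || any(ev$time < 0) ||
          any(ev$time > tr$edge.length[e]))
        stop2("corrupt history: events outside branch interval")
      for (i in seq_len(nrow(ev))) {
        if (match(ev$from[i], states) != s)
          stop2("corrupt history: event chain broken on edge ", e)
        s <- match(ev$to[i], states)
      }
    }
    node_states[tr$edge[e, 2L]] <- s
  }
  stats::setNames(states[node_states[seq_len(nt)]], tr$tip.label)
}

#' Simulate a complete tree + tip-state dataset
#'
#' Bundles [simulate_tree()] and [simulate_history()] with per-component
#' sub-seeds derived from one master seed, so each component can be
#' regenerated independently.
#'
#' @param n_tips Number of tips (ignored if `tree` is supplied).
#' @param model Model name or [transition_model()].
#' @param rates Per-transition rates (recycled if a single value).
#' @param root_state Root state or probability vector.
#' @param birth,death Tree process rates.
#' @param seed Master seed.
#' @param tree Optional tree to reuse instead of simulating one.
#' @param dir Optional directory; if given, writes `tree.nwk` and
#'   `states.tsv` in pipeline input formats.
#' @return List: `tree`, `tip_states`, `history`, `rates` (named ground
#'   truth), `model`, `seed`.
#' @export
simulate_dataset <- function(n_tips = 100L, model = "no_cohoming", rates,
                             root_state = "--", birth = 1, death = 0,
                             seed = 1L, tree = NULL, dir = NULL) {
  if (is.character(model)) model <- transition_model(model)
  if (length(rates) == 1L) rates <- rep(rates, model$k)
  if (is.null(tree))
    tree <- simulate_tree(n_tips, birth, death, seed = derive_seed(seed, 1L))
  hist <- simulate_history(tree, model, rates, root_state,
                           seed = derive_seed(seed, 2L))
  out <- list(tree = hist$tree, tip_states = hist$tip_states,
              history = hist,
              rates = stats::setNames(rates, model$transitions$label),
              model = model, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tree(out$tree, file.path(dir, "tree.nwk"))
    ad <- out$tip_states
    df <- data.frame(taxon = names(ad),
                     a = as.integer(substr(ad, 1L, 1L) == "A"),
                     d = as.integer(substr(ad, 2L, 2L) == "D"))
    utils::write.table(df, file.path(dir, "states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

sample_aa <- function(n, freq = HALO_AA_FREQ) {
  sample(names(freq), n, replace = TRUE, prob = freq)
}

sample_from_dist <- function(dist) {
  # dist: named probability vector over residues (e.g. c(S = 0.9, P = 0.1))
  sample(names(dist), 1L, prob = dist)
}

#' Synthesize an intein-annotated alignment from tip states
#'
#' Emulates the structure of a real intein-aware protein alignment: a
#' shared extein scaffold (one master sequence, per-row point
#' substitutions) with one alignment block per insertion site. Rows whose
#' taxon is invaded at a site carry residues across the block; uninvaded
#' rows carry an all-gap block of the same width. The +1 residue (first
#' C-extein residue after the block) is drawn per invasion status, which
#' by default reproduces the serine/proline dichotomy observed at
#' invasion-prone sites: invaded rows always get `S`, uninvaded rows get
#' `P` with probability 0.9 (else `S`).
#'
#' @param tip_states Named character vector over `"--"`, `"-D"`, `"A-"`,
#'   `"AD"` (site `a` = first letter, site `d` = second).
#' @param extein_len Length of each extein segment flanking the blocks.
#' @param intein_len Width of each intein block.
#' @param invaded_plus1,uninvaded_plus1 Named probability vectors for the
#'   +1 residue in each partition.
#' @param subst_rate Per-residue substitution probability applied to the
#'   extein scaffold per row.
#' @param seed Integer seed.
#' @return A list: `aln` (an [annotated_alignment()] with sites `"a"` and
#'   `"d"`), and `truth` (the generating tip states).
#' @export
synth_alignment <- function(tip_states, extein_len = 60L, intein_len = 80L,
                            invaded_plus1 = c(S = 1),
                            uninvaded_plus1 = c(P = 0.9, S = 0.1),
                            subst_rate = 0.05, seed = 1L) {
  stopifnot(all(tip_states %in% OCC_STATES))
  ntax <- length(tip_states)
  with_seed(seed, {
    master <- sample_aa(3L * extein_len)
    seg <- list(seq_len(extein_len),
                extein_len + seq_len(extein_len),
                2L * extein_len + seq_len(extein_len))
    rows <- character(ntax)
    for (i in seq_len(ntax)) {
      ext <- master
      mut <- stats::runif(length(ext)) < subst_rate
      ext[mut] <- sample_aa(sum(mut))
      inv_a <- substr(tip_states[i], 1L, 1L) == "A"
      inv_d <- substr(tip_states[i], 2L, 2L) == "D"
      block_a <- if (inv_a) sample_aa(intein_len) else rep("-", intein_len)
      block_d <- if (inv_d) sample_aa(intein_len) else rep("-", intein_len)
      # +1 residue of each site = first residue of the following segment
      ext[seg[[2L]][1L]] <-
        sample_from_dist(if (inv_a) invaded_plus1 else uninvaded_plus1)
      ext[seg[[3L]][1L]] <-
        sample_from_dist(if (inv_d) invaded_plus1 else uninvaded_plus1)
      rows[i] <- paste(c(ext[seg[[1L]]], block_a, ext[seg[[2L]]],
                         block_d, ext[seg[[3L]]]), collapse = "")
    }
    names(rows) <- names(tip_states)
    sites <- data.frame(
      site = c("a", "d"),
      start = c(extein_len, 2L * extein_len + intein_len),
      end = c(extein_len + intein_len, 2L * (extein_len + intein_len)))
    list(aln = annotated_alignment(rows, sites), truth = tip_states)
  })
}

#' Built-in synthetic conserved-block alignments
#'
#' Fixed synthetic consensus sequences for three intein splicing-domain
#' blocks and four LAGLIDADG-family HEN blocks (these are constructed
#' sequences for testing, not curated natural blocks), expanded into small
#' block alignments by seeded point mutation of the consensus.
#'
#' @param n_variants Sequences per block alignment.
#' @param mut_rate Per-residue mutation probability in the variants.
#' @param seed Integer seed.
#' @return List with elements `intein` and `hen`, each a named list of
#'   character vectors (block alignments), plus attribute `"consensus"`.
#' @export
synth_blocks <- function(n_variants = 8L, mut_rate = 0.1, seed = 1L) {
  consensus <- list(
    intein = c(
      splice_N  = "CLSFDTEILTREGGLVSIEDLVGE",
      splice_M  = "GVVVHNCSPTKELVYDLTVEDAGE",
      splice_C  = "VYDLEVEGNHNFFANGILVHNSKS"),
    hen = c(
      hen_1 = "KAYLAGLIDADGSISKDG",
      hen_2 = "GFSLAGLIDADGHFEKRP",
      hen_3 = "TRLAGLIDGDGYFSTDSK",
      hen_4 = "DNWLAGFIDADGELRVRK"))
  mutate_block <- function(cons, off) {
    with_seed(derive_seed(seed, off), {
      vapply(seq_len(n_variants), function(i) {
        ch <- strsplit(cons, "")[[1L]]
        mut <- stats::runif(length(ch)) < mut_rate
        ch[mut] <- sample_aa(sum(mut))
        paste(ch, collapse = "")
      }, character(1))
    })
  }
  out <- list(
    intein = stats::setNames(
      lapply(seq_along(consensus$intein),
             function(i) mutate_block(consensus$intein[[i]], i)),
      names(consensus$intein)),
    hen = stats::setNames(
      lapply(seq_along(consensus$hen),
             function(i) mutate_block(consensus$hen[[i]], 10L + i)),
      names(consensus$hen)))
  attr(out, "consensus") <- consensus
  out
}

#' Synthesize a proteome with planted inteins
#'
#' Generates random host proteins (i.i.d. residues from a haloarchaea-like
#' composition) and plants full and/or mini inteins at known positions: a
#' full intein is the three splicing blocks with the four HEN blocks
#' between them (joined by random linkers), a mini-intein the splicing
#' blocks only. Inteins are planted by concatenation with host segments
#' long enough that distinct plants never merge into one call at the
#' default `merge_gap`.
#'
#' @param n_proteins Number of proteins.
#' @param n_full,n_mini Number of full / mini inteins to plant. Plants are
#'   assigned round-robin over the first proteins; if `n_full + n_mini`
#'   exceeds `n_proteins`, some proteins receive several inteins.
#' @param blocks Block set from [synth_blocks()] (regenerated from `seed`
#'   if omitted).
#' @param linker_len Length of linkers between blocks inside an intein.
#' @param segment_len Length of host segments between planted inteins.
#' @param seed Integer seed.
#' @return List: `seqs` (named character vector), `truth` (data frame
#'   `seq`, `start`, `end`, `category`), and `blocks`.
#' @export
synth_proteome <- function(n_proteins = 20L, n_full = 8L, n_mini = 5L,
                           blocks = NULL, linker_len = 15L,
                           segment_len = 200L, seed = 1L) {
  if (is.null(blocks)) blocks <- synth_blocks(seed = derive_seed(seed, 99L))
  cons <- attr(blocks, "consensus")
  make_intein <- function(category) {
    mid <- if (category == "full")
      unlist(lapply(cons$hen, function(h) c(h, paste(sample_aa(linker_len),
                                                     collapse = ""))))
    else paste(sample_aa(linker_len), collapse = "")
    paste(c(cons$intein[["splice_N"]],
            paste(sample_aa(linker_len), collapse = ""),
            cons$intein[["splice_M"]],
            mid,
            cons$intein[["splice_C"]]), collapse = "")
  }
  with_seed(seed, {
    cats <- c(rep("full", n_full), rep("mini", n_mini))
    host <- if (n_full + n_mini > 0)
      rep(seq_len(min(n_proteins, max(1L, n_proteins))),
          length.out = length(cats))
    else integer(0)
    plants <- split(cats, host)
    seqs <- character(n_proteins)
    truth <- list()
    for (i in seq_len(n_proteins)) {
      parts <- paste(sample_aa(segment_len), collapse = "")
      my <- plants[[as.character(i)]]
      if (!is.null(my)) {
        for (cat in my) {
          itn <- make_intein(cat)
          start <- nchar(parts) + 1L
          parts <- paste0(parts, itn,
                          paste(sample_aa(segment_len), collapse = ""))
          truth[[length(truth) + 1L]] <- data.frame(
            seq = paste0("prot", i), start = start,
            end = start + nchar(itn) - 1L, category = cat)
        }
      }
      seqs[i] <- parts
    }
    names(seqs) <- paste0("prot", seq_len(n_proteins))
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(seq = character(0), start = integer(0),
                             end = integer(0), category = character(0))
    list(seqs = seqs, truth = truth, blocks = blocks, seed = seed)
  })
}
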