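# A tiny hand-built alignment: 8-column extein, one 4-column intein block
# at columns [8, 12) (0-based, half-open), then 8 more extein columns.
mini_aln <- function() {
  seqs <- c(
    inv1   = "MAKVTDKRWWWWSGEVLTDE",  # invaded: block WWWW, -1 = R, +1 = S
    inv2   = "MAKVTDDRWWVWSGEVLTDE",  # invaded, one substituted block residue
    uninv1 = "MAKVTDKR----PGEVLTDE",  # uninvaded: +1 = P
    gappy  = "MAKVT--W----SG-VLTDE"   # gaps around the block: -1 walks to W
  )
  annotated_alignment(seqs, data.frame(site = "d", start = 8, end = 12))
}

test_that("block occupancy defines invasion status", {
  aln <- mini_aln()
  inv <- invasion_status(aln, "d")
  expect_true(inv[["inv1"]])
  expect_true(inv[["inv2"]])
  expect_false(inv[["uninv1"]])
  expect_false(inv[["gappy"]])  # 1 of 4 block columns filled < 50%
  expect_error(invasion_status(aln, "z"), "not annotated")
})

test_that("flank extraction walks residues outward, skipping gaps", {
  aln <- mini_aln()
  fl <- extract_flanks(aln, "d", w = 3)
  expect_equal(fl$invaded$n_seq, 2L)
  expect_equal(fl$uninvaded$n_seq, 2L)
  expect_equal(fl$invaded$counts["R", "-1"], 2L)
  expect_equal(fl$invaded$counts["S", "+1"], 2L)
  expect_equal(fl$uninvaded$counts["P", "+1"], 1L)
  # the gappy row's -1 residue is W right before the block; its -2 skips
  # two gap columns back to T
  expect_equal(fl$uninvaded$counts["W", "-1"], 1L)
  expect_equal(fl$uninvaded$counts["T", "-2"], 1L)
  # coverage sums match column counts
  expect_equal(unname(colSums(fl$invaded$counts)),
               unname(fl$invaded$coverage))
})

test_that("short sequences reduce coverage with a warning", {
  aln <- mini_aln()
  expect_warning(fl <- extract_flanks(aln, "d", w = 10), "fewer than")
  expect_lt(max(fl$invaded$coverage), 10 * fl$invaded$n_seq)
})

test_that("flank extraction ignores all-gap columns outside the window", {
  aln <- mini_aln()
  fl1 <- extract_flanks(aln, "d", w = 3)
  padded <- vapply(aln$seqs, function(s)
    paste0("---", substr(s, 1, 8), "--", substr(s, 9, nchar(s)), "---"),
    character(1))
  aln2 <- annotated_alignment(padded,
                              data.frame(site = "d", start = 13, end = 17))
  fl2 <- extract_flanks(aln2, "d", w = 3)
  expect_equal(fl2$invaded$counts, fl1$invaded$counts)
  expect_equal(fl2$uninvaded$counts, fl1$uninvaded$counts)
})

test_that("partition sizes agree with the occupancy module", {
  sim <- simulate_dataset(n_tips = 30, rates = rep(1, 8), seed = 5)
  sa <- synth_alignment(sim$tip_states, seed = 6)
  fl <- extract_flanks(sa$aln, "d", w = 5)
  occ <- occupancy_from_alignment(sa$aln)
  expect_equal(fl$invaded$n_seq, sum(occ$presence[, "d"]))
  expect_equal(fl$uninvaded$n_seq, sum(!occ$presence[, "d"]))
})

test_that("logo information content follows the corrected formula", {
  fm <- structure(list(
    counts = matrix(0L, 20, 2, dimnames = list(inteinkit:::AA20,
                                               c("-1", "+1"))),
    coverage = c("-1" = 66L, "+1" = 20L),
    n_seq = 66L, partition = "invaded", site = "d", w = 1L),
    class = "flank_matrix")
  fm$counts["S", "+1"] <- 0L
  fm$counts["S", "-1"] <- 66L
  fm$counts[, "+1"] <- 1L  # uniform over all 20 residues
  ld <- logo_data(fm)
  # single-residue column: IC = log2(20) - e_n, maximal
  expect_equal(ld$columns$ic[ld$columns$position == "-1"],
               log2(20) - 19 / (2 * log(2) * 66), tolerance = 1e-12)
  # uniform column: corrected IC clamps to zero
  expect_equal(ld$columns$ic[ld$columns$position == "+1"], 0)

  # random column: entropy matches a direct computation
  set.seed(8)
  cnt <- rmultinom(1, 120, runif(20))[, 1]
  fm$counts[, "+1"] <- cnt
  fm$coverage["+1"] <- sum(cnt)
  ld2 <- logo_data(fm)
  f <- cnt / sum(cnt)
  H <- -sum(f[f > 0] * log2(f[f > 0]))
  expect_equal(ld2$columns$entropy[ld2$columns$position == "+1"], H,
               tolerance = 1e-12)
  expect_equal(ld2$columns$ic[ld2$columns$position == "+1"],
               max(log2(20) - H - 19 / (2 * log(2) * 120), 0),
               tolerance = 1e-12)
})

test_that("IC is maximal for single-residue columns at a given coverage", {
  mk_fm <- function(cnt) {
    counts <- matrix(0L, 20, 1, dimnames = list(inteinkit:::AA20, "+1"))
    counts[seq_along(cnt), 1] <- cnt
    structure(list(counts = counts, coverage = c("+1" = sum(cnt)),
                   n_seq = sum(cnt), partition = "invaded", site = "d",
                   w = 1L), class = "flank_matrix")
  }
  n <- 100L
  ic_single <- logo_data(mk_fm(n))$columns$ic
  expect_equal(ic_single, log2(20) - 19 / (2 * log(2) * n),
               tolerance = 1e-12)
  # any admixture strictly lowers IC; the uniform column bottoms out at 0
  for (k in c(1L, 10L, 50L)) {
    expect_lt(logo_data(mk_fm(c(n - k, k)))$columns$ic, ic_single)
  }
  expect_equal(logo_data(mk_fm(rep(5L, 20)))$columns$ic, 0)
})

test_that("junction residues bracket the insertion point", {
  aln <- mini_aln()
  expect_equal(unname(junction_residues(aln, "d", "inv1")), c("R", "S"))
  expect_equal(unname(junction_residues(aln, "d", "gappy")), c("W", "S"))
  expect_equal(unname(junction_residues(aln, "d", "uninv1")), c("R", "P"))
  seqs <- c(x = "----WWWW-S", y = "DAAAWWWWGS")
  a2 <- annotated_alignment(seqs, data.frame(site = "d", start = 4, end = 8))
  expect_error(junction_residues(a2, "d", "x"), "gapped upstream")
  expect_equal(unname(junction_residues(a2, "d", "y")), c("A", "G"))
})

test_that("+1 summary separates configured S/P partitions", {
  st <- setNames(rep(c("AD", "--"), each = 20), paste0("t", 1:40))
  sa <- synth_alignment(st, invaded_plus1 = c(S = 1),
                        uninvaded_plus1 = c(P = 1), seed = 10)
  fl <- extract_flanks(sa$aln, "d", w = 2)
  tab <- plus1_summary(fl$invaded, fl$uninvaded)
  expect_equal(tab["S", "invaded"], 20L)
  expect_equal(tab["P", "uninvaded"], 20L)
  expect_equal(sum(tab), 40L)

  # shuffling which rows count as invaded mixes the table, totals preserved
  shuffled <- sa$aln
  set.seed(1)
  names(shuffled$seqs) <- sample(names(shuffled$seqs))
  fl2 <- extract_flanks(shuffled, "d", w = 2)
  tab2 <- plus1_summary(fl2$invaded, fl2$uninvaded)
  expect_equal(sum(tab2), 40L)
})

test_that("alignment readers parse FASTA and NEXUS fixtures", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 description", "MKV-TD", ">s2", "MKVATD"), fa)
  seqs <- read_alignment(fa)
  expect_equal(seqs, c(s1 = "MKV-TD", s2 = "MKVATD"))

  nx <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=6;",
               "FORMAT DATATYPE=PROTEIN GAP=- MISSING=?;",
               "MATRIX", "s1 MKV-TD", "s2 MKVATD", ";", "END;"), nx)
  seqs2 <- read_alignment(nx)
  expect_equal(toupper(unname(seqs2)), unname(seqs))
})

test_that("annotated alignments validate their invariants", {
  expect_error(annotated_alignment(c(a = "MKV", b = "MK"),
                                   data.frame(site = "d", start = 0, end = 1)),
               "length")
  expect_error(annotated_alignment(c(a = "MKVV", b = "MKVV"),
                                   data.frame(site = "d", start = 2, end = 9)),
               "interval")
  expect_error(annotated_alignment(c(a = "MKVVMKVV", b = "MKVVMKVV"),
                                   data.frame(site = c("a", "d"),
                                              start = c(1, 2),
                                              end = c(3, 5))),
               "overlap")
})
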