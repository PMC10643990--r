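test_that("PSSM construction follows the log-odds formula", {
  # identical sequences: consensus scores positive, all others negative
  ps <- build_pssm(rep("ACDE", 3), alpha = 1)
  cons <- c("A", "C", "D", "E")
  for (p in 1:4) {
    expect_gt(ps$scores[p, cons[p]], 0)
    expect_true(all(ps$scores[p, setdiff(colnames(ps$scores), cons[p])] < 0))
  }
  expect_true(all(is.finite(ps$scores)))

  # single-column block {A, A, C, C}, alpha = 0.8, uniform background:
  # s(A) = log2((2 + 0.8/20) / ((4 + 0.8)/20))
  ps2 <- build_pssm(c("A", "A", "C", "C"), alpha = 0.8)
  b <- 1 / 20
  expect_equal(unname(ps2$scores[1, "A"]),
               log2((2 + 0.8 * b) / ((4 + 0.8) * b)), tolerance = 1e-12)
  expect_equal(unname(ps2$scores[1, "G"]),
               log2((0.8 * b) / ((4 + 0.8) * b)), tolerance = 1e-12)

  # consensus window score is the attainable maximum
  set.seed(4)
  blk <- vapply(1:6, function(i)
    paste(sample(inteinkit:::AA20, 12, TRUE), collapse = ""), character(1))
  ps3 <- build_pssm(blk)
  expect_equal(ps3$consensus_score, sum(apply(ps3$scores, 1, max)))

  expect_error(build_pssm("ACDE"), "at least 2")
  expect_error(build_pssm(rep("ACDE", 3), alpha = 0), "alpha")
})

test_that("gapped block columns use ungapped counts only", {
  ps <- build_pssm(c("A-", "AC", "AC"), alpha = 1)
  # column 2 counts: C twice, gap excluded (n_p = 2)
  expect_equal(unname(ps$scores[2, "C"]), log2((2 + 1 / 20) / (3 / 20)),
               tolerance = 1e-12)
})

test_that("scanning finds a planted consensus and matches brute force", {
  set.seed(15)
  blk <- c("CLSFDTEILTRE", "CLSFDTEVLTRE", "CLSYDTEILTRE")
  ps <- build_pssm(blk, name = "toy")
  host <- paste(sample(inteinkit:::AA20, 100, TRUE), collapse = "")
  planted <- paste0(substr(host, 1, 37), blk[1], substr(host, 38, 100))
  hits <- scan_sequence(ps, planted, id = "p1")
  expect_equal(hits$start[which.max(hits$score)], 38L)

  # exhaustive-window oracle on random sequences
  for (i in 1:10) {
    s <- paste(sample(inteinkit:::AA20, 60, TRUE), collapse = "")
    expect_equal(inteinkit:::score_windows(ps, inteinkit:::encode_aa(s)),
                 brute_scan_scores(ps, s), tolerance = 1e-12)
  }

  # threshold above the consensus score: nothing can match
  expect_equal(nrow(scan_sequence(ps, planted,
                                  threshold = ps$consensus_score + 1)), 0L)
  # ambiguity codes score zero, not an error
  expect_silent(scan_sequence(ps, gsub("L", "X", planted)))
  expect_warning(scan_sequence(ps, "MK", id = "tiny"), "shorter")
})

test_that("a PSSM rediscovers its own source sequences", {
  blk <- c("GFSLAGLIDADGHF", "GFSLAGLIDSDGHF", "GYSLAGLIDADGHF",
           "GFSLAGLVDADGHF")
  ps <- build_pssm(blk, name = "self")
  min_self <- min(vapply(blk, function(s)
    max(brute_scan_scores(ps, s)), numeric(1)))
  for (s in blk) {
    h <- scan_sequence(ps, s, threshold = min_self)
    expect_equal(h$start, 1L)
  }
})

test_that("hit merging collapses overlapping windows and nearby blocks", {
  set.seed(30)
  pro <- synth_proteome(n_proteins = 3, n_full = 2, n_mini = 0,
                        segment_len = 600, seed = 30)
  pssms <- lapply(names(pro$blocks$intein), function(nm)
    build_pssm(pro$blocks$intein[[nm]], name = nm))
  hits <- scan_proteome(pssms, pro$seqs)
  calls <- call_inteins(hits, merge_gap = 150)
  # two planted inteins, in different proteins ~600 residues of host apart
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$seq, pro$truth$seq)
  for (i in seq_len(nrow(calls))) {
    tr <- pro$truth[pro$truth$seq == calls$seq[i], ]
    expect_gte(calls$start[i], tr$start)
    expect_lte(calls$end[i], tr$end)
  }
  # several PSSM hits on one element still give one call
  expect_true(all(calls$n_hits >= 2L))
  expect_equal(nrow(call_inteins(hits[0, , drop = FALSE])), 0L)
})

test_that("HEN classification separates full from mini inteins", {
  pro <- synth_proteome(n_proteins = 6, n_full = 2, n_mini = 2, seed = 41)
  ipssms <- lapply(names(pro$blocks$intein), function(nm)
    build_pssm(pro$blocks$intein[[nm]], name = nm))
  hpssms <- lapply(names(pro$blocks$hen), function(nm)
    build_pssm(pro$blocks$hen[[nm]], name = nm))
  calls <- call_inteins(scan_proteome(ipssms, pro$seqs))
  calls <- classify_hen(calls, pro$seqs, hpssms)
  merged <- merge(calls, pro$truth, by = "seq")
  expect_equal(nrow(merged), 4L)
  expect_equal(merged$category.x, merged$category.y)
  expect_true(all(nzchar(calls$hen_blocks[calls$category == "full"])))
  expect_true(all(calls$hen_blocks[calls$category == "mini"] == ""))
})

test_that("full/mini transitions are monotone in the HEN threshold", {
  pro <- synth_proteome(n_proteins = 4, n_full = 2, n_mini = 1, seed = 52)
  ipssms <- lapply(names(pro$blocks$intein), function(nm)
    build_pssm(pro$blocks$intein[[nm]], name = nm))
  hpssms <- lapply(names(pro$blocks$hen), function(nm)
    build_pssm(pro$blocks$hen[[nm]], name = nm))
  calls <- call_inteins(scan_proteome(ipssms, pro$seqs))
  cmax <- max(vapply(hpssms, `[[`, numeric(1), "consensus_score"))
  thr <- seq(0, cmax + 5, length.out = 12)
  n_full <- vapply(thr, function(th)
    sum(classify_hen(calls, pro$seqs, hpssms,
                     threshold = th)$category == "full"), integer(1))
  expect_true(all(diff(n_full) <= 0L))  # full count never re-enters
  expect_equal(n_full[1], 2L)           # at 0 bits both true fulls match
  expect_equal(n_full[length(n_full)], 0L)  # above consensus nothing can
})

test_that("group summaries use intein-count denominators", {
  calls <- data.frame(
    seq = c("g1", "g1", "g2", "g2", "g3", "g4"),
    category = c("full", "full", "full", "mini", "mini", "full"))
  groups <- c(g1 = "Halo", g2 = "Halo", g3 = "Halo", g4 = "Thermo",
              g5 = "Empty")
  gs <- group_summary(calls, groups)
  halo <- gs[gs$group == "Halo", ]
  # 2 multi-intein genes carrying 4 inteins of which 3 have a HEN
  expect_equal(halo$multi_genes, 2L)
  expect_equal(halo$multi_inteins, 4L)
  expect_equal(halo$pct_multi_hen, 75)
  expect_equal(halo$single_genes, 1L)
  expect_equal(halo$pct_single_hen, 0)
  thermo <- gs[gs$group == "Thermo", ]
  expect_equal(thermo$multi_genes, 0L)
  expect_true(is.na(thermo$pct_multi_hen))
  empty <- gs[gs$group == "Empty", ]
  expect_equal(empty$single_genes, 0L)
  # percentages are invariant to row order
  gs2 <- group_summary(calls[sample(nrow(calls)), , drop = FALSE], groups)
  expect_equal(gs2[order(gs2$group), ], gs[order(gs$group), ],
               ignore_attr = TRUE)
})
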