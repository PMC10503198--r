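test_that("exact substrings place with identity 1 on the right locus", {
  set.seed(407)
  tseq <- random_seq(30000)
  target <- assembly(c(c3 = tseq))
  parent <- substr(tseq, 10001, 11001)        # 0-based offset 10000
  pls <- align_parent(parent, target)
  expect_length(pls, 1L)
  p <- pls[[1]]
  expect_equal(p$chrom, "c3")
  expect_equal(p$start, 10000)
  expect_equal(p$end, 11001)
  expect_equal(p$strand, "+")
  expect_equal(p$identity, 1)
  expect_equal(p$coverage, 1)

  # reverse complement of a target segment places on the minus strand
  pls <- align_parent(revcomp(parent), target)
  expect_length(pls, 1L)
  expect_equal(pls[[1]]$strand, "-")
  expect_equal(pls[[1]]$start, 10000)

  expect_error(align_parent(substr(tseq, 1, 80), target), "minimum")
})

test_that("identity of a mutated copy matches the alignment oracle", {
  set.seed(408)
  for (rep in 1:5) {
    parent <- random_seq(150)
    v <- strsplit(parent, "")[[1]]
    ps <- sample(10:140, 3)                    # 3 scattered substitutions
    for (p in ps) v[p] <- sample(setdiff(BASES, v[p]), 1)
    core <- paste(v, collapse = "")
    target <- assembly(c(t = paste0(random_seq(200), core, random_seq(200))))
    pls <- align_parent(parent, target)
    expect_length(pls, 1L)
    expect_equal(pls[[1]]$identity, 147 / 150)
    expect_equal(pls[[1]]$coverage, 1)
    # oracle cross-check on the raw sequences
    sm <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(parent, core, type = "global",
                                         substitutionMatrix = sm,
                                         gapOpening = 2, gapExtension = 1)
    expect_equal(Biostrings::nmatch(aln), 147)
  }
})

test_that("choose_best takes the max, ties are ambiguous, empty is absent", {
  mk <- function(score, chrom = "c1", start = 0)
    list(chrom = chrom, start = start, end = start + 100, strand = "+",
         identity = 1, coverage = 1, score = score)
  params <- align_params()
  best <- choose_best(list(mk(980), mk(400, "c2")), params)
  expect_equal(best$score, 980)
  expect_equal(best$score_margin, 580)
  expect_equal(choose_best(list(mk(980), mk(980, "c5")), params),
               "ambiguous")
  expect_equal(choose_best(list(), params), "no_alignment")
  # deterministic regardless of input order
  b1 <- choose_best(list(mk(700, "c2", 5), mk(900, "c1", 9)), params)
  b2 <- choose_best(list(mk(900, "c1", 9), mk(700, "c2", 5)), params)
  expect_identical(b1, b2)
})

test_that("project_child walks the coordinate map correctly", {
  mk_placement <- function(ops, lens, start, strand = "+", parent_len) {
    list(chrom = "c1", start = start, end = start + sum(lens[ops != "D"]),
         strand = strand, parent_len = parent_len,
         parent_aln_start = 0L, parent_aln_end = sum(lens[ops != "I"]),
         cigar_op = ops, cigar_len = lens)
  }
  # identity map: parent [4500,5500] placed at 0-based 4499
  p <- mk_placement("M", 1001L, 4499, parent_len = 1001L)
  r <- project_child(p, 4500L, 5000L)
  expect_equal(r$pos, 5000L)

  # insertion before the child shifts the target coordinate
  p <- mk_placement(c("M", "I", "M"), c(100L, 10L, 401L), 1000,
                    parent_len = 501L)
  r <- project_child(p, 1L, 301L)             # child at parent offset 300
  expect_equal(r$pos, 1000 + 300 + 10 + 1)
  # brute-force walk over the expanded edit script agrees
  expand <- rep(c("M", "I", "M"), c(100L, 10L, 401L))
  pp <- 0L; tt <- 1000L
  for (op in expand) {
    if (op == "M") { if (pp == 300L) break; pp <- pp + 1L; tt <- tt + 1L }
    else tt <- tt + 1L
  }
  expect_equal(r$pos, tt + 1L)

  # child inside a deletion-from-parent has no target base
  p <- mk_placement(c("M", "D", "M"), c(100L, 5L, 396L), 1000,
                    parent_len = 501L)
  expect_equal(project_child(p, 1L, 103L), "deleted")
  # ... but a child just past it projects with the deletion skipped
  r <- project_child(p, 1L, 106L)
  expect_equal(r$pos, 1000 + 100 + 0 + 1)

  # clipped ends count as deleted
  p <- mk_placement("M", 400L, 1000, parent_len = 501L)
  p$parent_aln_start <- 50L; p$parent_aln_end <- 450L
  expect_equal(project_child(p, 1L, 10L), "deleted")

  expect_error(project_child(p, 1L, 600L), "outside parent")
})

test_that("project_feature composes the failure taxonomy", {
  set.seed(409)
  src <- assembly(c(c1 = random_seq(40000), lost = random_seq(5000)))
  target <- assembly(c(c1 = src[["c1"]]))     # 'lost' dropped, no homolog
  snps <- data.table::data.table(
    chrom = c("c1", "lost"), pos = c(20000L, 2500L), id = NA_character_,
    ref = "A", alt = "G", qual = ".", filter = ".", info = ".",
    gt = NA_character_)
  feats <- build_flank_features(snps, 500L, src)
  r1 <- project_feature(feats[1], src, target)
  expect_equal(r1$status, "lifted")
  expect_equal(r1$target_pos, 20000L)
  expect_equal(r1$identity, 1)
  r2 <- project_feature(feats[2], src, target)
  expect_equal(r2$status, "unlifted_no_alignment")
})

test_that("an inverted segment lifts to a+b-pos on the minus strand", {
  set.seed(410)
  src <- generate_source(1, 100000, seed = 31)
  a <- 40001L; b <- 60000L
  sim <- apply_edit_script(src, edit_script(op_invert("chr1", a, b)))
  snps <- data.table::data.table(
    chrom = "chr1", pos = c(45000L, 50000L, 55000L), id = NA_character_,
    ref = substring(src[["chr1"]], c(45000, 50000, 55000),
                    c(45000, 50000, 55000)),
    alt = "A", qual = ".", filter = ".", info = ".", gt = NA_character_)
  feats <- build_flank_features(snps, 500L, src)
  for (i in 1:3) {
    r <- project_feature(feats[i], src, sim$target)
    expect_equal(r$status, "lifted")
    expect_equal(r$target_pos, a + b - snps$pos[i])
    expect_equal(r$target_strand, "-")
  }
})

test_that("self-lift and reverse-complement symmetry hold (properties)", {
  set.seed(411)
  src <- generate_source(1, 80000, seed = 77)
  snps <- plant_snps(src, 20, seed = 78)
  for (L in c(500L, 1980L)) {
    feats <- build_flank_features(snps, L, src)
    ix <- target_index(src)
    for (i in seq_len(nrow(feats))) {
      r <- project_feature(feats[i], src, ix)
      expect_equal(r$status, "lifted")
      expect_equal(r$target_pos, snps$pos[i])
      expect_equal(r$target_strand, "+")
    }
  }
  # target = reverse complement of source: pos -> len - pos + 1, strand '-'
  rc <- assembly(setNames(revcomp(src[["chr1"]]), "chr1"))
  len <- seq_lengths(src)[["chr1"]]
  feats <- build_flank_features(snps, 500L, src)
  for (i in seq_len(nrow(feats))) {
    r <- project_feature(feats[i], src, rc)
    expect_equal(r$status, "lifted")
    expect_equal(r$target_pos, len - snps$pos[i] + 1L)
    expect_equal(r$target_strand, "-")
  }
})

test_that("engine projection equals the optimal-alignment oracle", {
  # smaller pendant of the acceptance criterion, exercised on every run
  set.seed(412)
  n_checked <- 0L
  for (rep in 1:25) {
    plen <- sample(300:1200, 1)
    parent <- random_seq(plen)
    core <- mutate_seq(parent, sub_rate = 0.01, n_indel = 2L)
    tseq <- paste0(random_seq(100), core, random_seq(100))
    target <- assembly(c(t1 = tseq))
    child_off <- sample(20:(plen - 20), 1)
    pls <- align_parent(parent, target)
    best <- choose_best(pls, align_params())
    eng <- if (is.character(best)) NA_integer_ else {
      pr <- project_child(best, 1L, child_off + 1L)
      if (is.character(pr)) NA_integer_ else pr$pos
    }
    orc <- oracle_child(parent, tseq, child_off)
    if (orc$ambiguous || is.na(orc$pos)) next
    n_checked <- n_checked + 1L
    expect_equal(eng, orc$pos,
                 label = sprintf("engine pos (rep %d)", rep))
  }
  expect_gt(n_checked, 15L)   # the unambiguous cases dominate
})
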