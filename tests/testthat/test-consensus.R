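mk_snps <- function(n, chrom = "c1") {
  data.table::data.table(chrom = chrom, pos = seq_len(n) * 100L,
                         id = sprintf("s%d", seq_len(n)), ref = "A",
                         alt = "G", qual = ".", filter = ".", info = ".",
                         gt = NA_character_)
}

# fabricate a per-flank table: one row per (snp, flank); `lifts` is a list
# per snp of either NULL (unlifted) or c(chrom, pos, strand) per flank
mk_per_flank <- function(lifts, flanks = c(500L, 1980L)) {
  rows <- list()
  for (si in seq_along(lifts)) {
    for (fi in seq_along(flanks)) {
      lf <- lifts[[si]][[fi]]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        snp_idx = si, flank_len = flanks[fi],
        feature_id = sprintf("snp%d_flank%d", si, flanks[fi]),
        status = if (is.null(lf)) "unlifted_no_alignment" else "lifted",
        tchrom = if (is.null(lf)) NA_character_ else lf[[1]],
        tpos = if (is.null(lf)) NA_integer_ else as.integer(lf[[2]]),
        tstrand = if (is.null(lf)) NA_character_ else lf[[3]],
        identity = if (is.null(lf)) NA_real_ else 0.99,
        coverage = 1, score_margin = Inf,
        truncated_left = FALSE, truncated_right = FALSE)
    }
  }
  data.table::rbindlist(rows)
}

test_that("consensus status follows the all-flank same-location rule", {
  flanks <- c(500L, 1000L, 1250L, 1980L)
  lifts <- list(
    rep(list(list("c1", 100L, "+")), 4),                      # consistent
    c(rep(list(list("c1", 100L, "+")), 3), list(list("c2", 900L, "+"))),
    c(rep(list(list("c1", 100L, "+")), 3), list(NULL)),       # incomplete
    rep(list(list("c1", 100L, "-")), 4))                      # minus strand
  pf <- mk_per_flank(lifts, flanks)
  cons <- consensus_from_per_flank(pf, flanks, mk_snps(4))
  expect_equal(cons$status,
               c("consistent", "inconsistent", "incomplete", "consistent"))
  expect_equal(cons$retained, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cons$tpos[1], 100L)
  expect_equal(cons$strand_class, c("plus", NA, NA, "minus"))
  # a plus/minus disagreement at one coordinate is inconsistent too
  pf2 <- mk_per_flank(list(c(rep(list(list("c1", 100L, "+")), 3),
                             list(list("c1", 100L, "-")))), flanks)
  expect_equal(consensus_from_per_flank(pf2, flanks, mk_snps(1))$status,
               "inconsistent")
})

test_that("strand policies drop or rescue minus-strand SNPs", {
  flanks <- c(500L, 1980L)
  lifts <- list(rep(list(list("c1", 100L, "+")), 2),
                rep(list(list("c1", 200L, "-")), 2))
  snps <- mk_snps(2)
  snps$ref <- c("A", "A"); snps$alt <- c("G", "C,T")
  pf <- mk_per_flank(lifts, flanks)
  res <- structure(list(per_flank = pf,
                        consensus = consensus_from_per_flank(pf, flanks, snps),
                        flank_set = flanks, strand_policy = "drop_minus",
                        un_prefix_source = "chrUn",
                        un_prefix_target = "chrUn"),
                   class = "lift_result")
  dropped <- apply_strand_policy(res, "drop_minus")
  expect_equal(dropped$consensus$retained, c(TRUE, FALSE))
  expect_equal(dropped$consensus$ref, c("A", "A"))   # alleles untouched

  rescued <- apply_strand_policy(res, "rescue_minus")
  expect_equal(rescued$consensus$retained, c(TRUE, TRUE))
  expect_equal(rescued$consensus$ref, c("A", "T"))
  expect_equal(rescued$consensus$alt, c("G", "G,A"))
})

test_that("transition classes compare names with the unanchored prefix", {
  expect_equal(classify_transition("chr1A", "chr1A"), "same_chrom")
  expect_equal(classify_transition("chr2D", "chr4A"), "diff_chrom")
  expect_equal(classify_transition("chrUn", "chr5A"), "un_to_anchored")
  expect_equal(classify_transition("chr3B", "chrUn_9"), "anchored_to_un")
  expect_equal(classify_transition("chrUn_1", "chrUn_2"), "un_to_un")
  expect_equal(classify_transition("scaffold_1", "chr1", "scaffold"),
               "un_to_anchored")
  expect_equal(classify_transition(c("chr1", NA), c("chr1", "chr2")),
               c("same_chrom", NA))
})

test_that("summaries count what the consensus table says", {
  set.seed(413)
  src <- generate_source(1, 60000, seed = 51)
  snps <- plant_snps(src, 10, seed = 52)
  res <- lift_consensus(snps, src, src, flank_set = c(500L, 1000L))
  s <- summarize_lift(res)
  expect_equal(s$per_flank$lifted, c(10L, 10L))
  expect_equal(s$n_retained, 10L)
  expect_equal(s$strand$count[s$strand$strand_class == "plus"], 10L)
  expect_equal(s$strand$pct[s$strand$strand_class == "plus"], 100)
  expect_equal(s$transitions$transition, "same_chrom")

  # empty input -> all-zero report
  res0 <- lift_consensus(snps[0], src, src, flank_set = 500L)
  s0 <- summarize_lift(res0)
  expect_equal(s0$n_input, 0L)
  expect_equal(s0$n_retained, 0L)
})

test_that("counting identity holds on simulated runs (property)", {
  set.seed(414)
  w <- small_world(seed = 61)
  snps <- plant_snps(w$src, 120, seed = 62)
  res <- lift_consensus(snps, w$src, w$sim$target,
                        flank_set = c(500L, 1980L))
  st <- table(factor(res$consensus$status,
                     c("consistent", "inconsistent", "incomplete")))
  expect_equal(sum(st), nrow(snps))
  cons <- res$consensus[status == "consistent"]
  expect_equal(sum(cons$strand_class == "plus") +
                 sum(cons$strand_class == "minus"), nrow(cons))
})

test_that("density bins are ceiling(pos / bin_size) and conserve totals", {
  asm <- assembly(c(c1 = strrep("A", 2500000)))
  dt <- data.table::data.table(chrom = "c1",
                               pos = c(1L, 2L, 1000001L, 1000000L, 42L))
  d <- density_profile(dt, asm, bin_size = 1e6)
  expect_equal(nrow(d), 3L)                       # 2.5 Mb / 1 Mb -> 3 bins
  expect_equal(d$count, c(4L, 1L, 0L))            # pos == bin_size -> bin 1
  expect_equal(sum(d$count), nrow(dt))
  expect_equal(d$bin_end[3], 2500000L)            # last bin short
  expect_error(density_profile(dt, asm, bin_size = 0), "bin_size")

  set.seed(415)
  src <- generate_source(1, 50000, seed = 71)
  snps <- plant_snps(src, 40, seed = 72)
  res <- lift_consensus(snps, src, src, flank_set = 500L)
  d <- density_profile(res, src, bin_size = 7000)
  expect_equal(sum(d$count), sum(res$consensus$retained))
})
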