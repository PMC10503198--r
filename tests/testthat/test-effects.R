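# toy two-exon transcript used throughout: exons [101,200] and [301,400],
# CDS [123,200]+[301,381] (159 bases, 53 codons), intron 201..300
toy_tx <- function(strand = "+")
  transcript_model("toy", "c1", strand,
                   exons = rbind(c(101L, 200L), c(301L, 400L)),
                   cds = rbind(c(123L, 200L), c(301L, 381L)))

test_that("region labels over the junction sweep match the stated rules", {
  tx <- toy_tx("+")
  # expected labels derived from the positional rules by enumeration:
  # donor = first 2 intronic bases (201-202), acceptor = last 2 (299-300),
  # splice region = intronic 3-8 from a junction (203-208, 293-298) or
  # exonic 1-3 from a junction (198-200, 301-303)
  expected <- c(
    rep("exon", 3),                  # 195-197 (CDS)
    rep("splice_site_region", 3),    # 198-200
    rep("splice_site_donor", 2),     # 201-202
    rep("splice_site_region", 6),    # 203-208
    rep("intron", 84),               # 209-292
    rep("splice_site_region", 6),    # 293-298
    rep("splice_site_acceptor", 2),  # 299-300
    rep("splice_site_region", 3),    # 301-303
    rep("exon", 2))                  # 304-305 (CDS)
  got <- vapply(195:305, function(p) classify_region(p, "c1", tx), "")
  expect_equal(got, expected)

  # on the minus strand the junction roles swap sides
  txm <- toy_tx("-")
  expect_equal(classify_region(299, "c1", txm), "splice_site_donor")
  expect_equal(classify_region(300, "c1", txm), "splice_site_donor")
  expect_equal(classify_region(201, "c1", txm), "splice_site_acceptor")
})

test_that("every position gets exactly one label (total function)", {
  tx <- toy_tx("+")
  all_labels <- c("splice_site_donor", "splice_site_acceptor",
                  "splice_site_region", "utr5", "utr3", "exon", "intron",
                  "upstream", "downstream", "intergenic")
  got <- vapply(1:6000, function(p) classify_region(p, "c1", tx), "")
  expect_true(all(got %in% all_labels))
  # the expected partition, by construction of the toy transcript
  expect_equal(sum(got == "utr5"), 22)          # 101-122
  expect_equal(sum(got == "utr3"), 19)          # 382-400 (no right intron)
  expect_equal(sum(got == "upstream"), 100)     # 1-100
  expect_equal(sum(got == "downstream"), 5000)  # 401-5400
  expect_equal(sum(got == "intergenic"), 600)   # 5401-6000
})

test_that("up/downstream follow transcript orientation, window bounded", {
  expect_equal(classify_region(50, "c1", toy_tx("+")), "upstream")
  expect_equal(classify_region(50, "c1", toy_tx("-")), "downstream")
  expect_equal(classify_region(5400, "c1", toy_tx("+")), "downstream")
  expect_equal(classify_region(5401, "c1", toy_tx("+")), "intergenic")
  expect_equal(classify_region(50, "c2", toy_tx("+")), "intergenic")
})

test_that("strand mirror: '-' transcript equals '+' on the revcomp chrom", {
  set.seed(416)
  L <- 1000L
  ex <- rbind(c(201L, 300L), c(401L, 500L))
  cds <- rbind(c(231L, 300L), c(401L, 460L))   # 130 -> not %3: suppress
  mirror <- function(iv) cbind(L - iv[, 2] + 1L, L - iv[, 1] + 1L)
  suppressWarnings({
    plus <- transcript_model("p", "c1", "+", ex, cds)
    minus <- transcript_model("m", "c1", "-",
                              mirror(ex)[2:1, , drop = FALSE],
                              mirror(cds)[2:1, , drop = FALSE])
  })
  for (pos in seq(150L, 560L, by = 7L)) {
    lab_plus <- classify_region(pos, "c1", plus)
    lab_minus <- classify_region(L - pos + 1L, "c1", minus)
    expect_equal(lab_minus, lab_plus,
                 label = sprintf("mirror at %d", pos))
  }
})

test_that("coding-effect examples translate as stated", {
  # CDS "ATG GCT TAA" laid flat on a plus transcript
  seqc <- paste0(strrep("T", 100), "ATGGCTTAA", strrep("T", 100))
  asm <- assembly(c(c1 = seqc))
  tx <- transcript_model("t", "c1", "+", rbind(c(101L, 109L)),
                         rbind(c(101L, 109L)))
  expect_equal(classify_coding_effect(101L, "A", "G", tx, asm),
               "start_lost")                   # ATG -> GTG
  expect_equal(classify_coding_effect(109L, "A", "C", tx, asm),
               "stop_lost")                    # TAA -> TAC (Tyr)
  # TAC -> TAA: stop gained (build a CDS ending in TAC GGG)
  seqc2 <- paste0(strrep("T", 100), "ATGTACGGGTAA", strrep("T", 100))
  asm2 <- assembly(c(c1 = seqc2))
  tx2 <- transcript_model("t2", "c1", "+", rbind(c(101L, 112L)),
                          rbind(c(101L, 112L)))
  expect_equal(classify_coding_effect(106L, "C", "A", tx2, asm2),
               "stop_gained")                  # TAC -> TAA
  # CTA -> CTG, both Leu
  seqc3 <- paste0(strrep("T", 100), "ATGCTATAA", strrep("T", 100))
  asm3 <- assembly(c(c1 = seqc3))
  tx3 <- transcript_model("t3", "c1", "+", rbind(c(101L, 109L)),
                          rbind(c(101L, 109L)))
  expect_equal(classify_coding_effect(106L, "A", "G", tx3, asm3),
               "synonymous")
})

test_that("coding effects agree with the translate-and-diff oracle", {
  set.seed(417)
  L <- 3000L
  chrom <- random_seq(L)
  substr(chrom, 501, 503) <- "ATG"             # clean start codon
  asm <- assembly(c(c1 = chrom))
  suppressWarnings({
    txs <- list(
      transcript_model("f", "c1", "+", rbind(c(451L, 700L), c(801L, 1000L)),
                       rbind(c(501L, 700L), c(801L, 997L))),   # 397 -> warn
      transcript_model("r", "c1", "-", rbind(c(1501L, 1700L), c(1801L, 2000L)),
                       rbind(c(1540L, 1700L), c(1801L, 1960L))))
  })
  for (tx in txs) {
    cp <- flanklift:::cds_positions(tx)
    n3 <- (length(cp) %/% 3L) * 3L
    cp <- cp[seq_len(n3)]                      # complete codons only
    for (rep in 1:150) {
      pos <- sample(cp, 1)
      ref <- substring(chrom, pos, pos)
      alt <- sample(setdiff(BASES, ref), 1)
      expect_equal(classify_coding_effect(pos, ref, alt, tx, asm),
                   oracle_coding_effect(pos, alt, tx, asm),
                   label = sprintf("%s pos %d %s>%s", tx$id, pos, ref, alt))
    }
  }
})

test_that("impact buckets map regions and coding effects as documented", {
  expect_equal(impact_bucket("exon", "missense"), "moderate")
  expect_equal(impact_bucket("exon", "synonymous"), "low")
  expect_equal(impact_bucket("exon", "stop_gained"), "high")
  expect_equal(impact_bucket("exon", "start_lost"), "high")
  expect_equal(impact_bucket("splice_site_donor", "none"), "high")
  expect_equal(impact_bucket("splice_site_acceptor", "none"), "high")
  expect_equal(impact_bucket("splice_site_region", "none"), "low")
  expect_equal(impact_bucket("intergenic", "none"), "modifier")
  expect_equal(impact_bucket(c("intron", "utr3", "upstream"), "none"),
               rep("modifier", 3))
})

test_that("annotate emits one effect per (SNP, transcript, alt)", {
  set.seed(418)
  chrom <- random_seq(10000)
  asm <- assembly(c(c1 = chrom))
  # two isoforms: SNP at 1550 is exonic in iso1, intronic in iso2
  iso1 <- transcript_model("iso1", "c1", "+", rbind(c(1001L, 2000L)))
  iso2 <- transcript_model("iso2", "c1", "+",
                           rbind(c(1001L, 1400L), c(1701L, 2000L)))
  snps <- data.table::data.table(
    chrom = "c1", pos = c(1550L, 9000L), id = NA_character_,
    ref = substring(chrom, c(1550, 9000), c(1550, 9000)),
    alt = c("A", "C"), qual = ".", filter = ".", info = ".",
    gt = NA_character_)
  snps$alt[1] <- setdiff(BASES, snps$ref[1])[1]
  eff <- annotate_effects(snps, list(iso1, iso2), asm)
  e1 <- eff[snp_idx == 1]
  expect_equal(nrow(e1), 2L)
  expect_setequal(e1$region, c("exon", "intron"))
  # SNP 6 kb beyond any transcript (window 5000) is intergenic
  e2 <- eff[snp_idx == 2]
  expect_equal(e2$region, "intergenic")
  expect_true(is.na(e2$transcript_id))

  s <- effect_summary(eff)
  expect_equal(sum(s$region$count), nrow(eff))
  expect_equal(sum(s$region$pct), 100, tolerance = 0.101)
})

test_that("gene models round-trip through GFF3", {
  td <- withr::local_tempdir()
  g <- file.path(td, "m.gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
    "c1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1;confidence=high",
    "c1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
    "c1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1",
    "c1\tsrc\tCDS\t123\t200\t.\t+\t0\tParent=t1",
    "c1\tsrc\tCDS\t301\t381\t.\t+\t0\tParent=t1"), g)
  txs <- read_gene_models(g)
  expect_length(txs, 1L)
  expect_equal(txs[[1]]$id, "t1")
  expect_equal(txs[[1]]$biotype, "coding")
  expect_equal(txs[[1]]$confidence, "high")
  expect_equal(txs[[1]]$exons, rbind(c(101L, 200L), c(301L, 400L)))
  expect_equal(txs[[1]]$cds, rbind(c(123L, 200L), c(301L, 381L)))

  writeLines(c("c1\tsrc\texon\t10\t20\t.\t+\t.\tParent=ghost"), g)
  expect_error(read_gene_models(g), "line 1")

  writeLines(c("c1\tsrc\tgene\t10"), g)
  expect_error(read_gene_models(g), "malformed")
})
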