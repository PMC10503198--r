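# shared fixtures: tiny random sequences, mutation helpers and the
# independent alignment / translation oracles used across test files

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# point-mutate + indel a sequence; returns the mutated string
mutate_seq <- function(s, sub_rate = 0.01, n_indel = 0L, max_indel = 10L) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  ns <- rbinom(1L, length(v), sub_rate)
  if (ns > 0) {
    ps <- sample(length(v), ns)
    for (p in ps) v[p] <- sample(setdiff(BASES, v[p]), 1L)
  }
  for (k in seq_len(n_indel)) {
    p <- sample(length(v) - max_indel - 1L, 1L)
    d <- sample(max_indel, 1L)
    if (runif(1) < 0.5) v <- v[-(p:(p + d - 1L))]
    else v <- append(v, sample(BASES, d, replace = TRUE), after = p)
  }
  paste(v, collapse = "")
}

# independent child-projection oracle: optimal global(pattern)-local(subject)
# alignment via Biostrings::pairwiseAlignment with the same scoring as the
# engine (match 1, mismatch -1, gap of length L costs 2 + L).
# child_off is the 0-based offset of the child base in the parent.
oracle_child <- function(parent, target_seq, child_off, amb_halo = 6L) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(parent, target_seq,
                                       type = "global-local",
                                       substitutionMatrix = sm,
                                       gapOpening = 2, gapExtension = 1)
  pg <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sg <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  soff <- Biostrings::start(Biostrings::subject(aln)) - 1L
  p <- 0L; t <- soff; childcol <- NA_integer_; res <- NA_integer_
  for (ci in seq_along(pg)) {
    isP <- pg[ci] != "-"; isS <- sg[ci] != "-"
    if (isP && p == child_off) {
      if (!isS) return(list(pos = NA_integer_, ambiguous = TRUE))
      res <- t + 1L; childcol <- ci
      break
    }
    if (isP) p <- p + 1L
    if (isS) t <- t + 1L
  }
  if (is.na(childcol)) return(list(pos = NA_integer_, ambiguous = TRUE))
  lo <- max(1L, childcol - amb_halo)
  hi <- min(length(pg), childcol + amb_halo)
  amb <- any(pg[lo:hi] == "-") || any(sg[lo:hi] == "-")
  list(pos = res, ambiguous = amb)
}

# independent coding-effect oracle: translate the whole reference and
# mutated CDS and diff the proteins
oracle_coding_effect <- function(pos, alt, tx, asm) {
  cp <- flanklift:::cds_positions(tx)
  seqc <- asm[[tx$chrom]]
  bases <- substring(seqc, cp, cp)
  if (tx$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  idx <- match(pos, cp)
  altb <- if (tx$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  mut <- bases
  mut[idx] <- altb
  n3 <- (length(bases) %/% 3L) * 3L
  ref_aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(paste(bases[1:n3], collapse = "")))), "")[[1]]
  alt_aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(paste(mut[1:n3], collapse = "")))), "")[[1]]
  dif <- which(ref_aa != alt_aa)
  ref_codon1 <- paste(bases[1:3], collapse = "")
  alt_codon1 <- paste(mut[1:3], collapse = "")
  if (ref_codon1 == "ATG" && alt_codon1 != "ATG" && idx <= 3L)
    return("start_lost")
  if (length(dif) == 0L) return("synonymous")
  d <- dif[1]
  if (ref_aa[d] != "*" && alt_aa[d] == "*") return("stop_gained")
  if (ref_aa[d] == "*" && alt_aa[d] != "*") return("stop_lost")
  "missense"
}

# small deterministic simulator world used by several files
small_world <- function(seed = 11) {
  src <- generate_source(3, c(200000, 150000, 100000), 3,
                         c(30000, 20000, 15000), seed = seed)
  script <- edit_script(
    op_invert("chr1", 50001, 70000),
    op_relocate("chr2", 30001, 40000, "chr3", 50001, "+"),
    op_anchor("chrUn_1", "chr1", 150001, "+"),
    op_drop("chrUn_2"),
    seed = 5)
  sim <- apply_edit_script(src, script)
  list(src = src, sim = sim, script = script)
}
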