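# effect_context: minimal transcript-relative variant effect classifier.
# Region classes follow the conventions of standard variant annotators:
# splice donor/acceptor = first/last 2 intronic bases of an intron in
# transcript orientation; splice region = intronic bases 3-8 or exonic bases
# 1-3 from a junction; up/downstream within a configurable window (5 kb).

#' Construct a transcript model
#'
#' @param id transcript identifier.
#' @param chrom sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons 2-column matrix/data.frame of 1-based inclusive exon
#'   intervals, non-overlapping.
#' @param cds optional CDS intervals (subset of exon space); presence makes
#'   the transcript coding.
#' @param confidence free-text attribute (e.g. high/low confidence gene
#'   model); carried through, never used for filtering.
#' @return a list of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand, exons, cds = NULL,
                             confidence = NA_character_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1])) stopf("exon end < start in %s", id)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stopf("overlapping exons in %s", id)
  if (!is.null(cds) && length(cds)) {
    cds <- matrix(as.integer(as.matrix(cds)), ncol = 2)
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(cds)))
      if (!any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2]))
        stopf("CDS interval outside exons in %s", id)
    cdslen <- sum(cds[, 2] - cds[, 1] + 1L)
    if (cdslen %% 3L != 0L)
      warnf("CDS length of %s (%d) is not divisible by 3; classified best-effort",
            id, cdslen)
  } else cds <- NULL
  structure(list(id = id, chrom = chrom, strand = strand, exons = exons,
                 cds = cds,
                 biotype = if (is.null(cds)) "noncoding" else "coding",
                 confidence = confidence),
            class = "transcript_model")
}

in_any <- function(pos, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(FALSE)
  any(pos >= iv[, 1] & pos <= iv[, 2])
}

#' Classify a position relative to one transcript
#'
#' Most-specific-wins precedence: splice donor > splice acceptor > splice
#' region > 5'/3' UTR > exon > intron > upstream/downstream > intergenic.
#'
#' @param pos 1-based genomic position.
#' @param chrom sequence name of the position.
#' @param tx a [transcript_model].
#' @param updown_window up/downstream window in bases (default 5000).
#' @return one of `"splice_site_donor"`, `"splice_site_acceptor"`,
#'   `"splice_site_region"`, `"utr5"`, `"utr3"`, `"exon"`, `"intron"`,
#'   `"upstream"`, `"downstream"`, `"intergenic"`.
#' @export
classify_region <- function(pos, chrom, tx, updown_window = 5000L) {
  if (!identical(chrom, tx$chrom)) return("intergenic")
  ex <- tx$exons
  span <- c(ex[1, 1], ex[nrow(ex), 2])
  if (pos < span[1] || pos > span[2]) {
    d <- if (pos < span[1]) span[1] - pos else pos - span[2]
    if (d > updown_window) return("intergenic")
    left <- pos < span[1]
    if (tx$strand == "+") return(if (left) "upstream" else "downstream")
    return(if (left) "downstream" else "upstream")
  }
  # introns between consecutive exons
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      is_ <- ex[i, 2] + 1L; ie <- ex[i + 1, 1] - 1L
      if (is_ > ie) next
      if (pos >= is_ && pos <= ie) {
        donor <- if (tx$strand == "+") c(is_, is_ + 1L) else c(ie - 1L, ie)
        accept <- if (tx$strand == "+") c(ie - 1L, ie) else c(is_, is_ + 1L)
        donor <- donor[donor >= is_ & donor <= ie]
        accept <- setdiff(accept[accept >= is_ & accept <= ie], donor)
        if (pos %in% donor) return("splice_site_donor")
        if (pos %in% accept) return("splice_site_acceptor")
        dist <- min(pos - is_, ie - pos) + 1L    # 1-based from junction
        if (dist >= 3L && dist <= 8L) return("splice_site_region")
        return("intron")
      }
    }
  }
  # exonic: splice region within 3 bases of an exon/intron junction
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex))) {
      near <- FALSE
      if (i > 1 && pos >= ex[i, 1] && pos <= min(ex[i, 2], ex[i, 1] + 2L))
        near <- TRUE
      if (i < nrow(ex) && pos <= ex[i, 2] && pos >= max(ex[i, 1], ex[i, 2] - 2L))
        near <- TRUE
      if (near && pos >= ex[i, 1] && pos <= ex[i, 2])
        return("splice_site_region")
    }
  }
  # exonic, by CDS
  if (!is.null(tx$cds)) {
    if (in_any(pos, tx$cds)) return("exon")
    cs <- tx$cds[1, 1]; ce <- tx$cds[nrow(tx$cds), 2]
    if (tx$strand == "+") {
      if (pos < cs) return("utr5")
      if (pos > ce) return("utr3")
    } else {
      if (pos > ce) return("utr5")
      if (pos < cs) return("utr3")
    }
  }
  "exon"
}

# genomic CDS positions in transcript (5'->3') order
cds_positions <- function(tx) {
  if (is.null(tx$cds)) return(integer(0))
  p <- unlist(lapply(seq_len(nrow(tx$cds)),
                     function(i) tx$cds[i, 1]:tx$cds[i, 2]),
              use.names = FALSE)
  if (tx$strand == "-") rev(p) else p
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify the coding effect of a SNV inside a CDS
#'
#' Locates the codon, substitutes the alternate base (complemented for
#' minus-strand transcripts) and translates reference vs alternate codon
#' with the standard genetic code.
#'
#' @param pos,ref,alt 1-based position and plus-strand alleles.
#' @param tx a coding [transcript_model].
#' @param asm the [assembly] holding the transcript's chromosome.
#' @return one of `"start_lost"`, `"stop_gained"`, `"stop_lost"`,
#'   `"synonymous"`, `"missense"`.
#' @export
classify_coding_effect <- function(pos, ref, alt, tx, asm) {
  if (tx$biotype != "coding") stopf("transcript %s is not coding", tx$id)
  cp <- cds_positions(tx)
  idx <- match(pos, cp)
  if (is.na(idx)) stopf("position %d is not in the CDS of %s", pos, tx$id)
  codon_i <- (idx - 1L) %/% 3L
  cod_pos <- cp[(codon_i * 3L + 1L):min(codon_i * 3L + 3L, length(cp))]
  if (length(cod_pos) < 3L) return("missense")   # trailing partial codon
  seqc <- asm[[tx$chrom]]
  bases <- substring(seqc, cod_pos, cod_pos)
  if (tx$strand == "-") bases <- comp_base(bases)
  ref_codon <- paste(bases, collapse = "")
  off <- idx - 1L - codon_i * 3L
  altb <- if (tx$strand == "-") comp_base(alt) else alt
  alt_bases <- bases
  alt_bases[off + 1L] <- altb
  alt_codon <- paste(alt_bases, collapse = "")
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (codon_i == 0L && ref_codon == "ATG" && alt_codon != "ATG")
    return("start_lost")
  if (!identical(ref_aa, "*") && identical(alt_aa, "*")) return("stop_gained")
  if (identical(ref_aa, "*") && !identical(alt_aa, "*")) return("stop_lost")
  if (identical(ref_aa, alt_aa)) return("synonymous")
  "missense"
}

#' Impact bucket of an effect
#'
#' @param region region label from [classify_region].
#' @param coding_effect coding-effect label or `"none"`.
#' @return `"high"`, `"moderate"`, `"low"` or `"modifier"` (vectorized).
#' @export
impact_bucket <- function(region, coding_effect = "none") {
  out <- rep("modifier", length(region))
  out[region %in% c("splice_site_donor", "splice_site_acceptor")] <- "high"
  out[coding_effect %in% c("start_lost", "stop_gained", "stop_lost")] <- "high"
  out[coding_effect == "missense"] <- "moderate"
  low <- (coding_effect == "synonymous") |
    (region == "splice_site_region" &
       !coding_effect %in% c("start_lost", "stop_gained", "stop_lost",
                             "missense"))
  out[low & out != "high"] <- "low"
  out
}

#' Annotate SNPs against a set of transcript models
#'
#' Emits one effect per (SNP, transcript, alternate allele) for every
#' transcript whose span plus the window contains the SNP; SNPs hitting
#' nothing get a single intergenic effect per alternate allele.  Percentages
#' in the summary are over effects, not SNPs.
#'
#' @param snps SNP `data.table` ([read_vcf] shape).
#' @param transcripts list of [transcript_model]s.
#' @param asm the source [assembly] (needed to translate codons).
#' @param updown_window up/downstream window in bases.
#' @return a `data.table` of effects: `snp_idx`, `chrom`, `pos`, `alt`,
#'   `transcript_id`, `region`, `coding_effect`, `impact`.
#' @export
annotate_effects <- function(snps, transcripts, asm,
                             updown_window = 5000L) {
  spans <- data.table::rbindlist(lapply(transcripts, function(tx)
    data.table::data.table(chrom = tx$chrom,
                           start = tx$exons[1, 1],
                           end = tx$exons[nrow(tx$exons), 2])))
  rows <- list()
  for (si in seq_len(nrow(snps))) {
    pos <- snps$pos[si]; chrom <- snps$chrom[si]
    alts <- strsplit(snps$alt[si], ",", fixed = TRUE)[[1]]
    hit <- which(spans$chrom == chrom &
                   pos >= spans$start - updown_window &
                   pos <= spans$end + updown_window)
    if (length(hit) == 0L) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        snp_idx = si, chrom = chrom, pos = pos, alt = alts,
        transcript_id = NA_character_, region = "intergenic",
        coding_effect = "none")
      next
    }
    for (ti in hit) {
      tx <- transcripts[[ti]]
      reg <- classify_region(pos, chrom, tx, updown_window)
      for (a in alts) {
        ce <- "none"
        if (reg == "exon" && tx$biotype == "coding" && in_any(pos, tx$cds))
          ce <- classify_coding_effect(pos, snps$ref[si], a, tx, asm)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          snp_idx = si, chrom = chrom, pos = pos, alt = a,
          transcript_id = tx$id, region = reg, coding_effect = ce)
      }
    }
  }
  eff <- data.table::rbindlist(rows)
  eff[, impact := impact_bucket(region, coding_effect)]
  eff[]
}

#' Summary table of effect categories
#'
#' @param effects the table from [annotate_effects].
#' @return a list of `data.table`s: `region` (category, count, percentage
#'   over effects), `impact`, `coding` counts.
#' @export
effect_summary <- function(effects) {
  n <- nrow(effects)
  reg <- effects[, .(count = .N), by = .(category = region)]
  reg[, pct := if (n) round(100 * count / n, 2) else 0]
  data.table::setorder(reg, category)
  imp <- effects[, .(count = .N), by = .(category = impact)]
  imp[, pct := if (n) round(100 * count / n, 2) else 0]
  cod <- effects[coding_effect != "none",
                 .(count = .N), by = .(category = coding_effect)]
  list(region = reg[], impact = imp[], coding = cod[], n_effects = n)
}

#' Read transcript models from a GFF3 file
#'
#' Expects the standard gene -> mRNA -> exon/CDS hierarchy with `ID` and
#' `Parent` attributes; `transcript` is accepted as a synonym of `mRNA`.
#'
#' @param path a GFF3 file.
#' @return a list of [transcript_model]s.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(f)
  if (any(nc < 9L))
    stopf("line %d: malformed GFF3 (fewer than 9 columns)",
          lineno[nc < 9L][1])
  g <- data.table::data.table(
    chrom = vapply(f, `[`, "", 1L), type = vapply(f, `[`, "", 3L),
    start = as.integer(vapply(f, `[`, "", 4L)),
    end = as.integer(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L), attr = vapply(f, `[`, "", 9L),
    line = lineno)
  if (anyNA(g$start) || anyNA(g$end))
    stopf("line %d: non-numeric coordinates",
          g$line[is.na(g$start) | is.na(g$end)][1])
  getattr <- function(a, key) {
    pat <- paste0("(?:^|.*;)", key, "=([^;]*).*")
    hit <- grepl(paste0("(^|;)", key, "="), a)
    out <- rep(NA_character_, length(a))
    out[hit] <- sub(pat, "\\1", a[hit])
    out
  }
  mr <- g[type %in% c("mRNA", "transcript")]
  tx_id <- getattr(mr$attr, "ID")
  if (anyNA(tx_id))
    stopf("line %d: mRNA without ID attribute", mr$line[is.na(tx_id)][1])
  ex <- g[type == "exon"]; cd <- g[type == "CDS"]
  ex_par <- getattr(ex$attr, "Parent"); cd_par <- getattr(cd$attr, "Parent")
  orphan <- !is.na(ex_par) & !ex_par %in% tx_id
  if (any(orphan))
    stopf("line %d: exon Parent '%s' matches no mRNA",
          ex$line[orphan][1], ex_par[orphan][1])
  out <- vector("list", length(tx_id))
  for (i in seq_along(tx_id)) {
    eset <- ex[which(ex_par == tx_id[i])]
    if (nrow(eset) == 0L)
      eset <- mr[i, .(chrom, start, end)]     # exonless mRNA: span is exon
    cset <- cd[which(cd_par == tx_id[i])]
    out[[i]] <- transcript_model(
      id = tx_id[i], chrom = mr$chrom[i], strand = mr$strand[i],
      exons = cbind(eset$start, eset$end),
      cds = if (nrow(cset)) cbind(cset$start, cset$end) else NULL,
      confidence = getattr(mr$attr[i], "confidence"))
  }
  out
}
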