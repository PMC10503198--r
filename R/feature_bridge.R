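# feature_bridge: SNPs <-> parent/child flank features.
# The parent window spans SNP +/- L bases (2L+1 bp when untruncated) and the
# child is the SNP base itself, linked by a deterministic feature id.

#' Default set of flank lengths
#'
#' The default multi-flank consensus uses windows of 500, 1,000, 1,250 and
#' 1,980 bases on either side of the SNP.  1,980 bp corresponds to half the
#' average transcript length of a typical annotated plant genome (a 3,961 bp
#' parent), a proxy for the expected span of conserved sequence; the shorter
#' lengths probe the stability of each projection.
#'
#' @return integer vector `c(500L, 1000L, 1250L, 1980L)`.
#' @export
default_flank_set <- function() c(500L, 1000L, 1250L, 1980L)

#' Validate a user-supplied flank set
#'
#' Flank lengths are deduplicated and sorted ascending.  A singleton set is
#' allowed (consensus degenerates to that single lift).  Lengths whose
#' untruncated parent window (2L+1) falls below the minimum alignable length
#' trigger a warning: every untruncated parent they produce will be rejected
#' by the aligner.
#'
#' @param flank_set integer vector of flank lengths (bases), all >= 1.
#' @param min_len minimum alignable parent length in bases (default 100).
#' @return the sorted, deduplicated flank set.
#' @export
validate_flank_set <- function(flank_set, min_len = 100L) {
  flank_set <- sort(unique(as.integer(flank_set)))
  if (length(flank_set) == 0L || anyNA(flank_set) || any(flank_set < 1L))
    stopf("flank_set must be positive integers")
  short <- flank_set[2L * flank_set + 1L < min_len]
  if (length(short))
    warnf(paste0("flank length(s) %s give untruncated windows shorter than ",
                 "the %d bp alignability floor"),
          paste(short, collapse = ", "), min_len)
  flank_set
}

#' Build parent/child flank features for a SNP set
#'
#' One feature per SNP: the parent window `[pos - L, pos + L]` clamped at the
#' sequence ends (truncation flagged), the child at the SNP position.
#' Windows shorter than `min_len` are still emitted but flagged `too_short`;
#' SNPs on sequences absent from the assembly get status `chrom_missing`.
#'
#' @param snps a SNP `data.table` ([read_vcf] shape).
#' @param flank_len flank length L in bases (window spans `2L+1`).
#' @param asm the source [assembly].
#' @param min_len minimum alignable parent length (bases).
#' @return a `data.table` with `feature_id`, `snp_idx`, `chrom`, `child_pos`,
#'   `flank_len`, `parent_start`, `parent_end` (1-based inclusive),
#'   `truncated_left`, `truncated_right`, `too_short`, `chrom_missing`.
#' @export
build_flank_features <- function(snps, flank_len, asm, min_len = 100L) {
  flank_len <- as.integer(flank_len)
  if (flank_len < 1L) stopf("flank_len must be >= 1")
  lens <- seq_lengths(asm)
  clen <- lens[snps$chrom]
  missing <- is.na(clen)
  ps <- pmax(1L, snps$pos - flank_len)
  pe <- pmin(as.integer(clen), snps$pos + flank_len)
  pe[missing] <- NA_integer_
  dt <- data.table::data.table(
    feature_id = sprintf("snp%d_flank%d", seq_len(nrow(snps)), flank_len),
    snp_idx = seq_len(nrow(snps)),
    chrom = snps$chrom,
    child_pos = snps$pos,
    flank_len = flank_len,
    parent_start = ps,
    parent_end = pe,
    truncated_left = !missing & ps > snps$pos - flank_len,
    truncated_right = !missing & pe < snps$pos + flank_len,
    too_short = !missing & (pe - ps + 1L) < min_len,
    chrom_missing = missing)
  dt[]
}

#' Resolve a projected feature back to its SNP lift outcome
#'
#' @param projected a list (or one-row data.frame) with `feature_id`,
#'   `status`, and when lifted `target_chrom`, `target_pos`, `target_strand`,
#'   plus optional metadata (`identity`, `coverage`, `score_margin`).
#' @param features the feature table the projection came from
#'   ([build_flank_features]).
#' @return a list (`LiftOutcome`): `snp_idx`, `flank_len`, `status`, and the
#'   target coordinates when `status == "lifted"`.
#' @export
feature_to_snp <- function(projected, features) {
  i <- match(projected$feature_id, features$feature_id)
  if (is.na(i))
    stopf("unknown feature_id '%s' (pipeline corruption?)",
          projected$feature_id)
  out <- list(snp_idx = features$snp_idx[i],
              flank_len = features$flank_len[i],
              status = projected$status,
              target_chrom = NA_character_, target_pos = NA_integer_,
              target_strand = NA_character_,
              identity = projected$identity %||% NA_real_,
              coverage = projected$coverage %||% NA_real_,
              score_margin = projected$score_margin %||% NA_real_)
  if (identical(projected$status, "lifted")) {
    out$target_chrom <- projected$target_chrom
    out$target_pos <- projected$target_pos
    out$target_strand <- projected$target_strand
  }
  out
}
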