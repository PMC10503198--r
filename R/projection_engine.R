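# projection_engine: place a parent window on the target assembly and deduce
# the child's single-base coordinate.  The aligner searches every target
# sequence and both strands (no chromosome-to-chromosome restriction), so a
# SNP may land on a different chromosome or a newly anchored scaffold.

#' Alignment and projection parameters
#'
#' @param k seed k-mer size (exact-match seeding).
#' @param index_stride index every `index_stride`-th target k-mer.
#' @param query_stride query every `query_stride`-th parent k-mer.
#' @param band half-width of the banded extension around the chained seeds.
#' @param max_occ seeds occurring more often than this in the target are
#'   skipped (repeat masking at the seed level).
#' @param max_gap_mult maximum seed gap within a chain, as a multiple of the
#'   parent length.
#' @param max_clusters at most this many candidate loci are extended per
#'   parent and strand.
#' @param min_len minimum alignable parent length in bases; shorter parents
#'   are rejected (the classic short-read mappers' floor).
#' @param min_identity,min_coverage placements below either fraction are
#'   discarded.
#' @param match,mismatch,gap_open,gap_extend alignment scoring; a gap of
#'   length L costs `gap_open + gap_extend * L`.
#' @param min_margin the best placement must beat the runner-up score by more
#'   than this (ties across loci are ambiguous).
#' @param aligner `"internal"` (the only implemented backend).
#' @return a list of class `align_params`.
#' @export
align_params <- function(k = 15L, index_stride = 4L, query_stride = 5L,
                         band = 32L, max_occ = 64L, max_gap_mult = 2,
                         max_clusters = 16L, min_len = 100L,
                         min_identity = 0.5, min_coverage = 0.5,
                         match = 1, mismatch = -1, gap_open = 2,
                         gap_extend = 1, min_margin = 0,
                         aligner = "internal") {
  stopifnot(k >= 4, k <= 31, index_stride >= 1, query_stride >= 1,
            band >= 1, min_len >= 1, min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1, min_margin >= 0)
  if (!identical(aligner, "internal"))
    stopf("only the internal aligner backend is implemented")
  structure(list(k = as.integer(k), index_stride = as.integer(index_stride),
                 query_stride = as.integer(query_stride),
                 band = as.integer(band), max_occ = as.integer(max_occ),
                 max_gap_mult = max_gap_mult,
                 max_clusters = as.integer(max_clusters),
                 min_len = as.integer(min_len), min_identity = min_identity,
                 min_coverage = min_coverage, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_margin = min_margin,
                 aligner = aligner),
            class = "align_params")
}

#' Build a reusable k-mer index of a target assembly
#'
#' @param target an [assembly].
#' @param params an [align_params].
#' @return an external-pointer index of class `target_index`.
#' @export
target_index <- function(target, params = align_params()) {
  if (length(target) == 0L) stopf("target assembly is empty")
  xp <- cpp_build_index(names(target), as.character(target),
                        params$k, params$index_stride)
  structure(list(ptr = xp, names = names(target),
                 lengths = seq_lengths(target)),
            class = "target_index")
}

as_target_index <- function(target, params) {
  if (inherits(target, "target_index")) target
  else target_index(target, params)
}

#' Align a parent window to the whole target assembly
#'
#' Exact-match k-mer seeding, colinear chaining per (sequence, strand) and
#' banded affine-gap extension.  All placements passing the identity and
#' coverage thresholds are returned; the count of raw candidate placements
#' (before thresholding) is attached as attribute `n_raw`.
#'
#' @param parent_seq parent nucleotide string (length >= `params$min_len`).
#' @param target an [assembly] or a prebuilt [target_index].
#' @param params an [align_params].
#' @return a list of placements, each a list with `chrom`, `start`/`end`
#'   (0-based half-open on the target), `strand`, `identity`, `coverage`,
#'   `score`, `parent_aln_start`/`parent_aln_end` (0-based half-open in the
#'   oriented parent) and the coordinate map (`cigar_op`, `cigar_len`; ops
#'   `M` consume both, `I` target only, `D` parent only).
#' @export
align_parent <- function(parent_seq, target, params = align_params()) {
  if (nchar(parent_seq) < params$min_len)
    stopf("parent length %d is below the minimum alignable length %d",
          nchar(parent_seq), params$min_len)
  ix <- as_target_index(target, params)
  pls <- cpp_align_parent(ix$ptr, parent_seq,
                          params$query_stride, params$max_occ, params$band,
                          params$max_gap_mult, params$max_clusters,
                          params$gap_open, params$gap_extend,
                          params$min_identity, params$min_coverage)
  n_raw <- attr(pls, "n_raw")
  pls <- lapply(pls, function(p) {
    # coordinate-map conservation, asserted on every placement
    tcons <- sum(p$cigar_len[p$cigar_op != "D"])
    pcons <- sum(p$cigar_len[p$cigar_op != "I"])
    stopifnot(tcons == p$end - p$start,
              pcons == p$parent_aln_end - p$parent_aln_start)
    p
  })
  # deduplicate same-locus placements from overlapping seed clusters
  if (length(pls) > 1L) {
    sc <- vapply(pls, function(p) p$score, 0)
    keep <- rep(TRUE, length(pls))
    for (i in seq_along(pls)) {
      if (!keep[i]) next
      for (j in seq_along(pls)) {
        if (i == j || !keep[j]) next
        a <- pls[[i]]; b <- pls[[j]]
        if (a$chrom == b$chrom && a$strand == b$strand &&
            min(a$end, b$end) - max(a$start, b$start) >
              0.5 * min(a$end - a$start, b$end - b$start)) {
          keep[if (sc[i] >= sc[j]) j else i] <- FALSE
        }
      }
    }
    pls <- pls[keep]
  }
  attr(pls, "n_raw") <- n_raw
  pls
}

#' Choose the best placement, or signal ambiguity
#'
#' Placements are ordered by (score desc, chrom, start, strand) so the choice
#' is deterministic.  If the best score does not exceed the runner-up at a
#' different locus by more than `min_margin`, the parent is ambiguous.
#'
#' @param placements list of placements from [align_parent].
#' @param params an [align_params].
#' @return the best placement, or the character signal `"no_alignment"` /
#'   `"ambiguous"`.
#' @export
choose_best <- function(placements, params = align_params()) {
  if (length(placements) == 0L) return("no_alignment")
  o <- order(-vapply(placements, function(p) p$score, 0),
             vapply(placements, function(p) p$chrom, ""),
             vapply(placements, function(p) p$start, 0),
             vapply(placements, function(p) p$strand, ""))
  placements <- placements[o]
  best <- placements[[1]]
  if (length(placements) > 1L) {
    second <- placements[[2]]
    if (best$score - second$score <= params$min_margin)
      return("ambiguous")
    best$score_margin <- best$score - second$score
  } else {
    best$score_margin <- Inf
  }
  best
}

#' Project the child base through a placement's coordinate map
#'
#' Walks the edit operations accumulating parent- and target-consumed bases
#' until the child offset is reached.  If the child base falls inside a
#' deletion-from-parent run, or outside the aligned parent span (clipped
#' ends), the child has no target base and the deleted signal is returned.
#' For minus-strand placements the child offset is counted from the right
#' edge of the oriented parent (the parent was reverse-complemented before
#' alignment), so the returned coordinate is the target base aligned to the
#' child.
#'
#' @param placement a placement from [align_parent].
#' @param parent_start 1-based start of the parent window on the source.
#' @param child_pos 1-based SNP position on the source.
#' @return a list with `chrom`, `pos` (1-based target) and `strand`, or the
#'   character signal `"deleted"`.
#' @export
project_child <- function(placement, parent_start, child_pos) {
  m <- placement$parent_len
  off <- child_pos - parent_start           # 0-based offset in parent
  if (off < 0L || off >= m) stopf("child outside parent window")
  if (placement$strand == "-") off <- m - 1L - off
  if (off < placement$parent_aln_start || off >= placement$parent_aln_end)
    return("deleted")
  p <- placement$parent_aln_start
  t <- placement$start
  ops <- placement$cigar_op
  lens <- placement$cigar_len
  for (r in seq_along(ops)) {
    len <- lens[r]
    if (ops[r] == "M") {
      if (off < p + len)
        return(list(chrom = placement$chrom,
                    pos = as.integer(t + (off - p) + 1),
                    strand = placement$strand))
      p <- p + len; t <- t + len
    } else if (ops[r] == "D") {
      if (off < p + len) return("deleted")
      p <- p + len
    } else {                                # I: target only
      t <- t + len
    }
  }
  "deleted"
}

#' Project one flank feature onto the target assembly
#'
#' Extracts the parent sequence, aligns it, picks the best placement and
#' walks the coordinate map to the child base.
#'
#' @param feature one row of [build_flank_features] (as list or data.frame).
#' @param source the source [assembly].
#' @param target an [assembly] or prebuilt [target_index].
#' @param params an [align_params].
#' @return a list (`ProjectedFeature`): `feature_id`, `status` (one of
#'   `lifted`, `unlifted_no_alignment`, `unlifted_ambiguous`,
#'   `unlifted_child_deleted`, `unlifted_below_threshold`, `too_short`,
#'   `chrom_missing`), and when lifted `target_chrom`, `target_pos`,
#'   `target_strand`, `identity`, `coverage`, `score_margin`.
#' @export
project_feature <- function(feature, source, target, params = align_params()) {
  out <- list(feature_id = feature$feature_id, status = NA_character_,
              target_chrom = NA_character_, target_pos = NA_integer_,
              target_strand = NA_character_, identity = NA_real_,
              coverage = NA_real_, score_margin = NA_real_)
  if (isTRUE(feature$chrom_missing)) { out$status <- "chrom_missing"; return(out) }
  if (isTRUE(feature$too_short)) { out$status <- "too_short"; return(out) }
  pseq <- substr(source[[feature$chrom]], feature$parent_start,
                 feature$parent_end)
  pls <- align_parent(pseq, target, params)
  if (length(pls) == 0L) {
    out$status <- if ((attr(pls, "n_raw") %||% 0L) > 0L)
      "unlifted_below_threshold" else "unlifted_no_alignment"
    return(out)
  }
  best <- choose_best(pls, params)
  if (identical(best, "ambiguous")) { out$status <- "unlifted_ambiguous"; return(out) }
  proj <- project_child(best, feature$parent_start, feature$child_pos)
  if (identical(proj, "deleted")) { out$status <- "unlifted_child_deleted"; return(out) }
  out$status <- "lifted"
  out$target_chrom <- proj$chrom
  out$target_pos <- proj$pos
  out$target_strand <- proj$strand
  out$identity <- best$identity
  out$coverage <- best$coverage
  out$score_margin <- best$score_margin
  out
}
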