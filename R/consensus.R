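# consensus_lift: run the projection at every flank length, keep only SNPs
# lifted to the identical (chrom, pos, strand) at all of them, apply the
# strand policy, classify chromosome transitions and summarize.

# shared core: align one parent sequence and project its child
.project_parent <- function(pseq, parent_start, child_pos, ix, params) {
  out <- list(status = NA_character_, target_chrom = NA_character_,
              target_pos = NA_integer_, target_strand = NA_character_,
              identity = NA_real_, coverage = NA_real_,
              score_margin = NA_real_)
  pls <- align_parent(pseq, ix, params)
  if (length(pls) == 0L) {
    out$status <- if ((attr(pls, "n_raw") %||% 0L) > 0L)
      "unlifted_below_threshold" else "unlifted_no_alignment"
    return(out)
  }
  best <- choose_best(pls, params)
  if (identical(best, "ambiguous")) {
    out$status <- "unlifted_ambiguous"
    return(out)
  }
  proj <- project_child(best, parent_start, child_pos)
  if (identical(proj, "deleted")) {
    out$status <- "unlifted_child_deleted"
    return(out)
  }
  list(status = "lifted", target_chrom = proj$chrom, target_pos = proj$pos,
       target_strand = proj$strand, identity = best$identity,
       coverage = best$coverage, score_margin = best$score_margin)
}

#' Lift a SNP set at several flank lengths and take the consensus
#'
#' Runs the flank-anchored projection once per flank length and combines the
#' per-flank outcomes: a SNP is `consistent` when every flank length lifted
#' it to the identical (chromosome, position, strand); `incomplete` when at
#' least one flank length failed to lift; `inconsistent` when all lifted but
#' the locations differ.  Only consistent SNPs can be retained; the strand
#' policy then decides the fate of minus-strand lifts.
#'
#' @param snps SNP `data.table` ([read_vcf] shape).
#' @param source,target source and target [assembly] objects (`target` may
#'   be a prebuilt [target_index]).
#' @param flank_set flank lengths in bases (default [default_flank_set]).
#' @param params an [align_params].
#' @param strand_policy `"drop_minus"` (default: minus-strand consistent
#'   SNPs are not retained) or `"rescue_minus"` (kept, alleles
#'   complemented).
#' @param un_prefix_source,un_prefix_target sequence-name prefix marking
#'   unanchored scaffolds (default `"chrUn"`).
#' @param verbose print per-flank progress.
#' @return an object of class `lift_result`: a list with `per_flank` (one
#'   row per SNP x flank length), `consensus` (one row per SNP), plus the
#'   configuration used.
#' @export
lift_consensus <- function(snps, source, target,
                           flank_set = default_flank_set(),
                           params = align_params(),
                           strand_policy = c("drop_minus", "rescue_minus"),
                           un_prefix_source = "chrUn",
                           un_prefix_target = "chrUn",
                           verbose = FALSE) {
  strand_policy <- match.arg(strand_policy)
  flank_set <- validate_flank_set(flank_set, params$min_len)
  ix <- as_target_index(target, params)
  n <- nrow(snps)
  per <- vector("list", length(flank_set))
  for (fi in seq_along(flank_set)) {
    L <- flank_set[fi]
    feats <- build_flank_features(snps, L, source, params$min_len)
    pseqs <- substr(source[feats$chrom], feats$parent_start,
                    feats$parent_end)
    status <- character(n)
    tchrom <- rep(NA_character_, n); tpos <- rep(NA_integer_, n)
    tstrand <- rep(NA_character_, n); ident <- rep(NA_real_, n)
    cov <- rep(NA_real_, n); marg <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (feats$chrom_missing[i]) { status[i] <- "chrom_missing"; next }
      if (feats$too_short[i]) { status[i] <- "too_short"; next }
      r <- .project_parent(pseqs[i], feats$parent_start[i],
                           feats$child_pos[i], ix, params)
      status[i] <- r$status
      if (r$status == "lifted") {
        tchrom[i] <- r$target_chrom; tpos[i] <- r$target_pos
        tstrand[i] <- r$target_strand; ident[i] <- r$identity
        cov[i] <- r$coverage; marg[i] <- r$score_margin
      }
    }
    per[[fi]] <- data.table::data.table(
      snp_idx = feats$snp_idx, flank_len = L, feature_id = feats$feature_id,
      status = status, tchrom = tchrom, tpos = tpos, tstrand = tstrand,
      identity = ident, coverage = cov, score_margin = marg,
      truncated_left = feats$truncated_left,
      truncated_right = feats$truncated_right)
    if (verbose)
      message(sprintf("flank %d: %d/%d lifted", L,
                      sum(status == "lifted"), n))
  }
  per_flank <- data.table::rbindlist(per)
  consensus <- consensus_from_per_flank(per_flank, flank_set, snps,
                                        un_prefix_source, un_prefix_target)
  res <- structure(list(per_flank = per_flank, consensus = consensus,
                        flank_set = flank_set, params = params,
                        strand_policy = strand_policy,
                        un_prefix_source = un_prefix_source,
                        un_prefix_target = un_prefix_target),
                   class = "lift_result")
  apply_strand_policy(res, strand_policy)
}

#' Recompute the consensus from per-flank outcomes
#'
#' Pure bookkeeping over an existing per-flank table, so consensus subsets
#' for different flank sets can be compared without re-aligning.
#'
#' @param per_flank the `per_flank` table of a [lift_consensus] result.
#' @param flank_set the flank lengths to combine (must be a subset of those
#'   present in `per_flank`).
#' @param snps the SNP table the lift was run on.
#' @param un_prefix_source,un_prefix_target unanchored-name prefixes.
#' @return the consensus `data.table` (one row per SNP), with `retained`
#'   set to `status == "consistent"` (no strand policy applied).
#' @export
consensus_from_per_flank <- function(per_flank, flank_set, snps,
                                     un_prefix_source = "chrUn",
                                     un_prefix_target = "chrUn") {
  flank_set <- sort(unique(as.integer(flank_set)))
  if (nrow(per_flank) > 0L) {
    miss <- setdiff(flank_set, unique(per_flank$flank_len))
    if (length(miss))
      stopf("per_flank table has no outcomes for flank length %d", miss[1])
  }
  w <- per_flank[flank_len %in% flank_set]
  nf <- length(flank_set)
  agg <- w[, {
    lifted <- status == "lifted"
    loc <- paste(tchrom[lifted], tpos[lifted], tstrand[lifted])
    st <- if (sum(lifted) < nf) "incomplete"
          else if (data.table::uniqueN(loc) == 1L) "consistent"
          else "inconsistent"
    k <- which(lifted)[1]
    list(status = st,
         tchrom = if (st == "consistent") tchrom[k] else NA_character_,
         tpos = if (st == "consistent") tpos[k] else NA_integer_,
         tstrand = if (st == "consistent") tstrand[k] else NA_character_,
         identity_min = if (any(lifted)) min(identity[lifted]) else NA_real_,
         truncated = any(truncated_left) || any(truncated_right))
  }, by = snp_idx]
  data.table::setorder(agg, snp_idx)
  cons <- data.table::data.table(
    snp_idx = seq_len(nrow(snps)), chrom = snps$chrom, pos = snps$pos,
    id = snps$id, ref = snps$ref, alt = snps$alt)
  cons <- agg[cons, on = "snp_idx"]
  cons[is.na(status), status := "incomplete"]   # defensive; should not occur
  cons[, strand_class := data.table::fifelse(
    status == "consistent" & tstrand == "-", "minus",
    data.table::fifelse(status == "consistent", "plus", NA_character_))]
  cons[, transition := data.table::fifelse(
    status == "consistent",
    classify_transition(chrom, tchrom, un_prefix_source, un_prefix_target),
    NA_character_)]
  cons[, retained := status == "consistent"]
  data.table::setcolorder(cons, c("snp_idx", "chrom", "pos", "id", "ref",
                                  "alt", "status", "tchrom", "tpos",
                                  "tstrand", "strand_class", "transition",
                                  "retained", "identity_min", "truncated"))
  cons[]
}

#' Apply a strand policy to consensus outcomes
#'
#' Under `drop_minus` (the default final-dataset definition) consistent
#' minus-strand SNPs are not retained.  Under `rescue_minus` they stay
#' retained with reference and alternate alleles complemented (the lifted
#' VCF then reports plus-strand alleles of the target).
#'
#' @param result a `lift_result` from [lift_consensus].
#' @param policy `"drop_minus"` or `"rescue_minus"`.
#' @return the modified `lift_result`.
#' @export
apply_strand_policy <- function(result, policy = c("drop_minus",
                                                   "rescue_minus")) {
  policy <- match.arg(policy)
  cons <- data.table::copy(result$consensus)
  cons[, retained := status == "consistent"]
  minus <- cons$status == "consistent" & cons$strand_class == "minus"
  if (policy == "drop_minus") {
    cons[minus, retained := FALSE]
  } else if (any(minus)) {
    cons[minus, `:=`(ref = comp_base(ref),
                     alt = vapply(strsplit(alt, ",", fixed = TRUE),
                                  function(a) paste(comp_base(a),
                                                    collapse = ","), ""))]
  }
  result$consensus <- cons
  result$strand_policy <- policy
  result
}

#' Classify the chromosome transition of a lifted SNP
#'
#' Compares source and target sequence names; names starting with the
#' unanchored prefix are treated as unanchored scaffolds.
#'
#' @param src_chrom,tgt_chrom source and target sequence names (vectorized).
#' @param un_prefix_source,un_prefix_target unanchored-name prefixes.
#' @return character vector with levels `same_chrom`, `diff_chrom`,
#'   `un_to_anchored`, `anchored_to_un`, `un_to_un`.
#' @export
classify_transition <- function(src_chrom, tgt_chrom,
                                un_prefix_source = "chrUn",
                                un_prefix_target = "chrUn") {
  if (length(src_chrom) == 0L) return(character(0))
  na <- is.na(src_chrom) | is.na(tgt_chrom)
  s <- ifelse(na, "", src_chrom)
  t <- ifelse(na, "", tgt_chrom)
  su <- startsWith(s, un_prefix_source)
  tu <- startsWith(t, un_prefix_target)
  out <- character(length(s))
  out[su & tu] <- "un_to_un"
  out[su & !tu] <- "un_to_anchored"
  out[!su & tu] <- "anchored_to_un"
  both <- !su & !tu
  out[both] <- ifelse(s[both] == t[both], "same_chrom", "diff_chrom")
  out[na] <- NA_character_
  out
}

#' Summarize a lift result
#'
#' @param result a `lift_result`.
#' @return a list of `data.table`s: `per_flank` lifted counts, `consensus`
#'   status counts, `strand` partition with percentages (over consistent
#'   SNPs), `transitions` (source chrom x target chrom counts with class),
#'   and scalar `n_input`, `n_retained`.
#' @export
summarize_lift <- function(result) {
  pf <- result$per_flank[, .(lifted = sum(status == "lifted"), total = .N),
                         by = flank_len]
  cons <- result$consensus
  st <- cons[, .(count = .N), by = status]
  consistent <- cons[status == "consistent"]
  strand <- consistent[, .(count = .N), by = strand_class]
  strand[, pct := if (nrow(consistent)) 100 * count / nrow(consistent)
         else 0]
  trans <- consistent[, .(count = .N), by = .(chrom, tchrom, transition)]
  data.table::setorder(trans, -count)
  list(per_flank = pf[], consensus = st[], strand = strand[],
       transitions = trans[], n_input = nrow(cons),
       n_retained = sum(cons$retained))
}

#' @export
print.lift_result <- function(x, ...) {
  s <- summarize_lift(x)
  cat(sprintf("lift_result: %d SNPs, flank set {%s}\n", s$n_input,
              paste(x$flank_set, collapse = ", ")))
  for (i in seq_len(nrow(s$per_flank)))
    cat(sprintf("  flank %4d: %d/%d lifted\n", s$per_flank$flank_len[i],
                s$per_flank$lifted[i], s$per_flank$total[i]))
  cat(sprintf("  consensus: %d consistent, %d retained (policy %s)\n",
              sum(x$consensus$status == "consistent"), s$n_retained,
              x$strand_policy))
  invisible(x)
}

#' Per-chromosome binned SNP density
#'
#' Counts SNPs per fixed-width bin; positions are 1-based and a position
#' equal to a bin boundary falls in the lower bin (`bin = ceiling(pos /
#' bin_size)`).  The last bin of each chromosome may be short.  Bins with no
#' SNPs are reported with count 0 so the profile covers the whole assembly.
#'
#' @param x a `lift_result` (retained SNPs at their target coordinates) or a
#'   `data.table` with `chrom` and `pos` columns.
#' @param asm the [assembly] the coordinates refer to.
#' @param bin_size bin width in bases (default 10 Mb).
#' @return a `data.table` with `chrom`, `bin_start`, `bin_end` (1-based
#'   inclusive) and `count`; `sum(count)` equals the number of input SNPs.
#' @export
density_profile <- function(x, asm, bin_size = 1e7) {
  if (bin_size < 1) stopf("bin_size must be >= 1")
  if (inherits(x, "lift_result"))
    dt <- x$consensus[retained == TRUE, .(chrom = tchrom, pos = tpos)]
  else dt <- data.table::data.table(chrom = x$chrom, pos = x$pos)
  lens <- seq_lengths(asm)
  bad <- !dt$chrom %in% names(lens)
  if (any(bad)) stopf("position on sequence absent from assembly: %s",
                      dt$chrom[bad][1])
  nb <- pmax(1L, as.integer(ceiling(lens / bin_size)))
  grid <- data.table::data.table(
    chrom = rep(names(lens), nb),
    bin = unlist(lapply(nb, seq_len), use.names = FALSE))
  grid[, bin_start := as.integer((bin - 1) * bin_size + 1)]
  grid[, bin_end := as.integer(pmin(bin * bin_size, lens[chrom]))]
  cnt <- dt[, .(count = .N), by = .(chrom, bin = ceiling(pos / bin_size))]
  out <- cnt[grid, on = c("chrom", "bin")]
  out[is.na(count), count := 0L]
  data.table::setcolorder(out, c("chrom", "bin", "bin_start", "bin_end",
                                 "count"))
  data.table::setorder(out, chrom, bin)
  out[]
}
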