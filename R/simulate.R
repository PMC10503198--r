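# synthetic_assembly: generate source/target assembly pairs related by a
# known edit script (inversions, relocations, scaffold anchoring/dropping,
# small indels, point divergence) plus planted SNPs, and keep the exact
# source->target coordinate function (the truth map) as the testing oracle.

#' Generate a random source assembly
#'
#' I.i.d. bases at a given GC content; chromosomes are named `chr1..chrN`
#' and unanchored scaffolds `chrUn_1..`.  Reproducible from the seed.
#'
#' @param n_chroms number of anchored chromosomes.
#' @param chrom_lengths lengths in bases (recycled to `n_chroms`).
#' @param n_unanchored number of unanchored scaffolds.
#' @param un_lengths their lengths in bases.
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed (NULL = use current RNG state).
#' @return an [assembly].
#' @export
generate_source <- function(n_chroms, chrom_lengths, n_unanchored = 0L,
                            un_lengths = integer(0), gc = 0.45,
                            seed = NULL) {
  stopifnot(n_chroms >= 1, gc > 0, gc < 1)
  chrom_lengths <- rep_len(as.integer(chrom_lengths), n_chroms)
  if (n_unanchored > 0)
    un_lengths <- rep_len(as.integer(un_lengths), n_unanchored)
  if (any(c(chrom_lengths, un_lengths) < 1)) stopf("lengths must be >= 1")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    nm <- c(paste0("chr", seq_len(n_chroms)),
            if (n_unanchored > 0) paste0("chrUn_", seq_len(n_unanchored)))
    lens <- c(chrom_lengths, un_lengths)
    seqs <- vapply(lens, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    assembly(setNames(seqs, nm))
  })
}

# ---- edit script --------------------------------------------------------

#' Assembly edit operations
#'
#' Builders for the operations of an [edit_script]: segment inversion,
#' segment relocation to another chromosome, anchoring of an unanchored
#' scaffold into a chromosome, dropping a scaffold, uniform point
#' divergence, and small indels.  Intervals are 1-based inclusive on the
#' source; `dst_pos` means "insert before this base" (`len + 1` appends).
#'
#' @param chrom,scaffold,src_chrom,dst_chrom sequence names.
#' @param start,end 1-based inclusive interval bounds.
#' @param dst_pos 1-based insertion point on the destination.
#' @param orientation `"+"` or `"-"` for inserted segments.
#' @param rate per-base event rate.
#' @param max_len maximum indel length in bases.
#' @return an op list understood by [edit_script].
#' @name edit_ops
NULL

#' @rdname edit_ops
#' @export
op_invert <- function(chrom, start, end)
  list(type = "invert", chrom = chrom, start = as.integer(start),
       end = as.integer(end))

#' @rdname edit_ops
#' @export
op_relocate <- function(src_chrom, start, end, dst_chrom, dst_pos,
                        orientation = "+")
  list(type = "relocate", chrom = src_chrom, start = as.integer(start),
       end = as.integer(end), dst_chrom = dst_chrom,
       dst_pos = as.integer(dst_pos), orientation = orientation)

#' @rdname edit_ops
#' @export
op_anchor <- function(scaffold, dst_chrom, dst_pos, orientation = "+")
  list(type = "anchor", chrom = scaffold, dst_chrom = dst_chrom,
       dst_pos = as.integer(dst_pos), orientation = orientation)

#' @rdname edit_ops
#' @export
op_drop <- function(scaffold) list(type = "drop", chrom = scaffold)

#' @rdname edit_ops
#' @export
op_diverge <- function(rate) list(type = "diverge", rate = rate)

#' @rdname edit_ops
#' @export
op_indel <- function(rate, max_len = 10L)
  list(type = "indel", rate = rate, max_len = as.integer(max_len))

#' Build an assembly edit script
#'
#' @param ... ops from [op_invert], [op_relocate], [op_anchor], [op_drop],
#'   [op_diverge], [op_indel] (or a single list of them).
#' @param seed RNG seed used for the stochastic ops (indel positions,
#'   inserted bases, divergence).
#' @return a list of class `edit_script`.
#' @export
edit_script <- function(..., seed = 1L) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1]]) && is.null(ops[[1]]$type))
    ops <- ops[[1]]
  structure(list(ops = ops, seed = as.integer(seed)), class = "edit_script")
}

validate_script <- function(source, script) {
  lens <- seq_lengths(source)
  ops <- script$ops
  iv <- list()   # structural intervals per chrom
  add_iv <- function(chrom, a, b) {
    cur <- iv[[chrom]] %||% NULL
    iv[[chrom]] <<- rbind(cur, c(a, b))
  }
  removed <- character(0)
  for (op in ops) {
    if (op$type %in% c("diverge", "indel")) next
    if (!op$chrom %in% names(lens))
      stopf("edit op on unknown sequence '%s'", op$chrom)
    if (op$type %in% c("invert", "relocate")) {
      if (op$start < 1 || op$end > lens[[op$chrom]] || op$start > op$end)
        stopf("interval [%d,%d] out of bounds on %s", op$start, op$end,
              op$chrom)
      add_iv(op$chrom, op$start, op$end)
    }
    if (op$type %in% c("anchor", "drop")) {
      add_iv(op$chrom, 1L, lens[[op$chrom]])
      removed <- c(removed, op$chrom)
    }
  }
  for (chrom in names(iv)) {
    m <- iv[[chrom]][order(iv[[chrom]][, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stopf("overlapping structural ops on %s", chrom)
  }
  for (op in ops) {
    if (!op$type %in% c("relocate", "anchor")) next
    if (!op$dst_chrom %in% names(lens))
      stopf("destination sequence '%s' unknown", op$dst_chrom)
    if (op$dst_chrom %in% removed)
      stopf("cannot insert into dropped/anchored sequence '%s'",
            op$dst_chrom)
    if (op$dst_pos < 1 || op$dst_pos > lens[[op$dst_chrom]] + 1L)
      stopf("dst_pos %d out of bounds on %s", op$dst_pos, op$dst_chrom)
    m <- iv[[op$dst_chrom]]
    if (!is.null(m) &&
        any(m[, 1] < op$dst_pos & op$dst_pos <= m[, 2]))
      stopf("dst_pos %d on %s falls inside another structural interval",
            op$dst_pos, op$dst_chrom)
  }
  invisible(TRUE)
}

#' Apply an edit script to a source assembly
#'
#' Structural ops first (applied on original source coordinates; they must
#' not overlap), then small indels, then point divergence.  The returned
#' truth map records the exact piecewise source-to-target coordinate
#' function; substitutions do not alter the map, indels shift it within a
#' piece, dropped-scaffold bases are unmapped.
#'
#' @param source an [assembly].
#' @param script an [edit_script].
#' @return a list with `target` ([assembly]) and `truth` (a `data.table`
#'   truth map: `src_chrom`, `src_start`, `src_end` 0-based half-open,
#'   `tgt_chrom`, `tgt_start`, `tgt_end`, `strand`).
#' @export
apply_edit_script <- function(source, script) {
  stopifnot(inherits(script, "edit_script"))
  validate_script(source, script)
  lens <- seq_lengths(source)
  ops <- script$ops
  removed <- vapply(Filter(function(o) o$type %in% c("anchor", "drop"), ops),
                    function(o) o$chrom, "")
  surviving <- setdiff(names(source), removed)

  # structural layout: ordered pieces per target chromosome
  # piece: list(src, s0, e0, strand, seq) -- s0/e0 0-based half-open;
  # insert pieces have src = NA and carry their own sequence
  layout <- list()
  for (C in surviving) {
    L <- lens[[C]]
    cuts <- c(1L, L + 1L)
    for (op in ops) {
      if (op$type %in% c("invert", "relocate") && op$chrom == C)
        cuts <- c(cuts, op$start, op$end + 1L)
      if (op$type %in% c("relocate", "anchor") && op$dst_chrom == C)
        cuts <- c(cuts, op$dst_pos)
    }
    cuts <- sort(unique(cuts))
    pieces <- list()
    for (ci in seq_len(length(cuts) - 1L)) {
      b <- cuts[ci]
      # insertions anchored at this boundary, in op order
      for (op in ops) {
        if (op$type == "relocate" && op$dst_chrom == C && op$dst_pos == b)
          pieces[[length(pieces) + 1L]] <-
            list(src = op$chrom, s0 = op$start - 1L, e0 = op$end,
                 strand = op$orientation, seq = NULL)
        if (op$type == "anchor" && op$dst_chrom == C && op$dst_pos == b)
          pieces[[length(pieces) + 1L]] <-
            list(src = op$chrom, s0 = 0L, e0 = lens[[op$chrom]],
                 strand = op$orientation, seq = NULL)
      }
      s <- cuts[ci]; e <- cuts[ci + 1L] - 1L   # 1-based inclusive segment
      drop_seg <- FALSE; strand <- "+"
      for (op in ops) {
        if (!op$type %in% c("invert", "relocate") || op$chrom != C) next
        if (op$type == "relocate" && op$start == s && op$end == e)
          drop_seg <- TRUE
        if (op$type == "invert" && op$start == s && op$end == e)
          strand <- "-"
      }
      if (!drop_seg)
        pieces[[length(pieces) + 1L]] <-
          list(src = C, s0 = s - 1L, e0 = e, strand = strand, seq = NULL)
    }
    # trailing insertions at position L + 1
    b <- L + 1L
    for (op in ops) {
      if (op$type == "relocate" && op$dst_chrom == C && op$dst_pos == b)
        pieces[[length(pieces) + 1L]] <-
          list(src = op$chrom, s0 = op$start - 1L, e0 = op$end,
               strand = op$orientation, seq = NULL)
      if (op$type == "anchor" && op$dst_chrom == C && op$dst_pos == b)
        pieces[[length(pieces) + 1L]] <-
          list(src = op$chrom, s0 = 0L, e0 = lens[[op$chrom]],
               strand = op$orientation, seq = NULL)
    }
    layout[[C]] <- pieces
  }

  indel_ops <- Filter(function(o) o$type == "indel", ops)
  div_ops <- Filter(function(o) o$type == "diverge", ops)

  with_seed(script$seed, {
    # small indels: split pieces, shifting the map within a chromosome
    for (io in indel_ops) {
      for (C in names(layout)) {
        newp <- list()
        for (p in layout[[C]]) {
          plen <- if (is.na(p$src)) nchar(p$seq) else p$e0 - p$s0
          nev <- rbinom(1L, plen, io$rate)
          if (nev == 0L) { newp[[length(newp) + 1L]] <- p; next }
          xs <- sort(sample.int(plen, min(nev, plen)))
          cur <- p
          off <- 0L   # bases already emitted from the original piece
          for (x in xs) {
            xl <- x - 1L - off          # offset within remaining piece
            plen_cur <- if (is.na(cur$src)) nchar(cur$seq)
                        else cur$e0 - cur$s0
            if (xl < 0L || xl >= plen_cur) next
            d <- sample.int(io$max_len, 1L)
            if (runif(1) < 0.5) {       # deletion of source/piece bases
              d <- min(d, plen_cur - xl)
              sp <- split_piece(cur, xl)
              sp2 <- split_piece(sp$right, d)
              newp[[length(newp) + 1L]] <- sp$left
              cur <- sp2$right
              off <- off + xl + d
            } else {                    # insertion of novel target bases
              ins <- paste(sample(c("A", "C", "G", "T"), d, TRUE),
                           collapse = "")
              sp <- split_piece(cur, xl)
              newp[[length(newp) + 1L]] <- sp$left
              newp[[length(newp) + 1L]] <-
                list(src = NA_character_, s0 = 0L, e0 = d, strand = "+",
                     seq = ins)
              cur <- sp$right
              off <- off + xl
            }
          }
          newp[[length(newp) + 1L]] <- cur
        }
        layout[[C]] <- Filter(function(p)
          (if (is.na(p$src)) nchar(p$seq) else p$e0 - p$s0) > 0L, newp)
      }
    }

    # materialise target sequences + truth map
    tseqs <- character(0)
    truth <- list()
    for (C in names(layout)) {
      parts <- character(0)
      t0 <- 0L
      for (p in layout[[C]]) {
        if (is.na(p$src)) {
          parts <- c(parts, p$seq)
          t0 <- t0 + nchar(p$seq)
        } else {
          s <- substr(source[[p$src]], p$s0 + 1L, p$e0)
          if (p$strand == "-") s <- revcomp(s)
          parts <- c(parts, s)
          plen <- p$e0 - p$s0
          truth[[length(truth) + 1L]] <- data.table::data.table(
            src_chrom = p$src, src_start = p$s0, src_end = p$e0,
            tgt_chrom = C, tgt_start = t0, tgt_end = t0 + plen,
            strand = p$strand)
          t0 <- t0 + plen
        }
      }
      tseqs[C] <- paste(parts, collapse = "")
    }

    # point divergence on the target (does not alter the map)
    for (dv in div_ops) {
      for (C in names(tseqs)) {
        L <- nchar(tseqs[C])
        ns <- rbinom(1L, L, dv$rate)
        if (ns == 0L) next
        ps <- sample.int(L, ns)
        v <- strsplit(tseqs[C], "", fixed = TRUE)[[1]]
        alts <- c("A", "C", "G", "T")
        for (p in ps) {
          choices <- setdiff(alts, v[p])
          v[p] <- choices[sample.int(3L, 1L)]
        }
        tseqs[C] <- paste(v, collapse = "")
      }
    }

    truth <- if (length(truth)) data.table::rbindlist(truth)
             else data.table::data.table(
               src_chrom = character(0), src_start = integer(0),
               src_end = integer(0), tgt_chrom = character(0),
               tgt_start = integer(0), tgt_end = integer(0),
               strand = character(0))
    list(target = assembly(tseqs), truth = truth)
  })
}

# split a piece at target-offset x (0 <= x <= len): left = first x target
# bases, right = the rest; respects strand for source-backed pieces
split_piece <- function(p, x) {
  if (is.na(p$src)) {
    left <- p; right <- p
    left$seq <- substr(p$seq, 1L, x); left$e0 <- x
    right$seq <- substr(p$seq, x + 1L, nchar(p$seq))
    right$e0 <- nchar(right$seq)
    return(list(left = left, right = right))
  }
  plen <- p$e0 - p$s0
  stopifnot(x >= 0L, x <= plen)
  if (p$strand == "+") {
    left <- list(src = p$src, s0 = p$s0, e0 = p$s0 + x, strand = "+",
                 seq = NULL)
    right <- list(src = p$src, s0 = p$s0 + x, e0 = p$e0, strand = "+",
                  seq = NULL)
  } else {
    left <- list(src = p$src, s0 = p$e0 - x, e0 = p$e0, strand = "-",
                 seq = NULL)
    right <- list(src = p$src, s0 = p$s0, e0 = p$e0 - x, strand = "-",
                  seq = NULL)
  }
  list(left = left, right = right)
}

#' Look planted positions up in a truth map
#'
#' @param truth the truth map from [apply_edit_script] (or [read_truth]).
#' @param chrom,pos source sequence names and 1-based positions
#'   (vectorized).
#' @return a `data.table` with `chrom`, `pos`, `tchrom`, `tpos`, `tstrand`
#'   (NA when the base is unmapped) and `piece_left`/`piece_right`, the
#'   distance in bases to the containing piece's edges.
#' @export
truth_lookup <- function(truth, chrom, pos) {
  q <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                              p0 = as.integer(pos) - 1L,
                              qi = seq_along(chrom))
  tr <- data.table::copy(truth)
  tr[, `:=`(ps = src_start, pe = src_end)]
  hit <- tr[q, on = .(src_chrom == chrom, src_start <= p0, src_end > p0)]
  data.table::setorder(hit, qi)
  p0 <- q$pos[hit$qi] - 1L
  tpos <- data.table::fifelse(hit$strand == "+",
                              hit$tgt_start + (p0 - hit$ps) + 1L,
                              hit$tgt_start + (hit$pe - 1L - p0) + 1L)
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         tchrom = hit$tgt_chrom, tpos = tpos,
                         tstrand = hit$strand,
                         piece_left = p0 - hit$ps,
                         piece_right = hit$pe - 1L - p0)
}

#' Write / read a truth map as TSV
#' @param truth a truth map `data.table`.
#' @param path file path.
#' @return `path` / the truth map.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("src_chrom", "tgt_chrom",
                                                    "strand")))
}

#' Plant random SNPs on an assembly
#'
#' Samples `n` distinct positions uniformly over the assembly; the reference
#' allele is the assembly base, the alternate a random different base.
#'
#' @param source an [assembly].
#' @param n number of SNPs.
#' @param seed RNG seed.
#' @param exclude_N skip positions whose base is N.
#' @return a SNP `data.table` in [read_vcf] shape, sorted by (assembly
#'   order, position).
#' @export
plant_snps <- function(source, n, seed = NULL, exclude_N = TRUE) {
  lens <- seq_lengths(source)
  total <- sum(as.numeric(lens))
  if (n > total) stopf("cannot plant %d SNPs on %0.f bases", n, total)
  cum <- cumsum(as.numeric(lens))
  with_seed(seed, {
    g <- sample(total, n)
    ci <- findInterval(g - 1, c(0, cum), rightmost.closed = FALSE)
    pos <- as.integer(g - c(0, cum)[ci])
    chrom <- names(lens)[ci]
    ref <- substring(source[chrom], pos, pos)
    if (exclude_N) {
      tries <- 0L
      while (any(bad <- ref == "N") && tries < 50L) {
        k <- sum(bad)
        g2 <- sample(total, k)
        ci2 <- findInterval(g2 - 1, c(0, cum), rightmost.closed = FALSE)
        pos[bad] <- as.integer(g2 - c(0, cum)[ci2])
        chrom[bad] <- names(lens)[ci2]
        ref <- substring(source[chrom], pos, pos)
        tries <- tries + 1L
      }
      if (any(ref == "N")) stopf("could not avoid N bases after 50 tries")
    }
    dup <- duplicated(paste(chrom, pos))
    while (any(dup)) {
      k <- sum(dup)
      g2 <- sample(total, k)
      ci2 <- findInterval(g2 - 1, c(0, cum), rightmost.closed = FALSE)
      pos[dup] <- as.integer(g2 - c(0, cum)[ci2])
      chrom[dup] <- names(lens)[ci2]
      dup <- duplicated(paste(chrom, pos))
    }
    ref <- substring(source[chrom], pos, pos)
    bases <- c("A", "C", "G", "T")
    alt <- vapply(ref, function(r) {
      ch <- setdiff(bases, r)
      ch[sample.int(length(ch), 1L)]
    }, "", USE.NAMES = FALSE)
    o <- order(match(chrom, names(lens)), pos)
    data.table::data.table(
      chrom = chrom[o], pos = pos[o],
      id = sprintf("snp%d", seq_len(n)),
      ref = ref[o], alt = alt[o], qual = ".", filter = ".", info = ".",
      gt = NA_character_)
  })
}

#' Evaluate a lift result against the truth map
#'
#' @param result a `lift_result` from [lift_consensus].
#' @param truth the simulator truth map.
#' @param snps the planted SNP table the lift was run on.
#' @param exclusion breakpoint-adjacent exclusion zone in bases (default
#'   1980, the longest default flank): SNPs closer than this to a piece
#'   edge may legitimately fail the consensus and are excluded from the
#'   clear-recovery rate.
#' @return a list (`EvalReport`): counts of recovered / mis-lifted /
#'   correct rejections, `recovery_rate` (exact recoveries over
#'   truth-mapped SNPs), `recovery_rate_clear` (same, breakpoint-adjacent
#'   SNPs excluded), `transition_mismatches`, and a per-transition table.
#' @export
evaluate_lift <- function(result, truth, snps, exclusion = 1980L) {
  tl <- truth_lookup(truth, snps$chrom, snps$pos)
  cons <- result$consensus
  stopifnot(nrow(cons) == nrow(tl))
  mapped <- !is.na(tl$tchrom)
  consistent <- cons$status == "consistent"
  exact <- consistent & mapped & cons$tchrom == tl$tchrom &
    cons$tpos == tl$tpos & cons$tstrand == tl$tstrand
  exact[is.na(exact)] <- FALSE
  mislift <- consistent & !exact
  correct_rej <- !mapped & !cons$retained
  near <- mapped & (tl$piece_left < exclusion | tl$piece_right < exclusion)
  expected_tr <- classify_transition(snps$chrom, tl$tchrom,
                                     result$un_prefix_source,
                                     result$un_prefix_target)
  tr_mismatch <- sum(exact & cons$transition != expected_tr, na.rm = TRUE)
  per_tr <- data.table::data.table(
    transition = expected_tr[mapped])[, .(n = .N), by = transition]
  list(n = nrow(cons),
       n_mapped = sum(mapped),
       recovered = sum(exact),
       mislift = sum(mislift),
       correct_rejections = sum(correct_rej),
       n_unmapped = sum(!mapped),
       recovery_rate = if (sum(mapped)) sum(exact) / sum(mapped) else NA,
       recovery_rate_clear = if (sum(mapped & !near))
         sum(exact & !near) / sum(mapped & !near) else NA,
       transition_mismatches = tr_mismatch,
       near_breakpoint = sum(near),
       per_transition = per_tr[])
}
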