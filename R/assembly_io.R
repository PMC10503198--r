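# assembly_io: FASTA / VCF / GFF3 under one explicit coordinate convention.
# External coordinates are 1-based inclusive; internal interval arithmetic is
# 0-based half-open (see to_zero_based / to_one_based).

#' Construct an assembly
#'
#' An assembly is a named set of upper-case nucleotide sequences with
#' random access by name.  Sequence names must be unique and non-empty.
#'
#' @param sequences named character vector of A/C/G/T/N strings
#'   (case-insensitive on input; stored upper-case).
#' @return an object of class `assembly`: a named character vector with a
#'   `lengths` attribute (named integer vector of sequence lengths).
#' @export
assembly <- function(sequences) {
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm)) || anyNA(nm))
    stopf("all sequences must have non-empty names")
  if (anyDuplicated(nm))
    stopf("duplicate sequence name: %s", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(sequences))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopf("sequence '%s' contains non-ACGTN residues", nm[bad][1])
  names(seqs) <- nm
  structure(seqs, lengths = setNames(nchar(seqs), nm), class = "assembly")
}

#' @export
as.character.assembly <- function(x, ...) c(unclass(x))

#' @export
print.assembly <- function(x, ...) {
  l <- seq_lengths(x)
  cat(sprintf("assembly: %d sequence(s), %s bp total\n",
              length(x), format(sum(as.numeric(l)), big.mark = ",")))
  show <- head(l, 8)
  for (i in seq_along(show))
    cat(sprintf("  %-20s %12s bp\n", names(show)[i],
                format(show[i], big.mark = ",")))
  if (length(l) > 8) cat(sprintf("  ... and %d more\n", length(l) - 8))
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param x an `assembly`.
#' @return named integer vector of lengths in bases.
#' @export
seq_lengths <- function(x) attr(x, "lengths")

#' Read a FASTA file into an assembly
#'
#' Accepts plain or gzip/bgzip-compressed FASTA.  Soft-masked lower-case
#' residues are upper-cased.  Header order is preserved.
#'
#' @param path path to a FASTA file.
#' @return an [assembly].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) stopf("no sequences in %s", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stopf("line 1: expected FASTA header ('>') in %s", path)
  nm <- sub("^>\\s*(\\S*).*$", "\\1", lines[hdr])
  if (any(!nzchar(nm))) {
    ln <- which(hdr)[!nzchar(nm)][1]
    stopf("line %d: malformed FASTA header (empty name)", ln)
  }
  if (anyDuplicated(nm))
    stopf("duplicate sequence name '%s'", nm[duplicated(nm)][1])
  grp <- cumsum(hdr)
  body <- !hdr
  bad <- body & grepl("[^ACGTNacgtn]", lines)
  if (any(bad)) stopf("line %d: non-IUPAC residue in sequence", which(bad)[1])
  seqs <- vapply(split(lines[body], grp[body]),
                 function(x) paste(x, collapse = ""), character(1))
  # groups with no body lines (empty sequences) still get an entry
  out <- setNames(character(length(nm)), as.character(seq_along(nm)))
  out[names(seqs)] <- seqs
  names(out) <- nm
  assembly(out)
}

#' Write an assembly to FASTA
#'
#' @param asm an [assembly].
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(asm, path, width = 60L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (nm in names(asm)) {
    writeLines(paste0(">", nm), con)
    s <- asm[[nm]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# ---- VCF ----------------------------------------------------------------

#' Read SNVs from a VCF file
#'
#' Reads a VCF 4.x file into a `data.table` of single-nucleotide variants.
#' Non-SNV records (indels, symbolic alleles) are skipped and counted, as are
#' records whose reference base is not A/C/G/T (reason `ambiguous_ref`).
#' Genotype (FORMAT + sample) columns are carried through verbatim as one
#' opaque text column `gt`.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return a `data.table` with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt` (comma-joined alternate alleles), `qual`, `filter`, `info`, `gt`;
#'   attributes `skipped` (named counts of skipped records), `samples`
#'   (sample column names) and `meta` (the `##` header lines).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  meta <- lines[startsWith(lines, "##")]
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1L) stopf("missing #CHROM header line in %s", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  samples <- if (length(hdr) > 9L) hdr[-(1:9)] else character(0)
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  skipped <- c(non_snv = 0L, ambiguous_ref = 0L)
  if (length(body) == 0L) {
    dt <- data.table::data.table(
      chrom = character(0), pos = integer(0), id = character(0),
      ref = character(0), alt = character(0), qual = character(0),
      filter = character(0), info = character(0), gt = character(0))
  } else {
    f <- data.table::tstrsplit(body, "\t", fixed = TRUE, names = FALSE,
                               keep = 1:8)
    gt <- sub("^([^\t]*\t){8}", "", body)
    gt[!grepl("^([^\t]*\t){8}", body)] <- NA_character_
    dt <- data.table::data.table(
      chrom = f[[1]], pos = as.integer(f[[2]]), id = f[[3]], ref = f[[4]],
      alt = f[[5]], qual = f[[6]], filter = f[[7]], info = f[[8]], gt = gt)
    is_snv <- nchar(dt$ref) == 1L &
      !grepl("[^ACGT,]|([ACGT][ACGT])", dt$alt) & dt$alt != ""
    amb <- is_snv & !dt$ref %in% c("A", "C", "G", "T")
    skipped["non_snv"] <- sum(!is_snv)
    skipped["ambiguous_ref"] <- sum(amb)
    dt <- dt[is_snv & !amb]
  }
  data.table::setattr(dt, "skipped", skipped)
  data.table::setattr(dt, "samples", samples)
  data.table::setattr(dt, "meta", meta)
  dt[]
}

#' Write SNP records to a VCF file
#'
#' Records must already be sorted by (`contigs` order, position); unsorted
#' input is an error.  INFO keys added by the lift pipeline are declared in
#' the header.
#'
#' @param records a `data.table` in the shape produced by [read_vcf].
#' @param path output path.
#' @param contigs named integer vector of contig lengths defining the sort
#'   order (e.g. `seq_lengths(target)`); every record's `chrom` must be
#'   present.
#' @param extra_info character vector of extra `##INFO` declaration lines.
#' @param samples sample column names (written to the `#CHROM` line when
#'   records carry genotype text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, contigs, extra_info = character(0),
                      samples = character(0)) {
  ord <- match(records$chrom, names(contigs))
  if (anyNA(ord))
    stopf("record chrom '%s' absent from target contigs",
          records$chrom[is.na(ord)][1])
  if (nrow(records) > 1L) {
    o <- order(ord, records$pos)
    if (!identical(o, seq_len(nrow(records))))
      stopf("records are not sorted by (target contig order, pos)")
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           extra_info)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- nrow(records) > 0L && !all(is.na(records$gt))
  if (has_gt) cols <- c(cols, "FORMAT", samples)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = "\t")), con)
  if (nrow(records) > 0L) {
    fix <- paste(records$chrom, records$pos, records$id, records$ref,
                 records$alt, records$qual, records$filter, records$info,
                 sep = "\t")
    if (has_gt) {
      gt <- records$gt
      gt[is.na(gt)] <- "."
      fix <- paste(fix, gt, sep = "\t")
    }
    writeLines(fix, con)
  }
  invisible(path)
}

# ---- GFF3 (flank-feature dialect) ---------------------------------------

#' Write flank features to GFF3
#'
#' Each feature becomes two rows: a parent of type `region` carrying
#' `ID=<feature_id>` and a 1-bp child of type `SNP` carrying `ID` and
#' `Parent`.  All rows are on strand `+` (input SNP sets carry no strand;
#' the plus-strand convention is asserted at the boundary).
#'
#' @param features a `data.table` from [build_flank_features].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  if (anyDuplicated(features$feature_id))
    stopf("feature ids are not unique")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  parent <- paste(features$chrom, "flanklift", "region",
                  features$parent_start, features$parent_end, ".", "+", ".",
                  paste0("ID=", features$feature_id), sep = "\t")
  child <- paste(features$chrom, "flanklift", "SNP",
                 features$child_pos, features$child_pos, ".", "+", ".",
                 paste0("ID=", features$feature_id, "_snp;Parent=",
                        features$feature_id), sep = "\t")
  writeLines(as.vector(rbind(parent, child)), con)
  invisible(path)
}

#' Read flank features back from GFF3
#'
#' @param path a GFF3 file written by [write_gff3].
#' @return a `data.table` with `feature_id`, `chrom`, `parent_start`,
#'   `parent_end`, `child_pos` (all 1-based inclusive).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.table::data.table(feature_id = character(0),
                                  chrom = character(0),
                                  parent_start = integer(0),
                                  parent_end = integer(0),
                                  child_pos = integer(0)))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 9L) stopf("malformed GFF3: fewer than 9 columns")
  dt <- data.table::data.table(chrom = f[[1]], type = f[[3]],
                               start = as.integer(f[[4]]),
                               end = as.integer(f[[5]]), attr = f[[9]])
  getattr <- function(a, key) {
    pat <- paste0("(?:^|.*;)", key, "=([^;]*).*")
    hit <- grepl(paste0("(^|;)", key, "="), a)
    out <- rep(NA_character_, length(a))
    out[hit] <- sub(pat, "\\1", a[hit])
    out
  }
  par <- dt[type == "region"]
  chd <- dt[type == "SNP"]
  par_id <- getattr(par$attr, "ID")
  chd_parent <- getattr(chd$attr, "Parent")
  orphan <- !chd_parent %in% par_id
  if (any(orphan))
    stopf("child feature without matching parent: %s", chd_parent[orphan][1])
  idx <- match(par_id, chd_parent)
  if (anyNA(idx)) stopf("parent feature without child: %s", par_id[is.na(idx)][1])
  data.table::data.table(feature_id = par_id, chrom = par$chrom,
                         parent_start = par$start, parent_end = par$end,
                         child_pos = chd$start[idx])
}
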