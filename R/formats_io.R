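## Reading, writing and preprocessing of the standard formats.
##
## All internal coordinates are 0-based half-open; SAM and GTF are converted
## on read, BED is written natively 0-based. Collapsed reads are plain
## data.frames: one row per distinct (sequence, origin, pair_weight), with
## `count` holding the number of original reads or pairs collapsed into it.

#' Read a FASTQ file
#'
#' Gzip-transparent 4-line FASTQ reader returning sequences only (base
#' qualities are discarded: the pipeline is alignment-driven and counts
#' reads, not base qualities). A malformed record aborts with an error
#' naming the first bad record index.
#'
#' @param path FASTQ file, optionally gzipped.
#' @return named character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    idx <- locate_fastq_error(path)
    stop(sprintf("malformed FASTQ record at index %d in %s: %s",
                 idx, path, conditionMessage(res)))
  }
  out <- toupper(as.character(res))
  names(out) <- sub("[ \t].*$", "", names(res))
  out
}

## find the first structurally bad 4-line record (for error reporting)
locate_fastq_error <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    rec <- readLines(con, n = 4L)
    if (length(rec) == 0L) return(i + 1L)
    i <- i + 1L
    if (length(rec) < 4L || !startsWith(rec[1], "@") ||
        !startsWith(rec[3], "+") || nchar(rec[2]) != nchar(rec[4]) ||
        grepl("[^ACGTNacgtn]", rec[2])) {
      return(i)
    }
  }
}

#' Write sequences as FASTQ
#'
#' @param seqs named character vector of sequences.
#' @param path output path (".gz" suffix gzips).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs) %||% paste0("read", seq_along(seqs))
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Collapse duplicate read sequences
#'
#' De-duplicates identical sequences while retaining multiplicities, so each
#' distinct sequence is aligned once and its count carried through calling
#' and quantification. Output is sorted by sequence, making the result
#' independent of input order.
#'
#' @param seqs character vector of read sequences.
#' @param origin provenance label, one of `"SE"`, `"MERGED_PAIR"`,
#'   `"MATE1"`, `"MATE2"` (recycled).
#' @param pair_weight weight each original read contributes to library
#'   totals: 1 for SE reads and merged pairs, 0.5 per mate of a split pair.
#' @return data.frame with columns `read_id`, `sequence`, `count`,
#'   `origin`, `pair_weight`.
#' @export
collapse_reads <- function(seqs, origin = "SE", pair_weight = 1) {
  if (length(seqs) == 0) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      count = integer(0), origin = character(0),
                      pair_weight = numeric(0)))
  }
  origin <- rep_len(origin, length(seqs))
  pair_weight <- rep_len(pair_weight, length(seqs))
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) stop("sequences must be over {A,C,G,T,N}")
  key <- paste(seqs, origin, pair_weight, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    sequence = vapply(parts, `[`, "", 1L),
    count = as.integer(tab),
    origin = vapply(parts, `[`, "", 2L),
    pair_weight = as.numeric(vapply(parts, `[`, "", 3L))
  )
  out <- out[order(out$sequence, out$origin), , drop = FALSE]
  out <- data.frame(read_id = sprintf("cr%06d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

## expand a collapsed table back to the input multiset (testing aid)
expand_reads <- function(collapsed) {
  rep(collapsed$sequence, collapsed$count)
}

#' Merge read pairs by 3' overlap
#'
#' Attempts to merge each pair into one pseudo-single-end read using the
#' overlap between the end of mate 1 and the start of the
#' reverse-complemented mate 2. The best (longest) overlap of at least
#' `min_overlap` bases with a mismatch fraction at most `max_mismatch_frac`
#' wins; overlap bases are taken from mate 1. Pairs with no acceptable
#' overlap are emitted as two independent reads, each with `pair_weight`
#' 0.5 so every pair still contributes exactly 1 to library totals.
#'
#' @param mate1,mate2 character vectors of mate sequences in sequencing
#'   orientation (mate 2 is reverse-complemented internally).
#' @param ids optional read ids; mates are paired positionally, and if both
#'   mates carry ids they must agree after stripping a `/1`/`/2` suffix.
#' @param min_overlap minimum acceptable overlap length (nt).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap.
#' @return data.frame with columns `pair_id`, `sequence`, `origin`
#'   (`MERGED_PAIR`, `MATE1` or `MATE2`) and `pair_weight`.
#' @export
merge_pairs <- function(mate1, mate2, ids = NULL, min_overlap = 10L,
                        max_mismatch_frac = 0.05) {
  if (length(mate1) != length(mate2)) {
    stop("pairing error: mate vectors differ in length")
  }
  n <- length(mate1)
  if (is.null(ids)) ids <- sprintf("pair%06d", seq_len(n))
  base_id <- function(x) sub("/[12]$", "", x)
  if (!is.null(names(mate1)) && !is.null(names(mate2)) &&
      !all(base_id(names(mate1)) == base_id(names(mate2)))) {
    stop("pairing error: mate ids do not match")
  }
  mate1 <- toupper(mate1)
  rc2 <- revcomp(toupper(mate2))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m1 <- mate1[i]; m2 <- rc2[i]
    n1 <- nchar(m1); n2 <- nchar(m2)
    merged <- NA_character_
    a <- utf8ToInt(m1); b <- utf8ToInt(m2)
    for (o in seq.int(min(n1, n2), min_overlap)) {
      if (o < min_overlap) break
      mism <- sum(a[(n1 - o + 1L):n1] != b[1:o])
      if (mism / o <= max_mismatch_frac) {
        merged <- paste0(m1, substr(m2, o + 1L, n2))
        break
      }
    }
    if (!is.na(merged)) {
      rows[[i]] <- data.frame(pair_id = ids[i], sequence = merged,
                              origin = "MERGED_PAIR", pair_weight = 1)
    } else {
      rows[[i]] <- data.frame(pair_id = ids[i],
                              sequence = c(m1, toupper(mate2[i])),
                              origin = c("MATE1", "MATE2"),
                              pair_weight = c(0.5, 0.5))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Preprocess a library into collapsed reads
#'
#' Single-end libraries are collapsed directly; paired-end libraries are
#' first reduced to a single stream by [merge_pairs()].
#'
#' @param fastq1 path to the (first) FASTQ file.
#' @param fastq2 optional path to the mate-2 FASTQ file.
#' @param min_overlap,max_mismatch_frac see [merge_pairs()].
#' @return collapsed read data.frame (see [collapse_reads()]).
#' @export
prepare_reads <- function(fastq1, fastq2 = NULL, min_overlap = 10L,
                          max_mismatch_frac = 0.05) {
  r1 <- read_fastq(fastq1)
  if (is.null(fastq2)) return(collapse_reads(unname(r1), "SE", 1))
  r2 <- read_fastq(fastq2)
  if (length(r1) != length(r2)) {
    stop("pairing error: mate files differ in record count")
  }
  merged <- merge_pairs(unname(r1), unname(r2), ids = names(r1),
                        min_overlap = min_overlap,
                        max_mismatch_frac = max_mismatch_frac)
  parts <- lapply(split(merged, paste(merged$origin, merged$pair_weight)),
                  function(g) {
                    collapse_reads(g$sequence, g$origin[1], g$pair_weight[1])
                  })
  out <- do.call(rbind, parts)
  out <- out[order(out$sequence, out$origin), , drop = FALSE]
  out$read_id <- sprintf("cr%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

## ---- SAM parsing ----------------------------------------------------------

#' Parse SAM alignments into per-read aligned segments
#'
#' Converts primary and supplementary SAM records into aligned segments
#' with read intervals expressed on the original forward read, so chimeric
#' (split) alignments can be inspected for back-splice geometry. Hard and
#' soft clips are treated identically for read-coordinate reconstruction;
#' reverse-strand records are mirrored back to forward-read coordinates.
#' Secondary alignments (flag 0x100) and unmapped records are ignored;
#' records whose CIGAR query width disagrees with the stored sequence are
#' skipped and counted.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @return data.frame with one row per aligned segment: `read_id`, `chrom`,
#'   `strand`, `read_start`, `read_end`, `ref_start`, `ref_end` (all 0-based
#'   half-open), `read_len`, `mapq`, `edit_distance`. The number of skipped
#'   records is attached as attribute `n_skipped`.
#' @export
parse_sam_segments <- function(sam) {
  lines <- if (length(sam) == 1L && file.exists(sam)) readLines(sam) else sam
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), read_start = integer(0),
                      read_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), read_len = integer(0),
                      mapq = integer(0), edit_distance = integer(0))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_skipped <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 11L) { n_skipped <- n_skipped + 1L; next }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L) next
    cigar <- f[6]
    if (cigar == "*") next
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
    qlen <- sum(lens[ops %in% c("M", "I", "S", "=", "X", "H")])
    lead <- 0L
    j <- 1L
    while (j <= length(ops) && ops[j] %in% c("S", "H")) {
      lead <- lead + lens[j]; j <- j + 1L
    }
    trail <- 0L
    j <- length(ops)
    while (j >= 1L && ops[j] %in% c("S", "H")) {
      trail <- trail + lens[j]; j <- j - 1L
    }
    qaln <- sum(lens[ops %in% c("M", "I", "=", "X")])
    if (qaln == 0L) { n_skipped <- n_skipped + 1L; next }
    seq <- f[10]
    if (seq != "*") {
      soft_qlen <- sum(lens[ops %in% c("M", "I", "S", "=", "X")])
      if (nchar(seq) != soft_qlen) { n_skipped <- n_skipped + 1L; next }
    }
    ref_w <- sum(lens[ops %in% c("M", "D", "N", "=", "X")])
    rs <- as.integer(f[4]) - 1L
    rev <- bitwAnd(flag, 16L) != 0L
    q0 <- lead
    q1 <- qlen - trail
    if (rev) {  # mirror to forward-read coordinates
      tmp <- q0
      q0 <- qlen - q1
      q1 <- qlen - tmp
    }
    nm <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    ed <- if (length(nm)) as.integer(sub("^NM:i:", "", nm[1])) else NA_integer_
    rows[[i]] <- data.frame(
      read_id = f[1], chrom = f[3], strand = if (rev) "-" else "+",
      read_start = q0, read_end = q1, ref_start = rs, ref_end = rs + ref_w,
      read_len = qlen, mapq = as.integer(f[5]), edit_distance = ed
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), read_start = integer(0),
                      read_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), read_len = integer(0),
                      mapq = integer(0), edit_distance = integer(0))
  }
  rownames(out) <- NULL
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d SAM records with inconsistent CIGAR/sequence",
                    n_skipped))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Split parsed segments into chimeric and linear read pools
#'
#' @param segments output of [parse_sam_segments()].
#' @return list with `chimeric` (segments of reads with >= 2 aligned
#'   segments) and `linear` (single-segment reads).
#' @export
split_chimeric <- function(segments) {
  if (nrow(segments) == 0) return(list(chimeric = segments, linear = segments))
  n_seg <- table(segments$read_id)
  multi <- names(n_seg)[n_seg >= 2L]
  list(
    chimeric = segments[segments$read_id %in% multi, , drop = FALSE],
    linear = segments[!segments$read_id %in% multi, , drop = FALSE]
  )
}

## ---- annotation -----------------------------------------------------------

#' Read exon models from a GTF/GFF file
#'
#' @param path GTF/GFF file.
#' @return data.frame of exons with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open), `exon_number`
#'   (transcript 5'->3' order).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  ## assign transcript-order exon numbers from coordinates
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  df$exon_number <- stats::ave(seq_len(nrow(df)), df$transcript_id,
                               FUN = function(ii) {
                                 k <- length(ii)
                                 if (df$strand[ii[1]] == "-") rev(seq_len(k))
                                 else seq_len(k)
                               })
  rownames(df) <- NULL
  df
}

#' Write exon models as GTF
#'
#' @param exons exon data.frame in the [read_gtf()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand
  )
  gr$type <- "exon"
  gr$source <- "circpipe"
  gr$gene_id <- exons$gene_id
  gr$transcript_id <- exons$transcript_id
  gr$exon_number <- as.character(exons$exon_number)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

## ---- results output -------------------------------------------------------

#' Write circRNA calls as BED6+
#'
#' Standard BED6 (0-based half-open) followed by `splice_strength` and
#' `abundance` columns.
#'
#' @param calls circRNA call data.frame (see [aggregate_calls()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circ_bed <- function(calls, path) {
  bed <- data.frame(
    chrom = calls$chrom, start = calls$start, end = calls$end,
    name = calls$circ_id, score = calls$support, strand = calls$strand,
    splice_strength = round(calls$total, 3),
    abundance = if ("abundance" %in% names(calls)) calls$abundance else NA
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write fusion circRNA calls as TSV
#'
#' One row per fusion circRNA with both reciprocal junctions.
#'
#' @param fusion_circs data.frame from [pair_fusion_circs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fusion_tsv <- function(fusion_circs, path) {
  utils::write.table(fusion_circs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
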