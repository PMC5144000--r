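## Pseudo-circular realignment quantification.
##
## For each called circRNA the monomer sequence (genomic span between the
## BSJ coordinates, or the concatenated annotated exons within the span
## when a gene annotation is supplied) is repeated twice; a linear match
## can then cross the BSJ image (the "seam") at the monomer length. A read
## counts toward a circRNA iff its best alignment crosses the seam with at
## least `min_overhang` aligned bases on both sides, and each read or pair
## contributes its collapse count times its pair weight to at most one
## circRNA; reads tied between circRNAs are left unassigned.

#' Build pseudo-circular references for circRNA calls
#'
#' @param calls aggregated circRNA call data.frame
#'   (see [aggregate_calls()]).
#' @param genome named [Biostrings::DNAStringSet].
#' @param annotation optional exon data.frame (see [read_gtf()]); when
#'   given, the monomer is the concatenation of the host transcript's
#'   exons intersected with the circle span, clipped to the BSJ ends. The
#'   host transcript is the same-strand transcript with the largest exonic
#'   overlap; calls without one fall back to the genomic span with a
#'   warning.
#' @return data.frame with `circ_id`, coordinates, `monomer`, `doubled`
#'   and `seam` (= monomer length) columns.
#' @export
build_pseudo_reference <- function(calls, genome, annotation = NULL) {
  if (nrow(calls) == 0) {
    return(data.frame(circ_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), monomer = character(0),
                      doubled = character(0), seam = integer(0)))
  }
  n_fallback <- 0L
  monomer <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    mono <- NA_character_
    if (!is.null(annotation)) {
      ex <- annotation[annotation$chrom == cl$chrom &
                         annotation$strand == cl$strand &
                         annotation$start < cl$end &
                         annotation$end > cl$start, , drop = FALSE]
      if (nrow(ex) > 0) {
        ## pick host transcript with the largest exonic overlap
        ov <- pmin(ex$end, cl$end) - pmax(ex$start, cl$start)
        by_tx <- tapply(ov, ex$transcript_id, sum)
        host <- names(by_tx)[which.max(by_tx)]
        hx <- ex[ex$transcript_id == host, , drop = FALSE]
        hx$start <- pmax(hx$start, cl$start)
        hx$end <- pmin(hx$end, cl$end)
        hx <- hx[order(hx$start), , drop = FALSE]
        pieces <- vapply(seq_len(nrow(hx)), function(j) {
          extract_genome(genome, hx$chrom[j], hx$start[j], hx$end[j], "+")
        }, "")
        mono <- paste(pieces, collapse = "")
        if (cl$strand == "-") mono <- revcomp(mono)
      } else {
        n_fallback <- n_fallback + 1L
      }
    }
    if (is.na(mono)) {
      mono <- extract_genome(genome, cl$chrom, cl$start, cl$end, cl$strand)
    }
    monomer[i] <- mono
  }
  if (n_fallback > 0L) {
    warning(sprintf(
      "%d calls had no overlapping transcript; using genomic span",
      n_fallback))
  }
  data.frame(circ_id = calls$circ_id, chrom = calls$chrom,
             strand = calls$strand, start = calls$start, end = calls$end,
             monomer = monomer, doubled = paste0(monomer, monomer),
             seam = nchar(monomer))
}

#' Quantify circRNA abundance by seam-spanning realignment
#'
#' Realigns all collapsed reads (both orientations, exact full-length
#' matching) to the doubled pseudo-circular references and counts, per
#' circRNA, the weight of reads whose alignment crosses the seam with at
#' least `min_overhang` bases on both sides. A read matching the seam
#' context of more than one circRNA is a tie and left unassigned; a read
#' matching one circRNA at both monomer images is counted once.
#'
#' @param refs pseudo-reference data.frame from [build_pseudo_reference()].
#' @param reads collapsed read data.frame.
#' @param min_overhang minimum aligned bases on each side of the seam.
#' @return list with `abundance` (named numeric vector by `circ_id`),
#'   `n_ambiguous` (weight left unassigned by ties) and `assigned_weight`.
#' @export
quantify <- function(refs, reads, min_overhang = 4L) {
  ab <- stats::setNames(numeric(nrow(refs)), refs$circ_id)
  if (nrow(refs) == 0 || nrow(reads) == 0) {
    return(list(abundance = ab, n_ambiguous = 0, assigned_weight = 0))
  }
  doubled <- Biostrings::DNAStringSet(refs$doubled)
  names(doubled) <- refs$circ_id
  seam <- stats::setNames(refs$seam, refs$circ_id)
  seqs <- reads$sequence
  rls <- nchar(seqs)
  usable <- !grepl("N", seqs, fixed = TRUE) & rls >= 2L * min_overhang
  hit_refs <- vector("list", nrow(reads))  # per read: circ_ids with seam hits
  for (rl in unique(rls[usable])) {
    idx <- which(usable & rls == rl)
    pats <- c(seqs[idx], revcomp(seqs[idx]))
    pd <- Biostrings::PDict(pats)
    for (ci in seq_along(doubled)) {
      L <- seam[ci]
      if (rl > 2L * L) next  # read wraps beyond the doubled sequence
      m <- Biostrings::matchPDict(pd, doubled[[ci]])
      cnt <- S4Vectors::elementNROWS(m)
      for (h in which(cnt > 0)) {
        ri <- idx[(h - 1L) %% length(idx) + 1L]
        p0 <- IRanges::start(m[[h]]) - 1L  # 0-based
        crosses <- p0 <= L - min_overhang & p0 + rl >= L + min_overhang
        if (any(crosses)) {
          hit_refs[[ri]] <- union(hit_refs[[ri]], names(doubled)[ci])
        }
      }
    }
  }
  n_ambiguous <- 0
  assigned <- 0
  w <- reads$count * reads$pair_weight
  for (ri in seq_len(nrow(reads))) {
    hr <- hit_refs[[ri]]
    if (is.null(hr)) next
    if (length(hr) > 1L) {
      n_ambiguous <- n_ambiguous + w[ri]
    } else {
      ab[hr] <- ab[hr] + w[ri]
      assigned <- assigned + w[ri]
    }
  }
  list(abundance = ab, n_ambiguous = n_ambiguous, assigned_weight = assigned)
}

#' Write the abundance table as TSV
#'
#' Columns: circ_id, coordinates, junction support, realignment abundance,
#' and placeholders for host-gene metrics filled by the downstream stage.
#'
#' @param calls aggregated circRNA calls with an `abundance` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write pseudo-circular references as FASTA
#'
#' @param refs data.frame from [build_pseudo_reference()].
#' @param path output path.
#' @param doubled write the doubled sequence (default) or the monomer.
#' @return `path`, invisibly.
#' @export
write_pseudo_fasta <- function(refs, path, doubled = TRUE) {
  x <- Biostrings::DNAStringSet(if (doubled) refs$doubled else refs$monomer)
  names(x) <- sprintf("%s %s:%d-%d(%s)", refs$circ_id, refs$chrom,
                      refs$start, refs$end, refs$strand)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
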