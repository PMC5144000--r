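## Bundled naive split-read aligner.
##
## An exact seed-and-extend aligner (15-nt seeds, no indels or mismatches)
## sufficient for error-free synthetic reads. Real-data runs should use an
## external SAM-producing split-read aligner (e.g. BWA-MEM); its output
## enters the pipeline through the same parse_sam_segments() path as the
## SAM emitted here.
##
## Per read it searches four candidate segments -- the longest exact prefix
## and suffix matches of the read and of its reverse complement -- which is
## enough to recover the two flanks of a junction-spanning read on either
## strand, including cross-strand fusions.

NAIVE_SEED_LEN <- 15L

## longest common prefix length of two equal-alphabet strings, compared
## from `start` (1-based) in both
lcp_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' Align collapsed reads with the bundled exact aligner
#'
#' Produces SAM text: full-length exact matches become single linear
#' records; otherwise the longest exact prefix and suffix matches of the
#' read (in both orientations) are emitted as a primary plus supplementary
#' split alignment. Seeds with more than one equally long best extension
#' are ambiguous and dropped with a counter.
#'
#' @param reads collapsed read data.frame (see [collapse_reads()]).
#' @param genome named [Biostrings::DNAStringSet].
#' @param seed_len exact seed length; segments shorter than this are
#'   invisible to the aligner.
#' @param max_hits_per_seed seed occurrence cap; seeds more repetitive than
#'   this are skipped.
#' @return character vector of SAM lines (with `@SQ` header), with
#'   attribute `n_ambiguous` counting dropped ambiguous segments.
#' @export
naive_align_chimeric <- function(reads, genome, seed_len = NAIVE_SEED_LEN,
                                 max_hits_per_seed = 16L) {
  stopifnot(is.data.frame(reads), nrow(reads) >= 0)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome))
  )
  if (nrow(reads) == 0) return(structure(header, n_ambiguous = 0L))
  chrom_raw <- lapply(as.character(genome), charToRaw)
  chrom_len <- vapply(chrom_raw, length, integer(1))

  seqs <- reads$sequence
  rls <- nchar(seqs)
  usable <- rls >= seed_len & !grepl("N", seqs, fixed = TRUE)
  rc <- rep(NA_character_, length(seqs))
  rc[usable] <- revcomp(seqs[usable])

  ## ---- stage 1: full-length exact matches (both orientations) ----
  full_hit <- vector("list", length(seqs))   # list(chrom, pos0, strand)
  for (rl in unique(rls[usable])) {
    idx <- which(usable & rls == rl)
    pats <- c(seqs[idx], rc[idx])
    pd <- Biostrings::PDict(pats)
    for (ch in names(genome)) {
      m <- Biostrings::matchPDict(pd, genome[[ch]])
      cnt <- S4Vectors::elementNROWS(m)
      hit <- which(cnt > 0)
      for (h in hit) {
        ri <- idx[(h - 1L) %% length(idx) + 1L]
        strand <- if (h <= length(idx)) "+" else "-"
        pos0 <- IRanges::start(m[[h]])[1] - 1L
        prev <- full_hit[[ri]]
        if (is.null(prev)) {
          full_hit[[ri]] <- list(chrom = ch, pos0 = pos0, strand = strand,
                                 n = cnt[h])
        } else {
          prev$n <- prev$n + cnt[h]
          full_hit[[ri]] <- prev
        }
      }
    }
  }

  ## ---- stage 2: seed-and-extend for the rest ----
  ## four searches per read: prefix/suffix of read (forward strand) and of
  ## its reverse complement (reverse strand, mapped back to forward read
  ## coordinates by the SAM convention)
  need <- which(usable & vapply(full_hit, is.null, logical(1)))
  seg_per_read <- vector("list", length(seqs))
  n_ambiguous <- 0L
  if (length(need)) {
    kinds <- c("fp", "fs", "rp", "rs")  # fwd-prefix, fwd-suffix, rev-prefix, rev-suffix
    seed_of <- function(s, kind) {
      rl <- nchar(s)
      if (kind %in% c("fp", "rp")) substr(s, 1L, seed_len)
      else substr(s, rl - seed_len + 1L, rl)
    }
    pats <- character(0)
    meta <- list()
    for (k in kinds) {
      src <- if (startsWith(k, "f")) seqs[need] else rc[need]
      pats <- c(pats, vapply(seq_along(need), function(i) seed_of(src[i], k), ""))
      meta <- c(meta, lapply(seq_along(need), function(i) list(ri = need[i], kind = k)))
    }
    pd <- Biostrings::PDict(pats)
    hits <- vector("list", length(pats))  # per pattern: data.frame(chrom, pos0)
    for (ch in names(genome)) {
      m <- Biostrings::matchPDict(pd, genome[[ch]])
      cnt <- S4Vectors::elementNROWS(m)
      for (h in which(cnt > 0)) {
        if (cnt[h] > max_hits_per_seed) next
        hits[[h]] <- rbind(hits[[h]],
                           data.frame(chrom = ch,
                                      pos0 = IRanges::start(m[[h]]) - 1L))
      }
    }
    ## extend each seed hit to the longest exact match anchored at the
    ## read end it seeds
    for (h in seq_along(pats)) {
      hh <- hits[[h]]
      if (is.null(hh) || nrow(hh) == 0) next
      info <- meta[[h]]
      ri <- info$ri
      kind <- info$kind
      s <- if (startsWith(kind, "f")) seqs[ri] else rc[ri]
      sraw <- charToRaw(s)
      rl <- length(sraw)
      best_len <- 0L
      best <- NULL
      n_best <- 0L
      for (j in seq_len(nrow(hh))) {
        ch <- hh$chrom[j]; p0 <- hh$pos0[j]
        g <- chrom_raw[[ch]]
        if (kind %in% c("fp", "rp")) {
          ## anchored at sequence start: extend rightward from the seed
          avail <- min(rl, chrom_len[ch] - p0)
          ext <- lcp_len(sraw, g[(p0 + 1L):(p0 + avail)])
          qs <- 0L; qe <- ext; gs <- p0; ge <- p0 + ext
        } else {
          ## anchored at sequence end: extend leftward
          seed_start0 <- p0  # genome 0-based start of the seed
          left_avail <- min(rl, seed_start0 + seed_len)
          ext <- lcp_len(rev(sraw), rev(g[(seed_start0 + seed_len - left_avail + 1L):(seed_start0 + seed_len)]))
          qs <- rl - ext; qe <- rl
          ge <- seed_start0 + seed_len; gs <- ge - ext
        }
        if (ext < seed_len) next
        if (ext > best_len) {
          best_len <- ext
          best <- list(chrom = ch, gs = gs, ge = ge, qs = qs, qe = qe)
          n_best <- 1L
        } else if (ext == best_len) {
          n_best <- n_best + 1L
        }
      }
      if (is.null(best)) next
      if (n_best > 1L) { n_ambiguous <- n_ambiguous + 1L; next }
      orient <- if (startsWith(kind, "f")) "+" else "-"
      seg_per_read[[ri]] <- rbind(
        seg_per_read[[ri]],
        data.frame(chrom = best$chrom, strand = orient,
                   qs = best$qs, qe = best$qe, gs = best$gs, ge = best$ge,
                   kind = kind)
      )
    }
  }

  ## ---- emit SAM ----
  out <- character(0)
  for (ri in seq_along(seqs)) {
    rid <- reads$read_id[ri]
    s <- seqs[ri]
    rl <- rls[ri]
    fh <- full_hit[[ri]]
    if (!is.null(fh)) {
      if (fh$n > 1L) { n_ambiguous <- n_ambiguous + 1L; next }
      sq <- if (fh$strand == "+") s else rc[ri]
      flag <- if (fh$strand == "+") 0L else 16L
      out <- c(out, paste(rid, flag, fh$chrom, fh$pos0 + 1L, 60L,
                          sprintf("%dM", rl), "*", 0L, 0L, sq, "*",
                          "NM:i:0", sep = "\t"))
      next
    }
    segs <- seg_per_read[[ri]]
    if (is.null(segs) || nrow(segs) == 0) next
    ## de-duplicate identical segments found by different searches
    segs$fwd_qs <- ifelse(segs$strand == "+", segs$qs, rl - segs$qe)
    segs$fwd_qe <- ifelse(segs$strand == "+", segs$qe, rl - segs$qs)
    key <- paste(segs$chrom, segs$strand, segs$fwd_qs, segs$fwd_qe,
                 segs$gs, segs$ge)
    segs <- segs[!duplicated(key), , drop = FALSE]
    ## drop segments fully contained in another on the same locus
    keep <- rep(TRUE, nrow(segs))
    for (a in seq_len(nrow(segs))) {
      for (b in seq_len(nrow(segs))) {
        if (a != b && keep[a] &&
            segs$chrom[a] == segs$chrom[b] && segs$strand[a] == segs$strand[b] &&
            segs$fwd_qs[a] >= segs$fwd_qs[b] && segs$fwd_qe[a] <= segs$fwd_qe[b] &&
            (segs$fwd_qe[a] - segs$fwd_qs[a]) < (segs$fwd_qe[b] - segs$fwd_qs[b])) {
          keep[a] <- FALSE
        }
      }
    }
    segs <- segs[keep, , drop = FALSE]
    ord <- order(-(segs$qe - segs$qs))
    segs <- segs[ord, , drop = FALSE]
    for (j in seq_len(nrow(segs))) {
      sg <- segs[j, ]
      mlen <- sg$qe - sg$qs
      lead <- sg$qs
      trail <- rl - sg$qe
      cig <- paste0(if (lead) sprintf("%dS", lead) else "",
                    sprintf("%dM", mlen),
                    if (trail) sprintf("%dS", trail) else "")
      flag <- 0L
      if (sg$strand == "-") flag <- flag + 16L
      if (j > 1L) flag <- flag + 2048L
      sq <- if (sg$strand == "+") s else rc[ri]
      out <- c(out, paste(rid, flag, sg$chrom, sg$gs + 1L, 60L, cig,
                          "*", 0L, 0L, sq, "*", "NM:i:0", sep = "\t"))
    }
  }
  structure(c(header, out), n_ambiguous = n_ambiguous)
}
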