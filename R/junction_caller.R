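## Back-splice and fusion junction calling from chimeric alignments.
##
## A back-splice junction (BSJ) shows as a split read whose two segments
## lie on the same chromosome and strand but in inverted genomic order:
## the later part of the read maps upstream (in transcription direction)
## of the earlier part. Segments on different chromosomes or strands, or
## very distant same-strand segments, are examined as fusion junctions
## instead. The exact breakpoint is ambiguous within the microhomology
## window (identical sequence flanking both sides of the junction); every
## admissible partition of the read is scored with the splice-site model
## and the highest-scoring partition above the threshold is reported.

#' Default junction-caller configuration
#'
#' @param threshold minimum total (donor + acceptor) splice strength in
#'   bits for a reported junction.
#' @param min_circ_len minimum circle span (nt).
#' @param min_segment minimum aligned segment length (nt) on the read.
#' @param min_read_coverage minimum fraction of the read covered by the
#'   two segments.
#' @param microhomology_window maximum breakpoint shift examined on either
#'   side of the alignment-implied partition (nt).
#' @param circ_max_span same-chromosome same-strand segment pairs farther
#'   apart than this are routed to fusion handling instead of BSJ calling.
#' @param fusion_max_span maximum intra-gene span when pairing reciprocal
#'   fusion junctions into fusion circRNAs.
#' @param min_overhang minimum aligned bases on both sides of the
#'   pseudo-circular seam for a read to count in quantification.
#' @param min_overlap,max_mismatch_frac read-pair merging parameters.
#' @return named list of caller parameters.
#' @export
caller_config <- function(threshold = 10, min_circ_len = 100L,
                          min_segment = 15L, min_read_coverage = 0.9,
                          microhomology_window = 10L, circ_max_span = 1e6,
                          fusion_max_span = 1e6, min_overhang = 4L,
                          min_overlap = 10L, max_mismatch_frac = 0.05) {
  cfg <- list(threshold = threshold, min_circ_len = as.integer(min_circ_len),
              min_segment = as.integer(min_segment),
              min_read_coverage = min_read_coverage,
              microhomology_window = as.integer(microhomology_window),
              circ_max_span = circ_max_span,
              fusion_max_span = fusion_max_span,
              min_overhang = as.integer(min_overhang),
              min_overlap = as.integer(min_overlap),
              max_mismatch_frac = max_mismatch_frac)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$threshold >= 0, cfg$min_circ_len >= 1L, cfg$min_segment >= 1L,
    cfg$min_read_coverage > 0, cfg$min_read_coverage <= 1,
    cfg$microhomology_window >= 0L, cfg$circ_max_span > 0,
    cfg$fusion_max_span > 0, cfg$min_overhang >= 1L,
    cfg$min_overlap >= 1L, cfg$max_mismatch_frac >= 0,
    cfg$max_mismatch_frac < 1
  )
  invisible(cfg)
}

## map a read boundary (0-based) to the genomic boundary under a segment's
## alignment; for "-" segments read coordinates run against the genome
map_boundary <- function(ref_start, ref_end, read_start, strand, t) {
  n <- max(length(t), length(strand))
  ifelse(rep_len(strand == "+", n),
         ref_start + (t - read_start),
         ref_end - (t - read_start))
}

#' Enumerate candidate junction segment pairs of chimeric reads
#'
#' For every read with two or more aligned segments, enumerates ordered
#' segment pairs (earlier read part first) that pass the segment-length and
#' read-coverage filters, and classifies each pair as back-splice geometry
#' (`"bsj"`: same chromosome and strand, genomic order inverted relative to
#' read order), fusion geometry (`"fusion"`: different chromosome or
#' strand, or same-strand pairs beyond `circ_max_span`), or collinear
#' linear splicing (dropped).
#'
#' @param chimeric segment data.frame (see [parse_sam_segments()]) of reads
#'   with >= 2 segments.
#' @param config a [caller_config()] list.
#' @return data.frame of candidate pairs with the columns of both segments
#'   (`.1` = earlier read part, `.2` = later) and a `geometry` column.
#' @export
select_bsj_candidates <- function(chimeric, config = caller_config()) {
  empty <- data.frame()
  if (nrow(chimeric) == 0) return(empty)
  out <- list()
  for (rid in unique(chimeric$read_id)) {
    segs <- chimeric[chimeric$read_id == rid, , drop = FALSE]
    rl <- segs$read_len[1]
    n <- nrow(segs)
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        s1 <- segs[a, ]; s2 <- segs[b, ]
        if (s1$read_start >= s2$read_start) next  # s1 = earlier read part
        len1 <- s1$read_end - s1$read_start
        len2 <- s2$read_end - s2$read_start
        if (len1 < config$min_segment || len2 < config$min_segment) next
        cov <- max(s1$read_end, s2$read_end) - s1$read_start -
          max(0L, s2$read_start - s1$read_end)
        if (cov / rl < config$min_read_coverage) next
        if (s2$read_start > s1$read_end) next  # uncovered junction gap
        same_locus <- s1$chrom == s2$chrom && s1$strand == s2$strand
        geometry <- NA_character_
        if (same_locus) {
          span <- max(s1$ref_end, s2$ref_end) - min(s1$ref_start, s2$ref_start)
          ## classify by the junction implied at the midpoint partition:
          ## a back-splice joins a donor to an upstream acceptor, so the
          ## circle length (donor minus acceptor in transcription
          ## direction) is positive; collinear pairs (linear splicing)
          ## give a negative length and are dropped
          t_mid <- floor((s2$read_start + s1$read_end) / 2)
          d_mid <- map_boundary(s1$ref_start, s1$ref_end, s1$read_start,
                                s1$strand, t_mid)
          a_mid <- map_boundary(s2$ref_start, s2$ref_end, s2$read_start,
                                s2$strand, t_mid)
          circ_len <- if (s1$strand == "+") d_mid - a_mid else a_mid - d_mid
          if (span > config$circ_max_span) geometry <- "fusion"
          else if (circ_len > 0) geometry <- "bsj"
        } else {
          geometry <- "fusion"
        }
        if (is.na(geometry)) next
        row <- data.frame(
          read_id = rid, read_len = rl, geometry = geometry,
          chrom1 = s1$chrom, strand1 = s1$strand,
          read_start1 = s1$read_start, read_end1 = s1$read_end,
          ref_start1 = s1$ref_start, ref_end1 = s1$ref_end,
          chrom2 = s2$chrom, strand2 = s2$strand,
          read_start2 = s2$read_start, read_end2 = s2$read_end,
          ref_start2 = s2$ref_start, ref_end2 = s2$ref_end
        )
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve the exact breakpoint of one candidate junction
#'
#' Enumerates every admissible partition point of the read within the
#' microhomology window (the read interval claimed by both segments),
#' evaluates the splice strength of the implied donor/acceptor pair at each
#' partition, and returns the partition with the maximum total score if it
#' reaches the threshold. Ties are broken by the smallest absolute shift
#' from the window midpoint, then by the leftmost acceptor coordinate.
#'
#' @param cand one row of [select_bsj_candidates()] output.
#' @param genome named [Biostrings::DNAStringSet].
#' @param model a [train_splice_model()] fit.
#' @param config a [caller_config()] list.
#' @return one-row data.frame describing the resolved junction, or `NULL`
#'   if no partition reaches the threshold. For `geometry == "bsj"` the
#'   columns are `chrom`, `strand`, `start`, `end` plus scores; for
#'   fusions, donor and acceptor locus columns plus scores.
#' @export
resolve_breakpoint <- function(cand, genome, model, config = caller_config()) {
  t_lo <- cand$read_start2
  t_hi <- cand$read_end1
  if (t_lo > t_hi) return(NULL)
  t_mid <- (t_lo + t_hi) / 2
  ts <- seq.int(t_lo, t_hi)
  ts <- ts[abs(ts - t_mid) <= config$microhomology_window + 0.5]
  if (length(ts) == 0) return(NULL)
  donor_pos <- map_boundary(cand$ref_start1, cand$ref_end1, cand$read_start1,
                            cand$strand1, ts)
  acceptor_pos <- map_boundary(cand$ref_start2, cand$ref_end2, cand$read_start2,
                               cand$strand2, ts)
  if (cand$geometry == "bsj") {
    if (cand$strand1 == "+") {
      start <- acceptor_pos; end <- donor_pos
    } else {
      start <- donor_pos; end <- acceptor_pos
    }
    valid <- start < end & (end - start) >= config$min_circ_len
  } else {
    valid <- rep(TRUE, length(ts))
  }
  if (!any(valid)) return(NULL)
  sc <- splice_strength(model, genome,
                        donor_chrom = cand$chrom1, donor_strand = cand$strand1,
                        donor_pos = donor_pos,
                        acceptor_chrom = cand$chrom2,
                        acceptor_strand = cand$strand2,
                        acceptor_pos = acceptor_pos)
  total <- ifelse(valid, sc$total, NA_real_)
  if (all(is.na(total))) return(NULL)
  best_score <- max(total, na.rm = TRUE)
  if (best_score < config$threshold) return(NULL)
  cands <- which(!is.na(total) & total == best_score)
  if (length(cands) > 1L) {
    sh <- abs(ts[cands] - t_mid)
    cands <- cands[sh == min(sh)]
    if (length(cands) > 1L) {
      cands <- cands[order(acceptor_pos[cands])]
    }
  }
  k <- cands[1L]
  if (cand$geometry == "bsj") {
    data.frame(
      read_id = cand$read_id, geometry = "bsj",
      chrom = cand$chrom1, strand = cand$strand1,
      start = start[k], end = end[k],
      donor_score = sc$donor_score[k], acceptor_score = sc$acceptor_score[k],
      total = sc$total[k], partition = ts[k]
    )
  } else {
    data.frame(
      read_id = cand$read_id, geometry = "fusion",
      donor_chrom = cand$chrom1, donor_strand = cand$strand1,
      donor_pos = donor_pos[k],
      acceptor_chrom = cand$chrom2, acceptor_strand = cand$strand2,
      acceptor_pos = acceptor_pos[k],
      donor_score = sc$donor_score[k], acceptor_score = sc$acceptor_score[k],
      total = sc$total[k], partition = ts[k]
    )
  }
}

## resolve all candidates of one read, keep the single best interpretation
## (BSJ and fusion compete on splice strength); equal best scores at
## different junctions are ambiguous and drop the read
resolve_read <- function(cands, genome, model, config) {
  res <- lapply(seq_len(nrow(cands)), function(i) {
    resolve_breakpoint(cands[i, , drop = FALSE], genome, model, config)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(NULL)
  totals <- vapply(res, function(r) r$total, numeric(1))
  best <- which(totals == max(totals))
  if (length(best) > 1L) {
    keys <- vapply(res[best], function(r) {
      if (r$geometry == "bsj") paste(r$chrom, r$strand, r$start, r$end)
      else paste(r$donor_chrom, r$donor_strand, r$donor_pos,
                 r$acceptor_chrom, r$acceptor_strand, r$acceptor_pos)
    }, "")
    if (length(unique(keys)) > 1L) return("ambiguous")
  }
  res[[best[1L]]]
}

#' Call back-splice and fusion junctions from chimeric reads
#'
#' Runs candidate selection, breakpoint resolution and per-junction
#' aggregation. Each read contributes its collapse count times its pair
#' weight to the support of the single junction it is resolved to; reads
#' with equally scored conflicting interpretations are dropped and counted.
#'
#' @param chimeric chimeric segment data.frame.
#' @param reads collapsed read data.frame (for counts and pair weights).
#' @param genome named [Biostrings::DNAStringSet].
#' @param model a [train_splice_model()] fit.
#' @param config a [caller_config()] list.
#' @return list with `circs` (aggregated circRNA calls), `fusions`
#'   (aggregated fusion junctions) and `n_ambiguous`.
#' @export
call_junctions <- function(chimeric, reads, genome, model,
                           config = caller_config()) {
  cands <- select_bsj_candidates(chimeric, config)
  weights <- stats::setNames(reads$count * reads$pair_weight, reads$read_id)
  per_read <- list()
  n_ambiguous <- 0L
  if (nrow(cands) > 0) {
    for (rid in unique(cands$read_id)) {
      r <- resolve_read(cands[cands$read_id == rid, , drop = FALSE],
                        genome, model, config)
      if (is.null(r)) next
      if (identical(r, "ambiguous")) { n_ambiguous <- n_ambiguous + 1L; next }
      r$support <- unname(weights[rid])
      if (is.na(r$support)) r$support <- 1
      per_read[[length(per_read) + 1L]] <- r
    }
  }
  bsj <- per_read[vapply(per_read, function(r) r$geometry == "bsj", logical(1))]
  fus <- per_read[vapply(per_read, function(r) r$geometry == "fusion", logical(1))]
  list(
    circs = aggregate_calls(bsj),
    fusions = aggregate_fusion_junctions(fus),
    n_ambiguous = n_ambiguous
  )
}

#' Aggregate per-read circRNA calls into junction-level calls
#'
#' @param calls list of one-row per-read BSJ data.frames (or a single
#'   data.frame with one row per supporting read).
#' @return data.frame with one row per distinct junction, ordered by
#'   (chrom, start, end), with summed `support` and the junction scores.
#' @export
aggregate_calls <- function(calls) {
  if (is.data.frame(calls)) calls <- split(calls, seq_len(nrow(calls)))
  if (length(calls) == 0) {
    return(data.frame(circ_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), donor_score = numeric(0),
                      acceptor_score = numeric(0), total = numeric(0),
                      support = numeric(0), n_reads = integer(0)))
  }
  df <- do.call(rbind, calls)
  if (!"support" %in% names(df)) df$support <- 1
  key <- paste(df$chrom, df$strand, df$start, df$end, sep = "\r")
  agg <- lapply(split(df, key), function(g) {
    data.frame(chrom = g$chrom[1], strand = g$strand[1],
               start = g$start[1], end = g$end[1],
               donor_score = max(g$donor_score),
               acceptor_score = max(g$acceptor_score),
               total = max(g$total),
               support = sum(g$support), n_reads = nrow(g))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out <- data.frame(circ_id = sprintf("circ_%05d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

aggregate_fusion_junctions <- function(calls) {
  if (length(calls) == 0) {
    return(data.frame(junction_id = character(0), donor_chrom = character(0),
                      donor_strand = character(0), donor_pos = integer(0),
                      acceptor_chrom = character(0),
                      acceptor_strand = character(0), acceptor_pos = integer(0),
                      donor_score = numeric(0), acceptor_score = numeric(0),
                      total = numeric(0), support = numeric(0),
                      n_reads = integer(0)))
  }
  df <- do.call(rbind, calls)
  key <- paste(df$donor_chrom, df$donor_strand, df$donor_pos,
               df$acceptor_chrom, df$acceptor_strand, df$acceptor_pos,
               sep = "\r")
  agg <- lapply(split(df, key), function(g) {
    data.frame(donor_chrom = g$donor_chrom[1], donor_strand = g$donor_strand[1],
               donor_pos = g$donor_pos[1], acceptor_chrom = g$acceptor_chrom[1],
               acceptor_strand = g$acceptor_strand[1],
               acceptor_pos = g$acceptor_pos[1],
               donor_score = max(g$donor_score),
               acceptor_score = max(g$acceptor_score), total = max(g$total),
               support = sum(g$support), n_reads = nrow(g))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$donor_chrom, out$donor_pos, out$acceptor_chrom,
                   out$acceptor_pos), , drop = FALSE]
  out <- data.frame(junction_id = sprintf("fusj_%04d", seq_len(nrow(out))),
                    out)
  rownames(out) <- NULL
  out
}

## transcription-direction span from an acceptor boundary (segment start)
## to a donor boundary (segment end) on one gene
locus_span <- function(strand, acceptor_pos, donor_pos) {
  if (strand == "+") donor_pos - acceptor_pos else acceptor_pos - donor_pos
}

#' Pair reciprocal fusion junctions into fusion circRNAs
#'
#' A fusion circRNA between loci A and B carries two junctions in a fixed
#' reciprocal order: A_j -> B_m and B_n -> A_i with i <= j on A and m <= n
#' on B (indices in transcription direction). Every junction pair
#' satisfying this geometry with both intra-locus spans positive and at
#' most `max_span` is reported; junctions participating in more than one
#' pairing are flagged.
#'
#' @param junctions aggregated fusion junction data.frame
#'   (see [call_junctions()]).
#' @param max_span maximum intra-locus span (bp).
#' @return data.frame with one row per fusion circRNA: both junction ids,
#'   coordinates, spans, per-junction support, and `multi_pairing`.
#' @export
pair_fusion_circs <- function(junctions, max_span = 1e6) {
  out <- list()
  n <- nrow(junctions)
  if (n >= 2) {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        j1 <- junctions[a, ]  # A_j -> B_m
        j2 <- junctions[b, ]  # B_n -> A_i
        if (j1$donor_chrom != j2$acceptor_chrom ||
            j1$donor_strand != j2$acceptor_strand) next
        if (j1$acceptor_chrom != j2$donor_chrom ||
            j1$acceptor_strand != j2$donor_strand) next
        span_a <- locus_span(j1$donor_strand, j2$acceptor_pos, j1$donor_pos)
        span_b <- locus_span(j1$acceptor_strand, j1$acceptor_pos, j2$donor_pos)
        if (span_a <= 0 || span_b <= 0) next  # i <= j and m <= n violated
        if (span_a > max_span || span_b > max_span) next
        ## canonical orientation: emit each reciprocal pair once, with the
        ## junction on the lexicographically smaller donor locus first
        out[[length(out) + 1L]] <- data.frame(
          junction_AB = j1$junction_id, junction_BA = j2$junction_id,
          chrom_A = j1$donor_chrom, strand_A = j1$donor_strand,
          A_start = if (j1$donor_strand == "+") j2$acceptor_pos else j1$donor_pos,
          A_end = if (j1$donor_strand == "+") j1$donor_pos else j2$acceptor_pos,
          chrom_B = j1$acceptor_chrom, strand_B = j1$acceptor_strand,
          B_start = if (j1$acceptor_strand == "+") j1$acceptor_pos else j2$donor_pos,
          B_end = if (j1$acceptor_strand == "+") j2$donor_pos else j1$acceptor_pos,
          support_AB = j1$support, support_BA = j2$support,
          total_AB = j1$total, total_BA = j2$total
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(junction_AB = character(0), junction_BA = character(0),
                      chrom_A = character(0), strand_A = character(0),
                      A_start = integer(0), A_end = integer(0),
                      chrom_B = character(0), strand_B = character(0),
                      B_start = integer(0), B_end = integer(0),
                      support_AB = numeric(0), support_BA = numeric(0),
                      total_AB = numeric(0), total_BA = numeric(0),
                      multi_pairing = logical(0)))
  }
  res <- do.call(rbind, out)
  ## each fusion circle is discovered twice (A/B roles swapped); keep the
  ## first, deterministic occurrence of each unordered junction pair
  key <- apply(cbind(res$junction_AB, res$junction_BA), 1L,
               function(x) paste(sort(x), collapse = "|"))
  res <- res[!duplicated(key), , drop = FALSE]
  used <- c(res$junction_AB, res$junction_BA)
  multi <- names(table(used))[table(used) > 1L]
  res$multi_pairing <- res$junction_AB %in% multi | res$junction_BA %in% multi
  rownames(res) <- NULL
  res
}
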