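## Benchmark simulator.
##
## Generates a fully synthetic genome with multi-exon genes whose exon
## boundaries carry splice-site windows sampled from a trained model, then
## simulates error-free reads: back-splice-junction-spanning reads from
## exon-derived circRNAs, linear decoy reads from the host transcripts,
## and reciprocal fusion-junction reads from simulated fusion circRNAs.
## Every read id encodes its truth record and all sampling is
## seed-deterministic.

#' Generate a synthetic genome with planted splice sites
#'
#' Chromosomes are uniform-random sequence carrying multi-exon genes laid
#' out with intergenic gaps; every exon boundary is overwritten with a
#' donor (exon 3' end) or acceptor (exon 5' start) window rejection-sampled
#' from the model until each site scores at least
#' `(threshold + margin) / 2` bits, so every donor/acceptor pair totals at
#' least `threshold + margin`.
#'
#' @param n_genes number of genes.
#' @param model a [train_splice_model()] fit used both to sample planted
#'   windows and to verify their scores.
#' @param n_chrom number of chromosomes (default spreads ~25 genes per
#'   chromosome, minimum 2).
#' @param exons_per_gene inclusive integer range.
#' @param exon_len,intron_len inclusive ranges (nt); exons shorter than
#'   20 nt are a configuration error. The default exon range keeps every
#'   exon at least as long as a 150 nt read so junction flanks stay within
#'   single exons.
#' @param intergenic gap between genes and at chromosome ends (nt).
#' @param minus_frac fraction of genes on the minus strand.
#' @param threshold caller threshold the planted sites must clear.
#' @param margin extra bits planted above the threshold.
#' @param seed RNG seed; identical seeds give byte-identical genomes.
#' @return object of class `synthetic_genome`: list with `genome`
#'   (DNAStringSet), `exons` (annotation data.frame as in [read_gtf()]),
#'   `planted` (site table with achieved scores), `model`, `threshold`,
#'   `seed`.
#' @export
make_genome <- function(n_genes = 50L, model, n_chrom = NULL,
                        exons_per_gene = c(3L, 6L), exon_len = c(150L, 300L),
                        intron_len = c(80L, 150L), intergenic = 500L,
                        minus_frac = 0.5, threshold = 10, margin = 2,
                        seed = 1L) {
  if (exon_len[1] < 20L) stop("exon length distribution yields exons < 20 nt")
  if (intron_len[1] < ACCEPTOR_INTRON + DONOR_INTRON) {
    stop(sprintf("introns must be at least %d nt to hold both site windows",
                 ACCEPTOR_INTRON + DONOR_INTRON))
  }
  if (intergenic < ACCEPTOR_INTRON + DONOR_INTRON) {
    stop("intergenic gap too small for terminal site windows")
  }
  if (is.null(n_chrom)) n_chrom <- max(2L, ceiling(n_genes / 25L))
  site_min <- (threshold + margin) / 2

  with_seed(seed, {
    ## rejection-sampled pools of high-scoring windows
    draw_sites <- function(dist, n) {
      out <- character(0)
      while (length(out) < n) {
        cand <- sample_kmer(dist, max(64L, 2L * (n - length(out))))
        sc <- score_site(dist, model$background, cand)
        out <- c(out, cand[!is.na(sc) & sc >= site_min])
      }
      out[seq_len(n)]
    }

    gene_chrom <- rep(seq_len(n_chrom), length.out = n_genes)
    strands <- ifelse(stats::runif(n_genes) < minus_frac, "-", "+")
    n_ex <- sample(seq.int(exons_per_gene[1], exons_per_gene[2]), n_genes,
                   replace = TRUE)
    total_sites <- sum(n_ex)
    donors <- draw_sites(model$donor, total_sites)
    acceptors <- draw_sites(model$acceptor, total_sites)
    site_i <- 0L

    chrom_seqs <- character(n_chrom)
    exon_rows <- list()
    planted_rows <- list()
    for (ch in seq_len(n_chrom)) {
      genes <- which(gene_chrom == ch)
      pos <- 0L
      parts <- character(0)
      for (g in genes) {
        pos <- pos + intergenic
        parts <- c(parts, random_dna(intergenic))
        ex_lens <- sample(seq.int(exon_len[1], exon_len[2]), n_ex[g],
                          replace = TRUE)
        in_lens <- if (n_ex[g] > 1L) {
          sample(seq.int(intron_len[1], intron_len[2]), n_ex[g] - 1L,
                 replace = TRUE)
        } else integer(0)
        starts <- integer(n_ex[g])
        for (e in seq_len(n_ex[g])) {
          starts[e] <- pos
          parts <- c(parts, random_dna(ex_lens[e]))
          pos <- pos + ex_lens[e]
          if (e < n_ex[g]) {
            parts <- c(parts, random_dna(in_lens[e]))
            pos <- pos + in_lens[e]
          }
        }
        ends <- starts + ex_lens
        gid <- sprintf("gene%04d", g)
        k <- n_ex[g]
        exon_rows[[g]] <- data.frame(
          gene_id = gid, transcript_id = paste0(gid, ".t1"),
          chrom = paste0("chr", ch), strand = strands[g],
          start = starts, end = ends,
          exon_number = if (strands[g] == "+") seq_len(k) else rev(seq_len(k))
        )
      }
      pos <- pos + intergenic
      parts <- c(parts, random_dna(intergenic))
      chrom_seqs[ch] <- paste(parts, collapse = "")
    }

    ## overwrite exon boundaries with planted windows
    for (g in seq_len(n_genes)) {
      ex <- exon_rows[[g]]
      ch <- match(ex$chrom[1], paste0("chr", seq_len(n_chrom)))
      for (e in seq_len(nrow(ex))) {
        site_i <- site_i + 1L
        dwin <- donors[site_i]
        awin <- acceptors[site_i]
        if (ex$strand[e] == "+") {
          ## acceptor at exon start, donor at exon end
          substr(chrom_seqs[ch], ex$start[e] - ACCEPTOR_INTRON + 1L,
                 ex$start[e] + ACCEPTOR_EXON) <- awin
          substr(chrom_seqs[ch], ex$end[e] - DONOR_EXON + 1L,
                 ex$end[e] + DONOR_INTRON) <- dwin
          dpos <- ex$end[e]; apos <- ex$start[e]
        } else {
          ## mirrored: donor at genomic exon start, acceptor at exon end
          substr(chrom_seqs[ch], ex$start[e] - DONOR_INTRON + 1L,
                 ex$start[e] + DONOR_EXON) <- revcomp(dwin)
          substr(chrom_seqs[ch], ex$end[e] - ACCEPTOR_EXON + 1L,
                 ex$end[e] + ACCEPTOR_INTRON) <- revcomp(awin)
          dpos <- ex$start[e]; apos <- ex$end[e]
        }
        planted_rows[[site_i]] <- data.frame(
          site = c("donor", "acceptor"), chrom = ex$chrom[e],
          strand = ex$strand[e], boundary = c(dpos, apos),
          gene_id = ex$gene_id[e], exon_number = ex$exon_number[e]
        )
      }
    }

    genome <- Biostrings::DNAStringSet(chrom_seqs)
    names(genome) <- paste0("chr", seq_len(n_chrom))
    exons <- do.call(rbind, exon_rows)
    exons <- exons[order(exons$chrom, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    planted <- do.call(rbind, planted_rows)
    sc_d <- splice_strength(model, genome,
                            donor_chrom = planted$chrom[planted$site == "donor"],
                            donor_strand = planted$strand[planted$site == "donor"],
                            donor_pos = planted$boundary[planted$site == "donor"],
                            acceptor_pos = planted$boundary[planted$site == "donor"])
    planted$score <- NA_real_
    planted$score[planted$site == "donor"] <- sc_d$donor_score
    sc_a <- splice_strength(model, genome,
                            donor_chrom = planted$chrom[planted$site == "acceptor"],
                            donor_strand = planted$strand[planted$site == "acceptor"],
                            donor_pos = planted$boundary[planted$site == "acceptor"],
                            acceptor_pos = planted$boundary[planted$site == "acceptor"])
    planted$score[planted$site == "acceptor"] <- sc_a$acceptor_score
    rownames(planted) <- NULL

    structure(
      list(genome = genome, exons = exons, planted = planted, model = model,
           threshold = threshold, seed = seed),
      class = "synthetic_genome"
    )
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "synthetic_genome: %d chromosomes (%s bp), %d genes, %d planted sites\n",
    length(x$genome), format(sum(Biostrings::width(x$genome)), big.mark = ","),
    length(unique(x$exons$gene_id)), nrow(x$planted)))
  invisible(x)
}

## RNA sequence of a transcript (5'->3')
transcript_seq <- function(sg, transcript_id) {
  ex <- sg$exons[sg$exons$transcript_id == transcript_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(ex)), function(i) {
    extract_genome(sg$genome, ex$chrom[i], ex$start[i], ex$end[i], "+")
  }, ""), collapse = "")
  if (ex$strand[1] == "-") revcomp(s) else s
}

## RNA sequence of a transcript-order exon index range [lo, hi]
exon_range_seq <- function(sg, transcript_id, lo, hi) {
  ex <- sg$exons[sg$exons$transcript_id == transcript_id &
                   sg$exons$exon_number >= lo & sg$exons$exon_number <= hi,
                 , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(ex)), function(i) {
    extract_genome(sg$genome, ex$chrom[i], ex$start[i], ex$end[i], "+")
  }, ""), collapse = "")
  list(seq = if (ex$strand[1] == "-") revcomp(s) else s,
       chrom = ex$chrom[1], strand = ex$strand[1],
       start = min(ex$start), end = max(ex$end))
}

#' Simulate circRNA definitions from exon models
#'
#' For every transcript with at least three exons, selects one or two
#' internal exons at random and forms a circle from all exons between the
#' selected ones (inclusive); a fraction of transcripts receives a second,
#' distinct circle. Circles whose concatenated exonic length is below
#' `min_len` are discarded.
#'
#' @param sg a [make_genome()] object.
#' @param frac_two_circ fraction of eligible transcripts given two circles.
#' @param min_len minimum concatenated exonic length (nt).
#' @param seed RNG seed.
#' @return data.frame of circle definitions with coordinates, the
#'   transcript-order exon range, and the monomer sequence.
#' @export
simulate_circs <- function(sg, frac_two_circ = 0.05, min_len = 100L,
                           seed = 1L) {
  txs <- unique(sg$exons$transcript_id)
  n_ex <- vapply(txs, function(t) sum(sg$exons$transcript_id == t), integer(1))
  eligible <- txs[n_ex >= 3L]
  with_seed(seed, {
    rows <- list()
    for (tid in eligible) {
      k <- n_ex[[tid]]
      pick <- function() sort(resample(2:(k - 1L),
                                       size = sample(1:2, 1L),
                                       replace = TRUE))
      sel <- list(pick())
      if (stats::runif(1) < frac_two_circ) {
        for (try in 1:10) {
          s2 <- pick()
          if (!identical(range(s2), range(sel[[1]]))) { sel <- c(sel, list(s2)); break }
        }
      }
      for (ci in seq_along(sel)) {
        lo <- min(sel[[ci]]); hi <- max(sel[[ci]])
        info <- exon_range_seq(sg, tid, lo, hi)
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = sprintf("simcirc_%s_%d", sub("\\.t1$", "", tid), ci),
          transcript_id = tid,
          gene_id = sg$exons$gene_id[sg$exons$transcript_id == tid][1],
          chrom = info$chrom, strand = info$strand,
          start = info$start, end = info$end,
          exon_lo = lo, exon_hi = hi,
          monomer = info$seq, len = nchar(info$seq)
        )
      }
    }
    out <- do.call(rbind, rows)
    out <- out[out$len >= min_len, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

## sample from a vector even when it has length 1
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

## uniform seam-spanning read start positions on a doubled sequence with a
## junction image at `jpos`; at least `min_anchor` bases on both sides
span_window <- function(jpos, read_len, min_anchor, max_pos) {
  lo <- max(0L, jpos + min_anchor - read_len)
  hi <- min(jpos - min_anchor, max_pos)
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

#' Simulate error-free SE or PE reads for circles and linear transcripts
#'
#' Circle reads are drawn uniformly among placements on the doubled
#' monomer that span the back-splice junction with at least `min_anchor`
#' bases on both sides; linear reads are drawn uniformly from transcripts
#' longer than `linear_min_len`. Paired-end mode first draws an insert
#' size from N(`insert_mean`, `insert_sd`) truncated to
#' `[read_len, monomer length]` (up to 100 redraws, then the definition is
#' skipped), then a leftmost position among junction-spanning placements
#' of the insert. Reads are error-free and every read id encodes its truth
#' record.
#'
#' @param sg a [make_genome()] object.
#' @param circs circle definitions from [simulate_circs()] (may have 0
#'   rows).
#' @param mode `"SE"` or `"PE"`.
#' @param read_len read length (nt).
#' @param n_reads_each reads (or pairs) per circle and per transcript.
#' @param insert_mean,insert_sd PE insert-size distribution (nt).
#' @param min_anchor minimum bases on each side of the junction for a read
#'   (SE) or insert (PE) to count as junction-spanning.
#' @param include_linear simulate linear decoy reads from the transcripts.
#' @param linear_min_len transcripts must be longer than this (nt).
#' @param seed RNG seed.
#' @return list with `reads` (named character vector; for PE, `mate1` and
#'   `mate2`) and `truth` (list of `circ` and `linear` data.frames with
#'   emitted read counts).
#' @export
simulate_reads <- function(sg, circs, mode = c("SE", "PE"), read_len = 100L,
                           n_reads_each = 20L, insert_mean = 200,
                           insert_sd = 50, min_anchor = 4L,
                           include_linear = TRUE, linear_min_len = 300L,
                           seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    m1 <- character(0); m2 <- character(0); se <- character(0)
    circ_truth <- list(); lin_truth <- list()
    if (!is.null(circs) && nrow(circs) > 0) {
      for (i in seq_len(nrow(circs))) {
        cc <- circs[i, ]
        L <- cc$len
        if (read_len > 2L * L) {
          warning(sprintf("circle %s shorter than half the read length; skipped",
                          cc$circ_id))
          next
        }
        doubled <- paste0(cc$monomer, cc$monomer)
        n_emit <- 0L
        if (mode == "SE") {
          win <- span_window(L, read_len, min_anchor, 2L * L - read_len)
          if (length(win) == 0) { warning("no junction-spanning placement"); next }
          p <- win[sample.int(length(win), n_reads_each, replace = TRUE)]
          rd <- substring(doubled, p + 1L, p + read_len)
          names(rd) <- sprintf("circ|%s|%d", cc$circ_id, seq_along(rd))
          se <- c(se, rd)
          n_emit <- length(rd)
        } else {
          for (r in seq_len(n_reads_each)) {
            ins <- NA_integer_
            for (try in 1:100) {
              cand <- round(stats::rnorm(1, insert_mean, insert_sd))
              if (cand >= read_len && cand <= L) { ins <- cand; break }
            }
            if (is.na(ins)) next
            win <- span_window(L, ins, min_anchor, 2L * L - ins)
            if (length(win) == 0) next
            p <- win[sample.int(length(win), 1L)]
            id <- sprintf("circ|%s|%d", cc$circ_id, r)
            m1 <- c(m1, stats::setNames(substring(doubled, p + 1L, p + read_len), id))
            m2 <- c(m2, stats::setNames(
              revcomp(substring(doubled, p + ins - read_len + 1L, p + ins)), id))
            n_emit <- n_emit + 1L
          }
        }
        circ_truth[[length(circ_truth) + 1L]] <- data.frame(
          circ_id = cc$circ_id, chrom = cc$chrom, strand = cc$strand,
          start = cc$start, end = cc$end, n_reads = n_emit
        )
      }
    }
    if (include_linear) {
      for (tid in unique(sg$exons$transcript_id)) {
        s <- transcript_seq(sg, tid)
        len <- nchar(s)
        if (len <= linear_min_len || len < read_len) next
        n_emit <- 0L
        if (mode == "SE") {
          p <- sample.int(len - read_len + 1L, n_reads_each, replace = TRUE) - 1L
          rd <- substring(s, p + 1L, p + read_len)
          names(rd) <- sprintf("lin|%s|%d", tid, seq_along(rd))
          se <- c(se, rd)
          n_emit <- length(rd)
        } else {
          for (r in seq_len(n_reads_each)) {
            ins <- NA_integer_
            for (try in 1:100) {
              cand <- round(stats::rnorm(1, insert_mean, insert_sd))
              if (cand >= read_len && cand <= len) { ins <- cand; break }
            }
            if (is.na(ins)) next
            p <- sample.int(len - ins + 1L, 1L) - 1L
            id <- sprintf("lin|%s|%d", tid, r)
            m1 <- c(m1, stats::setNames(substring(s, p + 1L, p + read_len), id))
            m2 <- c(m2, stats::setNames(
              revcomp(substring(s, p + ins - read_len + 1L, p + ins)), id))
            n_emit <- n_emit + 1L
          }
        }
        lin_truth[[length(lin_truth) + 1L]] <- data.frame(
          transcript_id = tid, length = len, n_reads = n_emit
        )
      }
    }
    truth <- list(
      circ = if (length(circ_truth)) do.call(rbind, circ_truth) else NULL,
      linear = if (length(lin_truth)) do.call(rbind, lin_truth) else NULL
    )
    if (mode == "SE") list(reads = se, truth = truth, mode = "SE", seed = seed)
    else list(mate1 = m1, mate2 = m2, truth = truth, mode = "PE", seed = seed)
  })
}

#' Simulate fusion circRNA events and junction-spanning reads
#'
#' Builds reciprocal fusion circles by selecting internal exon ranges of
#' two genes on different chromosomes (A over transcript-order exons
#' i..j, B over m..n, with i <= j and m <= n) and joining A_j to B_m and
#' B_n to A_i. Error-free reads are drawn spanning each of the two fusion
#' junctions per event.
#'
#' @param sg a [make_genome()] object (needs >= 2 multi-exon genes on
#'   different chromosomes).
#' @param n_events number of fusion circRNAs.
#' @param reads_per_junction error-free reads per junction.
#' @param read_len read length (nt).
#' @param min_anchor minimum bases on each side of the junction.
#' @param seed RNG seed.
#' @return list with `events` (definitions), `junctions` (truth table:
#'   two rows per event with donor/acceptor loci) and `reads`.
#' @export
simulate_fusions <- function(sg, n_events = 10L, reads_per_junction = 10L,
                             read_len = 100L, min_anchor = 4L, seed = 1L) {
  ex_by_tx <- split(sg$exons, sg$exons$transcript_id)
  multi <- names(ex_by_tx)[vapply(ex_by_tx, nrow, integer(1)) >= 3L]
  tx_chrom <- vapply(ex_by_tx, function(e) e$chrom[1], "")
  if (length(multi) < 2L || length(unique(tx_chrom[multi])) < 2L) {
    stop("need at least two multi-exon genes on different chromosomes")
  }
  with_seed(seed, {
    events <- list(); junctions <- list(); reads <- character(0)
    ev <- 0L
    while (ev < n_events) {
      ab <- sample(multi, 2L)
      if (tx_chrom[ab[1]] == tx_chrom[ab[2]]) next
      ev <- ev + 1L
      ka <- nrow(ex_by_tx[[ab[1]]]); kb <- nrow(ex_by_tx[[ab[2]]])
      ij <- sort(resample(2:(ka - 1L), 2L, replace = TRUE))
      mn <- sort(resample(2:(kb - 1L), 2L, replace = TRUE))
      a_part <- exon_range_seq(sg, ab[1], ij[1], ij[2])
      b_part <- exon_range_seq(sg, ab[2], mn[1], mn[2])
      circle <- paste0(a_part$seq, b_part$seq)
      LA <- nchar(a_part$seq); L <- nchar(circle)
      tx_a <- ex_by_tx[[ab[1]]]; tx_b <- ex_by_tx[[ab[2]]]
      bnd <- function(tx, num, side) {
        e <- tx[tx$exon_number == num, ]
        if (side == "donor") { if (e$strand == "+") e$end else e$start }
        else { if (e$strand == "+") e$start else e$end }
      }
      j1 <- data.frame(  # A_j -> B_m
        event = ev, junction = 1L,
        donor_chrom = a_part$chrom, donor_strand = a_part$strand,
        donor_pos = bnd(tx_a, ij[2], "donor"),
        acceptor_chrom = b_part$chrom, acceptor_strand = b_part$strand,
        acceptor_pos = bnd(tx_b, mn[1], "acceptor"),
        n_reads = reads_per_junction
      )
      j2 <- data.frame(  # B_n -> A_i
        event = ev, junction = 2L,
        donor_chrom = b_part$chrom, donor_strand = b_part$strand,
        donor_pos = bnd(tx_b, mn[2], "donor"),
        acceptor_chrom = a_part$chrom, acceptor_strand = a_part$strand,
        acceptor_pos = bnd(tx_a, ij[1], "acceptor"),
        n_reads = reads_per_junction
      )
      junctions <- c(junctions, list(j1, j2))
      events[[ev]] <- data.frame(
        event = ev, gene_A = tx_a$gene_id[1], gene_B = tx_b$gene_id[1],
        exon_i = ij[1], exon_j = ij[2], exon_m = mn[1], exon_n = mn[2],
        circle_len = L
      )
      doubled <- paste0(circle, circle)
      for (jn in 1:2) {
        jpos <- if (jn == 1L) L + LA else L
        win <- span_window(jpos, read_len, min_anchor, 2L * L - read_len)
        if (length(win) == 0) stop("no junction-spanning placement for fusion read")
        p <- win[sample.int(length(win), reads_per_junction, replace = TRUE)]
        rd <- substring(doubled, p + 1L, p + read_len)
        names(rd) <- sprintf("fusJ|%d|%d|%d", ev, jn, seq_along(rd))
        reads <- c(reads, rd)
      }
    }
    list(events = do.call(rbind, events),
         junctions = do.call(rbind, junctions),
         reads = reads, seed = seed)
  })
}

#' Write a simulated benchmark to disk
#'
#' Convenience wrapper producing genome FASTA, annotation GTF, FASTQ
#' read files and truth TSVs in `dir`.
#'
#' @param sg a [make_genome()] object.
#' @param sim a [simulate_reads()] result.
#' @param fus optional [simulate_fusions()] result; its reads are appended
#'   to the read files.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_benchmark <- function(sg, sim, fus = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(sg$genome, paths$genome)
  write_gtf(sg$exons, paths$gtf)
  extra <- if (!is.null(fus)) fus$reads else character(0)
  if (identical(sim$mode, "SE")) {
    paths$fastq <- file.path(dir, "reads.fq")
    write_fastq(c(sim$reads, extra), paths$fastq)
  } else {
    paths$fastq1 <- file.path(dir, "reads_1.fq")
    paths$fastq2 <- file.path(dir, "reads_2.fq")
    write_fastq(c(sim$mate1, extra), paths$fastq1)
    rc_extra <- if (length(extra)) stats::setNames(revcomp(extra), names(extra)) else extra
    write_fastq(c(sim$mate2, rc_extra), paths$fastq2)
  }
  if (!is.null(sim$truth$circ)) {
    paths$truth_circ <- file.path(dir, "truth_circ.tsv")
    utils::write.table(sim$truth$circ, paths$truth_circ, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$truth$linear)) {
    paths$truth_linear <- file.path(dir, "truth_linear.tsv")
    utils::write.table(sim$truth$linear, paths$truth_linear, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fus)) {
    paths$truth_fusion <- file.path(dir, "truth_fusion.tsv")
    utils::write.table(fus$junctions, paths$truth_fusion, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
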