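## Post-quantification metrics: relative contribution of a circRNA versus
## its host gene, and miRNA-guided cleavage-site counting on circRNA
## sequences.

#' Relative contribution of a circRNA to its host gene
#'
#' The quotient of the circRNA's estimated abundance over that of its
#' hosting gene. Library-preparation and sequencing biases are expected to
#' affect a circRNA and its host similarly, so the quotient enables
#' cross-sample comparison. Undefined (returned as `NA`, never 0) when the
#' host abundance is zero.
#'
#' @param circ_abundance,host_abundance non-negative abundances
#'   (vectorized).
#' @return numeric vector of quotients, `NA` where the host abundance is 0.
#' @export
relative_contribution <- function(circ_abundance, host_abundance) {
  if (any(circ_abundance < 0, na.rm = TRUE) ||
      any(host_abundance < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative")
  }
  ifelse(host_abundance > 0, circ_abundance / host_abundance, NA_real_)
}

#' Assign host genes to circRNA calls
#'
#' The host is the same-strand gene with the largest exonic overlap with
#' the circle span.
#'
#' @param calls aggregated circRNA calls.
#' @param annotation exon data.frame (see [read_gtf()]).
#' @return `calls` with a `host_gene` column (`NA` when no gene overlaps).
#' @export
assign_host_gene <- function(calls, annotation) {
  calls$host_gene <- vapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    ex <- annotation[annotation$chrom == cl$chrom &
                       annotation$strand == cl$strand &
                       annotation$start < cl$end &
                       annotation$end > cl$start, , drop = FALSE]
    if (nrow(ex) == 0) return(NA_character_)
    ov <- pmin(ex$end, cl$end) - pmax(ex$start, cl$start)
    names(which.max(tapply(ov, ex$gene_id, sum)))
  }, "")
  calls
}

#' Count miRNA binding sites on a circRNA sequence
#'
#' Slides the reverse complement of each full-length miRNA over the
#' doubled circle sequence (start positions within the first monomer copy
#' only, so sites spanning the back-splice junction are found exactly
#' once). A position is a site iff the total number of mismatches is at
#' most `max_mismatch` and no mismatch falls inside the miRNA seed region.
#' Such near-perfect full-length complementarity beyond the seed marks
#' candidate miRNA-guided (AGO2) cleavage sites.
#'
#' @param circ_seq circle monomer sequence (DNA alphabet).
#' @param mirnas named character vector of miRNA sequences (RNA or DNA;
#'   U is treated as T). Sequences outside 18-26 nt or with other letters
#'   are skipped with a warning.
#' @param max_mismatch maximum total mismatches per site (the default
#'   implements "fewer than 5").
#' @param seed_region 1-based inclusive miRNA positions of the seed.
#' @return total site count over all miRNAs, with per-miRNA counts as
#'   attribute `per_mirna`.
#' @export
mirna_cleavage_sites <- function(circ_seq, mirnas, max_mismatch = 4L,
                                 seed_region = c(2L, 8L)) {
  circ_seq <- toupper(circ_seq)
  L <- nchar(circ_seq)
  doubled_raw <- charToRaw(paste0(circ_seq, circ_seq))
  per <- stats::setNames(integer(length(mirnas)),
                         names(mirnas) %||% paste0("mir", seq_along(mirnas)))
  n_skipped <- 0L
  for (i in seq_along(mirnas)) {
    mir <- chartr("Uu", "Tt", toupper(mirnas[i]))
    k <- nchar(mir)
    if (k < 18L || k > 26L || grepl("[^ACGT]", mir) || L < k) {
      n_skipped <- n_skipped + 1L
      next
    }
    target <- charToRaw(revcomp(mir))  # antisense, aligned 3'->5' vs miRNA
    ## miRNA position p corresponds to target window index k - p + 1
    seed_idx <- (k - seed_region[2] + 1L):(k - seed_region[1] + 1L)
    total_mm <- integer(L)
    seed_mm <- integer(L)
    offs <- 0:(L - 1L)
    for (t in seq_len(k)) {
      mm <- as.integer(doubled_raw[offs + t] != target[t])
      total_mm <- total_mm + mm
      if (t %in% seed_idx) seed_mm <- seed_mm + mm
    }
    per[i] <- sum(total_mm <= max_mismatch & seed_mm == 0L)
  }
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d miRNAs (length outside 18-26 nt or invalid letters)",
                    n_skipped))
  }
  structure(sum(per), per_mirna = per)
}

#' Extend an abundance table with downstream metrics
#'
#' Adds host gene, relative contribution and miRNA site counts to
#' quantified circRNA calls, plus a `folding_energy` placeholder column
#' for optional ingestion of externally computed secondary-structure
#' results.
#'
#' @param calls aggregated, quantified circRNA calls.
#' @param refs pseudo-reference table (for monomer sequences).
#' @param annotation optional exon data.frame for host assignment.
#' @param gene_abundance optional named numeric vector of host-gene
#'   abundances (same units as circRNA abundance).
#' @param mirnas optional named character vector of miRNA sequences.
#' @return `calls` with `host_gene`, `host_abundance`, `rc`,
#'   `mirna_site_count` and `folding_energy` columns.
#' @export
annotate_downstream <- function(calls, refs, annotation = NULL,
                                gene_abundance = NULL, mirnas = NULL) {
  n <- nrow(calls)
  if (!is.null(annotation)) {
    calls <- assign_host_gene(calls, annotation)
  } else {
    calls$host_gene <- rep(NA_character_, n)
  }
  calls$host_abundance <- if (!is.null(gene_abundance)) {
    unname(gene_abundance[calls$host_gene])
  } else rep(NA_real_, n)
  calls$rc <- ifelse(
    is.na(calls$host_abundance), NA_real_,
    relative_contribution(calls$abundance, calls$host_abundance)
  )
  calls$mirna_site_count <- if (!is.null(mirnas)) {
    mono <- stats::setNames(refs$monomer, refs$circ_id)
    vapply(calls$circ_id, function(id) {
      suppressWarnings(as.integer(mirna_cleavage_sites(mono[[id]], mirnas)))
    }, integer(1))
  } else rep(NA_integer_, n)
  calls$folding_energy <- rep(NA_real_, n)
  calls
}
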