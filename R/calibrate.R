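## Splice-threshold calibration against an annotated genome.
##
## The default calling threshold of 10 bits is chosen so that the vast
## majority of annotated canonical splice junctions pass it. This check is
## reproducible on any genome + exon annotation: annotated donor/acceptor
## windows are split into a training and a held-out set, a model is
## trained on the training split, and the fraction of held-out junctions
## whose total (donor + acceptor) score reaches the threshold is reported.

#' Extract annotated splice-site windows from an exon annotation
#'
#' For every intron of every transcript, extracts the donor window of the
#' upstream exon and the acceptor window of the downstream exon
#' (transcription order, strand-aware).
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param exons exon data.frame (see [read_gtf()]).
#' @return data.frame with one row per intron: `transcript_id`, `donor`,
#'   `acceptor` window sequences (NA where a window runs off the
#'   chromosome).
#' @export
annotated_site_windows <- function(genome, exons) {
  rows <- list()
  for (tid in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$exon_number), , drop = FALSE]
    if (nrow(ex) < 2L) next
    for (k in seq_len(nrow(ex) - 1L)) {
      up <- ex[k, ]; down <- ex[k + 1L, ]
      dpos <- if (up$strand == "+") up$end else up$start
      apos <- if (down$strand == "+") down$start else down$end
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid,
        donor = extract_donor_window(genome, up$chrom, up$strand, dpos),
        acceptor = extract_acceptor_window(genome, down$chrom, down$strand,
                                           apos)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of held-out annotated junctions passing the threshold
#'
#' Splits the annotated junctions of a genome into a training and a
#' held-out half, trains a splice model on the training windows, and
#' returns the fraction of held-out junctions whose total splice strength
#' reaches `threshold`.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param exons exon annotation data.frame.
#' @param threshold total-score threshold in bits.
#' @param train_frac fraction of junctions used for training.
#' @param seed RNG seed for the split.
#' @param ... passed to [train_splice_model()].
#' @return the passing fraction, with the held-out totals as attribute
#'   `totals` and the trained model as attribute `model`.
#' @export
calibrate_threshold <- function(genome, exons, threshold = 10,
                                train_frac = 0.5, seed = 1L, ...) {
  win <- annotated_site_windows(genome, exons)
  win <- win[!is.na(win$donor) & !is.na(win$acceptor), , drop = FALSE]
  if (nrow(win) < 10L) stop("too few annotated junctions to calibrate")
  idx <- with_seed(seed, sample.int(nrow(win)))
  n_train <- max(5L, floor(train_frac * nrow(win)))
  train <- win[idx[seq_len(n_train)], ]
  held <- win[idx[-seq_len(n_train)], ]
  model <- train_splice_model(train$donor, train$acceptor, ...)
  totals <- score_site(model$donor, model$background, held$donor) +
    score_site(model$acceptor, model$background, held$acceptor)
  frac <- mean(totals >= threshold, na.rm = TRUE)
  structure(frac, totals = totals, model = model)
}
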