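## Maximum-entropy splice-site model
##
## Donor sites are modelled as 9-mers (last 3 exonic + first 6 intronic bases)
## and acceptor sites as 23-mers (last 20 intronic + first 3 exonic bases).
## Each site distribution is the maximum-entropy distribution over its k-mer
## space subject to empirical marginal constraints (position singletons,
## adjacent position pairs, or an arbitrary user-supplied constraint set).
## Splice strength is the log2-odds of a window under the site model versus
## a 0th-order background, in bits; the donor and acceptor scores are summed
## per junction and compared with a single threshold (default 10 bits).

DONOR_EXON <- 3L
DONOR_INTRON <- 6L
ACCEPTOR_INTRON <- 20L
ACCEPTOR_EXON <- 3L
DONOR_WIDTH <- DONOR_EXON + DONOR_INTRON     # 9
ACCEPTOR_WIDTH <- ACCEPTOR_INTRON + ACCEPTOR_EXON  # 23

## ---- constraint handling --------------------------------------------------

expand_constraints <- function(width, constraints) {
  if (is.character(constraints)) {
    constraints <- match.arg(constraints, c("singleton", "adjacent"))
    singles <- lapply(seq_len(width), identity)
    if (constraints == "singleton") return(singles)
    pairs <- lapply(seq_len(width - 1L), function(i) c(i, i + 1L))
    return(c(singles, pairs))
  }
  constraints <- lapply(constraints, function(p) sort(as.integer(p)))
  bad <- vapply(constraints, function(p) {
    length(p) == 0 || any(p < 1L | p > width) || anyDuplicated(p) > 0
  }, logical(1))
  if (any(bad)) stop("invalid constraint position sets")
  constraints
}

## keep only constraints not contained in a larger one (sub-marginals are
## implied by the containing marginal)
maximal_constraints <- function(constraints) {
  n <- length(constraints)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && keep[j] &&
          length(constraints[[i]]) < length(constraints[[j]]) &&
          all(constraints[[i]] %in% constraints[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  constraints[keep]
}

is_chain_constraints <- function(width, constraints) {
  maxc <- maximal_constraints(constraints)
  if (width == 1L) {
    return(length(maxc) == 1L && identical(maxc[[1]], 1L))
  }
  want <- lapply(seq_len(width - 1L), function(i) c(i, i + 1L))
  length(maxc) == length(want) &&
    setequal(
      vapply(maxc, paste, collapse = ",", FUN.VALUE = ""),
      vapply(want, paste, collapse = ",", FUN.VALUE = "")
    )
}

## ---- sequence coding ------------------------------------------------------

## rows = sequences, columns = positions, codes 1..4 (A,C,G,T), NA otherwise
code_seqs <- function(seqs, width = NULL) {
  if (length(seqs) == 0) return(matrix(integer(0), nrow = 0, ncol = width %||% 0))
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must all have the same width")
  if (!is.null(width) && w != width) {
    stop(sprintf("sequences must have width %d, got %d", width, w))
  }
  m <- matrix(
    match(unlist(strsplit(toupper(seqs), "", fixed = TRUE)), BASES),
    nrow = length(seqs), ncol = w, byrow = TRUE
  )
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- training -------------------------------------------------------------

#' Train a maximum-entropy k-mer distribution
#'
#' Fits the maximum-entropy distribution over fixed-width DNA windows that
#' matches the (pseudocount-smoothed) empirical marginals of the training
#' sequences on a set of position constraints.
#'
#' For `constraints = "singleton"` the solution is the product of position
#' marginals (closed form). For `constraints = "adjacent"` (position
#' singletons plus all adjacent pairs) the solution is the first-order
#' Markov chain consistent with the pairwise marginals, which is the exact
#' fixed point of iterative proportional scaling on a chain and is used for
#' any window width. Arbitrary constraint sets (e.g. including non-adjacent
#' pairs) are fitted by iterative proportional scaling over the fully
#' materialized k-mer table and are limited to `width <= 10`.
#'
#' @param seqs character vector of equal-width training windows (A/C/G/T;
#'   windows containing other letters are dropped with a warning).
#' @param constraints `"singleton"`, `"adjacent"`, or a list of integer
#'   position vectors.
#' @param pseudocount added to every cell of each imposed marginal table
#'   before normalization, keeping all probabilities strictly positive.
#' @param tol convergence tolerance on the maximum absolute marginal
#'   deviation (iterative scaling only).
#' @param max_iter maximum number of scaling sweeps.
#' @return an object of class `maxent_dist`.
#' @export
train_maxent <- function(seqs, constraints = "adjacent", pseudocount = 0.5,
                         tol = 1e-6, max_iter = 500L) {
  if (length(seqs) == 0) stop("no training sequences")
  keep <- grepl("^[ACGTacgt]+$", seqs)
  if (!all(keep)) {
    warning(sprintf("dropping %d training sequences with non-ACGT characters",
                    sum(!keep)))
    seqs <- seqs[keep]
  }
  if (length(seqs) == 0) stop("no usable training sequences after filtering")
  m <- code_seqs(seqs)
  width <- ncol(m)
  cons <- expand_constraints(width, constraints)
  maxc <- maximal_constraints(cons)
  arity <- vapply(maxc, length, integer(1))

  if (all(arity == 1L)) {
    marg <- position_marginals(m, pseudocount)
    return(new_maxent_dist("product", width, cons, list(pos = marg)))
  }
  if (is_chain_constraints(width, cons)) {
    pair <- lapply(seq_len(width - 1L), function(i) {
      tab <- table(factor(m[, i], levels = 1:4),
                   factor(m[, i + 1L], levels = 1:4))
      p <- unclass(tab) + pseudocount
      p / sum(p)
    })
    return(new_maxent_dist("chain", width, cons, list(pair = pair)))
  }
  if (width > 10L) {
    stop("general constraint sets require width <= 10 (table fitting)")
  }
  fit_ips_table(m, width, maxc, cons, pseudocount, tol, max_iter)
}

position_marginals <- function(m, pseudocount) {
  vapply(seq_len(ncol(m)), function(i) {
    cnt <- tabulate(m[, i], nbins = 4L) + pseudocount
    cnt / sum(cnt)
  }, numeric(4))  # 4 x width
}

## iterative proportional scaling over the materialized 4^width table
fit_ips_table <- function(m, width, maxc, cons, pseudocount, tol, max_iter) {
  n_out <- 4L^width
  pow4 <- 4L^(seq_len(width) - 1L)
  idx <- 0:(n_out - 1L)
  digit <- function(pos) (idx %/% pow4[pos]) %% 4L
  groups <- lapply(maxc, function(p) {
    g <- 0L
    for (j in seq_along(p)) g <- g + digit(p[j]) * 4L^(j - 1L)
    g + 1L
  })
  targets <- lapply(maxc, function(p) {
    g <- 0L
    for (j in seq_along(p)) {
      g <- g + (m[, p[j], drop = TRUE] - 1L) * 4L^(j - 1L)
    }
    cnt <- tabulate(g + 1L, nbins = 4L^length(p)) + pseudocount
    cnt / sum(cnt)
  })
  q <- rep(1 / n_out, n_out)
  dev <- Inf
  for (it in seq_len(max_iter)) {
    for (ci in seq_along(maxc)) {
      cur <- as.vector(rowsum(q, groups[[ci]]))
      ratio <- targets[[ci]] / cur
      q <- q * ratio[groups[[ci]]]
    }
    dev <- max(vapply(seq_along(maxc), function(ci) {
      max(abs(as.vector(rowsum(q, groups[[ci]])) - targets[[ci]]))
    }, numeric(1)))
    if (dev < tol) break
  }
  if (dev >= tol) {
    warning(sprintf(
      "iterative scaling stopped at max marginal deviation %.3g (tol %.3g); constraint marginals may be mutually inconsistent",
      dev, tol))
  }
  new_maxent_dist("table", width, cons, list(prob = q / sum(q)))
}

new_maxent_dist <- function(type, width, constraints, params) {
  structure(
    list(type = type, width = width, constraints = constraints,
         params = params),
    class = "maxent_dist"
  )
}

#' @export
print.maxent_dist <- function(x, ...) {
  cat(sprintf("maxent_dist: width %d, %s parameterization, %d constraints\n",
              x$width, x$type, length(x$constraints)))
  invisible(x)
}

## ---- probabilities and scores --------------------------------------------

## log2 probability of each sequence; NA for windows with non-ACGT bases
logprob_kmer <- function(dist, seqs) {
  m <- code_seqs(seqs, dist$width)
  if (nrow(m) == 0) return(numeric(0))
  bad <- apply(is.na(m), 1L, any)
  lp <- rep(NA_real_, nrow(m))
  ok <- which(!bad)
  if (length(ok) == 0) return(lp)
  mm <- m[ok, , drop = FALSE]
  if (dist$type == "product") {
    pos <- dist$params$pos
    v <- 0
    for (i in seq_len(dist$width)) v <- v + log2(pos[mm[, i], i])
    lp[ok] <- v
  } else if (dist$type == "chain") {
    pair <- dist$params$pair
    v <- log2(pair[[1]][cbind(mm[, 1], mm[, 2])])
    if (dist$width > 2L) {
      for (i in 2:(dist$width - 1L)) {
        pi_marg <- rowSums(pair[[i]])
        v <- v + log2(pair[[i]][cbind(mm[, i], mm[, i + 1L])]) -
          log2(pi_marg[mm[, i]])
      }
    }
    lp[ok] <- v
  } else {
    pow4 <- 4L^(seq_len(dist$width) - 1L)
    g <- as.integer((mm - 1L) %*% pow4)
    lp[ok] <- log2(dist$params$prob[g + 1L])
  }
  lp
}

## fully materialized probability vector (testing / small widths only)
materialize_dist <- function(dist) {
  if (dist$width > 10L) stop("width too large to materialize")
  n_out <- 4L^dist$width
  pow4 <- 4L^(seq_len(dist$width) - 1L)
  idx <- 0:(n_out - 1L)
  chars <- matrix("", n_out, dist$width)
  for (i in seq_len(dist$width)) {
    chars[, i] <- BASES[((idx %/% pow4[i]) %% 4L) + 1L]
  }
  seqs <- apply(chars, 1L, paste, collapse = "")
  p <- 2^logprob_kmer(dist, seqs)
  names(p) <- seqs
  p
}

## log2 background probability under a 0th-order (length-4 vector) or
## per-position (4 x width matrix) nucleotide distribution
logprob_background <- function(background, seqs, width) {
  m <- code_seqs(seqs, width)
  bad <- apply(is.na(m), 1L, any)
  lp <- rep(NA_real_, nrow(m))
  ok <- which(!bad)
  if (length(ok) == 0) return(lp)
  mm <- m[ok, , drop = FALSE]
  if (is.matrix(background)) {
    v <- 0
    for (i in seq_len(width)) v <- v + log2(background[mm[, i], i])
  } else {
    v <- rowSums(matrix(log2(background[as.vector(mm)]), nrow = length(ok)))
  }
  lp[ok] <- v
  lp
}

#' Score windows as log-odds against background
#'
#' Returns `log2(P_model(seq) / P_background(seq))` in bits for each window.
#' Windows containing `N` (or any non-ACGT base) are unscorable and return
#' `NA`, which callers treat as minus infinity.
#'
#' @param dist a [train_maxent()] fit.
#' @param background length-4 probability vector over A,C,G,T (0th order) or
#'   a 4 x width per-position matrix.
#' @param seqs character vector of windows of the model's width.
#' @return numeric vector of scores in bits (`NA` = unscorable).
#' @export
score_site <- function(dist, background, seqs) {
  logprob_kmer(dist, seqs) - logprob_background(background, seqs, dist$width)
}

## ---- sampling -------------------------------------------------------------

#' Sample k-mers from a fitted site distribution
#'
#' @param dist a [train_maxent()] fit.
#' @param n number of windows to draw.
#' @return character vector of `n` windows.
#' @export
sample_kmer <- function(dist, n) {
  w <- dist$width
  if (dist$type == "product") {
    pos <- dist$params$pos
    m <- vapply(seq_len(w), function(i) {
      sample.int(4L, n, replace = TRUE, prob = pos[, i])
    }, integer(n))
    m <- matrix(m, nrow = n)
  } else if (dist$type == "chain") {
    pair <- dist$params$pair
    m <- matrix(0L, n, w)
    j12 <- sample.int(16L, n, replace = TRUE, prob = as.vector(pair[[1]]))
    m[, 1] <- ((j12 - 1L) %% 4L) + 1L
    m[, 2] <- ((j12 - 1L) %/% 4L) + 1L
    if (w > 2L) {
      for (i in 2:(w - 1L)) {
        cond <- pair[[i]] / rowSums(pair[[i]])
        for (a in 1:4) {
          sel <- which(m[, i] == a)
          if (length(sel)) {
            m[sel, i + 1L] <- sample.int(4L, length(sel), replace = TRUE,
                                         prob = cond[a, ])
          }
        }
      }
    }
  } else {
    pow4 <- 4L^(seq_len(w) - 1L)
    g <- sample.int(length(dist$params$prob), n, replace = TRUE,
                    prob = dist$params$prob) - 1L
    m <- vapply(seq_len(w), function(i) ((g %/% pow4[i]) %% 4L) + 1L,
                integer(n))
    m <- matrix(m, nrow = n)
  }
  apply(matrix(BASES[m], nrow = n), 1L, paste, collapse = "")
}

## ---- the paired donor/acceptor model --------------------------------------

#' Train a donor/acceptor splice-site model
#'
#' Bundles a donor 9-mer distribution (3 exonic + 6 intronic bases), an
#' acceptor 23-mer distribution (20 intronic + 3 exonic bases) and a shared
#' 0th-order background into one scoring model.
#'
#' @param donor_seqs character vector of 9-mer donor training windows.
#' @param acceptor_seqs character vector of 23-mer acceptor training windows.
#' @param background length-4 probability vector over A,C,G,T.
#' @param constraints passed to [train_maxent()] for both sites.
#' @param pseudocount,tol,max_iter passed to [train_maxent()].
#' @return an object of class `splice_site_model`.
#' @export
train_splice_model <- function(donor_seqs, acceptor_seqs,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               constraints = "adjacent", pseudocount = 0.5,
                               tol = 1e-6, max_iter = 500L) {
  if (any(nchar(donor_seqs) != DONOR_WIDTH)) {
    stop(sprintf("donor training windows must be %d nt", DONOR_WIDTH))
  }
  if (any(nchar(acceptor_seqs) != ACCEPTOR_WIDTH)) {
    stop(sprintf("acceptor training windows must be %d nt", ACCEPTOR_WIDTH))
  }
  stopifnot(length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  names(background) <- BASES
  structure(
    list(
      donor = train_maxent(donor_seqs, constraints, pseudocount, tol, max_iter),
      acceptor = train_maxent(acceptor_seqs, constraints, pseudocount, tol,
                              max_iter),
      background = background,
      donor_window = c(exon = DONOR_EXON, intron = DONOR_INTRON),
      acceptor_window = c(intron = ACCEPTOR_INTRON, exon = ACCEPTOR_EXON)
    ),
    class = "splice_site_model"
  )
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat("splice_site_model\n")
  cat(sprintf("  donor:    %d-mer (%d exonic + %d intronic), %s fit\n",
              x$donor$width, x$donor_window["exon"], x$donor_window["intron"],
              x$donor$type))
  cat(sprintf("  acceptor: %d-mer (%d intronic + %d exonic), %s fit\n",
              x$acceptor$width, x$acceptor_window["intron"],
              x$acceptor_window["exon"], x$acceptor$type))
  invisible(x)
}

## ---- genomic window extraction --------------------------------------------

## A donor "boundary" is the 0-based half-open coordinate one past the last
## exonic base in genomic terms for "+" sites; for "-" sites it is the
## genomic start coordinate of the exon (the transcribed 3' exon end).
## Acceptor boundaries are symmetric: exon genomic start for "+", exon
## genomic end for "-".
extract_donor_window <- function(genome, chrom, strand, boundary) {
  mapply(function(ch, st, b) {
    if (st == "+") extract_genome(genome, ch, b - DONOR_EXON, b + DONOR_INTRON, "+")
    else extract_genome(genome, ch, b - DONOR_INTRON, b + DONOR_EXON, "-")
  }, chrom, strand, boundary, USE.NAMES = FALSE)
}

extract_acceptor_window <- function(genome, chrom, strand, boundary) {
  mapply(function(ch, st, b) {
    if (st == "+") extract_genome(genome, ch, b - ACCEPTOR_INTRON, b + ACCEPTOR_EXON, "+")
    else extract_genome(genome, ch, b - ACCEPTOR_EXON, b + ACCEPTOR_INTRON, "-")
  }, chrom, strand, boundary, USE.NAMES = FALSE)
}

#' Splice strength of donor/acceptor boundary pairs
#'
#' Extracts the strand-aware donor 9-mer and acceptor 23-mer around each
#' boundary, scores both against the model, and sums them. All coordinates
#' are 0-based half-open boundaries: for a `+` site the donor boundary is
#' the coordinate one past the exon's last base and the acceptor boundary is
#' the exon's start; `-` sites mirror this on the reverse strand.
#'
#' @param model a [train_splice_model()] fit.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param donor_chrom,donor_strand,donor_pos vectors describing donor sites.
#' @param acceptor_chrom,acceptor_strand,acceptor_pos vectors describing
#'   acceptor sites (recycled against the donor vectors).
#' @return data.frame with columns `donor_score`, `acceptor_score`, `total`
#'   (bits; `NA` where a window is unscorable or off-chromosome).
#' @export
splice_strength <- function(model, genome, donor_chrom, donor_strand,
                            donor_pos, acceptor_chrom = donor_chrom,
                            acceptor_strand = donor_strand, acceptor_pos) {
  n <- max(length(donor_pos), length(acceptor_pos))
  donor_chrom <- rep_len(donor_chrom, n)
  donor_strand <- rep_len(donor_strand, n)
  donor_pos <- rep_len(donor_pos, n)
  acceptor_chrom <- rep_len(acceptor_chrom, n)
  acceptor_strand <- rep_len(acceptor_strand, n)
  acceptor_pos <- rep_len(acceptor_pos, n)
  dwin <- extract_donor_window(genome, donor_chrom, donor_strand, donor_pos)
  awin <- extract_acceptor_window(genome, acceptor_chrom, acceptor_strand,
                                  acceptor_pos)
  ds <- rep(NA_real_, n)
  as_ <- rep(NA_real_, n)
  ok <- !is.na(dwin)
  if (any(ok)) ds[ok] <- score_site(model$donor, model$background, dwin[ok])
  ok <- !is.na(awin)
  if (any(ok)) as_[ok] <- score_site(model$acceptor, model$background, awin[ok])
  data.frame(donor_score = ds, acceptor_score = as_, total = ds + as_)
}

## ---- serialization --------------------------------------------------------

dist_to_list <- function(dist) {
  params <- switch(
    dist$type,
    product = list(pos = dist$params$pos),
    chain = list(pair = dist$params$pair),
    table = list(prob = dist$params$prob)
  )
  list(type = dist$type, width = dist$width,
       constraints = dist$constraints, params = params)
}

dist_from_list <- function(x) {
  params <- x$params
  ## jsonlite serializes matrices as nested arrays by row
  if (x$type == "product") {
    params$pos <- matrix(unlist(params$pos), nrow = 4L, byrow = TRUE)
  } else if (x$type == "chain") {
    params$pair <- lapply(params$pair, function(p) {
      matrix(unlist(p), 4L, 4L, byrow = TRUE)
    })
  } else {
    params$prob <- as.numeric(unlist(params$prob))
  }
  new_maxent_dist(x$type, as.integer(x$width),
                  lapply(x$constraints, as.integer), params)
}

#' Write / read a splice-site model as versioned JSON
#'
#' @param model a `splice_site_model`.
#' @param path file path.
#' @return `read_splice_model` returns the restored `splice_site_model`.
#' @export
write_splice_model <- function(model, path) {
  obj <- list(
    format = "circpipe_splice_model",
    version = 1L,
    background = as.list(model$background),
    donor_window = as.list(model$donor_window),
    acceptor_window = as.list(model$acceptor_window),
    donor = dist_to_list(model$donor),
    acceptor = dist_to_list(model$acceptor)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_splice_model
#' @export
read_splice_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "circpipe_splice_model")) {
    stop("not a circpipe splice model file")
  }
  bg <- unlist(obj$background)[BASES]
  structure(
    list(
      donor = dist_from_list(obj$donor),
      acceptor = dist_from_list(obj$acceptor),
      background = bg,
      donor_window = c(exon = DONOR_EXON, intron = DONOR_INTRON),
      acceptor_window = c(intron = ACCEPTOR_INTRON, exon = ACCEPTOR_EXON)
    ),
    class = "splice_site_model"
  )
}

## ---- synthetic training material ------------------------------------------

## Position weight matrices emulating the canonical GT..AG intron boundary
## composition: near-invariant GT / AG cores, a biased exonic CAG end, and a
## pyrimidine-rich tract upstream of the acceptor. These are synthetic
## parameters for self-contained training and benchmarking, not estimates
## from any genome.
donor_pwm <- function() {
  m <- cbind(
    c(0.30, 0.40, 0.20, 0.10),  # exon -3
    c(0.60, 0.10, 0.20, 0.10),  # exon -2
    c(0.10, 0.05, 0.80, 0.05),  # exon -1
    c(0.004, 0.003, 0.99, 0.003),  # intron +1 (G)
    c(0.004, 0.003, 0.003, 0.99),  # intron +2 (T)
    c(0.60, 0.05, 0.30, 0.05),  # intron +3
    c(0.70, 0.10, 0.10, 0.10),  # intron +4
    c(0.10, 0.05, 0.80, 0.05),  # intron +5 (G)
    c(0.20, 0.20, 0.10, 0.50)   # intron +6 (T)
  )
  rownames(m) <- BASES
  m
}

acceptor_pwm <- function() {
  tract <- c(0.05, 0.40, 0.05, 0.50)  # pyrimidine-rich
  m <- cbind(
    matrix(rep(tract, 17), nrow = 4),      # intron -20 .. -4
    c(0.05, 0.30, 0.05, 0.60),             # intron -3 (Y)
    c(0.99, 0.004, 0.003, 0.003),          # intron -2 (A)
    c(0.004, 0.003, 0.99, 0.003),          # intron -1 (G)
    c(0.25, 0.15, 0.50, 0.10),             # exon +1
    c(0.25, 0.25, 0.25, 0.25),             # exon +2
    c(0.25, 0.25, 0.25, 0.25)              # exon +3
  )
  rownames(m) <- BASES
  m
}

sample_pwm <- function(pwm, n) {
  w <- ncol(pwm)
  m <- vapply(seq_len(w), function(i) {
    sample.int(4L, n, replace = TRUE, prob = pwm[, i])
  }, integer(n))
  apply(matrix(BASES[matrix(m, nrow = n)], nrow = n), 1L, paste, collapse = "")
}

#' Generate synthetic donor/acceptor training windows
#'
#' Draws donor 9-mers and acceptor 23-mers from built-in synthetic position
#' weight matrices that emulate canonical GT..AG splice-site composition.
#' Used to train a self-contained model for simulation and testing; real
#' analyses should train on genome-derived site windows instead.
#'
#' @param n number of windows per site class.
#' @param seed RNG seed.
#' @return list with character vectors `donor` and `acceptor`.
#' @export
simulate_splice_training <- function(n = 1000L, seed = 1L) {
  with_seed(seed, {
    list(donor = sample_pwm(donor_pwm(), n),
         acceptor = sample_pwm(acceptor_pwm(), n))
  })
}

#' Default self-contained splice model
#'
#' Trains a splice-site model on synthetic canonical-composition training
#' windows ([simulate_splice_training()]). Deterministic given `seed`.
#'
#' @param n_train training windows per site class.
#' @param seed RNG seed for the training draw.
#' @param ... passed to [train_splice_model()].
#' @return a `splice_site_model`.
#' @export
default_splice_model <- function(n_train = 2000L, seed = 99L, ...) {
  tr <- simulate_splice_training(n_train, seed)
  train_splice_model(tr$donor, tr$acceptor, ...)
}
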