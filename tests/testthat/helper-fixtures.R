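## Shared fixtures (memoized per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_model <- function() {
  memo("model", default_splice_model(n_train = 1500L, seed = 424L))
}

## small genome shared by caller/quantifier/simulator tests
test_genome <- function() {
  memo("genome", make_genome(n_genes = 12L, model = test_model(), seed = 77L))
}

random_seqs <- function(n, k, seed) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, ""))
}

## ---- brute-force maximum-entropy oracle (direct convex optimization) ----
## Maximizes entropy subject to pseudocount-smoothed marginal constraints by
## minimizing the convex dual log Z(theta) - theta.b with BFGS over the
## fully enumerated outcome space. Independent of the package's iterative
## scaling / closed-form fitters.
oracle_maxent <- function(seqs, constraints, pseudocount = 0.5) {
  k <- nchar(seqs[1])
  bases <- c("A", "C", "G", "T")
  n_out <- 4L^k
  ## enumerate outcomes as a matrix of codes
  grid <- as.matrix(expand.grid(rep(list(1:4), k)))[, k:1, drop = FALSE]
  cons <- if (is.character(constraints)) {
    singles <- lapply(seq_len(k), identity)
    if (constraints == "singleton") singles
    else c(singles, lapply(seq_len(k - 1L), function(i) c(i, i + 1L)))
  } else constraints
  ## keep only maximal constraints, as the trainer does
  keep <- rep(TRUE, length(cons))
  for (i in seq_along(cons)) {
    for (j in seq_along(cons)) {
      if (i != j && keep[j] && length(cons[[i]]) < length(cons[[j]]) &&
          all(cons[[i]] %in% cons[[j]])) keep[i] <- FALSE
    }
  }
  cons <- cons[keep]
  m <- t(vapply(strsplit(seqs, ""), function(x) match(x, bases), integer(k)))
  m <- matrix(m, ncol = k)
  feats <- list(); targets <- numeric(0)
  for (cc in cons) {
    card <- 4L^length(cc)
    g_out <- rep(0L, n_out); g_emp <- rep(0L, nrow(m))
    for (j in seq_along(cc)) {
      g_out <- g_out + (grid[, cc[j]] - 1L) * 4L^(j - 1L)
      g_emp <- g_emp + (m[, cc[j]] - 1L) * 4L^(j - 1L)
    }
    tab <- tabulate(g_emp + 1L, nbins = card) + pseudocount
    tab <- tab / sum(tab)
    for (v in seq_len(card)) {
      feats[[length(feats) + 1L]] <- as.numeric(g_out == v - 1L)
      targets <- c(targets, tab[v])
    }
  }
  FM <- do.call(cbind, feats)
  dual <- function(theta) {
    s <- as.vector(FM %*% theta)
    M <- max(s)
    log(sum(exp(s - M))) + M - sum(theta * targets)
  }
  grad <- function(theta) {
    s <- as.vector(FM %*% theta)
    p <- exp(s - max(s)); p <- p / sum(p)
    as.vector(crossprod(FM, p)) - targets
  }
  fit <- stats::optim(rep(0, ncol(FM)), dual, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  s <- as.vector(FM %*% fit$par)
  p <- exp(s - max(s)); p <- p / sum(p)
  names(p) <- apply(grid, 1L, function(r) paste(bases[r], collapse = ""))
  p
}

## ---- exhaustive breakpoint-arbitration oracle ----
## Enumerates every partition in the microhomology window, extracts the
## donor/acceptor windows by direct string slicing (its own code path),
## scores them, and applies the same acceptance and tie-break rules.
oracle_resolve <- function(cand, genome, model, config = caller_config()) {
  chrom_str <- lapply(as.character(genome), identity)
  slice <- function(ch, s0, e0, strand) {
    s <- chrom_str[[ch]]
    if (s0 < 0 || e0 > nchar(s) || s0 >= e0) return(NA_character_)
    x <- substr(s, s0 + 1L, e0)
    if (strand == "-") {
      x <- paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
    }
    x
  }
  donor_win <- function(ch, strand, b) {
    if (strand == "+") slice(ch, b - 3L, b + 6L, "+") else slice(ch, b - 6L, b + 3L, "-")
  }
  acc_win <- function(ch, strand, b) {
    if (strand == "+") slice(ch, b - 20L, b + 3L, "+") else slice(ch, b - 3L, b + 20L, "-")
  }
  t_lo <- cand$read_start2; t_hi <- cand$read_end1
  if (t_lo > t_hi) return(NULL)
  t_mid <- (t_lo + t_hi) / 2
  best <- NULL
  for (t in t_lo:t_hi) {
    if (abs(t - t_mid) > config$microhomology_window + 0.5) next
    dp <- if (cand$strand1 == "+") cand$ref_start1 + (t - cand$read_start1)
          else cand$ref_end1 - (t - cand$read_start1)
    ap <- if (cand$strand2 == "+") cand$ref_start2 + (t - cand$read_start2)
          else cand$ref_end2 - (t - cand$read_start2)
    if (cand$geometry == "bsj") {
      st <- if (cand$strand1 == "+") ap else dp
      en <- if (cand$strand1 == "+") dp else ap
      if (!(st < en && en - st >= config$min_circ_len)) next
    }
    dw <- donor_win(cand$chrom1, cand$strand1, dp)
    aw <- acc_win(cand$chrom2, cand$strand2, ap)
    if (is.na(dw) || is.na(aw)) next
    ds <- score_site(model$donor, model$background, dw)
    as_ <- score_site(model$acceptor, model$background, aw)
    tot <- ds + as_
    if (is.na(tot)) next
    cand_rec <- list(t = t, total = tot, donor = dp, acceptor = ap,
                     shift = abs(t - t_mid))
    if (is.null(best) || tot > best$total ||
        (tot == best$total && (cand_rec$shift < best$shift ||
          (cand_rec$shift == best$shift && ap < best$acceptor)))) {
      best <- cand_rec
    }
  }
  if (is.null(best) || best$total < config$threshold) return(NULL)
  best
}

## ---- brute-force miRNA site oracle ----
oracle_mirna_sites <- function(circ_seq, mirna, max_mismatch = 4L,
                               seed_region = c(2L, 8L)) {
  circ_seq <- toupper(circ_seq)
  mir <- chartr("Uu", "Tt", toupper(mirna))
  k <- nchar(mir)
  L <- nchar(circ_seq)
  doubled <- paste0(circ_seq, circ_seq)
  target <- strsplit(paste(rev(strsplit(chartr("ACGT", "TGCA", mir), "")[[1]]),
                           collapse = ""), "")[[1]]
  count <- 0L
  for (ofs in 0:(L - 1L)) {
    win <- strsplit(substr(doubled, ofs + 1L, ofs + k), "")[[1]]
    mm_pos <- which(win != target)                 # indices in target window
    mir_pos <- k - mm_pos + 1L                     # map to miRNA coordinates
    in_seed <- mir_pos >= seed_region[1] & mir_pos <= seed_region[2]
    if (length(mm_pos) <= max_mismatch && !any(in_seed)) count <- count + 1L
  }
  count
}

junction_key <- function(d) paste(d$chrom, d$strand, d$start, d$end)

fusion_key <- function(d) {
  paste(d$donor_chrom, d$donor_strand, d$donor_pos,
        d$acceptor_chrom, d$acceptor_strand, d$acceptor_pos)
}
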