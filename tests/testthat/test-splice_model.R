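test_that("uniform training marginals give the uniform distribution", {
  bases <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  fit <- train_maxent(all3, constraints = "singleton", pseudocount = 0.5)
  p <- circpipe:::materialize_dist(fit)
  expect_equal(unname(p), rep(1 / 64, 64), tolerance = 1e-12)
})

test_that("singleton-only fits equal the product of position marginals", {
  seqs <- random_seqs(80, 4, seed = 101)
  fit <- train_maxent(seqs, constraints = "singleton", pseudocount = 0.5)
  ## closed form: per-position pseudocounted frequencies
  m <- t(vapply(strsplit(seqs, ""), function(x) match(x, c("A", "C", "G", "T")),
                integer(4)))
  for (s in c("ACGT", "TTAG", "GGGG")) {
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    expected <- prod(vapply(1:4, function(i) {
      (sum(m[, i] == codes[i]) + 0.5) / (nrow(m) + 2)
    }, numeric(1)))
    got <- 2^circpipe:::logprob_kmer(fit, s)
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("trained distributions match the brute-force convex oracle", {
  seqs <- random_seqs(50, 3, seed = 111)
  ## chain (adjacent-pair) fit
  fit <- train_maxent(seqs, constraints = "adjacent")
  p_fit <- circpipe:::materialize_dist(fit)
  p_oracle <- oracle_maxent(seqs, "adjacent")
  expect_lt(max(abs(p_fit[names(p_oracle)] - p_oracle)), 1e-4)

  ## general constraint set with a non-adjacent pair forces the iterative
  ## proportional scaling path
  cons <- list(1L, 2L, 3L, c(1L, 3L))
  fit2 <- train_maxent(seqs, constraints = cons)
  expect_equal(fit2$type, "table")
  p_fit2 <- circpipe:::materialize_dist(fit2)
  p_oracle2 <- oracle_maxent(seqs, cons)
  expect_lt(max(abs(p_fit2[names(p_oracle2)] - p_oracle2)), 1e-4)
})

test_that("chain closed form agrees with iterative scaling on the same constraints", {
  seqs <- random_seqs(60, 4, seed = 121)
  chain <- train_maxent(seqs, constraints = "adjacent")
  ## run the iterative-proportional-scaling engine directly on the same
  ## adjacent-pair constraints; its fixed point is the chain closed form
  m <- circpipe:::code_seqs(seqs)
  cons <- circpipe:::expand_constraints(4L, "adjacent")
  maxc <- circpipe:::maximal_constraints(cons)
  tab <- circpipe:::fit_ips_table(m, 4L, maxc, cons, pseudocount = 0.5,
                                  tol = 1e-10, max_iter = 2000L)
  expect_equal(tab$type, "table")
  p1 <- circpipe:::materialize_dist(chain)
  p2 <- circpipe:::materialize_dist(tab)
  expect_lt(max(abs(p1[names(p2)] - p2)), 1e-5)
})

test_that("site scoring is log2 odds against background", {
  seqs <- random_seqs(40, 3, seed = 131)
  fit <- train_maxent(seqs, constraints = "singleton")
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  ## model == background gives 0 bits everywhere
  unif <- train_maxent(apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3)),
                             1L, paste, collapse = ""),
                       constraints = "singleton")
  expect_equal(score_site(unif, bg, c("ACG", "TTT")), c(0, 0),
               tolerance = 1e-10)
  ## hand-set ratio: P_model("GTA") = 0.5, P_bg("GTA") = 0.125 -> 2 bits
  toy <- circpipe:::new_maxent_dist(
    "table", 3L, list(1L),
    list(prob = {
      p <- rep(0.5 / 63, 64)
      idx <- sum((match(c("G", "T", "A"), c("A", "C", "G", "T")) - 1L) *
                   4L^(0:2)) + 1L
      p[idx] <- 0.5
      p
    })
  )
  ## per-position background giving each observed base probability 0.5
  bg_mat <- matrix(1 / 6, nrow = 4, ncol = 3,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  bg_mat["G", 1] <- 0.5; bg_mat["T", 2] <- 0.5; bg_mat["A", 3] <- 0.5
  expect_equal(score_site(toy, bg_mat, "GTA"), 2, tolerance = 1e-12)
  ## exhaustive-table oracle on a random model
  tbl <- circpipe:::materialize_dist(fit)
  for (s in c("AAA", "CGT", "TGC")) {
    expect_equal(score_site(fit, bg, s), log2(tbl[[s]] / 0.25^3),
                 tolerance = 1e-10)
  }
  ## N is unscorable
  expect_true(is.na(score_site(fit, bg, "ANG")))
})

test_that("donor distribution is normalized and scoring is strand-symmetric", {
  model <- test_model()
  p <- circpipe:::materialize_dist(model$donor)
  expect_equal(sum(p), 1, tolerance = 1e-6)

  sg <- test_genome()
  pl <- sg$planted[sg$planted$site == "donor", ][1:10, ]
  fwd <- splice_strength(model, sg$genome, donor_chrom = pl$chrom,
                         donor_strand = pl$strand, donor_pos = pl$boundary,
                         acceptor_pos = pl$boundary)$donor_score
  ## mirrored genome: the reverse complement locus scored on the other strand
  rc_genome <- Biostrings::reverseComplement(sg$genome)
  names(rc_genome) <- names(sg$genome)
  L <- stats::setNames(Biostrings::width(sg$genome), names(sg$genome))
  rc_pos <- L[pl$chrom] - pl$boundary
  rc_strand <- ifelse(pl$strand == "+", "-", "+")
  rev <- splice_strength(model, rc_genome, donor_chrom = pl$chrom,
                         donor_strand = rc_strand, donor_pos = unname(rc_pos),
                         acceptor_pos = unname(rc_pos))$donor_score
  expect_equal(fwd, rev, tolerance = 1e-9)
})

test_that("training windows sampled from a fitted model recover its marginals", {
  model <- test_model()
  redraw <- withr::with_seed(141, sample_kmer(model$donor, 4000))
  refit <- train_maxent(redraw, constraints = "adjacent")
  ## compare singleton marginals implied by the pairwise tables
  marg <- function(d, i) {
    if (i == 1L) rowSums(d$params$pair[[1]]) else colSums(d$params$pair[[i - 1L]])
  }
  for (i in c(1L, 4L, 9L)) {
    expect_equal(marg(refit, i), marg(model$donor, i), tolerance = 0.05)
  }
})

test_that("models serialize to JSON and back without changing scores", {
  model <- test_model()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_splice_model(model, tmp)
  back <- read_splice_model(tmp)
  probes <- simulate_splice_training(20, seed = 151)
  expect_equal(score_site(back$donor, back$background, probes$donor),
               score_site(model$donor, model$background, probes$donor),
               tolerance = 1e-12)
  expect_equal(score_site(back$acceptor, back$background, probes$acceptor),
               score_site(model$acceptor, model$background, probes$acceptor),
               tolerance = 1e-12)
})

test_that("random genomic positions score near or below zero on average", {
  model <- test_model()
  sg <- test_genome()
  withr::with_seed(161, {
    chrom <- sample(names(sg$genome), 300, replace = TRUE)
    pos <- vapply(chrom, function(ch) {
      sample(50:(length(sg$genome[[ch]]) - 50), 1L)
    }, integer(1))
  })
  sc <- splice_strength(model, sg$genome, donor_chrom = chrom,
                        donor_strand = "+", donor_pos = unname(pos),
                        acceptor_pos = unname(pos))
  expect_lt(mean(sc$total, na.rm = TRUE), 0)
  ## and essentially none reach the calling threshold
  expect_lt(mean(sc$total >= 10, na.rm = TRUE), 0.02)
})

test_that("a model trains from the bundled synthetic window FASTAs", {
  donor_fa <- system.file("extdata", "synthetic_donor_sites.fa",
                          package = "circpipe")
  acceptor_fa <- system.file("extdata", "synthetic_acceptor_sites.fa",
                             package = "circpipe")
  donor <- as.character(Biostrings::readDNAStringSet(donor_fa))
  acceptor <- as.character(Biostrings::readDNAStringSet(acceptor_fa))
  model <- train_splice_model(donor, acceptor)
  ## the fixture windows score highly under the model trained on them
  expect_gt(mean(score_site(model$donor, model$background, donor)), 4)
  expect_gt(mean(score_site(model$acceptor, model$background, acceptor)), 8)
})

test_that("degenerate training input is rejected or cleaned", {
  expect_error(train_maxent(character(0)), "no training sequences")
  expect_warning(fit <- train_maxent(c("ACG", "ANG", "TTT"),
                                     constraints = "singleton"),
                 "dropping 1")
  expect_equal(fit$width, 3L)
  expect_error(suppressWarnings(train_maxent(c("NNN"), "singleton")),
               "no usable")
})
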