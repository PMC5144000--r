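test_that("genome generation is seed-deterministic down to the written files", {
  model <- test_model()
  g1 <- make_genome(n_genes = 4L, model = model, seed = 401)
  g2 <- make_genome(n_genes = 4L, model = model, seed = 401)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  Biostrings::writeXStringSet(g1$genome, file.path(d1, "g.fa"))
  Biostrings::writeXStringSet(g2$genome, file.path(d2, "g.fa"))
  write_gtf(g1$exons, file.path(d1, "g.gtf"))
  write_gtf(g2$exons, file.path(d2, "g.gtf"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "g.gtf")),
                   readLines(file.path(d2, "g.gtf")))
  ## a different seed changes the sequence
  g3 <- make_genome(n_genes = 4L, model = model, seed = 402)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("every planted site scores at or above the caller threshold", {
  sg <- test_genome()
  expect_true(all(sg$planted$score >= (sg$threshold + 2) / 2))
  ## donor/acceptor pairs across any exon boundary clear the total threshold
  d <- sg$planted$score[sg$planted$site == "donor"]
  a <- sg$planted$score[sg$planted$site == "acceptor"]
  expect_true(min(d) + min(a) >= sg$threshold)
})

test_that("degenerate simulator configurations are fatal", {
  model <- test_model()
  expect_error(make_genome(4L, model, exon_len = c(10L, 30L), seed = 1),
               "exons < 20")
  expect_error(make_genome(4L, model, intron_len = c(10L, 20L), seed = 1),
               "introns")
})

test_that("circle definitions follow the internal-exon rule and length filter", {
  sg <- test_genome()
  circs <- simulate_circs(sg, seed = 411)
  n_ex <- table(sg$exons$transcript_id)
  for (i in seq_len(nrow(circs))) {
    k <- n_ex[[circs$transcript_id[i]]]
    expect_gte(circs$exon_lo[i], 2L)
    expect_lte(circs$exon_hi[i], k - 1L)
  }
  ## a transcript with exactly 3 exons can only circle exon 2
  tx3 <- names(n_ex)[n_ex == 3L]
  if (length(tx3) > 0) {
    c3 <- circs[circs$transcript_id %in% tx3, ]
    expect_true(all(c3$exon_lo == 2L & c3$exon_hi == 2L))
  }
  ## monomer length equals the concatenated exon lengths and passes min_len
  expect_true(all(circs$len >= 100L))
  expect_equal(circs$len, nchar(circs$monomer))
  ## a high min_len filters short candidates
  circs_hi <- simulate_circs(sg, min_len = 400L, seed = 411)
  expect_true(all(circs_hi$len >= 400L))
  expect_lt(nrow(circs_hi), nrow(circs))
})

test_that("the two-circle fraction behaves binomially", {
  model <- test_model()
  sg <- make_genome(n_genes = 60L, model = model, n_chrom = 2L, seed = 421)
  circs <- simulate_circs(sg, frac_two_circ = 0.3, seed = 422)
  per_tx <- table(circs$transcript_id)
  n_two <- sum(per_tx == 2L)
  n_elig <- length(per_tx)
  ## binomial tolerance: +- 4 sd around 0.3 * n (second draws can fail the
  ## distinctness retry or the length filter, so allow the low side)
  expect_lt(n_two, 0.3 * n_elig + 4 * sqrt(n_elig * 0.3 * 0.7))
  expect_gt(n_two, 0.3 * n_elig - 4 * sqrt(n_elig * 0.3 * 0.7))
})

test_that("simulated circle reads cross the junction and match the truth counts", {
  sg <- test_genome()
  circs <- simulate_circs(sg, seed = 431)
  sim <- simulate_reads(sg, circs, "SE", read_len = 100, n_reads_each = 20,
                        seed = 432)
  ## truth counts equal emitted counts (Methods: 20 reads each)
  expect_true(all(sim$truth$circ$n_reads == 20L))
  circ_ids <- sub("^circ\\|([^|]+)\\|.*$", "\\1",
                  grep("^circ\\|", names(sim$reads), value = TRUE))
  expect_equal(as.integer(table(circ_ids)[circs$circ_id]),
               sim$truth$circ$n_reads, ignore_attr = TRUE)
  ## record count = sum of truth counts
  expect_equal(length(sim$reads),
               sum(sim$truth$circ$n_reads) + sum(sim$truth$linear$n_reads))
  ## exhaustive post-check: every circ read occurs in the doubled monomer
  ## across the seam with at least 4 nt on both sides
  for (i in seq_len(nrow(circs))) {
    cc <- circs[i, ]
    rds <- sim$reads[grep(paste0("circ[|]", cc$circ_id, "[|]"),
                          names(sim$reads))]
    dbl <- paste0(cc$monomer, cc$monomer)
    for (rd in rds) {
      p <- as.integer(regexpr(rd, dbl, fixed = TRUE)) - 1L
      expect_gte(p, 0L)
      expect_lte(p, cc$len - 4L)
      expect_gte(p + nchar(rd), cc$len + 4L)
    }
  }
  ## determinism
  sim2 <- simulate_reads(sg, circs, "SE", read_len = 100, n_reads_each = 20,
                         seed = 432)
  expect_identical(sim$reads, sim2$reads)
})

test_that("paired-end inserts span the junction and mates are reverse mates", {
  sg <- test_genome()
  circs <- simulate_circs(sg, seed = 441)
  sim <- simulate_reads(sg, circs[1:3, ], mode = "PE", read_len = 80,
                        n_reads_each = 10, insert_mean = 150, insert_sd = 30,
                        seed = 442, include_linear = FALSE)
  expect_equal(length(sim$mate1), length(sim$mate2))
  expect_gt(length(sim$mate1), 0)
  for (i in seq_along(sim$mate1)) {
    id <- names(sim$mate1)[i]
    cc <- circs[circs$circ_id == sub("^circ\\|([^|]+)\\|.*$", "\\1", id), ]
    dbl <- paste0(cc$monomer, cc$monomer)
    ## enumerate all placements of both mates (a mate lying inside one
    ## monomer copy also matches at its image) and require a consistent
    ## insert placement spanning the seam with 4 nt margins
    all_pos <- function(s) {
      as.integer(gregexpr(s, dbl, fixed = TRUE)[[1]]) - 1L
    }
    p1s <- all_pos(sim$mate1[i])
    p2s <- all_pos(revcomp(sim$mate2[i]))
    spanning <- any(vapply(p1s, function(p1) {
      any(p2s >= p1 & p1 <= cc$len - 4L & p2s + 80L >= cc$len + 4L)
    }, logical(1)))
    expect_true(all(p1s >= 0L) && all(p2s >= 0L))
    expect_true(spanning)
  }
})

test_that("fusion events obey the reciprocal exon-range construction", {
  sg <- test_genome()
  fus <- simulate_fusions(sg, n_events = 5L, reads_per_junction = 10L,
                          read_len = 100L, seed = 451)
  ## 2 junctions per event
  expect_equal(nrow(fus$junctions), 10L)
  expect_equal(unname(table(fus$junctions$event)), rep(2L, 5),
               ignore_attr = TRUE)
  ## i <= j and m <= n
  expect_true(all(fus$events$exon_i <= fus$events$exon_j))
  expect_true(all(fus$events$exon_m <= fus$events$exon_n))
  ## junctions connect different chromosomes
  expect_true(all(fus$junctions$donor_chrom != fus$junctions$acceptor_chrom))
  ## reads realign across the constructed joint: both flanks exact
  for (ev in fus$events$event) {
    ex_a <- circpipe:::exon_range_seq(
      sg, paste0(fus$events$gene_A[ev], ".t1"),
      fus$events$exon_i[ev], fus$events$exon_j[ev])
    ex_b <- circpipe:::exon_range_seq(
      sg, paste0(fus$events$gene_B[ev], ".t1"),
      fus$events$exon_m[ev], fus$events$exon_n[ev])
    circle <- paste0(ex_a$seq, ex_b$seq)
    dbl <- paste0(circle, circle)
    rds <- fus$reads[grep(sprintf("fusJ[|]%d[|]", ev), names(fus$reads))]
    expect_equal(length(rds), 20L)
    expect_true(all(vapply(rds, function(r) grepl(r, dbl, fixed = TRUE),
                           logical(1))))
  }
  ## reads per junction match the truth table
  expect_true(all(fus$junctions$n_reads == 10L))
  ## determinism
  fus2 <- simulate_fusions(sg, n_events = 5L, reads_per_junction = 10L,
                           read_len = 100L, seed = 451)
  expect_identical(fus$reads, fus2$reads)
})

test_that("benchmark files round-trip through the package readers", {
  sg <- test_genome()
  circs <- simulate_circs(sg, seed = 461)
  sim <- simulate_reads(sg, circs[1:2, ], "SE", read_len = 100,
                        n_reads_each = 5, seed = 462, include_linear = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_benchmark(sg, sim, dir = dir)
  back_g <- Biostrings::readDNAStringSet(paths$genome)
  expect_equal(as.character(back_g), as.character(sg$genome),
               ignore_attr = TRUE)
  back_r <- read_fastq(paths$fastq)
  expect_equal(unname(back_r), unname(sim$reads))
  expect_equal(names(back_r), names(sim$reads))
})
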