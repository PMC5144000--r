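make_segs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(read_id = r$id, chrom = r$chrom, strand = r$strand,
               read_start = r$q[1], read_end = r$q[2],
               ref_start = r$g[1], ref_end = r$g[2],
               read_len = r$rl, mapq = 60L, edit_distance = 0L)
  }))
}

test_that("candidate selection recognizes back-splice geometry only", {
  cfg <- caller_config()
  ## canonical: first 50 nt -> chr1:2000-2050, last 50 nt -> chr1:1000-1050
  chim <- make_segs(
    list(id = "r1", chrom = "chr1", strand = "+", q = c(0, 50),
         g = c(2000, 2050), rl = 100),
    list(id = "r1", chrom = "chr1", strand = "+", q = c(50, 100),
         g = c(1000, 1050), rl = 100)
  )
  cands <- select_bsj_candidates(chim, cfg)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$geometry, "bsj")

  ## collinear order (second segment downstream) is linear splicing
  chim$ref_start[2] <- 3000; chim$ref_end[2] <- 3050
  expect_equal(nrow(select_bsj_candidates(chim, cfg)), 0L)

  ## strand-discordant split on one chromosome is examined as fusion
  chim$strand[2] <- "-"
  cands <- select_bsj_candidates(chim, cfg)
  expect_equal(cands$geometry, "fusion")

  ## different chromosomes: fusion
  chim$strand[2] <- "+"; chim$chrom[2] <- "chr2"
  expect_equal(select_bsj_candidates(chim, cfg)$geometry, "fusion")

  ## same chromosome, same strand, collinear but very distant: fusion routing
  chim$chrom[2] <- "chr1"; chim$ref_start[2] <- 5e6; chim$ref_end[2] <- 5e6 + 50
  expect_equal(select_bsj_candidates(chim, cfg)$geometry, "fusion")

  ## short segments are filtered
  chim2 <- make_segs(
    list(id = "r2", chrom = "chr1", strand = "+", q = c(0, 10),
         g = c(2000, 2010), rl = 100),
    list(id = "r2", chrom = "chr1", strand = "+", q = c(10, 100),
         g = c(1000, 1090), rl = 100)
  )
  expect_equal(nrow(select_bsj_candidates(chim2, cfg)), 0L)
})

test_that("three-segment reads enumerate all qualifying pairs", {
  ## relax coverage so any ordered pair can qualify
  cfg <- caller_config(min_read_coverage = 0.5, min_segment = 15)
  chim <- make_segs(
    list(id = "r3", chrom = "chr1", strand = "+", q = c(0, 40),
         g = c(5000, 5040), rl = 120),
    list(id = "r3", chrom = "chr1", strand = "+", q = c(40, 80),
         g = c(3000, 3040), rl = 120),
    list(id = "r3", chrom = "chr1", strand = "+", q = c(80, 120),
         g = c(1000, 1040), rl = 120)
  )
  cands <- select_bsj_candidates(chim, cfg)
  ## brute-force oracle: ordered pairs with earlier read part first,
  ## coverage >= 0.5 * 120, inverted genomic order
  brute <- 0L
  for (a in 1:3) for (b in 1:3) {
    if (chim$read_start[a] >= chim$read_start[b]) next
    if (chim$read_start[b] > chim$read_end[a]) next
    cov <- max(chim$read_end[a], chim$read_end[b]) - chim$read_start[a]
    if (cov / 120 < 0.5) next
    if (chim$ref_start[b] < chim$ref_start[a]) brute <- brute + 1L
  }
  expect_equal(nrow(cands), brute)
  expect_gt(nrow(cands), 1L)
})

test_that("breakpoint resolution matches exhaustive enumeration with planted sites", {
  model <- test_model()
  sg <- test_genome()
  cfg <- caller_config()
  circs <- simulate_circs(sg, seed = 201)
  sim <- simulate_reads(sg, circs, "SE", read_len = 100, n_reads_each = 3,
                        seed = 202)
  reads <- collapse_reads(unname(sim$reads))
  pools <- split_chimeric(parse_sam_segments(
    naive_align_chimeric(reads, sg$genome)))
  cands <- select_bsj_candidates(pools$chimeric, cfg)
  expect_gt(nrow(cands), 10)
  n_checked <- 0L
  for (i in seq_len(nrow(cands))) {
    got <- resolve_breakpoint(cands[i, , drop = FALSE], sg$genome, model, cfg)
    want <- oracle_resolve(cands[i, , drop = FALSE], sg$genome, model, cfg)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$partition, want$t)
      expect_equal(got$total, want$total, tolerance = 1e-9)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10)
})

test_that("resolution rejects junctions below the threshold and honors unique partitions", {
  model <- test_model()
  sg <- test_genome()
  ## a candidate at random (unplanted) positions scores below threshold
  cand <- data.frame(read_id = "rX", read_len = 100L, geometry = "bsj",
                     chrom1 = "chr1", strand1 = "+",
                     read_start1 = 0L, read_end1 = 50L,
                     ref_start1 = 3333L, ref_end1 = 3383L,
                     chrom2 = "chr1", strand2 = "+",
                     read_start2 = 50L, read_end2 = 100L,
                     ref_start2 = 2222L, ref_end2 = 2272L)
  expect_null(resolve_breakpoint(cand, sg$genome, model))
  ## an unattainable threshold rejects even planted junctions
  circs <- simulate_circs(sg, seed = 211)
  sim <- simulate_reads(sg, circs[1, ], "SE", read_len = 100,
                        n_reads_each = 5, seed = 212)
  reads <- collapse_reads(unname(sim$reads))
  pools <- split_chimeric(parse_sam_segments(
    naive_align_chimeric(reads, sg$genome)))
  cands <- select_bsj_candidates(pools$chimeric)
  strict <- caller_config(threshold = 1000)
  for (i in seq_len(nrow(cands))) {
    expect_null(resolve_breakpoint(cands[i, , drop = FALSE], sg$genome,
                                   model, strict))
  }
  ## zero-ambiguity candidate: the unique partition is returned unchanged
  zero <- cands[cands$read_end1 == cands$read_start2, ]
  if (nrow(zero) > 0) {
    r <- resolve_breakpoint(zero[1, , drop = FALSE], sg$genome, model)
    expect_equal(r$partition, zero$read_end1[1])
  }
})

test_that("per-junction aggregation sums pair weights times collapse counts", {
  mk <- function(id, support) {
    data.frame(read_id = id, geometry = "bsj", chrom = "chr1", strand = "+",
               start = 1000L, end = 1400L, donor_score = 6, acceptor_score = 7,
               total = 13, partition = 50L, support = support)
  }
  agg <- aggregate_calls(list(mk("a", 2), mk("b", 1), mk("c", 1)))
  expect_equal(agg$support, 4)
  expect_equal(agg$n_reads, 3L)
  ## merged pair (1.0) + one split mate (0.5)
  agg <- aggregate_calls(list(mk("a", 1.0), mk("b", 0.5)))
  expect_equal(agg$support, 1.5)

  ## random group-by oracle
  withr::with_seed(221, {
    calls <- lapply(1:50, function(i) {
      d <- mk(paste0("r", i), sample(c(0.5, 1, 2), 1))
      d$start <- sample(c(1000L, 2000L, 3000L), 1)
      d$end <- d$start + 400L
      d
    })
  })
  agg <- aggregate_calls(calls)
  df <- do.call(rbind, calls)
  want <- tapply(df$support, df$start, sum)
  expect_equal(agg$support, as.numeric(want[as.character(agg$start)]),
               ignore_attr = TRUE)
  ## deterministic output order
  expect_equal(agg$start, sort(agg$start))
})

test_that("reciprocal fusion junctions pair into fusion circRNAs", {
  jx <- function(id, dch, dst, dp, ach, ast, ap) {
    data.frame(junction_id = id, donor_chrom = dch, donor_strand = dst,
               donor_pos = dp, acceptor_chrom = ach, acceptor_strand = ast,
               acceptor_pos = ap, donor_score = 7, acceptor_score = 8,
               total = 15, support = 10, n_reads = 10L)
  }
  ## A_j (chrA:5000) -> B_m (chrB:2000); B_n (chrB:3000) -> A_i (chrA:4000)
  j1 <- jx("fusj_0001", "chrA", "+", 5000L, "chrB", "+", 2000L)
  j2 <- jx("fusj_0002", "chrB", "+", 3000L, "chrA", "+", 4000L)
  fc <- pair_fusion_circs(rbind(j1, j2))
  expect_equal(nrow(fc), 1L)
  expect_equal(fc$A_start, 4000L)
  expect_equal(fc$A_end, 5000L)
  expect_equal(fc$B_start, 2000L)
  expect_equal(fc$B_end, 3000L)
  expect_false(fc$multi_pairing)

  ## a lone junction suggests a linear fusion transcript, not a circle
  expect_equal(nrow(pair_fusion_circs(j1)), 0L)

  ## ordering violated (i > j): acceptor on A downstream of the donor
  j2bad <- jx("fusj_0002", "chrB", "+", 3000L, "chrA", "+", 6000L)
  expect_equal(nrow(pair_fusion_circs(rbind(j1, j2bad))), 0L)

  ## span cap
  j2far <- jx("fusj_0002", "chrB", "+", 3000L, "chrA", "+", 5000L - 2e6)
  expect_equal(nrow(pair_fusion_circs(rbind(j1, j2far))), 0L)
})

test_that("every reported call clears the splice-strength threshold", {
  model <- test_model()
  sg <- test_genome()
  circs <- simulate_circs(sg, seed = 231)
  sim <- simulate_reads(sg, circs, "SE", read_len = 100, n_reads_each = 5,
                        seed = 232)
  fus <- simulate_fusions(sg, n_events = 3, reads_per_junction = 5,
                          read_len = 100, seed = 233)
  reads <- collapse_reads(unname(c(sim$reads, fus$reads)))
  pools <- split_chimeric(parse_sam_segments(
    naive_align_chimeric(reads, sg$genome)))
  called <- call_junctions(pools$chimeric, reads, sg$genome, model)
  expect_true(all(called$circs$total >= 10))
  expect_true(all(called$fusions$total >= 10))
  ## and the fusion truth junctions are recovered
  expect_true(all(fusion_key(fus$junctions) %in% fusion_key(called$fusions)))
})
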