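test_that("diagnostic index k-mer sets are type-exclusive by construction", {
  idx <- canonical_index()
  setF <- unlist(idx$kmers[idx$regions$mitotype == "F"], use.names = FALSE)
  setM <- unlist(idx$kmers[idx$regions$mitotype == "M"], use.names = FALSE)
  expect_length(intersect(setF, setM), 0)
  expect_true(all(lengths(idx$kmers) > 0))

  pair <- canonical_pair()
  # brute-force check: no F-diagnostic k-mer occurs anywhere in the M genome
  gM <- pair$genomeM$sequence
  doubledM <- paste0(gM, substr(gM, 1, idx$k - 1))
  rcM <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(doubledM)))
  hitsM <- vapply(setF, function(km) {
    grepl(km, doubledM, fixed = TRUE) || grepl(km, rcM, fixed = TRUE)
  }, logical(1))
  expect_false(any(hitsM))

  # M k-mers spanning the 16S insertion are absent from the F genome
  ins <- pair$event_log[pair$event_log$type == "insertion" &
                          pair$event_log$feature == "16S", ]
  span <- substr(gM, ins$pos_M - 5, ins$pos_M + 35)
  expect_false(grepl(span, pair$genomeF$sequence, fixed = TRUE))
})

test_that("identical genomes leave the index empty and short regions are rejected", {
  null_pair <- generate_lineage_pair(
    synth_config(seed = 3, divergence_target = 0, structural_events = FALSE)
  )
  regions <- tibble::tibble(mitotype = c("F", "M"), name = "r",
                            start = 100L, end = 400L)
  expect_warning(idx <- build_diagnostic_index(null_pair, regions),
                 "empty")
  expect_true(all(lengths(idx$kmers) == 0))

  pair <- canonical_pair()
  short <- tibble::tibble(mitotype = "F", name = "tiny", start = 1L, end = 20L)
  expect_error(build_diagnostic_index(pair, short, k = 31), "at least k")
  exact_k <- tibble::tibble(mitotype = c("F", "M"), name = "one",
                            start = 8400L, end = 8430L)
  idx1 <- build_diagnostic_index(pair, exact_k, k = 31)
  expect_true(all(lengths(idx1$kmers) <= 1L))
})

test_that("error-free single-mitotype reads never cross-assign", {
  pair <- canonical_pair()
  idx <- canonical_index()
  rs <- simulate_reads(pair, synth_config(seed = 21, coverage = 10,
                                          error_rate = 0, mixture = 1))
  res <- assign_reads(rs, idx)
  f_counts <- res$region_counts[res$region_counts$mitotype == "F", ]
  expect_true(all(f_counts$matching_reads == 0L))
  expect_false(any(res$assignments$mitotype == "F"))
  expect_identical(call_homoplasmy(res$region_counts), "homoplasmic_M")
})

test_that("per-100-bases normalization and edge cases behave", {
  counts <- tibble::tibble(region = "r", mitotype = "M",
                           region_length = 300L, matching_reads = 45L,
                           per_100_bases = 45 * 100 / 300)
  expect_equal(counts$per_100_bases, 15)

  idx <- canonical_index()
  empty <- assign_reads(tibble::tibble(id = character(0), sequence = character(0)),
                        idx)
  expect_true(all(empty$region_counts$matching_reads == 0L))
  expect_identical(call_homoplasmy(empty$region_counts), "insufficient")

  shorties <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "AC"))
  res <- assign_reads(shorties, idx)
  expect_identical(res$n_too_short, 2L)

  # homoplasmy thresholds
  mk <- function(f, m) tibble::tibble(region = c("x", "y"),
                                      mitotype = c("F", "M"),
                                      region_length = 300L,
                                      matching_reads = c(f, m),
                                      per_100_bases = c(f, m) / 3)
  expect_identical(call_homoplasmy(mk(1000L, 0L)), "homoplasmic_F")
  expect_identical(call_homoplasmy(mk(200L, 20L)), "heteroplasmic")
  expect_identical(call_homoplasmy(mk(2L, 3L)), "insufficient")
})

test_that("M-assigned coverage rises monotonically with the M mixture fraction", {
  pair <- canonical_pair()
  idx <- canonical_index()
  per100 <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(mix) {
    rs <- simulate_reads(pair, synth_config(seed = 22, coverage = 8,
                                            error_rate = 0, mixture = mix))
    rc <- assign_reads(rs, idx)$region_counts
    sum(rc$per_100_bases[rc$mitotype == "M"])
  }, 0)
  expect_true(all(diff(per100) >= 0))
  expect_identical(per100[1], 0)
})

test_that("reads covering a diagnostic region are recovered at realistic error rates", {
  pair <- canonical_pair()
  idx <- canonical_index()
  k <- idx$k
  rs <- simulate_reads(pair, synth_config(seed = 23, coverage = 15,
                                          error_rate = 0.005, mixture = 1))
  res <- assign_reads(rs, idx)
  # ground truth: reads overlapping an M diagnostic region by >= k+1 bases
  regsM <- idx$regions[idx$regions$mitotype == "M", ]
  # recover read origins from an error-free re-simulation at the same seed
  # (start positions are drawn before errors, so they coincide)
  rs0 <- simulate_reads(pair, synth_config(seed = 23, coverage = 15,
                                           error_rate = 0, mixture = 1))
  LM <- nchar(pair$genomeM$sequence)
  doubled <- paste0(pair$genomeM$sequence, pair$genomeM$sequence)
  read_start <- vapply(rs0$reads$sequence, function(s) {
    as.integer(regexpr(s, doubled, fixed = TRUE))
  }, 1L)
  rl <- rs0$read_length
  overlaps <- vapply(read_start, function(s) {
    any(vapply(seq_len(nrow(regsM)), function(j) {
      a <- max(s, regsM$start[j]); b <- min(s + rl - 1L, regsM$end[j])
      wrap_a <- max(s, regsM$start[j] + LM); wrap_b <- min(s + rl - 1L, regsM$end[j] + LM)
      (b - a + 1L) >= k + 1L || (wrap_b - wrap_a + 1L) >= k + 1L
    }, logical(1)))
  }, logical(1))
  eligible <- which(overlaps)
  assigned_m <- res$assignments$mitotype[eligible] == "M"
  expect_gte(mean(assigned_m), 0.95)
})
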