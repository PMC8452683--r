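test_that("primer site search handles exact hits, both strands and the origin", {
  withr::with_seed(8, {
    g <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  })
  primer <- substr(g, 101, 120)
  hits <- find_primer_sites(g, primer, max_mismatch = 0)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$position, 101L)
  expect_identical(plus$mismatches, 0L)

  # the same site is found on the minus strand by its reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  minus <- find_primer_sites(g, rc, max_mismatch = 0)
  minus <- minus[minus$strand == "-", ]
  expect_identical(minus$position, 120L)

  # a primer spanning the circular origin is still found
  wrap <- paste0(substr(g, 291, 300), substr(g, 1, 10))
  whits <- find_primer_sites(g, wrap, max_mismatch = 0)
  expect_true(291L %in% whits$position[whits$strand == "+"])
})

test_that("the 3' clamp vetoes otherwise-tolerated mismatches", {
  withr::with_seed(9, {
    g <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  })
  primer <- substr(g, 51, 70)
  ch <- strsplit(primer, "")[[1]]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]   # 3'-terminal mismatch
  clamped <- paste(ch, collapse = "")
  hits <- find_primer_sites(g, clamped, max_mismatch = 2, clamp = 3)
  expect_false(51L %in% hits$position[hits$strand == "+"])
  # same mismatch outside the clamp is tolerated
  ch2 <- strsplit(primer, "")[[1]]
  ch2[5] <- setdiff(c("A", "C", "G", "T"), ch2[5])[1]
  hits2 <- find_primer_sites(g, paste(ch2, collapse = ""), max_mismatch = 2, clamp = 3)
  expect_true(51L %in% hits2$position[hits2$strand == "+"])
})

test_that("amplification uses circular arithmetic and inclusive footprints", {
  withr::with_seed(10, {
    g <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  })
  # forward 5' end at 90, reverse 5' end at 9: 20-bp product across the origin
  fwd <- paste0(substr(g, 90, 100), substr(g, 1, 4))       # 15-mer at 90
  rev_site <- paste0(substr(g, 95, 100), substr(g, 1, 9))  # 15-mer ending at 9
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_site)))
  pp <- primer_pair("p", "test", fwd, rev, max_mismatch = 0)
  amp <- amplify(g, pp)
  expect_identical(amp$length, 20L)
  expect_identical(amp$start, 90L)
  expect_identical(amp$end, 9L)
  expect_identical(amp$sequence, paste0(substr(g, 90, 100), substr(g, 1, 9)))

  # no reverse site means no product
  norev <- primer_pair("p2", "test", fwd, strrep("A", 20), max_mismatch = 0)
  expect_identical(nrow(amplify(g, norev)), 0L)
})

test_that("amplicon sizes are invariant under genome rotation", {
  pair <- canonical_pair()
  des <- canonical_assay()
  g <- pair$genomeF$sequence
  base <- vapply(des$primers, function(p) {
    a <- amplify(g, p); if (nrow(a)) a$length[1] else NA_integer_
  }, 1L)
  for (off in c(1000L, 9000L, 17000L)) {
    rot <- paste0(substr(g, off + 1, nchar(g)), substr(g, 1, off))
    rotated <- vapply(des$primers, function(p) {
      a <- amplify(rot, p); if (nrow(a)) a$length[1] else NA_integer_
    }, 1L)
    expect_identical(rotated, base)
  }
})

test_that("the designed 16S amplicons differ by exactly the indel length", {
  pair <- canonical_pair()
  des <- canonical_assay()
  ampF <- amplify(pair$genomeF, des$primers$p16S)
  ampM <- amplify(pair$genomeM, des$primers$p16S)
  expect_identical(ampM$length - ampF$length, 127L)
})

test_that("band patterns classify into F, M, HET and FAIL", {
  def <- assay_def(tibble::tibble(
    locus = c("cytb", "cytb", "16S", "16S"),
    mitotype = c("F", "M", "F", "M"),
    size = c(301, 212, 377, 503)
  ), tolerance = 5)

  bandsF <- tibble::tibble(locus = c("cytb", "16S"), size = c(301, 377))
  expect_identical(classify_multiplex(bandsF, def)$call, "F")
  bandsM <- tibble::tibble(locus = c("cytb", "16S"), size = c(212, 503))
  expect_identical(classify_multiplex(bandsM, def)$call, "M")
  het <- tibble::tibble(locus = c("cytb", "cytb", "16S", "16S"),
                        size = c(301, 212, 377, 503))
  expect_identical(classify_multiplex(het, def)$call, "HET")
  expect_identical(classify_multiplex(tibble::tibble(locus = character(0),
                                                     size = numeric(0)),
                                      def)$call, "FAIL")
  # single interpretable locus is enough; sizes within tolerance still match
  one <- tibble::tibble(locus = "16S", size = 379)
  expect_identical(classify_multiplex(one, def)$call, "F")

  expect_error(assay_def(tibble::tibble(locus = "cytb", mitotype = c("F", "M"),
                                        size = c(300, 305)), tolerance = 5),
               "overlap")
})

test_that("multiplex calls recover the true mitotype for 200 simulated individuals", {
  pair <- canonical_pair()
  des <- canonical_assay()
  withr::with_seed(12, {
    truth <- sample(c("F", "M"), 200, replace = TRUE)
  })
  calls <- vapply(seq_along(truth), function(i) {
    g <- if (truth[i] == "F") pair$genomeF else pair$genomeM
    run_multiplex(g, des$primers, des$def, sample_id = paste0("ind", i))$call
  }, "")
  expect_identical(calls, truth)

  # a heteroplasmic template mixture shows both band sets
  expect_identical(
    run_multiplex(list(pair$genomeF, pair$genomeM), des$primers, des$def)$call,
    "HET"
  )
})
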