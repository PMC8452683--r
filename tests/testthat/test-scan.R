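test_that("fixed-difference columns follow the set-disjointness rule", {
  aln <- group_alignment(c("ACGTA", "ACGTA", "ATGTC", "AGGTC"),
                         c("F", "F", "M", "M"))
  expect_identical(fixed_difference_columns(aln), c(2L, 5L))

  # identical rows in both groups
  same <- group_alignment(c("ACGT", "ACGT"), c("F", "M"))
  expect_identical(fixed_difference_columns(same), integer(0))

  # gap counts as a fifth state
  gap <- group_alignment(c("A-GT", "AAGT"), c("F", "M"))
  expect_identical(fixed_difference_columns(gap), 2L)

  # a shared state in one group blocks the call (M={A,G} vs F={A})
  shared <- group_alignment(c("A", "A", "G"), c("F", "M", "M"))
  expect_identical(fixed_difference_columns(shared), integer(0))

  expect_error(group_alignment(c("ACGT", "ACRT"), c("F", "M")), "ambiguity")
  expect_error(group_alignment(c("ACGT", "ACGT"), c("F", "F")), "at least one row")
})

test_that("scanner agrees with the brute-force oracle on random alignments", {
  withr::with_seed(11, {
    for (i in 1:25) {
      n_rows <- sample(2:10, 1)
      n_cols <- sample(20:200, 1)
      aln <- random_gapped_alignment(n_rows, n_cols)
      expect_identical(fixed_difference_columns(aln),
                       oracle_fixed_differences(aln$rows, aln$labels))
    }
  })
})

test_that("sliding-window profile counts divergent columns per window", {
  prof <- sliding_window_profile(c(3, 8), 10, window = 4, step = 1)
  expect_identical(prof$counts, c(1L, 1L, 1L, 0L, 1L, 1L, 1L))

  expect_identical(sliding_window_profile(integer(0), 50, window = 10)$counts,
                   rep(0L, 41))
  allpos <- sliding_window_profile(1:30, 30, window = 7)$counts
  expect_true(all(allpos == 7L))
  expect_error(sliding_window_profile(c(1), 5, window = 10), "window exceeds")
})

test_that("profile conserves total window-coverage multiplicity", {
  withr::with_seed(21, {
    for (i in 1:10) {
      L <- sample(50:400, 1)
      w <- sample(2:20, 1)
      pos <- sort(sample(L, sample(0:30, 1)))
      prof <- sliding_window_profile(pos, L, window = w, step = 1)
      # each divergent column is counted once per window covering it
      multiplicity <- vapply(pos, function(p) {
        sum(prof$starts <= p & prof$starts + w - 1L >= p)
      }, 0L)
      expect_identical(sum(prof$counts), sum(multiplicity))
      expect_true(all(prof$counts >= 0L & prof$counts <= w))
    }
  })
})

test_that("p-distance uses pairwise deletion and bootstraps its SE", {
  expect_equal(p_distance("ACGT", "ACGA", bootstrap_reps = 0)$distance, 0.25)

  same <- p_distance("ACGT", "ACGT", bootstrap_reps = 50, seed = 1)
  expect_equal(same$distance, 0)
  expect_equal(same$se, 0)

  gapped <- p_distance("AC-T", "ACGT", bootstrap_reps = 0)
  expect_equal(gapped$distance, 0)
  expect_identical(gapped$n_sites, 3L)

  expect_error(p_distance("---", "AAA", bootstrap_reps = 0), "zero comparable")
  expect_error(p_distance("ACG", "AC", bootstrap_reps = 0), "equal gapped length")
})

test_that("p-distance is symmetric, bounded, and its bootstrap SE shrinks with length", {
  withr::with_seed(31, {
    for (i in 1:10) {
      L <- sample(20:100, 1)
      a <- paste(sample(c("A", "C", "G", "T", "-"), L, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T", "-"), L, TRUE), collapse = "")
      ab <- tryCatch(p_distance(a, b, bootstrap_reps = 0), error = function(e) NULL)
      if (is.null(ab)) next
      ba <- p_distance(b, a, bootstrap_reps = 0)
      expect_identical(ab$distance, ba$distance)
      expect_gte(ab$distance, 0); expect_lte(ab$distance, 1)
    }
  })

  # fixed 5% divergence, growing length: SE trend is monotone decreasing
  se_at <- function(L) {
    withr::with_seed(7, {
      a <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      ch <- strsplit(a, "")[[1]]
      flip <- sample(L, round(0.05 * L))
      ch[flip] <- vapply(ch[flip], function(x) setdiff(c("A", "C", "G", "T"), x)[1], "")
      p_distance(a, paste(ch, collapse = ""), bootstrap_reps = 200, seed = 3)$se
    })
  }
  ses <- vapply(c(1000, 10000, 100000), se_at, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("indel locator reports maximal runs with carrier and feature", {
  rec <- locate_indels(c(F = "A--T", M = "AGGT"))
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$aln_start, 2L)
  expect_identical(rec$length, 2L)
  expect_identical(rec$carrier, "M")

  expect_identical(nrow(locate_indels(c(F = "ACGT", M = "ACGT"))), 0L)

  both <- locate_indels(c(F = "A--TAC", M = "AGGT-C"))
  expect_identical(both$carrier, c("M", "F"))
  expect_identical(both$length, c(2L, 1L))

  pair <- canonical_pair()
  recs <- locate_indels(pair)
  in16S <- recs[recs$feature == "16S", ]
  expect_identical(nrow(in16S), 1L)
  expect_identical(in16S$length, 127L)
  expect_identical(in16S$carrier, "M")
})

test_that("per-feature divergence ranks hotspots over conserved genes and partitions the total", {
  pair <- canonical_pair()
  tab <- per_feature_divergence(pair)
  p_of <- function(nm) tab$p_distance[tab$feature == nm]
  expect_lt(p_of("cox2"), p_of("cytb"))
  expect_lt(p_of("12S"), p_of("16S"))

  # fixed differences partition the genome-wide two-sequence count
  aln <- group_alignment(c(pair$alignment$F, pair$alignment$M), c("F", "M"))
  expect_identical(sum(tab$fixed_differences),
                   length(fixed_difference_columns(aln)))

  null_pair <- generate_lineage_pair(
    synth_config(seed = 2, divergence_target = 0, structural_events = FALSE)
  )
  null_tab <- per_feature_divergence(null_pair)
  expect_true(all(null_tab$p_distance == 0))
  expect_true(all(null_tab$fixed_differences == 0L))
})

test_that("group alignments round-trip through FASTA plus label table", {
  pair <- canonical_pair()
  fa <- withr::local_tempfile(fileext = ".fasta")
  gr <- withr::local_tempfile(fileext = ".tsv")
  x <- Biostrings::DNAStringSet(c(f1 = pair$alignment$F, m1 = pair$alignment$M))
  Biostrings::writeXStringSet(x, fa)
  writeLines(c("f1\tF", "m1\tM"), gr)
  aln <- read_group_alignment(fa, gr)
  expect_identical(aln$labels, c("F", "M"))
  expect_identical(aln$rows[1], pair$alignment$F)
})
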