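# Shared fixtures, built once per test run. The canonical pair is the
# default-configuration lineage pair at seed 1.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

canonical_config <- function() synth_config(seed = 1)

canonical_pair <- function() {
  cached("pair1", function() generate_lineage_pair(canonical_config()))
}

canonical_assay <- function() {
  cached("assay1", function() design_assay_primers(canonical_pair()))
}

canonical_index <- function() {
  cached("index1", function() build_diagnostic_index(canonical_pair()))
}

# independent brute-force oracle for the fixed-difference rule:
# per column, compare every M state against every F state
oracle_fixed_differences <- function(rows, labels) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  out <- integer(0)
  for (j in seq_len(ncol(mat))) {
    statesF <- mat[labels == "F", j]
    statesM <- mat[labels == "M", j]
    all_diff <- TRUE
    for (sm in statesM) for (sf in statesF) {
      if (sm == sf) all_diff <- FALSE
    }
    if (all_diff) out <- c(out, j)
  }
  out
}

random_gapped_alignment <- function(n_rows, n_cols, gap_prob = 0.1) {
  rows <- vapply(seq_len(n_rows), function(i) {
    paste(sample(c("A", "C", "G", "T", "-"), n_cols, replace = TRUE,
                 prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)),
          collapse = "")
  }, "")
  labels <- c("F", "M", sample(c("F", "M"), n_rows - 2L, replace = TRUE))
  group_alignment(rows, labels)
}
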