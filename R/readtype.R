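kmers_of <- function(seq, k, circular = FALSE) {
  L <- nchar(seq)
  if (circular && L >= k) seq <- paste0(seq, substr(seq, 1L, k - 1L))
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, 1:n, k:(n + k - 1L))
}

# canonical (strand-collapsed) k-mers: lexicographic min of k-mer and its
# reverse complement; the rc k-mers of seq are the reversed k-mer list of
# rc(seq), so one reverseComplement call serves the whole sequence
canonical_kmers <- function(seq, k, circular = FALSE) {
  fwd <- kmers_of(seq, k, circular)
  if (length(fwd) == 0L) return(character(0))
  rc <- rev(kmers_of(revcomp(seq), k, circular))
  pmin(fwd, rc)
}

#' Build a mitotype-diagnostic k-mer index
#'
#' For each declared region, collects the canonical (strand-collapsed)
#' k-mers of that region on its own genome and removes every k-mer that
#' occurs anywhere in the other mitotype's genome (both strands, across the
#' circular origin). The resulting per-region sets are unique to one
#' mitotype by construction; any k-mer still shared between the pooled F and
#' M sets is dropped from both.
#'
#' @param pair A `lineage_pair`.
#' @param regions Tibble with columns `mitotype` (`"F"`/`"M"`), `name`,
#'   `start`, `end` (1-based inclusive, on that mitotype's genome). Defaults
#'   to [select_diagnostic_regions()] on the pair.
#' @param k K-mer size.
#' @return An object of class `diagnostic_index`: list with `k`, `regions`
#'   (with `length` and `n_kmers`) and `kmers` (named list of per-region
#'   character vectors).
#' @export
build_diagnostic_index <- function(pair, regions = NULL, k = 31L) {
  stopifnot(inherits(pair, "lineage_pair"))
  k <- as.integer(k)
  regions <- as_tibble(regions %||% select_diagnostic_regions(pair))
  stopifnot(all(c("mitotype", "name", "start", "end") %in% names(regions)))
  genomes <- list(F = pair$genomeF, M = pair$genomeM)
  if (any(regions$end - regions$start + 1L < k)) {
    abort("every region must be at least k bases long")
  }
  bad <- vapply(seq_len(nrow(regions)), function(i) {
    regions$end[i] > nchar(genomes[[regions$mitotype[i]]]$sequence) ||
      regions$start[i] < 1L
  }, logical(1))
  if (any(bad)) abort("region outside its genome")

  other_all <- list(
    F = unique(canonical_kmers(genomes$M$sequence, k, circular = TRUE)),
    M = unique(canonical_kmers(genomes$F$sequence, k, circular = TRUE))
  )
  sets <- lapply(seq_len(nrow(regions)), function(i) {
    g <- genomes[[regions$mitotype[i]]]
    km <- unique(canonical_kmers(
      substr(g$sequence, regions$start[i], regions$end[i]), k
    ))
    setdiff(km, other_all[[regions$mitotype[i]]])
  })
  names(sets) <- paste(regions$mitotype, regions$name, sep = ":")
  shared <- intersect(
    unlist(sets[regions$mitotype == "F"], use.names = FALSE),
    unlist(sets[regions$mitotype == "M"], use.names = FALSE)
  )
  if (length(shared) > 0L) sets <- lapply(sets, setdiff, y = shared)
  if (all(lengths(sets) == 0L)) {
    warn("diagnostic index is empty after subtracting shared k-mers")
  }
  regions$length <- regions$end - regions$start + 1L
  regions$n_kmers <- lengths(sets)
  structure(list(k = k, regions = regions, kmers = sets),
            class = "diagnostic_index")
}

#' @export
print.diagnostic_index <- function(x, ...) {
  cat(sprintf("<diagnostic_index> k=%d, %d regions\n", x$k, nrow(x$regions)))
  print(as.data.frame(x$regions))
  invisible(x)
}

#' Select default diagnostic regions from the divergence profile
#'
#' Mirrors the study's choice of mitotype-specific genome regions: ranks
#' sliding windows of the true pairwise alignment by fixed-difference
#' density (the M-lineage 16S insertion ranks first since every inserted
#' column is a fixed difference) and keeps the top non-overlapping windows,
#' projected back onto each genome's own coordinates.
#'
#' @param pair A `lineage_pair`.
#' @param width Window width in alignment columns.
#' @param n_regions Number of distinct windows to keep.
#' @return Region tibble suitable for [build_diagnostic_index()].
#' @export
select_diagnostic_regions <- function(pair, width = 300L, n_regions = 2L) {
  stopifnot(inherits(pair, "lineage_pair"))
  a <- seq_chars(pair$alignment$F)
  b <- seq_chars(pair$alignment$M)
  L <- length(a)
  prof <- sliding_window_profile(which(a != b), L, window = width, step = 1L)
  ord <- order(prof$counts, decreasing = TRUE)
  chosen <- integer(0)
  for (w in prof$starts[ord]) {
    if (length(chosen) >= n_regions) break
    if (all(abs(w - chosen) >= width)) chosen <- c(chosen, w)
  }
  posF <- cumsum(a != "-")
  posM <- cumsum(b != "-")
  dplyr::bind_rows(lapply(seq_along(chosen), function(i) {
    cols <- chosen[i]:(chosen[i] + width - 1L)
    nm <- paste0("diag", i)
    tibble(
      mitotype = c("F", "M"), name = nm,
      start = c(min(posF[cols][a[cols] != "-"]), min(posM[cols][b[cols] != "-"])),
      end = c(max(posF[cols][a[cols] != "-"]), max(posM[cols][b[cols] != "-"]))
    )
  }))
}

#' Assign reads to mitotypes with a diagnostic k-mer index
#'
#' A read matches a region when at least `min_hits` of the read's canonical
#' k-mers belong to that region's diagnostic set. Reads matching regions of
#' both mitotypes are discarded as ambiguous; reads shorter than k are
#' skipped and tallied. Region counts are normalized to matching reads per
#' 100 bases of region length.
#'
#' @param reads A `read_set` from [simulate_reads()], or a tibble with
#'   columns `id` and `sequence`.
#' @param index A [build_diagnostic_index()] result.
#' @param min_hits Minimum diagnostic k-mers required for a region match.
#' @return List with `region_counts` (tibble: `region`, `mitotype`,
#'   `region_length`, `matching_reads`, `per_100_bases`), `assignments`
#'   (per-read tibble: `id`, `mitotype` in F/M/ambiguous/none) and
#'   `n_too_short`.
#' @export
assign_reads <- function(reads, index, min_hits = 2L) {
  stopifnot(inherits(index, "diagnostic_index"))
  tbl <- if (inherits(reads, "read_set")) reads$reads else as_tibble(reads)
  k <- index$k
  region_ids <- names(index$kmers)
  region_mito <- index$regions$mitotype

  n_too_short <- 0L
  hit_counts <- matrix(0L, nrow = nrow(tbl), ncol = length(region_ids),
                       dimnames = list(NULL, region_ids))
  rc_seqs <- if (nrow(tbl) > 0L) revcomp(tbl$sequence) else character(0)
  for (i in seq_len(nrow(tbl))) {
    s <- tbl$sequence[i]
    if (nchar(s) < k) { n_too_short <- n_too_short + 1L; next }
    fwd <- kmers_of(s, k)
    km <- unique(pmin(fwd, rev(kmers_of(rc_seqs[i], k))))
    for (j in seq_along(region_ids)) {
      hit_counts[i, j] <- sum(km %in% index$kmers[[j]])
    }
  }
  matched <- hit_counts >= min_hits
  mito_hit <- vapply(seq_len(nrow(tbl)), function(i) {
    m <- unique(region_mito[matched[i, ]])
    if (nchar(tbl$sequence[i]) < k) NA_character_
    else if (length(m) == 0L) "none"
    else if (length(m) == 1L) m
    else "ambiguous"
  }, "")
  usable <- !is.na(mito_hit) & mito_hit %in% c("F", "M")
  matching_reads <- vapply(seq_along(region_ids), function(j) {
    sum(matched[, j] & usable & mito_hit == region_mito[j])
  }, 0L)
  region_counts <- tibble(
    region = index$regions$name,
    mitotype = region_mito,
    region_length = index$regions$length,
    matching_reads = as.integer(matching_reads),
    per_100_bases = matching_reads * 100 / index$regions$length
  )
  assignments <- tibble(id = tbl$id %||% seq_len(nrow(tbl)), mitotype = mito_hit)
  list(region_counts = region_counts, assignments = assignments,
       n_too_short = n_too_short)
}

#' Call sample-level homoplasmy from region read counts
#'
#' Sums assigned reads per mitotype over all diagnostic regions of one
#' sample: `heteroplasmic` when both mitotypes reach `min_reads`, homoplasmic
#' toward the only mitotype reaching it, `insufficient` otherwise.
#'
#' @param region_counts Tibble from [assign_reads()].
#' @param min_reads Minimum supporting reads per mitotype.
#' @return Character scalar: `"homoplasmic_F"`, `"homoplasmic_M"`,
#'   `"heteroplasmic"` or `"insufficient"`.
#' @export
call_homoplasmy <- function(region_counts, min_reads = 5L) {
  region_counts <- as_tibble(region_counts)
  totF <- sum(region_counts$matching_reads[region_counts$mitotype == "F"])
  totM <- sum(region_counts$matching_reads[region_counts$mitotype == "M"])
  okF <- totF >= min_reads; okM <- totM >= min_reads
  if (okF && okM) "heteroplasmic"
  else if (okF) "homoplasmic_F"
  else if (okM) "homoplasmic_M"
  else "insufficient"
}
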