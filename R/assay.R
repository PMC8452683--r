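#' Primer pair definition
#'
#' @param name Pair label.
#' @param locus Target locus (`"cytb"`, `"16S"`, ...).
#' @param forward,reverse Primer sequences, both written 5'->3' (the reverse
#'   primer anneals to the + strand, i.e. its site on the + strand is its
#'   reverse complement).
#' @param max_mismatch Maximum mismatches tolerated outside the clamp.
#' @param clamp Number of 3'-terminal bases that must match exactly.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, locus, forward, reverse,
                        max_mismatch = 2L, clamp = 3L) {
  assert_dna(c(forward, reverse), "primer")
  lens <- nchar(c(forward, reverse))
  if (any(lens < 15L | lens > 35L)) abort("primer lengths must be 15-35 bases")
  if (clamp > min(lens)) abort("clamp cannot exceed primer length")
  structure(
    list(name = name, locus = locus, forward = forward, reverse = reverse,
         max_mismatch = as.integer(max_mismatch), clamp = as.integer(clamp)),
    class = "primer_pair"
  )
}

# Match one primer on one strand of a (possibly circular) genome.
# Returns 1-based 5'-end positions of the primer on the + strand coordinate
# system, with mismatch counts; enforces the exact 3'-clamp rule.
match_one_strand <- function(seq, primer, strand, max_mismatch, clamp) {
  L <- nchar(seq)
  plen <- nchar(primer)
  subject <- seq
  if (plen > 1L) subject <- paste0(seq, substr(seq, 1L, plen - 1L))  # circular
  pattern <- if (strand == "+") primer else revcomp(primer)
  hits <- Biostrings::matchPattern(
    pattern, Biostrings::DNAString(subject), max.mismatch = max_mismatch
  )
  starts <- Biostrings::start(hits)
  starts <- starts[starts <= L]
  if (length(starts) == 0L) {
    return(tibble(position = integer(0), strand = character(0),
                  mismatches = integer(0)))
  }
  pat_chars <- seq_chars(pattern)
  sub_chars <- seq_chars(subject)
  keep <- logical(length(starts)); mm <- integer(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    site <- sub_chars[s:(s + plen - 1L)]
    diffs <- which(site != pat_chars)
    mm[i] <- length(diffs)
    # clamp = primer 3' end: last bases on +, first bases of the rc site on -
    clamp_idx <- if (strand == "+") (plen - clamp + 1L):plen else 1L:clamp
    keep[i] <- mm[i] <= max_mismatch && !any(diffs %in% clamp_idx)
  }
  starts <- starts[keep]; mm <- mm[keep]
  five_prime <- if (strand == "+") starts else starts + plen - 1L
  five_prime <- ((five_prime - 1L) %% L) + 1L
  tibble(position = as.integer(five_prime), strand = strand, mismatches = mm)
}

#' Find primer annealing sites on a circular genome
#'
#' Scans both strands, across the origin for circular genomes. A site is
#' reported when total mismatches are at most `max_mismatch` and the
#' 3'-terminal `clamp` bases match exactly.
#'
#' @param genome An [annotated_genome()] or a DNA string.
#' @param primer Primer sequence, 5'->3'.
#' @param max_mismatch,clamp Matching tolerance and exact 3' clamp width.
#' @return Tibble: `position` (1-based + strand coordinate of the primer's
#'   5' end), `strand`, `mismatches`.
#' @export
find_primer_sites <- function(genome, primer, max_mismatch = 2L, clamp = 3L) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  assert_dna(primer, "primer")
  dplyr::bind_rows(
    match_one_strand(seq, primer, "+", max_mismatch, clamp),
    match_one_strand(seq, primer, "-", max_mismatch, clamp)
  )
}

#' Amplify a primer pair on a circular genome
#'
#' Simulates PCR in the canonical orientation (forward primer on the +
#' strand, reverse primer on the - strand). The product runs from the
#' forward primer's 5' end to the reverse primer's 5' end, inclusive of both
#' primer footprints (gel-size convention), with circular wrap allowed.
#' Spans longer than `max_product` are suppressed; if several spans remain,
#' the shortest is reported first and all are flagged ambiguous.
#'
#' @param genome An [annotated_genome()].
#' @param pair A [primer_pair()].
#' @param max_product Maximum product size in bp.
#' @return Tibble (possibly zero rows = no product): `genome_id`, `locus`,
#'   `start`, `end`, `length`, `sequence`, `ambiguous`.
#' @export
amplify <- function(genome, pair, max_product = 2000L) {
  stopifnot(inherits(pair, "primer_pair"))
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  id <- if (inherits(genome, "annotated_genome")) genome$id else "genome"
  L <- nchar(seq)
  fwd <- match_one_strand(seq, pair$forward, "+", pair$max_mismatch, pair$clamp)
  rev <- match_one_strand(seq, pair$reverse, "-", pair$max_mismatch, pair$clamp)
  empty <- tibble(genome_id = character(0), locus = character(0),
                  start = integer(0), end = integer(0), length = integer(0),
                  sequence = character(0), ambiguous = logical(0))
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  combos <- expand.grid(f = fwd$position, r = rev$position)
  combos$len <- circular_span(combos$f, combos$r, L)
  combos <- combos[combos$len <= max_product, , drop = FALSE]
  if (nrow(combos) == 0L) return(empty)
  combos <- combos[order(combos$len), , drop = FALSE]
  tibble(
    genome_id = id, locus = pair$locus,
    start = as.integer(combos$f), end = as.integer(combos$r),
    length = as.integer(combos$len),
    sequence = vapply(seq_len(nrow(combos)), function(i) {
      circular_substr(seq, combos$f[i], combos$r[i])
    }, ""),
    ambiguous = nrow(combos) > 1L
  )
}

#' Multiplex assay definition
#'
#' Expected band sizes per locus and mitotype with a shared size tolerance.
#' Windows of the two mitotypes must not overlap at any locus.
#'
#' @param sizes Tibble with columns `locus`, `mitotype` (`"F"`/`"M"`),
#'   `size` (bp).
#' @param tolerance Half-width of the size window in bp.
#' @return An object of class `assay_def`.
#' @export
assay_def <- function(sizes, tolerance = 5L) {
  sizes <- as_tibble(sizes)
  stopifnot(all(c("locus", "mitotype", "size") %in% names(sizes)))
  for (loc in unique(sizes$locus)) {
    s <- sizes[sizes$locus == loc, ]
    if (all(c("F", "M") %in% s$mitotype)) {
      sf <- s$size[s$mitotype == "F"]; sm <- s$size[s$mitotype == "M"]
      if (any(abs(outer(sf, sm, "-")) <= 2L * tolerance)) {
        abort(sprintf("assay windows overlap between mitotypes at locus %s", loc))
      }
    }
  }
  structure(list(sizes = sizes, tolerance = as.integer(tolerance)),
            class = "assay_def")
}

#' Classify a multiplex PCR band pattern into a mitotype call
#'
#' Size-based decision rule of the multiplex mitotype assay: `F` if only
#' F-sized bands are seen at one or more loci, `M` if only M-sized bands,
#' `HET` if both mitotypes' band sets are present (the assay detects both
#' mtDNAs whatever their concentration), and `FAIL` if no band is
#' interpretable.
#'
#' @param bands Tibble with columns `locus`, `size` (observed bands, bp).
#' @param def An [assay_def()].
#' @param sample_id Optional sample label.
#' @return An object of class `multiplex_call`: list with `sample_id`,
#'   `bands` (with matched mitotype, NA if uninterpretable) and `call`.
#' @examples
#' def <- assay_def(tibble::tibble(
#'   locus = c("cytb", "cytb", "16S", "16S"),
#'   mitotype = c("F", "M", "F", "M"),
#'   size = c(301, 212, 377, 503)
#' ))
#' classify_multiplex(tibble::tibble(locus = c("cytb", "16S"),
#'                                   size = c(301, 377)), def)$call
#' @export
classify_multiplex <- function(bands, def, sample_id = NA_character_) {
  stopifnot(inherits(def, "assay_def"))
  bands <- as_tibble(bands)
  if (nrow(bands) > 0L) {
    bands$mitotype <- vapply(seq_len(nrow(bands)), function(i) {
      s <- def$sizes[def$sizes$locus == bands$locus[i], ]
      hit <- which(abs(s$size - bands$size[i]) <= def$tolerance)
      if (length(hit) == 1L) s$mitotype[hit] else NA_character_
    }, "")
  } else {
    bands$mitotype <- character(0)
  }
  seen <- unique(stats::na.omit(bands$mitotype))
  call <- if (length(seen) == 0L) "FAIL"
          else if (setequal(seen, "F")) "F"
          else if (setequal(seen, "M")) "M"
          else "HET"
  structure(list(sample_id = sample_id, bands = bands, call = call),
            class = "multiplex_call")
}

#' @export
print.multiplex_call <- function(x, ...) {
  cat(sprintf("<multiplex_call> %s: %s (%d bands)\n",
              x$sample_id, x$call, nrow(x$bands)))
  invisible(x)
}

#' Design a synthetic multiplex mitotype assay for a lineage pair
#'
#' Designs primer pairs against the generated genomes that reproduce the
#' logic of the published size-based assay: a shared 16S pair placed on
#' conserved flanks of the M-lineage insertion, whose F and M products
#' differ by exactly the insertion length; and mitotype-specific cytb pairs
#' whose forward 3' clamp sits on a fixed difference, so each amplifies one
#' mitotype only and the two products have distinct sizes.
#'
#' @param pair A `lineage_pair` from [diverge_lineages()].
#' @param plen Primer length.
#' @param size_16S Target F-genome product size for the 16S pair.
#' @param size_cytb_F,size_cytb_M Target product sizes for the F- and
#'   M-specific cytb pairs.
#' @param max_mismatch,clamp Matching tolerance passed to the primers.
#' @return List with `primers` (named list of [primer_pair()]; the cytb
#'   pairs are mitotype-specific) and `def` (the [assay_def()] built from
#'   the realized product sizes).
#' @export
design_assay_primers <- function(pair, plen = 20L, size_16S = 377L,
                                 size_cytb_F = 301L, size_cytb_M = 212L,
                                 max_mismatch = 2L, clamp = 3L) {
  stopifnot(inherits(pair, "lineage_pair"))
  a <- seq_chars(pair$alignment$F)
  b <- seq_chars(pair$alignment$M)
  seqF <- pair$genomeF$sequence
  seqM <- pair$genomeM$sequence
  nF <- nchar(seqF)

  # per-F-position: does this site differ, and is there an insertion just after?
  colF <- which(a != "-")
  diff_at <- (a != b)[colF]
  brk_after <- c(diff(colF) > 1L, FALSE)

  conserved_window <- function(s, w = plen) {
    s >= 1L && s + w - 1L <= nF &&
      !any(diff_at[s:(s + w - 1L)]) && !any(brk_after[s:(s + w - 2L)])
  }
  slide_to_conserved <- function(s, dir) {
    while (!conserved_window(s)) {
      s <- s + dir
      if (s < 1L || s + plen - 1L > nF) abort("no conserved primer site found")
    }
    s
  }

  ev <- pair$event_log
  ins16 <- ev[ev$type == "insertion" & ev$feature == "16S", ]
  if (nrow(ins16) != 1L) abort("pair lacks the 16S insertion event")
  mid <- ins16$pos_F[1L]
  ins_len <- ins16$length[1L]
  # forward upstream of the insertion point, reverse downstream
  f16 <- slide_to_conserved(mid - (size_16S - ins_len) %/% 2L - plen %/% 2L, -1L)
  r16_end <- slide_to_conserved(f16 + size_16S - plen, +1L) + plen - 1L
  if (r16_end - plen + 1L <= mid) abort("16S reverse primer does not clear the insertion")
  p16 <- primer_pair("p16S", "16S",
                     forward = substr(seqF, f16, f16 + plen - 1L),
                     reverse = revcomp(substr(seqF, r16_end - plen + 1L, r16_end)),
                     max_mismatch = max_mismatch, clamp = clamp)

  # mitotype-specific cytb pairs: forward 3' base on a fixed difference
  cytb <- feature_interval(pair$genomeF, "cytb")
  subs <- ev[ev$type == "substitution" & ev$feature == "cytb", ]
  if (nrow(subs) < 2L) abort("cytb carries too few fixed differences for assay design")
  pick_site <- function(target_size) {
    for (d in subs$pos_F) {
      fstart <- d - plen + 1L                     # substituted site at the 3' end
      if (fstart < cytb$start) next
      if (any(diff_at[fstart:(d - 1L)]) || any(brk_after[fstart:(d - 1L)])) next
      rend <- fstart + target_size - 1L
      if (rend + plen > nF) next
      rstart <- slide_to_conserved(rend - plen + 1L, +1L)
      return(list(fstart = fstart, rend = rstart + plen - 1L))
    }
    abort("no usable cytb fixed-difference site found")
  }
  shift_of <- function(p) sum(ins16$length[ins16$pos_F < p]) +
    sum(ev$length[ev$type == "insertion" & ev$pos_F < p])
  posM_of <- function(p) {
    ins <- ev[ev$type == "insertion", ]
    p + sum(ins$length[ins$pos_F < p])
  }
  sF <- pick_site(size_cytb_F)
  pcytbF <- primer_pair("pcytbF", "cytb",
                        forward = substr(seqF, sF$fstart, sF$fstart + plen - 1L),
                        reverse = revcomp(substr(seqF, sF$rend - plen + 1L, sF$rend)),
                        max_mismatch = max_mismatch, clamp = clamp)
  sM <- pick_site(size_cytb_M)
  fM <- posM_of(sM$fstart); rM <- posM_of(sM$rend)
  pcytbM <- primer_pair("pcytbM", "cytb",
                        forward = substr(seqM, fM, fM + plen - 1L),
                        reverse = revcomp(substr(seqM, rM - plen + 1L, rM)),
                        max_mismatch = max_mismatch, clamp = clamp)

  primers <- list(p16S = p16, pcytbF = pcytbF, pcytbM = pcytbM)
  sizes <- dplyr::bind_rows(
    size_row(pair$genomeF, p16, "F"),
    size_row(pair$genomeM, p16, "M"),
    size_row(pair$genomeF, pcytbF, "F"),
    size_row(pair$genomeM, pcytbM, "M")
  )
  list(primers = primers, def = assay_def(sizes))
}

size_row <- function(genome, pair, mitotype) {
  amp <- amplify(genome, pair)
  if (nrow(amp) == 0L) {
    abort(sprintf("designed primer pair %s yields no product on genome %s",
                  pair$name, genome$id))
  }
  tibble(locus = pair$locus, mitotype = mitotype, size = amp$length[1L])
}

#' Run a multiplex assay on one sample and call its mitotype
#'
#' Amplifies every primer pair on every genome present in the sample (one
#' genome for a homoplasmic individual, both for a heteroplasmic one), pools
#' the band sizes and classifies them with [classify_multiplex()].
#'
#' @param genomes A single [annotated_genome()] or list of them.
#' @param primers List of [primer_pair()]s.
#' @param def An [assay_def()].
#' @param sample_id Sample label.
#' @return A `multiplex_call`.
#' @export
run_multiplex <- function(genomes, primers, def, sample_id = NA_character_) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  bands <- dplyr::bind_rows(lapply(genomes, function(g) {
    dplyr::bind_rows(lapply(primers, function(p) {
      amp <- amplify(g, p)
      if (nrow(amp) == 0L) NULL else tibble(locus = p$locus, size = amp$length[1L])
    }))
  }))
  if (nrow(bands) > 0L) bands <- dplyr::distinct(bands)
  classify_multiplex(bands, def, sample_id = sample_id)
}
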