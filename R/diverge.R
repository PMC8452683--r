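#' Diverge a reference genome into an F/M mitotype pair
#'
#' Applies site-wise substitutions at a rate of `baseline x class multiplier`
#' (hotspot / conserved / baseline per feature), with the baseline calibrated
#' so the expected genome-wide p-distance equals `config$divergence_target`.
#' Substitutions inside protein-coding genes are constrained to preserve the
#' reading frame: internal codons may not become stops, the start codon must
#' remain a valid table-5 start and the stop codon must remain a stop (the
#' rare site where no alternative base satisfies this is left unchanged).
#' Two M-lineage structural events are then added: an insertion (default
#' 127 bp, A/T-rich) at the midpoint of 16S, and a C-terminal cox1 extension
#' (default 10 codons) inserted immediately before the stop codon.
#'
#' The returned pair carries the true gapped alignment of the two genomes and
#' an event log, so downstream scanning can be validated against ground
#' truth.
#'
#' @param ref An [annotated_genome()] with `rate_class` per feature, usually
#'   from [build_reference_genome()].
#' @param config A [synth_config()]. The divergence step draws from a random
#'   stream seeded with `config$seed + 1` so it is reproducible independently
#'   of the genome build.
#' @return An object of class `lineage_pair`: list with `genomeF`, `genomeM`
#'   ([annotated_genome()]s), `alignment` (gapped strings `F` and `M` of
#'   equal length), and `event_log` (tibble: type, pos_F, pos_M, ref, alt,
#'   length, feature).
#' @examples
#' pair <- generate_lineage_pair(synth_config(seed = 1))
#' pair$event_log[pair$event_log$type == "insertion", ]
#' @export
diverge_lineages <- function(ref, config) {
  stopifnot(inherits(ref, "annotated_genome"), inherits(config, "synth_config"))
  L <- nchar(ref$sequence)
  feats <- ref$features
  sF <- seq_chars(ref$sequence)

  # per-site rate multipliers from feature rate classes
  mult <- rep(1, L)
  site_feature <- rep(NA_character_, L)
  for (i in seq_len(nrow(feats))) {
    idx <- feats$start[i]:feats$end[i]
    mult[idx] <- switch(feats$rate_class[i],
      hotspot = config$hotspot_multiplier,
      conserved = config$conserved_multiplier,
      1
    )
    site_feature[idx] <- feats$name[i]
  }
  rate <- if (config$divergence_target > 0) {
    pmin(config$divergence_target * L / sum(mult) * mult, 0.75)
  } else {
    rep(0, L)
  }

  cds <- feats[feats$kind == "CDS", ]

  withr::with_seed(config$seed + 1L, {
    sub_sites <- which(stats::runif(L) < rate)
    sM <- sF
    kept <- logical(length(sub_sites))
    for (j in seq_along(sub_sites)) {
      pos <- sub_sites[j]
      cand <- setdiff(DNA_BASES, sF[pos])
      ci <- which(cds$start <= pos & cds$end >= pos)
      if (length(ci) == 1L) {
        codon_idx <- (pos - cds$start[ci]) %/% 3L           # 0-based codon index
        cstart <- cds$start[ci] + 3L * codon_idx
        within <- pos - cstart + 1L                          # 1..3
        n_codons <- (cds$end[ci] - cds$start[ci] + 1L) %/% 3L
        # frame check against the codon as mutated so far, not the reference:
        # two tolerated single changes could otherwise combine into a stop
        codon <- sM[cstart:(cstart + 2L)]
        ok <- vapply(cand, function(b) {
          cd <- codon
          cd[within] <- b
          cds_str <- paste(cd, collapse = "")
          if (codon_idx == 0L) {
            cds_str %in% START_CODONS_TBL5
          } else if (codon_idx == n_codons - 1L) {
            cds_str %in% STOP_CODONS_TBL5
          } else {
            !(cds_str %in% STOP_CODONS_TBL5)
          }
        }, logical(1))
        cand <- cand[ok]
      }
      if (length(cand) > 0L) {
        kept[j] <- TRUE
        sM[pos] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
    }
    sub_sites <- sub_sites[kept]

    # structural events, described as (insert after F position, sequence)
    events <- list()
    if (config$cox1_extension_aa > 0L) {
      cox1 <- feature_interval(ref, "cox1")
      ext <- paste(sample(SENSE_CODONS, config$cox1_extension_aa, replace = TRUE),
                   collapse = "")
      events <- c(events, list(list(
        pos_after = cox1$end - 3L, seq = ext, feature = "cox1"
      )))
    }
    if (config$indel_16S_length > 0L) {
      r16 <- feature_interval(ref, "16S")
      at_rich <- sample(DNA_BASES, config$indel_16S_length, replace = TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4))
      events <- c(events, list(list(
        pos_after = (r16$start + r16$end) %/% 2L,
        seq = paste(at_rich, collapse = ""), feature = "16S"
      )))
    }
    build_pair(ref, sF, sM, sub_sites, site_feature, events, config)
  })
}

build_pair <- function(ref, sF, sM, sub_sites, site_feature, events, config) {
  L <- length(sF)
  ins_pos <- vapply(events, function(e) e$pos_after, 1L)
  ins_len <- vapply(events, function(e) nchar(e$seq), 1L)
  ord <- order(ins_pos)
  events <- events[ord]; ins_pos <- ins_pos[ord]; ins_len <- ins_len[ord]

  # splice insertions into M and matching gap runs into the aligned F row
  segsM <- character(0); segsF <- character(0)
  prev <- 0L
  for (i in seq_along(events)) {
    chunk <- chars_to_seq(sF[(prev + 1L):ins_pos[i]])
    chunkM <- chars_to_seq(sM[(prev + 1L):ins_pos[i]])
    segsF <- c(segsF, chunk, strrep("-", ins_len[i]))
    segsM <- c(segsM, chunkM, events[[i]]$seq)
    prev <- ins_pos[i]
  }
  segsF <- c(segsF, chars_to_seq(sF[(prev + 1L):L]))
  segsM <- c(segsM, chars_to_seq(sM[(prev + 1L):L]))
  alnF <- paste(segsF, collapse = "")
  alnM <- paste(segsM, collapse = "")
  seqM <- gsub("-", "", alnM, fixed = TRUE)

  # shift in M coordinates accumulated ahead of an F position
  shift_before <- function(p) sum(ins_len[ins_pos < p])
  pos_M_of <- function(p) p + vapply(p, shift_before, 1)

  featsM <- ref$features
  featsM$start <- as.integer(featsM$start + vapply(featsM$start, shift_before, 1))
  featsM$end <- as.integer(featsM$end + vapply(featsM$end, shift_before, 1))

  sub_log <- tibble(
    type = rep("substitution", length(sub_sites)),
    pos_F = sub_sites,
    pos_M = as.integer(pos_M_of(sub_sites)),
    ref = sF[sub_sites],
    alt = sM[sub_sites],
    length = rep(1L, length(sub_sites)),
    feature = site_feature[sub_sites]
  )
  ins_log <- tibble(
    type = rep("insertion", length(events)),
    pos_F = ins_pos,
    pos_M = as.integer(ins_pos + vapply(seq_along(events), function(i) {
      sum(ins_len[seq_len(i - 1L)])
    }, 1) + 1L),
    ref = rep("", length(events)),
    alt = vapply(events, function(e) e$seq, ""),
    length = ins_len,
    feature = vapply(events, function(e) e$feature, "")
  )

  genomeF <- ref
  genomeM <- annotated_genome(
    id = sub("^synthF", "synthM", ref$id),
    sequence = seqM,
    features = featsM,
    topology = ref$topology
  )
  structure(
    list(
      genomeF = genomeF,
      genomeM = genomeM,
      alignment = list(F = alnF, M = alnM),
      event_log = dplyr::bind_rows(sub_log, ins_log)
    ),
    class = "lineage_pair"
  )
}

#' @rdname diverge_lineages
#' @param config A [synth_config()].
#' @export
generate_lineage_pair <- function(config) {
  diverge_lineages(build_reference_genome(config), config)
}

#' @export
print.lineage_pair <- function(x, ...) {
  ns <- sum(x$event_log$type == "substitution")
  ni <- sum(x$event_log$type == "insertion")
  cat(sprintf(
    "<lineage_pair> F %d bp / M %d bp; %d substitutions, %d insertions (aligned length %d)\n",
    nchar(x$genomeF$sequence), nchar(x$genomeM$sequence), ns, ni,
    nchar(x$alignment$F)
  ))
  invisible(x)
}

#' Realized substitution divergence of a lineage pair
#'
#' Substitution count from the event log divided by the ungapped aligned
#' length (insertion columns excluded), i.e. the expected pairwise-deletion
#' p-distance of the pair.
#'
#' @param pair A `lineage_pair`.
#' @return Numeric scalar.
#' @export
realized_divergence <- function(pair) {
  stopifnot(inherits(pair, "lineage_pair"))
  sum(pair$event_log$type == "substitution") / nchar(pair$genomeF$sequence)
}
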