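#' Annotated mitochondrial genome
#'
#' Lightweight container for a (usually circular) mitogenome sequence plus its
#' feature table. Coordinates are 1-based inclusive throughout the R API.
#'
#' @param id Genome label.
#' @param sequence DNA string over {A,C,G,T}.
#' @param features Tibble with columns `name`, `kind` (CDS, tRNA, rRNA, NCR),
#'   `start`, `end` (1-based inclusive), `strand`, `rate_class` (hotspot,
#'   conserved, baseline).
#' @param topology `"circular"` or `"linear"`.
#'
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, features, topology = "circular") {
  if (nchar(sequence) == 0L) abort("sequence length must be > 0")
  assert_dna(sequence, "genome sequence")
  topology <- match.arg(topology, c("circular", "linear"))
  features <- as_tibble(features)
  needed <- c("name", "kind", "start", "end", "strand", "rate_class")
  if (!all(needed %in% names(features))) {
    abort(paste("features must have columns:", paste(needed, collapse = ", ")))
  }
  L <- nchar(sequence)
  if (any(features$start < 1L | features$end > L | features$start > features$end)) {
    abort("feature intervals must lie within [1, genome length] with start <= end")
  }
  ord <- order(features$start)
  if (any(features$end[ord][-nrow(features)] >= features$start[ord][-1L])) {
    abort("features must be non-overlapping")
  }
  structure(
    list(id = id, topology = topology, sequence = sequence, features = features),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s, %d bp, %d features\n",
              x$id, x$topology, nchar(x$sequence), nrow(x$features)))
  tab <- table(x$features$kind)
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.annotated_genome <- function(x) nchar(x$sequence)

# Fixed gene order and lengths (bp) of the synthetic bivalve mitogenome.
# All features are on the + strand and tile the genome contiguously; the two
# NCRs absorb any genome-length surplus over the fixed gene complement.
# Rate classes follow the divergence topography of the A. islandica mitotype
# pair: hotspots in atp6, cytb, cox3, nad4, nad4L, nad6, 16S, tRNA-Ile,
# tRNA-Cys and both NCRs; 12S, cox2, nad3, nad5 and the other tRNAs conserved.
feature_layout <- function(genome_length = 17428L) {
  trna <- function(aa) list(paste0("tRNA-", aa), "tRNA", 66L,
                            if (aa %in% c("Ile", "Cys")) "hotspot" else "conserved")
  rows <- list(
    list("cox1", "CDS", 1539L, "baseline"),
    trna("Gly"),
    list("cox2", "CDS", 690L, "conserved"),
    trna("His"),
    list("atp6", "CDS", 708L, "hotspot"),
    list("NCR1", "NCR", NA_integer_, "hotspot"),
    trna("Ile"),
    list("nad2", "CDS", 1026L, "baseline"),
    trna("Met"), trna("Trp"), trna("Ala"),
    list("nad1", "CDS", 927L, "baseline"),
    trna("Pro"),
    list("12S", "rRNA", 945L, "conserved"),
    trna("Val"),
    list("16S", "rRNA", 1245L, "hotspot"),
    trna("Leu1"), trna("Leu2"),
    list("nad3", "CDS", 354L, "conserved"),
    trna("Ser1"),
    list("nad4L", "CDS", 282L, "hotspot"),
    list("nad4", "CDS", 1383L, "hotspot"),
    trna("Cys"),
    list("cytb", "CDS", 1140L, "hotspot"),
    trna("Phe"),
    list("nad5", "CDS", 1713L, "conserved"),
    trna("Ser2"),
    list("nad6", "CDS", 480L, "hotspot"),
    trna("Thr"),
    list("cox3", "CDS", 780L, "hotspot"),
    trna("Lys"), trna("Asp"), trna("Arg"), trna("Asn"), trna("Glu"),
    list("NCR2", "NCR", NA_integer_, "hotspot"),
    trna("Tyr"), trna("Gln")
  )
  layout <- tibble(
    name = vapply(rows, `[[`, "", 1L),
    kind = vapply(rows, `[[`, "", 2L),
    length = vapply(rows, `[[`, 1L, 3L),
    rate_class = vapply(rows, `[[`, "", 4L)
  )
  fixed <- sum(layout$length, na.rm = TRUE)
  min_ncr <- 100L
  if (genome_length < fixed + 2L * min_ncr) {
    abort(sprintf(
      "feature set does not fit: genome_length %d < minimum %d",
      genome_length, fixed + 2L * min_ncr
    ))
  }
  ncr_total <- genome_length - fixed
  ncr1 <- as.integer(floor(ncr_total * 0.55))
  layout$length[layout$name == "NCR1"] <- ncr1
  layout$length[layout$name == "NCR2"] <- ncr_total - ncr1
  layout$end <- cumsum(layout$length)
  layout$start <- layout$end - layout$length + 1L
  layout$strand <- "+"
  layout[, c("name", "kind", "start", "end", "strand", "rate_class")]
}

# random codons excluding the table-5 stops TAA/TAG
ALL_CODONS <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS_TBL5)

random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

random_dna <- function(n, prob = NULL) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

#' Build the synthetic reference (F-type) mitogenome
#'
#' Generates a circular annotated genome with the canonical bivalve
#' mitochondrial gene complement — 12 protein-coding genes (atp6, cytb,
#' cox1-3, nad1-6, nad4L), 22 tRNAs, the 12S and 16S rRNAs and two
#' non-coding regions — all on the + strand. Every CDS starts with ATG, ends
#' with a stop codon and contains no internal stop under the invertebrate
#' mitochondrial genetic code (translation table 5). Deterministic for a
#' given seed.
#'
#' @param config A [synth_config()].
#' @return An [annotated_genome()] of exactly `config$genome_length` bases.
#' @examples
#' g <- build_reference_genome(synth_config(seed = 1))
#' g
#' @export
build_reference_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  layout <- feature_layout(config$genome_length)
  lens <- layout$end - layout$start + 1L
  withr::with_seed(config$seed, {
    pieces <- mapply(function(kind, len) {
      if (kind == "CDS") random_cds(len %/% 3L) else random_dna(len)
    }, layout$kind, lens)
    annotated_genome(
      id = sprintf("synthF_seed%d", config$seed),
      sequence = paste(pieces, collapse = ""),
      features = layout,
      topology = "circular"
    )
  })
}

feature_interval <- function(genome, name) {
  f <- genome$features[genome$features$name == name, ]
  if (nrow(f) != 1L) abort(sprintf("feature '%s' not found", name))
  f
}

#' Extract and translate a protein-coding gene
#'
#' Pulls the CDS interval from the genome and translates it with the
#' invertebrate mitochondrial genetic code (NCBI translation table 5). A
#' single trailing stop is removed, so the returned length is the protein
#' length in amino acids.
#'
#' @param genome An [annotated_genome()].
#' @param name CDS feature name, e.g. `"cox1"`.
#' @return Character scalar: the amino-acid sequence.
#' @export
translate_cds <- function(genome, name) {
  f <- feature_interval(genome, name)
  if (f$kind != "CDS") abort(sprintf("feature '%s' is not a CDS", name))
  nt <- substr(genome$sequence, f$start, f$end)
  if (nchar(nt) %% 3L != 0L) abort(sprintf("CDS '%s' length not divisible by 3", name))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("5"),
    no.init.codon = FALSE
  ))
  sub("\\*$", "", aa)
}
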