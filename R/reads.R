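#' Simulate sequencing reads from a mitotype mixture
#'
#' Draws reads uniformly from the two circular genomes of a lineage pair
#' (origin-spanning reads allowed). The number of reads is Poisson around
#' `coverage x mean genome length / read_length`; each read originates from
#' the M genome with probability `config$mixture` and its true source label
#' is retained. Sequencing errors are independent per-base substitutions at
#' `config$error_rate` (no indel errors). Uses the random stream seeded with
#' `config$seed + 2`.
#'
#' @param pair A `lineage_pair`.
#' @param config A [synth_config()]; `read_length`, `coverage`,
#'   `error_rate` and `mixture` are used.
#' @return An object of class `read_set`: list with `reads` (tibble: `id`,
#'   `sequence`, `qualities`, `truth`), `read_length`, `coverage`,
#'   `error_rate`, `mixture`.
#' @examples
#' pair <- generate_lineage_pair(synth_config(seed = 1))
#' rs <- simulate_reads(pair, synth_config(seed = 1, coverage = 0.5))
#' table(rs$reads$truth)
#' @export
simulate_reads <- function(pair, config) {
  stopifnot(inherits(pair, "lineage_pair"), inherits(config, "synth_config"))
  if (config$coverage <= 0) abort("coverage must be > 0")
  rl <- config$read_length
  seqs <- c(F = pair$genomeF$sequence, M = pair$genomeM$sequence)
  lens <- nchar(seqs)
  if (rl > min(lens)) abort("read_length exceeds genome length")

  withr::with_seed(config$seed + 2L, {
    n <- stats::rpois(1L, config$coverage * mean(lens) / rl)
    truth <- sample(c("F", "M"), n, replace = TRUE,
                    prob = c(1 - config$mixture, config$mixture))
    starts <- vapply(truth, function(tr) sample.int(lens[[tr]], 1L), 1L)
    reads <- vapply(seq_len(n), function(i) {
      circular_substr(seqs[[truth[i]]], starts[i], starts[i] + rl - 1L)
    }, "")
    if (config$error_rate > 0 && n > 0L) {
      n_err <- stats::rbinom(n, rl, config$error_rate)
      for (i in which(n_err > 0L)) {
        ch <- seq_chars(reads[i])
        at <- sample.int(rl, n_err[i])
        ch[at] <- vapply(ch[at], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
        reads[i] <- chars_to_seq(ch)
      }
    }
    structure(
      list(
        reads = tibble(
          id = sprintf("read%06d_%s", seq_len(n), truth),
          sequence = reads,
          qualities = strrep("I", rl),
          truth = truth
        ),
        read_length = rl, coverage = config$coverage,
        error_rate = config$error_rate, mixture = config$mixture
      ),
      class = "read_set"
    )
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads x %d bp (error %g, M mixture %g)\n",
              nrow(x$reads), x$read_length, x$error_rate, x$mixture))
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' @param readset A `read_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(readset, path) {
  stopifnot(inherits(readset, "read_set"))
  r <- readset$reads
  lines <- as.vector(rbind(paste0("@", r$id), r$sequence, "+", r$qualities))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file path.
#' @return Tibble with columns `id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    id = names(x),
    sequence = unname(as.character(x)),
    qualities = unname(as.character(Biostrings::quality(x)))
  )
}
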