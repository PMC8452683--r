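#' Write an annotated genome as FASTA
#'
#' @param genome An [annotated_genome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "annotated_genome"))
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a feature table as TSV
#'
#' Columns: seqid, kind, start, end (1-based inclusive), strand, name,
#' rate_class.
#'
#' @param genome An [annotated_genome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  stopifnot(inherits(genome, "annotated_genome"))
  f <- genome$features
  out <- data.frame(seqid = genome$id, kind = f$kind, start = f$start,
                    end = f$end, strand = f$strand, name = f$name,
                    rate_class = f$rate_class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a grouped alignment from aligned FASTA plus a label table
#'
#' @param fasta_path Aligned FASTA (rows of equal gapped length).
#' @param groups_path Two-column TSV without header: sequence name, group
#'   label (`F`/`M`).
#' @return A [group_alignment()].
#' @export
read_group_alignment <- function(fasta_path, groups_path) {
  rows <- read_fasta(fasta_path)
  g <- utils::read.table(groups_path, sep = "\t", header = FALSE,
                         col.names = c("name", "label"),
                         colClasses = "character")
  missing <- setdiff(names(rows), g$name)
  if (length(missing) > 0L) {
    abort(paste("no group label for:", paste(missing, collapse = ", ")))
  }
  labels <- g$label[match(names(rows), g$name)]
  group_alignment(unname(rows), labels, names = names(rows))
}

#' Write a divergence profile as TSV
#'
#' Columns: window_start (1-based), count.
#'
#' @param profile A `divergence_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "divergence_profile"))
  utils::write.table(
    data.frame(window_start = profile$starts, count = profile$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write positions or intervals as BED
#'
#' BED is 0-based half-open; 1-based inclusive inputs are converted.
#'
#' @param seqid Sequence name.
#' @param start,end 1-based inclusive coordinates.
#' @param name Interval names.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(seqid, start, end, name, path) {
  utils::write.table(
    data.frame(seqid = seqid, start = start - 1L, end = end, name = name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a tibble as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
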