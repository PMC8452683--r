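#' Grouped gapped alignment of F- and M-type sequences
#'
#' Container for an alignment whose rows are labelled by mitotype group
#' (`"F"` or `"M"`). Rows must be equal-length gapped strings over
#' {A,C,G,T,-}; IUPAC ambiguity codes are rejected because the
#' fixed-difference rule is undefined for partially overlapping states.
#'
#' @param rows Character vector of gapped sequences.
#' @param labels Character vector of group labels (`"F"`/`"M"`), one per row.
#' @param names Optional row names; defaults to `seq1..seqN`.
#' @return An object of class `group_alignment`.
#' @examples
#' aln <- group_alignment(c("ACGTA", "ACGTA", "ATGTC"), c("F", "F", "M"))
#' fixed_difference_columns(aln)
#' @export
group_alignment <- function(rows, labels, names = NULL) {
  if (length(rows) != length(labels)) abort("one label per row required")
  labels <- as.character(labels)
  if (!all(labels %in% c("F", "M"))) abort("labels must be 'F' or 'M'")
  if (!all(c("F", "M") %in% labels)) abort("each group needs at least one row")
  if (length(unique(nchar(rows))) != 1L) abort("all rows must have equal length")
  assert_dna(rows, "alignment rows", allow_gap = TRUE)
  if (is.null(names)) names <- paste0("seq", seq_along(rows))
  structure(
    list(names = names, rows = rows, labels = labels),
    class = "group_alignment"
  )
}

#' @export
print.group_alignment <- function(x, ...) {
  cat(sprintf("<group_alignment> %d columns; %d F rows, %d M rows\n",
              nchar(x$rows[1]), sum(x$labels == "F"), sum(x$labels == "M")))
  invisible(x)
}

aln_matrix <- function(rows) {
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

#' Diagnostic fixed-difference columns between mitotype groups
#'
#' A column is a fixed difference when every state observed in the M group
#' differs from every state observed in the F group — set-disjointness with
#' the gap character counted as a fifth nucleotide state. A column where the
#' two groups share even one state (e.g. M = {A,G}, F = {A}) is not
#' reported.
#'
#' @param aln A [group_alignment()].
#' @return Sorted integer vector of 1-based column indices.
#' @export
fixed_difference_columns <- function(aln) {
  stopifnot(inherits(aln, "group_alignment"))
  mat <- aln_matrix(aln$rows)
  matF <- mat[aln$labels == "F", , drop = FALSE]
  matM <- mat[aln$labels == "M", , drop = FALSE]
  L <- ncol(mat)
  disjoint <- vapply(seq_len(L), function(j) {
    !any(matM[, j] %in% matF[, j])
  }, logical(1))
  which(disjoint)
}

#' Sliding-window divergence profile
#'
#' Counts divergent (fixed-difference) columns in a window slid along the
#' alignment. Defaults mirror the genome-wide scan the mitotype comparison
#' uses: a 500-column window advanced 1 column at a time, in alignment
#' coordinates (no wrap across the origin).
#'
#' @param positions Integer vector of divergent column indices (1-based),
#'   e.g. from [fixed_difference_columns()].
#' @param aln_length Total number of alignment columns.
#' @param window Window width in columns.
#' @param step Step size in columns.
#' @return An object of class `divergence_profile`: list with `window`,
#'   `step`, `starts` (1-based window start columns), `counts` and
#'   `source_positions`.
#' @examples
#' sliding_window_profile(c(3, 8), 10, window = 4)$counts
#' @export
sliding_window_profile <- function(positions, aln_length, window = 500L, step = 1L) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L) abort("step must be >= 1")
  if (window > aln_length) abort("window exceeds alignment length")
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) > 0 &&
      (min(positions) < 1L || max(positions) > aln_length)) {
    abort("positions must lie within [1, aln_length]")
  }
  ind <- integer(aln_length)
  ind[positions] <- 1L
  cs <- c(0L, cumsum(ind))
  starts <- seq.int(1L, aln_length - window + 1L, by = step)
  counts <- cs[starts + window] - cs[starts]
  structure(
    list(window = window, step = step, starts = starts, counts = counts,
         source_positions = positions),
    class = "divergence_profile"
  )
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf(
    "<divergence_profile> window %d step %d: %d windows, max count %d at window start %d\n",
    x$window, x$step, length(x$counts),
    if (length(x$counts)) max(x$counts) else 0L,
    if (length(x$counts)) x$starts[which.max(x$counts)] else NA_integer_
  ))
  invisible(x)
}

#' p-distance with bootstrap standard error
#'
#' Proportion of mismatching sites between two equal-length gapped sequences
#' under pairwise deletion: columns with a gap in either row are excluded.
#' The standard error is estimated by resampling alignment columns with
#' replacement (`bootstrap_reps` replicates; replicates with no comparable
#' sites are dropped).
#'
#' @param seqA,seqB Gapped strings of equal length.
#' @param bootstrap_reps Number of bootstrap replicates; 0 skips the SE.
#' @param seed Optional seed for the bootstrap resampling.
#' @return List with `distance`, `se`, `n_sites` (comparable sites) and
#'   `bootstrap_reps`.
#' @examples
#' p_distance("ACGT", "ACGA", bootstrap_reps = 0)$distance
#' @export
p_distance <- function(seqA, seqB, bootstrap_reps = 1000L, seed = NULL) {
  if (nchar(seqA) != nchar(seqB)) abort("sequences must have equal gapped length")
  assert_dna(c(seqA, seqB), "sequences", allow_gap = TRUE)
  a <- seq_chars(seqA); b <- seq_chars(seqB)
  comparable <- a != "-" & b != "-"
  n <- sum(comparable)
  if (n == 0L) abort("zero comparable sites after pairwise deletion")
  mismatch <- comparable & (a != b)
  d <- sum(mismatch) / n
  se <- NA_real_
  if (bootstrap_reps > 0L) {
    L <- length(a)
    boot <- function() {
      idx <- sample.int(L, L, replace = TRUE)
      nc <- sum(comparable[idx])
      if (nc == 0L) NA_real_ else sum(mismatch[idx]) / nc
    }
    reps <- if (is.null(seed)) {
      replicate(bootstrap_reps, boot())
    } else {
      withr::with_seed(seed, replicate(bootstrap_reps, boot()))
    }
    se <- stats::sd(reps[!is.na(reps)])
  }
  list(distance = d, se = se, n_sites = n, bootstrap_reps = as.integer(bootstrap_reps))
}

# gapped row -> for each alignment column, the 1-based ungapped position
# (NA at gap columns)
aln_to_seq_pos <- function(aln_row) {
  ch <- seq_chars(aln_row)
  pos <- cumsum(ch != "-")
  pos[ch == "-"] <- NA_integer_
  pos
}

#' Locate indels in a pairwise alignment
#'
#' Reports maximal gap runs between the two rows of a pairwise alignment (or
#' the true alignment of a [diverge_lineages()] pair). A gap run in the F row
#' is an insertion carried by M, and vice versa. When feature tables are
#' available (always, for a `lineage_pair`), each indel is annotated with the
#' feature of the carrier genome that contains it.
#'
#' @param x A `lineage_pair`, or a list/character vector of two gapped
#'   strings named `F` and `M`.
#' @param featuresF,featuresM Optional feature tibbles (1-based `start`,
#'   `end`, `name`) for the F and M sequences; filled in automatically for a
#'   `lineage_pair`.
#' @return Tibble with columns `aln_start` (1-based alignment column),
#'   `length`, `carrier` (`"F"`/`"M"`, the genome carrying the inserted
#'   bases) and `feature` (containing feature on the carrier genome, or NA).
#' @examples
#' locate_indels(c(F = "A--T", M = "AGGT"))
#' @export
locate_indels <- function(x, featuresF = NULL, featuresM = NULL) {
  if (inherits(x, "lineage_pair")) {
    featuresF <- featuresF %||% x$genomeF$features
    featuresM <- featuresM %||% x$genomeM$features
    x <- x$alignment
  }
  rows <- unlist(x, use.names = TRUE)
  if (length(rows) != 2L) abort("a two-sequence alignment is required")
  if (is.null(names(rows)) || !all(c("F", "M") %in% names(rows))) {
    names(rows) <- c("F", "M")
  }
  if (nchar(rows[["F"]]) != nchar(rows[["M"]])) abort("rows must have equal length")
  assert_dna(rows, "alignment rows", allow_gap = TRUE)

  posF <- aln_to_seq_pos(rows[["F"]])
  posM <- aln_to_seq_pos(rows[["M"]])

  one_side <- function(gapped_in, carrier, pos_carrier, features) {
    ch <- seq_chars(rows[[gapped_in]])
    r <- rle(ch == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    recs <- lapply(which(keep), function(i) {
      cols <- starts[i]:ends[i]
      feat <- NA_character_
      if (!is.null(features)) {
        p <- stats::na.omit(pos_carrier[cols])
        if (length(p) > 0) {
          hit <- features$start <= min(p) & features$end >= max(p)
          if (any(hit)) feat <- features$name[which(hit)[1L]]
        }
      }
      tibble(aln_start = starts[i], length = r$lengths[i],
             carrier = carrier, feature = feat)
    })
    dplyr::bind_rows(recs)
  }
  out <- dplyr::bind_rows(
    one_side("F", "M", posM, featuresM),
    one_side("M", "F", posF, featuresF)
  )
  if (nrow(out) == 0L) {
    return(tibble(aln_start = integer(0), length = integer(0),
                  carrier = character(0), feature = character(0)))
  }
  dplyr::arrange(out, .data$aln_start)
}

#' Per-feature divergence table of a lineage pair
#'
#' Projects each F-genome feature through the true alignment and computes,
#' over the feature's alignment columns (insertion columns inside the
#' feature included), the pairwise-deletion p-distance and the
#' fixed-difference count (gap counted as a fifth state). Alignment columns
#' not covered by any feature are pooled into an `intergenic` row, so the
#' fixed-difference counts partition the genome-wide total.
#'
#' @param pair A `lineage_pair`.
#' @return Tibble: `feature`, `kind`, `rate_class`, `n_columns`,
#'   `n_compared`, `p_distance`, `fixed_differences`.
#' @export
per_feature_divergence <- function(pair) {
  stopifnot(inherits(pair, "lineage_pair"))
  a <- seq_chars(pair$alignment$F)
  b <- seq_chars(pair$alignment$M)
  posF <- cumsum(a != "-")                 # F position at/preceding each column
  feats <- pair$genomeF$features
  colF <- which(a != "-")                  # alignment column of each F position

  ncols <- length(a)
  assigned <- logical(ncols)
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    cols <- colF[feats$start[i]]:colF[feats$end[i]]
    assigned[cols] <<- TRUE
    feature_row(feats$name[i], feats$kind[i], feats$rate_class[i], a[cols], b[cols])
  })
  inter <- which(!assigned)
  if (length(inter) > 0) {
    rows <- c(rows, list(feature_row("intergenic", "other", "baseline",
                                     a[inter], b[inter])))
  }
  dplyr::bind_rows(rows)
}

feature_row <- function(name, kind, rate_class, a, b) {
  comparable <- a != "-" & b != "-"
  n <- sum(comparable)
  tibble(
    feature = name, kind = kind, rate_class = rate_class,
    n_columns = length(a), n_compared = n,
    p_distance = if (n > 0) sum(a[comparable] != b[comparable]) / n else NA_real_,
    fixed_differences = sum(a != b)
  )
}
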