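#' Simulate a qPCR plate with standard curves
#'
#' Generates Ct values for a set of samples and targets under the
#' log-linear qPCR model `Ct = intercept - log_E(amount)`, where `E` is the
#' per-cycle amplification efficiency and `intercept` is the Ct of the 1-ng
#' standard, plus Gaussian cycle noise. Each target gets a standard dilution
#' series, and every measurement is run in replicate wells (duplicates by
#' default). Wells whose true amount is zero are flagged as
#' no-amplification (Ct is NA). Uses the random stream seeded with
#' `config$seed + 3`.
#'
#' @param truth Tibble with columns `sample`, `tissue`, `target`,
#'   `amount` (true ng of target; 0 means absent, negative is an error).
#' @param config A [synth_config()]; the `qpcr` block supplies
#'   efficiencies, intercepts, noise, replicates and standard amounts.
#' @return An object of class `qpcr_plate`: list with `wells` (tibble:
#'   `sample`, `tissue`, `target`, `well_type` standard/sample,
#'   `replicate`, `amount_known`, `ct`, `no_amplification`) and the
#'   generating `qpcr` settings.
#' @export
simulate_qpcr <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  truth <- as_tibble(truth)
  stopifnot(all(c("sample", "tissue", "target", "amount") %in% names(truth)))
  if (any(truth$amount < 0)) abort("non-positive amounts: true ng must be >= 0")
  q <- config$qpcr
  unknown <- setdiff(unique(truth$target), q$targets)
  if (length(unknown) > 0L) {
    abort(paste("targets missing from qpcr config:", paste(unknown, collapse = ", ")))
  }

  ct_of <- function(target, amount) {
    E <- q$efficiencies[[target]]
    q$intercepts[[target]] - log(amount) / log(E)
  }

  withr::with_seed(config$seed + 3L, {
    reps <- seq_len(q$replicates)
    std <- expand.grid(target = q$targets, amount_known = q$standard_amounts,
                       replicate = reps, stringsAsFactors = FALSE)
    std <- tibble(
      sample = "standard", tissue = NA_character_, target = std$target,
      well_type = "standard", replicate = std$replicate,
      amount_known = std$amount_known,
      ct = ct_of_vec(std$target, std$amount_known, ct_of) +
        stats::rnorm(nrow(std), 0, q$noise_sd),
      no_amplification = FALSE
    )
    smp <- truth[rep(seq_len(nrow(truth)), each = q$replicates), ]
    smp$replicate <- rep(reps, times = nrow(truth))
    zero <- smp$amount <= 0
    ct <- rep(NA_real_, nrow(smp))
    ct[!zero] <- ct_of_vec(smp$target[!zero], smp$amount[!zero], ct_of) +
      stats::rnorm(sum(!zero), 0, q$noise_sd)
    smp <- tibble(
      sample = smp$sample, tissue = smp$tissue, target = smp$target,
      well_type = "sample", replicate = smp$replicate,
      amount_known = NA_real_, ct = ct, no_amplification = zero
    )
    structure(list(wells = dplyr::bind_rows(std, smp), qpcr = q),
              class = "qpcr_plate")
  })
}

ct_of_vec <- function(targets, amounts, ct_of) {
  vapply(seq_along(targets), function(i) ct_of(targets[i], amounts[i]), 0)
}

#' @export
print.qpcr_plate <- function(x, ...) {
  w <- x$wells
  cat(sprintf("<qpcr_plate> %d wells (%d standard, %d sample), targets: %s\n",
              nrow(w), sum(w$well_type == "standard"),
              sum(w$well_type == "sample"),
              paste(unique(w$target), collapse = ", ")))
  invisible(x)
}
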