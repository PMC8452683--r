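#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct against log10(amount) over a dilution series.
#' The amplification efficiency is derived from the slope as
#' `E = 10^(-1/slope)` (a perfect doubling chemistry has slope -3.3219 and
#' E = 2). Curves with r-squared below 0.9 or an efficiency outside
#' (1, 2.2] are flagged, not rejected.
#'
#' @param dilutions Tibble/data frame with columns `amount` (ng, > 0) and
#'   `ct`, or two numeric vectors via `amount` and `ct`.
#' @param amount,ct Alternative vector interface.
#' @return An object of class `standard_curve`: `target`, `slope`,
#'   `intercept` (Ct at 1 ng), `efficiency`, `r_squared`, `flags`.
#' @examples
#' amt <- 10^seq(0, -4)
#' fit_standard_curve(amount = amt, ct = 18 - log2(amt))$efficiency
#' @export
fit_standard_curve <- function(dilutions = NULL, amount = NULL, ct = NULL,
                               target = NA_character_) {
  if (!is.null(dilutions)) {
    dilutions <- as_tibble(dilutions)
    amount <- dilutions$amount
    ct <- dilutions$ct
  }
  keep <- is.finite(amount) & is.finite(ct)
  amount <- amount[keep]; ct <- ct[keep]
  if (any(amount <= 0)) abort("standard amounts must be positive")
  if (length(unique(amount)) < 3L) {
    abort("a standard curve needs at least 3 distinct amounts")
  }
  fit <- stats::lm(ct ~ log10(amount))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  efficiency <- 10^(-1 / slope)
  flags <- character(0)
  if (r2 < 0.9) flags <- c(flags, "poor_fit")
  if (!is.finite(efficiency) || efficiency <= 1 || efficiency > 2.2) {
    flags <- c(flags, "efficiency_out_of_range")
  }
  structure(
    list(target = target, slope = slope, intercept = intercept,
         efficiency = efficiency, r_squared = r2, flags = flags),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %s: slope %.4f, E = %.4f, r2 = %.4f%s\n",
    x$target, x$slope, x$efficiency, x$r_squared,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""
  ))
  invisible(x)
}

#' Quantify a Ct measurement against a standard curve
#'
#' Implements `Concentration = Efficiency^dCt`: the amount is
#' `amount0 x E^(Ct0 - ct)` relative to a reference point `(Ct0, amount0)`.
#' By default the reference is the curve's 1-ng point (`Ct0 = intercept`),
#' which is identical to reading the amount off the fitted line.
#'
#' @param ct Observed Ct value(s); NA (no amplification) yields amount 0.
#' @param curve A [fit_standard_curve()] result.
#' @param reference Optional `c(ct0, amount0)` reference point.
#' @return Amount(s) in ng.
#' @export
quantify <- function(ct, curve, reference = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$efficiency) || curve$efficiency <= 1) {
    abort("degenerate curve: efficiency must exceed 1")
  }
  if (is.null(reference)) reference <- c(curve$intercept, 1)
  ct0 <- reference[[1L]]; amount0 <- reference[[2L]]
  if (amount0 <= 0) abort("reference amount must be positive")
  out <- amount0 * curve$efficiency^(ct0 - ct)
  out[is.na(ct)] <- 0
  out
}

#' Normalize a target amount to two housekeeping genes
#'
#' The relative quantity is the target amount divided by the geometric mean
#' of the two housekeeping amounts. Invariant under common rescaling of all
#' three inputs and symmetric in the housekeeping pair.
#'
#' @param target_ng Target amount(s).
#' @param hk1_ng,hk2_ng Housekeeping amounts (> 0).
#' @return Normalized ratio(s).
#' @examples
#' normalize_to_housekeeping(4, 2, 8)
#' @export
normalize_to_housekeeping <- function(target_ng, hk1_ng, hk2_ng) {
  if (any(hk1_ng <= 0) || any(hk2_ng <= 0)) {
    abort("housekeeping amounts must be positive")
  }
  target_ng / sqrt(hk1_ng * hk2_ng)
}

#' Call the tissue-level mitotype from normalized F and M ratios
#'
#' A tissue is homoplasmic when the minor mitotype's normalized amount
#' falls below the detection limit, heteroplasmic when both are detected,
#' and FAIL when neither is. For heteroplasmic tissues the imbalance is
#' `log10(major/minor)`, bucketed into under one, one-to-two, and over two
#' orders of magnitude.
#'
#' @param ratio_F,ratio_M Normalized amounts of the F- and M-type target.
#' @param detection_limit Normalized amount below which a type is absent.
#' @return An object of class `tissue_mitotype_call`: `ratio_F`, `ratio_M`,
#'   `call`, `log10_imbalance`, `imbalance_bucket`.
#' @examples
#' call_tissue_mitotype(1.0, 0.01, detection_limit = 1e-4)
#' @export
call_tissue_mitotype <- function(ratio_F, ratio_M, detection_limit = 1e-4) {
  if (ratio_F < 0 || ratio_M < 0) abort("ratios must be >= 0")
  detF <- ratio_F >= detection_limit
  detM <- ratio_M >= detection_limit
  if (!detF && !detM) {
    call <- "FAIL"; imb <- NA_real_; bucket <- NA_character_
  } else if (detF && detM) {
    call <- "heteroplasmic"
    imb <- log10(max(ratio_F, ratio_M) / min(ratio_F, ratio_M))
    bucket <- if (imb < 1) "<1 order" else if (imb <= 2) "1-2 orders" else ">2 orders"
  } else {
    call <- if (detF) "homoplasmic_F" else "homoplasmic_M"
    imb <- NA_real_; bucket <- NA_character_
  }
  structure(
    list(ratio_F = ratio_F, ratio_M = ratio_M, call = call,
         log10_imbalance = imb, imbalance_bucket = bucket),
    class = "tissue_mitotype_call"
  )
}

#' @export
print.tissue_mitotype_call <- function(x, ...) {
  cat(sprintf("<tissue_mitotype_call> %s (F %.3g, M %.3g%s)\n",
              x$call, x$ratio_F, x$ratio_M,
              if (!is.na(x$log10_imbalance)) {
                sprintf(", imbalance %.2f [%s]", x$log10_imbalance, x$imbalance_bucket)
              } else ""))
  invisible(x)
}

#' mtDNA copy-number fold change between carrier groups
#'
#' Ratio of group medians of normalized cytb amounts with a seeded
#' percentile bootstrap confidence interval.
#'
#' @param groupA,groupB Numeric vectors (>= 3 values each), e.g. M-carrier
#'   and F-carrier normalized copy numbers.
#' @param reps Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return List with `fold` (`median(A)/median(B)`), `ci` and `reps`.
#' @export
copy_number_fold <- function(groupA, groupB, reps = 1000L, conf = 0.95,
                             seed = NULL) {
  if (length(groupA) < 3L || length(groupB) < 3L) {
    abort("at least 3 individuals per group are required")
  }
  if (stats::median(groupB) <= 0 || stats::median(groupA) <= 0) {
    abort("degenerate group: non-positive median copy number")
  }
  fold <- stats::median(groupA) / stats::median(groupB)
  boot <- function() {
    stats::median(sample(groupA, replace = TRUE)) /
      stats::median(sample(groupB, replace = TRUE))
  }
  draws <- if (is.null(seed)) replicate(reps, boot())
           else withr::with_seed(seed, replicate(reps, boot()))
  alpha <- (1 - conf) / 2
  list(fold = fold,
       ci = unname(stats::quantile(draws, c(alpha, 1 - alpha))),
       reps = as.integer(reps))
}

#' Analyze a qPCR plate into per-sample mitotype quantities and calls
#'
#' Fits a standard curve per target from the plate's dilution series,
#' averages replicate wells on the Ct scale (flagging discordant replicates
#' with a Ct spread above 1 cycle), converts Ct to amounts via
#' Efficiency^dCt, normalizes the two mitotype targets to the geometric
#' mean of the two housekeeping genes and calls each sample/tissue as
#' homoplasmic or heteroplasmic. The default detection limit is the
#' normalized equivalent of a Ct-38 signal on each mitotype target's curve.
#'
#' @param plate A `qpcr_plate` (or list with a compatible `wells` tibble).
#' @param targets Named character vector `c(F = ..., M = ...)` mapping
#'   mitotypes to target names.
#' @param housekeeping Character vector of the two housekeeping targets
#'   (the best-stability pair is a configuration input here; a stability
#'   criterion such as NormFinder's would plug in upstream).
#' @param detection_ct Ct defining the detection limit.
#' @return List with `curves`, `quantities` (tibble: sample, tissue,
#'   target, ct, amount, normalized, flags) and `calls` (tibble: sample,
#'   tissue, ratio_F, ratio_M, call, log10_imbalance, imbalance_bucket).
#' @export
analyze_plate <- function(plate, targets = c(F = "cytbF", M = "cytbM"),
                          housekeeping = c("18S", "28S"),
                          detection_ct = 38) {
  wells <- as_tibble(plate$wells)
  stopifnot(length(housekeeping) == 2L, all(c("F", "M") %in% names(targets)))

  std <- wells[wells$well_type == "standard", ]
  curves <- lapply(split(std, std$target), function(d) {
    fit_standard_curve(amount = d$amount_known, ct = d$ct, target = d$target[1L])
  })

  smp <- wells[wells$well_type == "sample", ]
  grp <- dplyr::group_by(smp, .data$sample, .data$tissue, .data$target)
  agg <- dplyr::summarise(
    grp,
    ct = if (all(is.na(.data$ct))) NA_real_ else mean(.data$ct, na.rm = TRUE),
    discordant = sum(!is.na(.data$ct)) >= 2L &&
      diff(range(.data$ct, na.rm = TRUE)) > 1,
    .groups = "drop"
  )
  agg$amount <- vapply(seq_len(nrow(agg)), function(i) {
    quantify(agg$ct[i], curves[[agg$target[i]]])
  }, 0)

  wide <- function(target) {
    m <- agg[agg$target == target, c("sample", "tissue", "amount")]
    stats::setNames(m$amount, paste(m$sample, m$tissue, sep = "\r"))
  }
  hk1 <- wide(housekeeping[1L]); hk2 <- wide(housekeeping[2L])

  agg$normalized <- NA_real_
  for (i in which(agg$target %in% targets)) {
    key <- paste(agg$sample[i], agg$tissue[i], sep = "\r")
    if (key %in% names(hk1) && key %in% names(hk2) &&
        hk1[[key]] > 0 && hk2[[key]] > 0) {
      agg$normalized[i] <- normalize_to_housekeeping(agg$amount[i],
                                                     hk1[[key]], hk2[[key]])
    }
  }
  agg$flags <- ifelse(agg$amount <= 0, "below_detection",
                      ifelse(agg$discordant, "replicate_discord", ""))

  det_limit <- function(mito) {
    cv <- curves[[targets[[mito]]]]
    quantify(detection_ct, cv)
  }
  dlF <- det_limit("F"); dlM <- det_limit("M")

  keys <- unique(agg[, c("sample", "tissue")])
  calls <- dplyr::bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    sel <- agg$sample == keys$sample[i] & agg$tissue %in% keys$tissue[i]
    rF <- agg$normalized[sel & agg$target == targets[["F"]]]
    rM <- agg$normalized[sel & agg$target == targets[["M"]]]
    rF <- if (length(rF) == 1L && is.finite(rF)) rF else 0
    rM <- if (length(rM) == 1L && is.finite(rM)) rM else 0
    # detection limits on the normalized scale, per sample's housekeeping level
    key <- paste(keys$sample[i], keys$tissue[i], sep = "\r")
    gm <- if (key %in% names(hk1) && key %in% names(hk2)) {
      sqrt(hk1[[key]] * hk2[[key]])
    } else NA_real_
    cl <- call_tissue_mitotype(rF, rM,
                               detection_limit = min(dlF, dlM) / max(gm, 1e-12))
    tibble(sample = keys$sample[i], tissue = keys$tissue[i],
           ratio_F = rF, ratio_M = rM, call = cl$call,
           log10_imbalance = cl$log10_imbalance,
           imbalance_bucket = cl$imbalance_bucket)
  }))
  list(curves = curves, quantities = agg[, c("sample", "tissue", "target", "ct",
                                             "amount", "normalized", "flags")],
       calls = calls)
}
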