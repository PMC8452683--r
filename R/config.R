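#' Configuration for the synthetic DUI data generator
#'
#' Builds the single configuration object consumed by every generator in the
#' package: the annotated reference mitogenome, the diverged F/M lineage pair,
#' the read simulator, the qPCR plate simulator and the phenotype simulator.
#' One seed fixes all randomness; identical configurations produce
#' bit-identical outputs.
#'
#' Defaults encode the study conditions the generators emulate: a circular
#' 17,428-bp bivalve mitogenome, 5.5% genome-wide nucleotide divergence
#' between the female-transmitted (F) and male-transmitted (M) mitotypes with
#' rate hotspots (atp6, cytb, cox3, nad4, nad4L, nad6, 16S, tRNA-Ile,
#' tRNA-Cys and both non-coding regions) and conserved regions (12S, cox2,
#' nad3, nad5 and the remaining tRNAs), a 127-bp insertion in the M-type 16S
#' rRNA and a 10-amino-acid C-terminal extension of the M-type cox1.
#'
#' @param seed Integer seed fixing all randomness downstream.
#' @param genome_length Total genome length in bases.
#' @param divergence_target Expected substitutions per site between the two
#'   mitotypes (p-distance scale).
#' @param hotspot_multiplier,conserved_multiplier Substitution-rate scalars
#'   applied to hotspot / conserved features relative to baseline; the
#'   baseline rate is calibrated so the genome-wide expectation equals
#'   `divergence_target`.
#' @param indel_16S_length Length (bp) of the M-lineage insertion placed at
#'   the 16S midpoint. Set to 0 to disable.
#' @param cox1_extension_aa Number of amino acids appended to the M-lineage
#'   cox1 before its stop codon. Set to 0 to disable.
#' @param structural_events If `FALSE`, both structural events are disabled
#'   regardless of their lengths.
#' @param mixture Fraction of simulated reads drawn from the M genome.
#' @param read_length,coverage,error_rate Read simulator settings: read
#'   length (bp), expected fold coverage, per-base substitution error rate.
#' @param qpcr List of qPCR simulator settings: `targets`, per-target
#'   `efficiencies` and `intercepts` (Ct of the 1-ng standard), `noise_sd`
#'   (Gaussian Ct noise, cycles), `replicates` (wells per measurement) and
#'   `standard_amounts` (ng, the dilution series).
#' @param phenotype List of phenotype simulator settings: `n_per_group`
#'   (individuals per sex-by-mitotype cell), `sdlog` (log-normal dispersion),
#'   baseline group means (`ets_mean_F`, `cox_mean_F` in U/g tissue;
#'   `cs_mean_male` in U/g fresh weight; `copy_mean` in normalized cytb
#'   units) and the effects: `ets_M_ratio`, `cox_M_ratio` (M-carrier over
#'   F-carrier mean, both sexes), `cs_female_ratio` (female over male mean,
#'   both mitotypes) and `copy_fold_M` (mtDNA copy-number fold in M
#'   carriers).
#'
#' @return A list with class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$divergence_target
#' @export
synth_config <- function(seed = 1L,
                         genome_length = 17428L,
                         divergence_target = 0.055,
                         hotspot_multiplier = 3.0,
                         conserved_multiplier = 0.2,
                         indel_16S_length = 127L,
                         cox1_extension_aa = 10L,
                         structural_events = TRUE,
                         mixture = 0,
                         read_length = 100L,
                         coverage = 30,
                         error_rate = 0.001,
                         qpcr = list(),
                         phenotype = list()) {
  if (!is.numeric(seed) || length(seed) != 1L) abort("seed must be a single integer")
  if (divergence_target < 0 || divergence_target >= 0.75) {
    abort("divergence_target must lie in [0, 0.75)")
  }
  if (hotspot_multiplier <= 0 || conserved_multiplier <= 0) {
    abort("rate multipliers must be positive")
  }
  if (mixture < 0 || mixture > 1) abort("mixture must lie in [0, 1]")

  qpcr_defaults <- list(
    targets = c("cytbF", "cytbM", "18S", "28S"),
    efficiencies = c(cytbF = 1.96, cytbM = 1.94, `18S` = 1.92, `28S` = 1.98),
    intercepts = c(cytbF = 18, cytbM = 18, `18S` = 12, `28S` = 13),
    noise_sd = 0.15,
    replicates = 2L,
    standard_amounts = 10^seq(0, -4)
  )
  phenotype_defaults <- list(
    n_per_group = 20L,
    sdlog = 0.3,
    ets_mean_F = 30,
    cox_mean_F = 20,
    cs_mean_male = 10,
    copy_mean = 50,
    ets_M_ratio = 0.69,
    cox_M_ratio = 0.67,
    cs_female_ratio = 0.58,
    copy_fold_M = 3
  )
  qpcr <- utils::modifyList(qpcr_defaults, qpcr)
  phenotype <- utils::modifyList(phenotype_defaults, phenotype)
  if (any(qpcr$efficiencies <= 1 | qpcr$efficiencies > 2)) {
    abort("qPCR efficiencies must lie in (1, 2]")
  }
  if (qpcr$replicates < 1L) abort("qPCR replicate count must be >= 1")
  ratios <- c(phenotype$ets_M_ratio, phenotype$cox_M_ratio, phenotype$cs_female_ratio)
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    abort("invalid effect block: group-mean ratios must be positive and finite")
  }

  structure(
    list(
      seed = as.integer(seed),
      genome_length = as.integer(genome_length),
      divergence_target = divergence_target,
      hotspot_multiplier = hotspot_multiplier,
      conserved_multiplier = conserved_multiplier,
      indel_16S_length = if (structural_events) as.integer(indel_16S_length) else 0L,
      cox1_extension_aa = if (structural_events) as.integer(cox1_extension_aa) else 0L,
      mixture = mixture,
      read_length = as.integer(read_length),
      coverage = coverage,
      error_rate = error_rate,
      qpcr = qpcr,
      phenotype = phenotype
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  seed: %d  genome: %d bp  divergence: %.3f\n",
              x$seed, x$genome_length, x$divergence_target))
  cat(sprintf("  structural events: 16S +%d bp, cox1 +%d aa\n",
              x$indel_16S_length, x$cox1_extension_aa))
  cat(sprintf("  reads: %d bp at %gx, error %g, M mixture %g\n",
              x$read_length, x$coverage, x$error_rate, x$mixture))
  invisible(x)
}
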