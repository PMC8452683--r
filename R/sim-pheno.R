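#' Simulate per-individual enzyme activities and mtDNA copy numbers
#'
#' Draws a balanced sex-by-mitotype table of log-normal enzyme activities
#' with the configured group-mean structure: ETS (electron transport system
#' complexes I+III) and COX (complex IV) depend on the mitotype only
#' (M-carrier mean = `ets_M_ratio` / `cox_M_ratio` times the F-carrier
#' mean, in both sexes); CS (citrate synthase, nuclear-encoded) depends on
#' sex only (female mean = `cs_female_ratio` times the male mean, in both
#' mitotypes). Normalized mtDNA copy number is log-normal around
#' `copy_mean`, multiplied by `copy_fold_M` in M carriers. Uses the random
#' stream seeded with `config$seed + 4`.
#'
#' @param config A [synth_config()]; the `phenotype` block supplies group
#'   sizes, dispersion and effects.
#' @param n_per_group Optional override of individuals per sex-by-mitotype
#'   cell.
#' @return Tibble: `id`, `sex` (`female`/`male`), `mitotype` (`F`/`M`),
#'   `ETS`, `COX` (U per g tissue), `CS` (U per g fresh weight),
#'   `mtdna_copies` (normalized cytb units).
#' @examples
#' ph <- simulate_phenotypes(synth_config(seed = 7))
#' dplyr::count(ph, sex, mitotype)
#' @export
simulate_phenotypes <- function(config, n_per_group = NULL) {
  stopifnot(inherits(config, "synth_config"))
  p <- config$phenotype
  n <- as.integer(n_per_group %||% p$n_per_group)
  if (n < 1L) abort("group sizes must be >= 1")

  groups <- expand.grid(sex = c("female", "male"), mitotype = c("F", "M"),
                        stringsAsFactors = FALSE)
  # log-normal draws around a target arithmetic mean m: meanlog = log(m) - s^2/2
  rlnorm_mean <- function(n, m, s) stats::rlnorm(n, log(m) - s^2 / 2, s)

  withr::with_seed(config$seed + 4L, {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      sex <- groups$sex[i]; mito <- groups$mitotype[i]
      ets_m <- p$ets_mean_F * if (mito == "M") p$ets_M_ratio else 1
      cox_m <- p$cox_mean_F * if (mito == "M") p$cox_M_ratio else 1
      cs_m <- p$cs_mean_male * if (sex == "female") p$cs_female_ratio else 1
      copy_m <- p$copy_mean * if (mito == "M") p$copy_fold_M else 1
      tibble(
        sex = sex, mitotype = mito,
        ETS = rlnorm_mean(n, ets_m, p$sdlog),
        COX = rlnorm_mean(n, cox_m, p$sdlog),
        CS = rlnorm_mean(n, cs_m, p$sdlog),
        mtdna_copies = rlnorm_mean(n, copy_m, p$sdlog)
      )
    })
    out <- dplyr::bind_rows(rows)
    out$id <- sprintf("ind%05d", seq_len(nrow(out)))
    out[, c("id", "sex", "mitotype", "ETS", "COX", "CS", "mtdna_copies")]
  })
}

#' The population screening table of mitotype carriers
#'
#' Transcription of the published screening of 315 individuals across seven
#' North Atlantic populations: per population, the number of individuals
#' carrying the F (female-transmitted) and M (male-transmitted) mtDNA in
#' adductor muscle, plus the totals row.
#'
#' @return Tibble: `population`, `location`, `n`, `carriers_F`,
#'   `carriers_M`.
#' @export
population_screen_fixture <- function() {
  tibble(
    population = c("Norway", "Iceland", "Baltic Sea", "Helgoland", "US",
                   "Kattegat", "White Sea", "total"),
    location = c("69°39N 18°57E", "66°01N 14°51W",
                 "54°32N 10°42E", "54°09N 07°47E",
                 "41°00N 71°00W", "56°10N 11°48E",
                 "66°18N 33°38E", NA_character_),
    n = c(33L, 60L, 77L, 47L, 58L, 17L, 23L, 315L),
    carriers_F = c(30L, 50L, 77L, 47L, 56L, 17L, 23L, 300L),
    carriers_M = c(3L, 10L, 0L, 0L, 2L, 0L, 0L, 15L)
  )
}

#' Simulate (or transcribe) a population mitotype screen
#'
#' In sampling mode, draws binomial M-carrier counts per population at the
#' given carrier probabilities. In fixture mode, bypasses sampling and
#' returns the published screening table via
#' [population_screen_fixture()].
#'
#' @param pop_table Tibble with columns `population`, `n`,
#'   `carrier_probability` (ignored in fixture mode).
#' @param seed Seed for the binomial draws.
#' @param fixture If `TRUE`, return the transcribed table.
#' @return Tibble: `population`, `n`, `carriers_F`, `carriers_M` (fixture
#'   mode adds `location` and a totals row).
#' @export
simulate_population_screen <- function(pop_table = NULL, seed = 1L,
                                       fixture = FALSE) {
  if (fixture) return(population_screen_fixture())
  pop_table <- as_tibble(pop_table)
  stopifnot(all(c("population", "n", "carrier_probability") %in% names(pop_table)))
  if (any(pop_table$n < 0)) abort("negative n")
  if (any(pop_table$carrier_probability < 0 | pop_table$carrier_probability > 1)) {
    abort("carrier probabilities must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    m <- stats::rbinom(nrow(pop_table), pop_table$n, pop_table$carrier_probability)
    tibble(
      population = pop_table$population,
      n = as.integer(pop_table$n),
      carriers_F = as.integer(pop_table$n - m),
      carriers_M = as.integer(m)
    )
  })
}
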