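# Synthetic screening rosters.  The default configuration reproduces the
# cohort-flow counts of the screen-detected analysis population: 373
# survivors (stage I/II/III/IV = 296/40/22/4 plus 11 with missing stage),
# 182 lung-cancer-related deaths with eligible strata I/II/III = 49/19/65,
# 34 deaths from unrelated causes, and 34 subjects of indeterminate final
# status that reconcile the 623 screen-detected total.  The published
# stage-IV nonsurvivor count (70) is inconsistent with the published
# eligible-nonsurvivor total (182, vs 49+19+65+70 = 203); the default
# roster resolves this by carrying 49 stage-IV nonsurvivors so that both
# the 182 total and the I-III strata hold exactly.

#' Roster configuration
#'
#' Stage-stratum counts and marginal distributions for [make_roster()].
#' Defaults reproduce the screen-detected cohort flow (see the package
#' vignette): survivor strata 296/40/22/4 for stages I-IV, eligible
#' nonsurvivor strata 49/19/65/49, 34 unrelated deaths, 34
#' indeterminate-status subjects, and marginals of age 64 +/- 5 y, height
#' 1.7 +/- 0.1 m, weight 80 +/- 16 kg, a 54:36 male:female ratio,
#' survivor follow-up 1660 +/- 488 days (range 405-2744) and nonsurvivor
#' time to death 894 +/- 542 days (range 14-2399).
#'
#' @param survivor_stage_counts named integer vector, stages I-IV.
#' @param nonsurvivor_stage_counts named integer vector, stages I-IV
#'   (lung-cancer-related deaths only).
#' @param n_unrelated_deaths deaths from causes unrelated to lung cancer.
#' @param n_indeterminate screen-detected subjects with unknown final
#'   status (excluded by outcome classification downstream).
#' @param n_missing_stage_survivors survivors carrying a missing stage.
#' @param n_non_screen non-screen-detected subjects (excluded upstream).
#' @param age_mean,age_sd,height_mean,height_sd,weight_mean,weight_sd
#'   demographic marginals (years, m, kg).
#' @param pkyr_mean,pkyr_sd,pkyr_min pack-year marginal, truncated below
#'   at the screening-eligibility floor of 30 pack-years.
#' @param male_prob probability of male gender (54:36 ratio by default).
#' @param survivor_followup,nonsurvivor_survival length-4 vectors
#'   `(mean, sd, min, max)` in days for the survivor follow-up period and
#'   the nonsurvivor time from diagnosis to death.
#' @param candx_max latest possible day of diagnosis after randomization.
#' @param copd_prob marginal probability of a COPD history.
#' @param biomarkers if `TRUE`, emit per-subject CT biomarker columns
#'   (`muscle_area`, `fat_attenuation`, `emphysema`, `cac_grade`) drawn
#'   from group-conditional marginals so the modelling stages can run on
#'   a roster alone.
#' @param seed integer seed fixing all randomness.
#' @return A `roster_config` list.
#' @export
roster_config <- function(
    survivor_stage_counts = c(I = 296L, II = 40L, III = 22L, IV = 4L),
    nonsurvivor_stage_counts = c(I = 49L, II = 19L, III = 65L, IV = 49L),
    n_unrelated_deaths = 34L,
    n_indeterminate = 34L,
    n_missing_stage_survivors = 11L,
    n_non_screen = 50L,
    age_mean = 64, age_sd = 5,
    height_mean = 1.7, height_sd = 0.1,
    weight_mean = 80, weight_sd = 16,
    pkyr_mean = 56, pkyr_sd = 24, pkyr_min = 30,
    male_prob = 54 / 90,
    survivor_followup = c(mean = 1660, sd = 488, min = 405, max = 2744),
    nonsurvivor_survival = c(mean = 894, sd = 542, min = 14, max = 2399),
    candx_max = 1095,
    copd_prob = 0.3,
    biomarkers = TRUE,
    seed = 20180516L) {
  cfg <- as.list(environment())
  counts <- c(cfg$survivor_stage_counts, cfg$nonsurvivor_stage_counts,
              cfg$n_unrelated_deaths, cfg$n_indeterminate,
              cfg$n_missing_stage_survivors, cfg$n_non_screen)
  if (any(counts < 0)) stop2("all roster counts must be >= 0")
  if (any(c(cfg$age_sd, cfg$height_sd, cfg$weight_sd, cfg$pkyr_sd) <= 0))
    stop2("marginal standard deviations must be positive")
  class(cfg) <- "roster_config"
  cfg
}

# Group-conditional CT biomarker marginals (survivor, nonsurvivor):
# muscle area 32.6/29.2 cm^2, fat attenuation -92.5/-89.9 HU, emphysema
# fraction 0.13/0.15, CAC grade mean 1.0/2.0 (sd ~1.1) on the 0-3 scale.
.biomarker_marginals <- list(
  survivor = list(muscle = c(32.6, 7.9), fat = c(-92.5, 4.4),
                  emph = c(0.13, 0.12),
                  cac_probs = c(0.45, 0.25, 0.15, 0.15)),
  nonsurvivor = list(muscle = c(29.2, 6.4), fat = c(-89.9, 4.6),
                     emph = c(0.15, 0.14),
                     cac_probs = c(0.15, 0.15, 0.25, 0.45)))

.histology_levels <- c("adenocarcinoma", "squamous", "small_cell",
                       "large_cell", "unspecified")
.histology_probs <- c(0.52, 0.27, 0.05, 0.03, 0.13)

#' Generate a synthetic subject roster
#'
#' Emits one row per subject with the package's internal field names
#' (write with [write_table()]; [read_roster()] accepts either these or
#' the trial master-sheet headers).  Stage-stratum counts are honoured
#' exactly; survivors carry `death_lc = "alive"`, nonsurvivors split into
#' lung-cancer-related and unrelated deaths per the configuration, and
#' `candx_days < fup_days` holds for every subject.  Deterministic given
#' the configured seed.
#'
#' @param config a [roster_config()].
#' @return A `subject_roster` data frame.
#' @examples
#' r <- make_roster(roster_config(seed = 1))
#' table(r$death_lc)
#' @export
make_roster <- function(config = roster_config()) {
  stopifnot(inherits(config, "roster_config"))
  with_seed(config$seed, {
    groups <- list()
    add_group <- function(n, stage, death_lc, survival_spec,
                          screen = TRUE, bm_group = "survivor") {
      if (n == 0) return(invisible(NULL))
      groups[[length(groups) + 1]] <<- data.frame(
        stage = rep(stage, n), death_lc = rep(death_lc, n),
        screen_detected = rep(screen, n), bm_group = rep(bm_group, n),
        surv_mean = unname(survival_spec[1]),
        surv_sd = unname(survival_spec[2]),
        surv_min = unname(survival_spec[3]),
        surv_max = unname(survival_spec[4]),
        stringsAsFactors = FALSE)
    }
    sf <- config$survivor_followup
    ns <- config$nonsurvivor_survival
    for (st in names(config$survivor_stage_counts))
      add_group(config$survivor_stage_counts[[st]], st, "alive", sf)
    add_group(config$n_missing_stage_survivors, NA_character_, "alive", sf)
    for (st in names(config$nonsurvivor_stage_counts))
      add_group(config$nonsurvivor_stage_counts[[st]], st,
                "lung_cancer_death", ns, bm_group = "nonsurvivor")
    # unrelated deaths: spread over stages I-III deterministically
    if (config$n_unrelated_deaths > 0) {
      st_seq <- rep(c("I", "II", "III"),
                    length.out = config$n_unrelated_deaths)
      for (st in c("I", "II", "III"))
        add_group(sum(st_seq == st), st, "unrelated_death", ns,
                  bm_group = "nonsurvivor")
    }
    add_group(config$n_indeterminate, "I", "unknown", sf)
    add_group(config$n_non_screen, "I", "alive", sf, screen = FALSE)

    df <- do.call(rbind, groups)
    n <- nrow(df)
    df$pid <- sprintf("%06d", 100000L + seq_len(n))
    df$age <- round(rnorm_trunc(n, config$age_mean, config$age_sd, 40, 90))
    df$gender <- ifelse(runif(n) < config$male_prob, "male", "female")
    df$height <- round(rnorm_trunc(n, config$height_mean,
                                   config$height_sd, 1.4, 2.1), 2)
    df$weight <- round(rnorm_trunc(n, config$weight_mean,
                                   config$weight_sd, 40, 160), 1)
    df$pkyr <- round(rnorm_trunc(n, config$pkyr_mean, config$pkyr_sd,
                                 config$pkyr_min, 160), 1)
    df$copd <- runif(n) < config$copd_prob
    df$histology <- sample(.histology_levels, n, replace = TRUE,
                           prob = .histology_probs)
    df$candx_days <- floor(runif(n, 0, config$candx_max))
    surv_time <- round(rnorm_trunc(n, df$surv_mean, df$surv_sd,
                                   df$surv_min, df$surv_max))
    df$fup_days <- df$candx_days + surv_time

    if (isTRUE(config$biomarkers)) {
      bm <- .biomarker_marginals
      grp <- df$bm_group
      musc <- t(vapply(grp, function(g) bm[[g]]$muscle, numeric(2)))
      fat <- t(vapply(grp, function(g) bm[[g]]$fat, numeric(2)))
      emph <- t(vapply(grp, function(g) bm[[g]]$emph, numeric(2)))
      df$muscle_area <- pmax(round(rnorm(n, musc[, 1], musc[, 2]), 1), 5)
      df$fat_attenuation <- pmin(pmax(
        round(rnorm(n, fat[, 1], fat[, 2]), 1), -120), -60)
      df$emphysema <- pmin(pmax(
        round(rnorm(n, emph[, 1], emph[, 2]), 3), 0), 1)
      df$cac_grade <- vapply(grp, function(g)
        sample(0:3, 1, prob = bm[[g]]$cac_probs), 0L)
    }

    df$surv_mean <- df$surv_sd <- df$surv_min <- df$surv_max <- NULL
    df$bm_group <- NULL
    front <- c("pid", "age", "gender", "height", "weight", "pkyr",
               "stage", "screen_detected", "death_lc", "candx_days",
               "fup_days", "copd", "histology")
    df <- df[, c(front, setdiff(names(df), front))]
    rownames(df) <- NULL
    class(df) <- c("subject_roster", "data.frame")
    df
  })
}
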