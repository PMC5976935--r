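test_that("derived fields follow their closed forms", {
  r <- data.frame(pid = c("a", "b", "c"),
                  weight = c(80, 70, NA), height = c(1.7, 1.6, 1.8),
                  fup_days = c(1000, 500, 800),
                  candx_days = c(100, 500, 200))
  d <- derive_fields(r)
  expect_equal(round(d$bmi[1], 2), 27.68)   # 80 / 1.7^2
  expect_equal(d$survival_time[2], 0)       # fup == candx
  expect_true(is.na(d$bmi[3]))
  expect_true(d$derived_incomplete[3])
  expect_false(any(d$derived_incomplete[1:2]))
})

test_that("exclusion cascade reproduces the cohort flow", {
  ex <- default_cohort()$ex
  expect_equal(ex$eligible_nonsurvivors, 182)
  expect_equal(nrow(ex$nonsurvivors), 133)        # after stage IV drop
  expect_equal(nrow(ex$survivors), 358)           # 296 + 40 + 22
  expect_true(all(ex$survivors$stage %in% c("I", "II", "III")))
  expect_true(all(ex$nonsurvivors$death_lc == "lung_cancer_death"))
  log <- ex$log
  expect_equal(log$removed[log$rule == "death unrelated to lung cancer"],
               34)
  expect_equal(log$removed[log$rule == "indeterminate final status"], 34)
  expect_equal(log$removed[log$rule == "missing stage (survivors)"], 11)
  expect_equal(log$removed[log$rule == "stage IV (nonsurvivors)"], 49)
})

test_that("stage-IV-only rosters empty both groups with a clear log", {
  r <- make_roster(roster_config(
    survivor_stage_counts = c(I = 0L, II = 0L, III = 0L, IV = 10L),
    nonsurvivor_stage_counts = c(I = 0L, II = 0L, III = 0L, IV = 10L),
    n_unrelated_deaths = 0L, n_indeterminate = 0L,
    n_missing_stage_survivors = 0L, n_non_screen = 0L, seed = 71))
  ex <- apply_exclusions(r)
  expect_equal(nrow(ex$survivors), 0)
  expect_equal(nrow(ex$nonsurvivors), 0)
  expect_equal(sum(ex$log$removed[grepl("stage IV", ex$log$rule)]), 20)
})

test_that("the assignment solver is exact against brute force", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(2:5, 1); m <- n + sample(0:3, 1)
    cost <- matrix(runif(n * m), n, m)
    assign <- solve_lsap_cpp(cost)
    total <- sum(cost[cbind(seq_len(n), assign)])
    expect_equal(total, brute_force_assignment(cost), tolerance = 1e-12)
    expect_false(anyDuplicated(assign) > 0)
  }
})

test_that("identical subjects match at distance zero", {
  mk <- function(pid, grp) data.frame(
    pid = pid, age = 64, gender = "male", height = 1.7, weight = 80,
    pkyr = 50, stage = "I", candx_days = 100, fup_days = 1000,
    stringsAsFactors = FALSE)
  surv <- rbind(mk("s1"), mk("s2"))
  nons <- rbind(mk("n1"), mk("n2"))
  cfg <- match_config(variances = c(age = 1, bmi = 1, pkyr = 1,
                                    survival_time = 1))
  mc <- nsm_match(surv, nons, cfg)
  expect_equal(mc$pairs$distance, c(0, 0))
  expect_equal(mc$n_pairs, 2)
})

test_that("matching is invariant to affine rescaling of a criterion", {
  cc <- default_cohort()
  base <- cc$mc
  # express pack-years on a rescaled-and-shifted axis
  s2 <- cc$ex$survivors;  s2$pkyr <- 3 * s2$pkyr + 10
  n2 <- cc$ex$nonsurvivors; n2$pkyr <- 3 * n2$pkyr + 10
  rescaled <- nsm_match(s2, n2)
  expect_equal(rescaled$pairs$distance, base$pairs$distance,
               tolerance = 1e-10)
  expect_identical(rescaled$pairs$survivor_pid, base$pairs$survivor_pid)
  expect_identical(rescaled$pairs$nonsurvivor_pid,
                   base$pairs$nonsurvivor_pid)
})

test_that("matching is invariant to input row order", {
  cc <- default_cohort()
  set.seed(73)
  s2 <- cc$ex$survivors[sample(nrow(cc$ex$survivors)), ]
  n2 <- cc$ex$nonsurvivors[sample(nrow(cc$ex$nonsurvivors)), ]
  shuffled <- nsm_match(s2, n2)
  expect_identical(shuffled$pairs$survivor_pid,
                   cc$mc$pairs$survivor_pid)
  expect_identical(shuffled$pairs$nonsurvivor_pid,
                   cc$mc$pairs$nonsurvivor_pid)
})

test_that("per-stratum pair counts equal the minimum group size", {
  cc <- default_cohort()
  pairs <- cc$mc$pairs
  surv <- cc$ex$survivors; nons <- cc$ex$nonsurvivors
  for (st in c("I", "II", "III")) {
    expect_equal(sum(pairs$stage == st),
                 min(sum(surv$stage == st), sum(nons$stage == st)))
  }
  # matched subjects share stage and gender, and no pid repeats
  expect_false(anyDuplicated(pairs$survivor_pid) > 0)
  expect_false(anyDuplicated(pairs$nonsurvivor_pid) > 0)
  s_at <- surv[match(pairs$survivor_pid, surv$pid), ]
  n_at <- nons[match(pairs$nonsurvivor_pid, nons$pid), ]
  expect_identical(as.character(s_at$stage), as.character(n_at$stage))
  expect_identical(as.character(s_at$gender), as.character(n_at$gender))
})

test_that("optimal total distance never exceeds greedy", {
  cc <- default_cohort()
  greedy <- nsm_match(cc$ex$survivors, cc$ex$nonsurvivors,
                      match_config(method = "greedy"))
  expect_lte(sum(cc$mc$pairs$distance), sum(greedy$pairs$distance))
})

test_that("matching reduces a planted age imbalance", {
  mk_groups <- function(seed, shift) {
    set.seed(seed)
    mk <- function(n, prefix, age_mean) data.frame(
      pid = sprintf("%s%03d", prefix, seq_len(n)),
      age = rnorm(n, age_mean, 5),
      gender = sample(c("male", "female"), n, replace = TRUE),
      height = rnorm(n, 1.7, 0.1), weight = rnorm(n, 80, 10),
      pkyr = rnorm(n, 55, 15), stage = sample(c("I", "II"), n,
                                              replace = TRUE),
      candx_days = 100, fup_days = round(runif(n, 500, 2000)),
      stringsAsFactors = FALSE)
    list(surv = mk(120, "s", 64), nons = mk(40, "n", 64 + shift))
  }
  worse <- 0L
  for (seed in 1:20) {
    g <- mk_groups(seed, shift = 5)
    mc <- nsm_match(g$surv, g$nons)
    bal <- mc$balance
    age <- bal[bal$criterion == "age", ]
    if (age$smd_post > age$smd_pre) worse <- worse + 1L
    expect_lt(age$smd_post, age$smd_pre + 1e-9)
  }
  expect_equal(worse, 0L)
})

test_that("perfect pairs give zero post-match SMDs; one pair works", {
  mk <- function(pid, age) data.frame(
    pid = pid, age = age, gender = "female", height = 1.6, weight = 70,
    pkyr = 40, stage = "II", candx_days = 50, fup_days = 900,
    stringsAsFactors = FALSE)
  surv <- rbind(mk("s1", 60), mk("s2", 70))
  nons <- rbind(mk("n1", 60), mk("n2", 70))
  cfg <- match_config(variances = c(age = 25, bmi = 1, pkyr = 1,
                                    survival_time = 1))
  mc <- nsm_match(surv, nons, cfg)
  expect_equal(mc$balance$smd_post, rep(0, 4))
  # degenerate single-pair cohort computes without error
  mc1 <- nsm_match(mk("s1", 60), mk("n1", 62), cfg)
  expect_equal(mc1$n_pairs, 1)
  expect_true(all(is.finite(mc1$balance$smd_post)))
})

test_that("strata missing on one side yield zero pairs, logged", {
  mk <- function(pid, stage) data.frame(
    pid = pid, age = 64, gender = "male", height = 1.7, weight = 80,
    pkyr = 50, stage = stage, candx_days = 0, fup_days = 700,
    stringsAsFactors = FALSE)
  cfg <- match_config(variances = c(age = 1, bmi = 1, pkyr = 1,
                                    survival_time = 1))
  mc <- nsm_match(rbind(mk("s1", "I"), mk("s2", "II")), mk("n1", "I"),
                  cfg)
  expect_equal(mc$n_pairs, 1)
  expect_true("II" %in% mc$empty_strata)
})
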