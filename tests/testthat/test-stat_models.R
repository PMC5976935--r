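test_that("ratios are exactly exp(coefficient) with CIs that bracket", {
  cc <- default_cohort()
  d <- matched_model_data(cc$ex, cc$mc)
  for (fit in list(fit_logistic(d), fit_cox(d))) {
    expect_identical(fit$ratio, exp(fit$coefficient))
    expect_true(all(fit$ci_lo <= fit$ratio & fit$ratio <= fit$ci_hi))
  }
})

test_that("default model spec has ten coefficient terms", {
  cc <- default_cohort()
  d <- matched_model_data(cc$ex, cc$mc)
  logit <- fit_logistic(d)
  cox <- fit_cox(d)
  expect_equal(attr(logit, "model_df"), 10)
  expect_equal(attr(cox, "model_df"), 10)
  expect_equal(nrow(logit), 10)
  # three CAC indicators against the "none" reference
  expect_equal(sum(grepl("cac_grade", logit$term)), 3)
  expect_gt(attr(logit, "model_chisq"), 0)
  expect_lt(attr(logit, "model_p"), 1)
  # indicator stage coding expands the df
  logit11 <- fit_logistic(d, analysis_spec(stage_coding = "indicator"))
  expect_equal(attr(logit11, "model_df"), 11)
})

test_that("logistic OR equals the 2x2 cross-product ratio", {
  d <- data.frame(y = rep(c(0, 1), each = 50),
                  x = rep(c(0, 1, 0, 1), c(40, 10, 20, 30)))
  fit <- fit_logistic(d, analysis_spec(outcome = "y", covariates = "x"))
  expect_equal(fit$ratio, (30 * 40) / (20 * 10), tolerance = 1e-6)
})

test_that("logistic regression recovers null and planted effects", {
  set.seed(81)
  n <- 2000
  d0 <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  d0$y <- rbinom(n, 1, 0.5)
  f0 <- fit_logistic(d0, analysis_spec(outcome = "y",
                                       covariates = c("x1", "x2")))
  expect_true(all(abs(f0$coefficient) <= 3 * f0$se))

  # planted log-odds of 0.23 per HU on a fat-attenuation-like covariate
  set.seed(82)
  n <- 5000
  fat <- rnorm(n, -92.5, 4.4)
  eta <- 0.23 * (fat - mean(fat))
  d1 <- data.frame(fat = fat, y = rbinom(n, 1, plogis(eta)))
  f1 <- fit_logistic(d1, analysis_spec(outcome = "y",
                                       covariates = "fat"))
  expect_lt(abs(f1$coefficient - 0.23), 3 * f1$se)
})

test_that("logistic errors on separation and rank deficiency", {
  d <- data.frame(y = rep(c(0, 1), each = 20),
                  x = rep(c(0, 1), each = 20))
  expect_error(fit_logistic(d, analysis_spec(outcome = "y",
                                             covariates = "x")),
               "separation")
  d2 <- data.frame(y = rbinom(40, 1, 0.5), a = rnorm(40))
  d2$b <- 2 * d2$a
  expect_error(fit_logistic(d2, analysis_spec(outcome = "y",
                                              covariates = c("a", "b"))),
               "rank deficient")
  expect_error(fit_logistic(data.frame(y = rep(1, 10), x = rnorm(10)),
                            analysis_spec(outcome = "y",
                                          covariates = "x")),
               "both classes")
})

test_that("Cox model recovers a planted hazard ratio of 2", {
  d <- make_survival_data(5000, c(trt = log(2)),
                          covariate_types = c(trt = "binary"),
                          seed = 83)
  fit <- fit_cox(d, analysis_spec(covariates = "trt",
                                  time = "time", event = "event"))
  expect_lt(abs(fit$coefficient - log(2)), 3 * fit$se)
  expect_identical(fit$ratio, exp(fit$coefficient))
})

test_that("Cox model refuses event-free data", {
  d <- make_survival_data(50, c(x = 0), seed = 84)
  d$event <- 0L
  expect_error(fit_cox(d, analysis_spec(covariates = "x",
                                        time = "time",
                                        event = "event")),
               "no events")
  d2 <- make_survival_data(50, c(x = 0), seed = 84)
  d2$time[1] <- -5
  expect_error(fit_cox(d2, analysis_spec(covariates = "x",
                                         time = "time",
                                         event = "event")), ">= 0")
})

test_that("group comparison matches the Welch formula", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  gc <- group_compare(a, b)
  # oracle: direct Welch evaluation
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tstat <- (mean(a) - mean(b)) / se
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(gc$p_value, 2 * stats::pt(-abs(tstat), df))
  expect_equal(gc$mean_diff, mean(a) - mean(b))

  gc0 <- group_compare(a, a)
  expect_equal(gc0$p_value, 1)
  expect_equal(gc0$mean_diff, 0)
  expect_error(group_compare(1, a), "at least 2")

  set.seed(85)
  gc1 <- group_compare(rnorm(200, 0, 1), rnorm(200, 1, 1))
  expect_lt(gc1$p_value, 0.001)
})

test_that("stratified analysis localises a planted stage-I deficit", {
  set.seed(86)
  mk <- function(n, stage, grp, mu) data.frame(
    stage = stage, group = grp, muscle_area = rnorm(n, mu, 5),
    pkyr = runif(n, 30, 90), copd = rbinom(n, 1, 0.3) == 1)
  d <- rbind(mk(60, "I", "survivor", 33), mk(60, "I", "nonsurvivor", 27),
             mk(60, "II", "survivor", 32),
             mk(60, "II", "nonsurvivor", 32))
  tab <- stratified_analysis(d, "muscle_area", "group", "stage")
  expect_lt(tab$p_value[tab$stratum == "I"], 0.01)
  expect_gt(tab$p_value[tab$stratum == "II"], 0.05)

  # constant stratifier reduces to the unstratified comparison
  d$one <- "all"
  tab1 <- stratified_analysis(d, "muscle_area", "group", "one")
  gc <- group_compare(d$muscle_area[d$group == "nonsurvivor"],
                      d$muscle_area[d$group == "survivor"])
  expect_equal(tab1$p_value, gc$p_value)

  # pack-year boundary: exactly 50 goes to the "<=50" stratum
  d$pkyr <- rep(c(50, 70), length.out = nrow(d))
  tab2 <- stratified_analysis(d, "muscle_area", "group", "pkyr50")
  expect_setequal(tab2$stratum, c("<=50", ">50"))
  d50 <- d[d$pkyr == 50, ]
  expect_equal(tab2$n_a[tab2$stratum == "<=50"],
               sum(d50$group == sort(unique(d$group))[1]))

  # a stratum missing one group is flagged, not dropped
  d2 <- rbind(mk(30, "I", "survivor", 33),
              mk(30, "I", "nonsurvivor", 30),
              mk(5, "III", "survivor", 33))
  tab3 <- stratified_analysis(d2, "muscle_area", "group", "stage")
  expect_true("III" %in% tab3$stratum)
  expect_true(is.na(tab3$p_value[tab3$stratum == "III"]))
  expect_match(tab3$note[tab3$stratum == "III"], "absent")
})
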