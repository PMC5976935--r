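#' Simulate survival data with known effect sizes
#'
#' Event times are exponential with hazard `baseline_hazard * exp(X beta)`
#' (a proportional-hazards model by construction, so the planted
#' coefficients are the true log hazard ratios).  Censoring, when
#' requested, is independent exponential with its rate calibrated so the
#' expected censored fraction equals `censor_rate` at the cohort's mean
#' hazard.
#'
#' @param n number of subjects.
#' @param true_betas named numeric vector of log hazard ratios; one
#'   covariate per entry.
#' @param censor_rate target censored fraction in `[0, 1)`; 0 disables
#'   censoring.
#' @param covariate_types optional character vector (names matching
#'   `true_betas`) with entries `"normal"` (standard normal, default) or
#'   `"binary"` (Bernoulli 0.5).
#' @param baseline_hazard events per day for a subject at `X = 0`.
#' @param seed integer seed; same seed, same dataset.
#' @return `data.frame` with the covariates plus `time` (days) and
#'   `event` (1 = observed, 0 = censored).
#' @examples
#' d <- make_survival_data(200, c(trt = log(2)),
#'                         covariate_types = c(trt = "binary"), seed = 1)
#' mean(d$event)
#' @export
make_survival_data <- function(n, true_betas, censor_rate = 0,
                               covariate_types = NULL,
                               baseline_hazard = 1 / 1000, seed = 1L) {
  if (n < 1) stop2("n must be >= 1")
  if (censor_rate < 0 || censor_rate >= 1)
    stop2("censor_rate must be in [0, 1)")
  nm <- names(true_betas)
  if (is.null(nm) || any(!nzchar(nm)))
    stop2("true_betas must be a named vector")
  types <- stats::setNames(rep("normal", length(nm)), nm)
  if (!is.null(covariate_types)) types[names(covariate_types)] <-
    covariate_types
  with_seed(seed, {
    X <- vapply(nm, function(v) {
      switch(types[[v]],
             normal = rnorm(n),
             binary = rbinom(n, 1, 0.5),
             stop2("unknown covariate type: ", types[[v]]))
    }, numeric(n))
    X <- matrix(X, nrow = n, dimnames = list(NULL, nm))
    hazard <- baseline_hazard * exp(drop(X %*% true_betas))
    t_event <- rexp(n, rate = hazard)
    if (censor_rate > 0) {
      cens_rate <- mean(hazard) * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n, rate = cens_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    out <- as.data.frame(X)
    out$time <- time
    out$event <- event
    out
  })
}
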