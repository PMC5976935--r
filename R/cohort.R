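# Cohort construction: derived fields, the screen-detected exclusion
# cascade, and variance-normalised optimal 1:1 survivor/nonsurvivor
# matching stratified on stage and gender.

#' Derive BMI and survival time
#'
#' Adds `bmi = weight / height^2` (kg/m^2) and `survival_time =
#' fup_days - candx_days` (days from diagnosis to death or last known
#' alive).  Rows missing any input get a missing derived value and are
#' flagged in the logical `derived_incomplete` column.
#'
#' @param roster a `subject_roster` data frame.
#' @return the roster with `bmi`, `survival_time` and
#'   `derived_incomplete` columns.
#' @examples
#' r <- data.frame(pid = "a", weight = 80, height = 1.7,
#'                 fup_days = 1000, candx_days = 100)
#' derive_fields(r)$bmi
#' @export
derive_fields <- function(roster) {
  df <- as.data.frame(roster)
  df$bmi <- df$weight / df$height^2
  df$survival_time <- df$fup_days - df$candx_days
  df$derived_incomplete <- is.na(df$bmi) | is.na(df$survival_time)
  class(df) <- c("subject_roster", "data.frame")
  df
}

#' Apply the cohort exclusion cascade
#'
#' Reproduces the analysis-population flow: keep screen-detected
#' cancers; classify survivors (`death_lc == "alive"`) and nonsurvivors
#' (lung-cancer-related deaths only - deaths from unrelated causes and
#' subjects with indeterminate status are excluded); drop subjects with
#' missing stage; drop stage IV from both groups.  Every rule logs how
#' many subjects it removed.
#'
#' @param roster a `subject_roster` data frame.
#' @return list with `survivors`, `nonsurvivors` (stage I-III only),
#'   `log` (data frame: rule, removed, remaining) and
#'   `eligible_nonsurvivors` - the lung-cancer-death count before stage
#'   filtering.
#' @export
apply_exclusions <- function(roster) {
  df <- as.data.frame(roster)
  log <- data.frame(rule = character(), removed = integer(),
                    remaining = integer(), stringsAsFactors = FALSE)
  note <- function(rule, removed, remaining) {
    log[nrow(log) + 1L, ] <<- list(rule, as.integer(removed),
                                   as.integer(remaining))
  }
  n0 <- nrow(df)
  df <- df[!is.na(df$screen_detected) & df$screen_detected, , drop = FALSE]
  note("not screen-detected", n0 - nrow(df), nrow(df))

  surv <- df[!is.na(df$death_lc) & df$death_lc == "alive", , drop = FALSE]
  nonsurv <- df[!is.na(df$death_lc) &
                  df$death_lc == "lung_cancer_death", , drop = FALSE]
  n_unrelated <- sum(!is.na(df$death_lc) &
                       df$death_lc == "unrelated_death")
  n_other <- nrow(df) - nrow(surv) - nrow(nonsurv) - n_unrelated
  note("death unrelated to lung cancer", n_unrelated,
       nrow(surv) + nrow(nonsurv) + n_other)
  note("indeterminate final status", n_other, nrow(surv) + nrow(nonsurv))
  eligible_nonsurvivors <- nrow(nonsurv)

  drop_stage <- function(g, label) {
    n_missing <- sum(is.na(g$stage) | !nzchar(as.character(g$stage)))
    g2 <- g[!is.na(g$stage) & nzchar(as.character(g$stage)), , drop = FALSE]
    note(paste0("missing stage (", label, ")"), n_missing, nrow(g2))
    n_iv <- sum(g2$stage == "IV")
    g3 <- g2[g2$stage != "IV", , drop = FALSE]
    note(paste0("stage IV (", label, ")"), n_iv, nrow(g3))
    g3
  }
  surv <- drop_stage(surv, "survivors")
  nonsurv <- drop_stage(nonsurv, "nonsurvivors")
  list(survivors = surv, nonsurvivors = nonsurv, log = log,
       eligible_nonsurvivors = eligible_nonsurvivors)
}

#' Matching configuration
#'
#' Six matching criteria: four continuous (age, BMI, pack-years,
#' survival time), each normalised by its pooled variance, plus exact
#' agreement on gender and stage.  Stage is enforced as the matching
#' stratum; gender as an exact within-stratum cell.
#'
#' @param continuous names of the continuous criteria.
#' @param exact names of exact-match categorical criteria.
#' @param stratum name of the stratum criterion.
#' @param variances optional named variances; pooled over all eligible
#'   subjects when `NULL` (the default, and the frozen definition).
#' @param method `"optimal"` (global minimum-total-distance assignment,
#'   the default) or `"greedy"` (sequential nearest available, for
#'   sensitivity analysis).
#' @return A `match_config` list.
#' @export
match_config <- function(continuous = c("age", "bmi", "pkyr",
                                        "survival_time"),
                         exact = "gender", stratum = "stage",
                         variances = NULL,
                         method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (!is.null(variances)) {
    if (any(variances <= 0)) stop2("criterion variances must be positive")
    if (!all(continuous %in% names(variances)))
      stop2("variances must be named after the continuous criteria")
  }
  structure(list(continuous = continuous, exact = exact,
                 stratum = stratum, variances = variances,
                 method = method),
            class = "match_config")
}

# Greedy sequential assignment on a cost matrix (rows <= cols):
# repeatedly take the globally cheapest remaining pair.
.greedy_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  assign <- integer(n)
  row_free <- rep(TRUE, n); col_free <- rep(TRUE, m)
  for (step in seq_len(n)) {
    sub <- cost
    sub[!row_free, ] <- Inf
    sub[, !col_free] <- Inf
    idx <- which.min(sub)           # first minimum: deterministic ties
    i <- (idx - 1L) %% n + 1L
    j <- (idx - 1L) %/% n + 1L
    assign[i] <- j
    row_free[i] <- FALSE; col_free[j] <- FALSE
  }
  assign
}

#' Variance-normalised 1:1 matching of survivors to nonsurvivors
#'
#' Within each (stage, gender) cell, pairwise distances are
#' `d(i, j) = sqrt(sum_c (x_ic - x_jc)^2 / var_c)` over the continuous
#' criteria, with variances pooled over all eligible subjects of both
#' groups (so distances are invariant to affine rescaling of any
#' criterion).  A global minimum-total-distance 1:1 assignment is solved
#' per cell; the pair count per cell is the smaller group size, so every
#' possible match is used.  Subjects are pid-sorted first, making the
#' output invariant to input row order; records missing any criterion
#' are dropped and logged.
#'
#' @param survivors,nonsurvivors `subject_roster` data frames (after
#'   [apply_exclusions()]).
#' @param config a [match_config()].
#' @return A `matched_cohort`: list with `pairs` (survivor_pid,
#'   nonsurvivor_pid, stage, gender, distance), `balance` (see
#'   [balance_check()]), `variances`, `n_pairs`, `dropped_incomplete`.
#' @examples
#' ex <- apply_exclusions(make_roster(roster_config(seed = 1)))
#' mc <- nsm_match(ex$survivors, ex$nonsurvivors)
#' mc$n_pairs
#' @export
nsm_match <- function(survivors, nonsurvivors, config = match_config()) {
  stopifnot(inherits(config, "match_config"))
  if (nrow(survivors) == 0 || nrow(nonsurvivors) == 0)
    stop2("both groups must be nonempty after exclusions")
  prep <- function(g) {
    g <- as.data.frame(g)
    if (!all(c("bmi", "survival_time") %in% names(g)))
      g <- derive_fields(g)
    g[order(g$pid), , drop = FALSE]
  }
  surv <- prep(survivors)
  nons <- prep(nonsurvivors)
  crit <- config$continuous
  complete <- function(g) !Reduce(`|`, lapply(c(crit, config$exact,
                                                config$stratum),
                                              function(v) is.na(g[[v]])))
  ok_s <- complete(surv); ok_n <- complete(nons)
  dropped <- sum(!ok_s) + sum(!ok_n)
  surv <- surv[ok_s, , drop = FALSE]
  nons <- nons[ok_n, , drop = FALSE]

  vars <- config$variances
  if (is.null(vars)) {
    pooled <- rbind(surv[, crit, drop = FALSE], nons[, crit, drop = FALSE])
    vars <- vapply(pooled, var, numeric(1))
    if (any(vars <= 0))
      stop2("pooled variance is zero for criterion: ",
            paste(crit[vars <= 0], collapse = ", "))
  }
  vars <- vars[crit]

  cell_key <- function(g) interaction(g[[config$stratum]],
                                      g[[config$exact]], drop = TRUE)
  pairs <- list()
  empty_strata <- character()
  for (st in sort(unique(c(as.character(surv[[config$stratum]]),
                           as.character(nons[[config$stratum]]))))) {
    s_st <- surv[surv[[config$stratum]] == st, , drop = FALSE]
    n_st <- nons[nons[[config$stratum]] == st, , drop = FALSE]
    if (nrow(s_st) == 0 || nrow(n_st) == 0) {
      empty_strata <- c(empty_strata, st)
      next
    }
    for (gx in sort(unique(c(as.character(s_st[[config$exact]]),
                             as.character(n_st[[config$exact]]))))) {
      s_cell <- s_st[s_st[[config$exact]] == gx, , drop = FALSE]
      n_cell <- n_st[n_st[[config$exact]] == gx, , drop = FALSE]
      if (nrow(s_cell) == 0 || nrow(n_cell) == 0) next
      xs <- as.matrix(s_cell[, crit, drop = FALSE])
      xn <- as.matrix(n_cell[, crit, drop = FALSE])
      xs <- sweep(xs, 2, sqrt(vars), "/")
      xn <- sweep(xn, 2, sqrt(vars), "/")
      cost <- outer(rowSums(xs^2), rowSums(xn^2), "+") -
        2 * tcrossprod(xs, xn)
      cost <- sqrt(pmax(cost, 0))
      transposed <- nrow(cost) > ncol(cost)
      if (transposed) cost <- t(cost)
      assign <- if (config$method == "optimal") solve_lsap_cpp(cost)
                else .greedy_assign(cost)
      rows <- seq_len(nrow(cost))
      if (transposed) {
        s_idx <- assign; n_idx <- rows
      } else {
        s_idx <- rows; n_idx <- assign
      }
      d <- cost[cbind(rows, assign)]
      pairs[[length(pairs) + 1L]] <- data.frame(
        survivor_pid = s_cell$pid[s_idx],
        nonsurvivor_pid = n_cell$pid[n_idx],
        stage = st, gender = gx, distance = d,
        stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0) stop2("no matchable (stage, gender) cells")
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$survivor_pid), , drop = FALSE]
  rownames(pairs) <- NULL
  out <- structure(
    list(pairs = pairs, variances = vars,
         n_pairs = nrow(pairs),
         dropped_incomplete = dropped,
         empty_strata = empty_strata,
         balance = NULL),
    class = "matched_cohort")
  out$balance <- balance_check(out, surv, nons, config)
  out
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d pairs (%d subjects)\n",
              x$n_pairs, 2L * x$n_pairs))
  tab <- table(x$pairs$stage)
  cat("  pairs per stage:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  mean normalized distance %.3f\n", mean(x$pairs$distance)))
  invisible(x)
}

# Standardized mean difference with the pooled-SD denominator.
.smd <- function(a, b) {
  s <- sqrt((var(a) + var(b)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  abs(mean(a) - mean(b)) / s
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference (SMD) per continuous criterion across
#' the two groups, before matching (all eligible subjects) and after
#' (matched subjects only).
#'
#' @param cohort a `matched_cohort` from [nsm_match()].
#' @param survivors,nonsurvivors the pre-matching eligible groups (with
#'   derived fields; [derive_fields()] is applied if missing).
#' @param config the [match_config()] used.
#' @return data frame: `criterion`, `smd_pre`, `smd_post`.
#' @export
balance_check <- function(cohort, survivors, nonsurvivors,
                          config = match_config()) {
  stopifnot(inherits(cohort, "matched_cohort"))
  if (nrow(cohort$pairs) == 0) stop2("empty matched cohort")
  prep <- function(g) {
    g <- as.data.frame(g)
    if (!all(c("bmi", "survival_time") %in% names(g))) g <- derive_fields(g)
    g
  }
  surv <- prep(survivors); nons <- prep(nonsurvivors)
  ms <- surv[match(cohort$pairs$survivor_pid, surv$pid), , drop = FALSE]
  mn <- nons[match(cohort$pairs$nonsurvivor_pid, nons$pid), , drop = FALSE]
  crit <- config$continuous
  data.frame(
    criterion = crit,
    smd_pre = vapply(crit, function(v)
      .smd(surv[[v]][!is.na(surv[[v]])], nons[[v]][!is.na(nons[[v]])]),
      numeric(1)),
    smd_post = vapply(crit, function(v) .smd(ms[[v]], mn[[v]]),
                      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
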