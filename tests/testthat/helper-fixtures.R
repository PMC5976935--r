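# Shared fixtures, built in code at test time.

# A small, fast phantom used where exact geometry does not matter.
quick_phantom <- function(seed = 1, ...) {
  make_phantom(phantom_config(grid = c(128, 128), seed = seed, ...))
}

# Eligible groups and matched cohort from the default synthetic roster.
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      roster <- make_roster(roster_config(seed = 1))
      ex <- apply_exclusions(roster)
      mc <- nsm_match(ex$survivors, ex$nonsurvivors)
      cache <<- list(roster = roster, ex = ex, mc = mc)
    }
    cache
  }
})

# Matched-cohort rows joined with outcome columns for the model stage.
matched_model_data <- function(ex, mc) {
  surv <- derive_fields(ex$survivors)
  nons <- derive_fields(ex$nonsurvivors)
  out <- rbind(
    transform(surv[match(mc$pairs$survivor_pid, surv$pid), ],
              nonsurvivor = 0L),
    transform(nons[match(mc$pairs$nonsurvivor_pid, nons$pid), ],
              nonsurvivor = 1L))
  out$event <- out$nonsurvivor
  out
}

# Roster CSV with the trial master-sheet headers, written to a temp file.
write_nlst_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  path
}

# Brute-force minimum-cost assignment by permutation enumeration (n <= 6).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n <= 6, n <= ncol(cost))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    cols <- p[seq_len(n)]
    tot <- sum(cost[cbind(seq_len(n), cols)])
    if (tot < best) best <- tot
  }
  best
}
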