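#' Lottery amounts used in the risky decision-making task
#'
#' The 21 unique dollar amounts offered as lottery outcomes, from $4 to $66.
#' The $4 amount appears only on the catch trial that opens each run (it is
#' first-order stochastically dominated by the certain $5 option); the
#' remaining 20 amounts are crossed with the six uncertainty levels.
#'
#' @return Numeric vector of 21 dollar amounts in ascending order.
#' @seealso [build_choice_set()], [uncertainty_levels()]
#' @export
#' @examples
#' amount_list()
amount_list <- function() {
  c(4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 23, 26, 30, 34, 39, 44, 50,
    57, 66)
}

#' Uncertainty levels of the choice task
#'
#' Three known-risk levels (explicit win probabilities 25, 50, 75%) and three
#' ambiguity levels (occluded fractions 24, 50, 74% of an objectively 50%
#' lottery).
#'
#' @return A data frame with columns `context` ("risk"/"ambiguity"), `p`
#'   (objective win probability) and `A` (occluded fraction; 0 on risk
#'   trials).
#' @export
uncertainty_levels <- function() {
  data.frame(
    context = rep(c("risk", "ambiguity"), each = 3L),
    p = c(0.25, 0.50, 0.75, 0.50, 0.50, 0.50),
    A = c(0, 0, 0, 0.24, 0.50, 0.74),
    stringsAsFactors = FALSE
  )
}

# Fixed trial timing (seconds). Display 4 s, response window 2 s,
# confirmation 0.5 s; the ITI jitter is 5 +/- 0.75 s plus a (2 - RT)
# compensation that makes total trial length response-independent, so onsets
# only need the jitter draw.
.TRIAL_FIXED_S <- 4 + 2 + 0.5
.JITTER_RANGE_S <- c(4.25, 5.75)
.SAFE_VALUE <- 5
.DECISION_S <- 4

#' Build the full trial schedule of the choice task
#'
#' Generates the task's choice set: each of the 20 non-catch lottery amounts
#' paired once with each of the 6 uncertainty levels (120 unique trials at
#' four runs), randomly ordered in equal shares of 30 per run, plus one
#' dominated $4 catch trial (p = 50%, no ambiguity) opening each run, for 124
#' trials in total. Onsets accumulate the fixed 6.5 s display/response/
#' confirmation sequence plus a uniform jitter on [4.25, 5.75] s.
#'
#' With `n_runs` other than 4 the schedule keeps 30 non-catch trials per run:
#' for `n_runs` a multiple of 4 every (amount, level) pair appears
#' `n_runs / 4` times; for smaller `n_runs` a seeded subset of pairs is used.
#'
#' @param n_runs Number of runs (default 4).
#' @param seed Integer seed; the schedule is fully reproducible from it.
#' @return A `trial_schedule` data frame with one row per trial and columns
#'   `trial_id`, `run_id`, `position`, `context`, `p`, `A`, `v`,
#'   `safe_value`, `is_catch`, `onset_s`, `duration_s`. Attributes: `n_runs`,
#'   `seed`, `run_duration_s` (per-run duration in seconds).
#' @export
#' @examples
#' sched <- build_choice_set(4, seed = 1)
#' nrow(sched)           # 124
#' sum(!sched$is_catch)  # 120
build_choice_set <- function(n_runs = 4L, seed = 1L) {
  if (length(n_runs) != 1L || !is.finite(n_runs) || n_runs < 1 ||
      n_runs != round(n_runs)) {
    stop("`n_runs` must be a positive integer")
  }
  n_runs <- as.integer(n_runs)
  stopifnot(length(seed) == 1L, is.finite(seed))

  levels <- uncertainty_levels()
  amounts <- setdiff(amount_list(), 4)
  grid <- expand.grid(v = amounts, level = seq_len(nrow(levels)),
                      KEEP.OUT.ATTRS = FALSE)
  per_run <- 30L
  n_noncatch <- per_run * n_runs

  withr::with_seed(as.integer(seed), {
    n_rep <- n_noncatch %/% nrow(grid)
    n_extra <- n_noncatch %% nrow(grid)
    rows <- rep(seq_len(nrow(grid)), n_rep)
    if (n_extra > 0) rows <- c(rows, sample(seq_len(nrow(grid)), n_extra))
    rows <- sample(rows) # random order; cut into equal run shares
    run_of <- rep(seq_len(n_runs), each = per_run)

    trials <- vector("list", n_runs)
    run_duration <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      idx <- rows[run_of == r]
      df <- data.frame(
        run_id = r,
        position = seq_len(per_run + 1L),
        context = c("risk", levels$context[grid$level[idx]]),
        p = c(0.5, levels$p[grid$level[idx]]),
        A = c(0, levels$A[grid$level[idx]]),
        v = c(4, grid$v[idx]),
        safe_value = .SAFE_VALUE,
        is_catch = c(TRUE, rep(FALSE, per_run)),
        stringsAsFactors = FALSE
      )
      jitter <- stats::runif(nrow(df), .JITTER_RANGE_S[1], .JITTER_RANGE_S[2])
      step <- .TRIAL_FIXED_S + jitter
      df$onset_s <- cumsum(c(0, step[-length(step)]))
      df$duration_s <- .DECISION_S
      run_duration[r] <- df$onset_s[nrow(df)] + step[length(step)]
      trials[[r]] <- df
    }
    out <- do.call(rbind, trials)
  })

  out$trial_id <- seq_len(nrow(out))
  out <- out[, c("trial_id", "run_id", "position", "context", "p", "A", "v",
                 "safe_value", "is_catch", "onset_s", "duration_s")]
  rownames(out) <- NULL
  structure(out,
            n_runs = n_runs, seed = as.integer(seed),
            run_duration_s = run_duration,
            class = c("trial_schedule", "data.frame"))
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("Trial schedule: %d trials, %d runs (%d catch), seed %d\n",
              nrow(x), attr(x, "n_runs"), sum(x$is_catch), attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}
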