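# Shared synthetic fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Small full session: 8 units, 12 correct trials per condition cell.
small_session <- function() {
  if (is.null(fixture_env$session)) {
    tc <- task_config(trials_per_condition = 12L)
    un <- ground_truth_units(8, seed = 101)
    fixture_env$session <- generate_session(tc, un, seed = 102)
  }
  fixture_env$session
}

# Brute-force AUROC oracle: exhaustive pair counting.
auroc_bruteforce <- function(rf, away) {
  wins <- 0
  for (a in rf) for (b in away)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(rf) * length(away))
}
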