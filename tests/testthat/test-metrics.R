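# AUROC, DrugMI, Cohen's D-prime, ANOVA gating, response types, population
# summaries.

test_that("AUROC equals exhaustive pair counting on random inputs", {
  # spec-level property: exact agreement with the brute-force oracle for
  # every input up to 50 trials/side
  set.seed(111)
  for (i in 1:60) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    rf <- sample(0:15, n1, replace = TRUE) / sample(c(1, 2, 4), 1)
    away <- sample(0:15, n2, replace = TRUE)
    expect_equal(auroc(rf, away), auroc_bruteforce(rf, away),
                 tolerance = 1e-12)
  }
  # worked example: rf = [2,3,4], away = [1,2,3] -> (6 + 0.5*2)/9
  expect_equal(auroc(c(2, 3, 4), c(1, 2, 3)), 7 / 9, tolerance = 1e-12)
  # symmetry and boundaries
  expect_equal(auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auroc(c(10, 11), c(1, 2)), 1)
  expect_true(is.na(auroc(numeric(0), c(1, 2))))
})

test_that("auroc_flip folds on the no-drug value only", {
  fl <- auroc_flip(c(0.4, 0.6, 0.5), c(0.45, 0.55, 0.3))
  expect_equal(fl$auroc_nodrug, c(0.6, 0.6, 0.5))
  expect_equal(fl$auroc_drug, c(0.55, 0.55, 0.3))
  expect_equal(fl$flipped, c(TRUE, FALSE, FALSE))
})

test_that("DrugMI matches the printed formula and is antisymmetric", {
  expect_equal(drug_mi(10, 10), 0)
  expect_equal(drug_mi(10, 0), 1)
  expect_equal(drug_mi(30, 21), 9 / 51, tolerance = 1e-12)
  expect_true(is.na(drug_mi(0, 0)))
  set.seed(112)
  a <- runif(20, 0, 50); b <- runif(20, 0, 50)
  expect_equal(drug_mi(a, b), -drug_mi(b, a))
  expect_true(all(abs(drug_mi(a, b)) <= 1))
})

test_that("Cohen's D-prime: formula and estimator recovery", {
  expect_equal(cohens_dprime(c(1, 2, 3), c(1, 2, 3)), 0)
  # means 12 vs 10, pooled SD 4 -> 0.5
  rf <- c(8, 12, 16); aw <- c(6, 10, 14)   # sd 4 each, means 12 / 10
  expect_equal(cohens_dprime(rf, aw), 0.5, tolerance = 1e-12)
  expect_true(is.na(cohens_dprime(c(2, 2), c(2, 2))))
  # planted standardized effect 0.8, n = 60/side: mean estimate 0.8 +- 0.03
  set.seed(113)
  est <- vapply(1:1000, function(i)
    cohens_dprime(rnorm(60, 0.8), rnorm(60, 0)), numeric(1))
  expect_equal(mean(est), 0.8, tolerance = 0.03)
})

test_that("response-type rules reproduce the worked examples", {
  expect_equal(classify_response_type(10, 20, 12), "visual")
  expect_equal(classify_response_type(10, 15, 16), "visuo-attention")
  expect_equal(classify_response_type(10, 11, 13), "attention")
  expect_equal(classify_response_type(10, 10.5, 10), "other")
  # zero baseline handled via the additive floor
  expect_equal(classify_response_type(0, 5, 1), "visual")
})

test_that("planted response types are recovered through the pipeline", {
  tc <- task_config(trials_per_condition = 30L)
  un <- ground_truth_units(12, gain_variance = 0.05, seed = 114)
  s <- generate_session(tc, un, seed = 115, eye_args = NULL)
  tr <- filter_trials(s$trials)
  r <- epoch_rates(s$spikes, tr)
  rf_tr <- tr$trial_id[tr$attention == "RF" & tr$drug == "off"]
  nod <- tr$trial_id[tr$drug == "off"]
  got <- vapply(un$unit_id, function(u) {
    ru <- r[r$unit_id == u, ]
    base <- mean(ru$rate[ru$epoch == "baseline" & ru$trial_id %in% nod])
    trans <- mean(ru$rate[ru$epoch == "post_stim" & ru$trial_id %in% nod])
    pre <- mean(ru$rate[ru$epoch == "pre_dim" & ru$trial_id %in% rf_tr])
    classify_response_type(base, trans, pre)
  }, character(1))
  expect_gte(mean(got == un$response_type_true), 0.75)
})

test_that("anova_gate flags planted effects and excludes degenerate units", {
  set.seed(116)
  mk_unit <- function(uid, att_gain, drug_gain, n = 30) {
    grid <- expand.grid(attention = c("RF", "away1", "away2"),
                        motion = c("dir1", "dir2"), drug = c("off", "on"),
                        rep = seq_len(n), stringsAsFactors = FALSE)
    mu <- 10 * ifelse(grid$attention == "RF", att_gain, 1) *
      ifelse(grid$drug == "on", drug_gain, 1)
    grid$rate <- rpois(nrow(grid), mu * 0.5) / 0.5
    grid$trial_id <- seq_len(nrow(grid)) + match(uid, c("a", "b")) * 10000
    grid$unit_id <- uid
    grid
  }
  df <- rbind(mk_unit("a", 1.5, 1), mk_unit("b", 1, 0.7))
  rates <- data.frame(unit_id = df$unit_id, trial_id = df$trial_id,
                      epoch = "pre_dim", spike_count = df$rate * 0.5,
                      duration_s = 0.5, rate = df$rate)
  trials <- df[, c("trial_id", "attention", "motion", "drug")]
  g <- anova_gate(rates, trials)
  expect_true(g$attention_modulated[g$unit_id == "a"])
  expect_false(g$drug_modulated[g$unit_id == "a"] &&
                 g$p_drug[g$unit_id == "a"] < 0.001)  # no planted drug effect
  expect_true(g$drug_modulated[g$unit_id == "b"])
  # zero-variance unit is excluded
  rates0 <- rates[rates$unit_id == "a", ]
  rates0$rate <- 5; rates0$unit_id <- "z"
  expect_null(anova_gate(rates0, trials))
})

test_that("population histogram normalizes per-unit peaks", {
  p <- rbind(u1 = c(1, 5, 10, 5), u2 = c(2, 10, 20, 10))
  h <- population_histogram(p)
  # same shape at different amplitude: identical contribution, SEM 0
  expect_equal(h$mean, c(0.1, 0.5, 1, 0.5))
  expect_equal(h$sem, c(0, 0, 0, 0))
  # single unit: its own normalized PSTH with peak 1
  h1 <- population_histogram(p[1, , drop = FALSE])
  expect_equal(max(h1$mean), 1)
  expect_warning(population_histogram(rbind(p, u3 = c(0, 0, 0, 0))),
                 "all-zero")
})

test_that("BH adjustment reproduces the step-up thresholds", {
  r <- fdr_adjust(c(0.01, 0.02, 0.04), q = 0.05)
  expect_true(all(r$rejected))
  expect_false(any(fdr_adjust(rep(1, 5))$rejected))
  expect_equal(fdr_adjust(0.03)$adjusted, 0.03)
  expect_false(all(fdr_adjust(c(0.01, 0.04, 0.2))$rejected))
})

test_that("population_tests returns sane paired statistics on a plant", {
  set.seed(117)
  n <- 40
  m <- data.frame(unit_id = sprintf("u%02d", 1:n), epoch = "pre_dim",
                  auroc_nodrug = runif(n, 0.55, 0.9))
  m$auroc_drug <- m$auroc_nodrug + rnorm(n, 0, 0.02)
  m$auroc_nodrug_flipped <- m$auroc_nodrug
  m$auroc_drug_flipped <- m$auroc_drug
  m$drug_mi <- rnorm(n, 0.15, 0.17)
  groups <- rep(c("narrow", "broad"), each = n / 2)
  pt <- population_tests(m, groups)
  expect_equal(nrow(pt$per_group), 2)
  expect_true(all(pt$per_group$mi_t > 0))
  expect_true(any(grepl("drugstate", pt$anova$term)))
  expect_true(all(pt$anova$eta2p >= 0 & pt$anova$eta2p <= 1))
  # degenerate group skipped
  pt2 <- population_tests(m, c("solo", groups[-1]))
  expect_false("solo" %in% pt2$per_group$group)
})
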