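# Per-unit and population quantification of attention and drug effects.

#' Area under the ROC curve between two rate distributions
#'
#' Probability that a random attend-RF trial rate exceeds a random
#' attend-away trial rate, ties counted one half (the Mann-Whitney
#' correspondence): `AUROC = [#(rf > away) + 0.5 #(rf = away)] / (n1 n2)`.
#' Both attend-away locations are pooled by the caller.
#'
#' @param rf Rates (spikes/s) on attend-RF trials.
#' @param away Rates on attend-away trials.
#' @return AUROC in [0, 1], or `NA` if either side has fewer than 2 trials.
#' @export
auroc <- function(rf, away) {
  rf <- rf[is.finite(rf)]; away <- away[is.finite(away)]
  if (length(rf) < 2 || length(away) < 2) return(NA_real_)
  r <- rank(c(rf, away))
  n1 <- length(rf)
  # Mann-Whitney U from the rank sum of the rf sample (midranks handle ties)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * length(away))
}

#' Fold AUROC pairs for cells preferring the attend-away condition
#'
#' Units whose no-drug AUROC is below 0.5 (attention reduces their firing)
#' have both conditions transformed `x -> 1 - x`; the flip decision is made
#' on the no-drug value only (strict inequality, 0.5 unchanged).
#'
#' @param auroc_nodrug,auroc_drug Paired per-unit AUROCs.
#' @return data.frame `auroc_nodrug`, `auroc_drug`, `flipped`.
#' @export
auroc_flip <- function(auroc_nodrug, auroc_drug) {
  stopifnot(length(auroc_nodrug) == length(auroc_drug))
  flip <- !is.na(auroc_nodrug) & auroc_nodrug < 0.5
  data.frame(
    auroc_nodrug = ifelse(flip, 1 - auroc_nodrug, auroc_nodrug),
    auroc_drug = ifelse(flip, 1 - auroc_drug, auroc_drug),
    flipped = flip)
}

#' Drug modulation index
#'
#' `DrugMI = (Activity_no_drug - Activity_drug) /
#'           (Activity_no_drug + Activity_drug)`, bounded in [-1, 1];
#' positive when the drug suppresses firing. Undefined (NA) when both
#' activities are zero.
#'
#' @param rate_nodrug,rate_drug Mean rates (spikes/s), vectorised.
#' @return MI values in [-1, 1].
#' @export
drug_mi <- function(rate_nodrug, rate_drug) {
  stopifnot(all(rate_nodrug >= 0, na.rm = TRUE),
            all(rate_drug >= 0, na.rm = TRUE))
  s <- rate_nodrug + rate_drug
  ifelse(s == 0, NA_real_, (rate_nodrug - rate_drug) / s)
}

#' Cohen's D-prime between attention conditions
#'
#' `(mean rate attend RF - mean rate attend away) / pooled SD`, pooled SD
#' with n-1 weighting; positive when the attend-RF mean is larger.
#'
#' @param rf,away Trial rates per side (>= 2 each).
#' @return D-prime, or NA when the pooled SD is zero.
#' @export
cohens_dprime <- function(rf, away) {
  rf <- rf[is.finite(rf)]; away <- away[is.finite(away)]
  if (length(rf) < 2 || length(away) < 2) return(NA_real_)
  sp2 <- ((length(rf) - 1) * stats::var(rf) +
            (length(away) - 1) * stats::var(away)) /
    (length(rf) + length(away) - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(rf) - mean(away)) / sqrt(sp2)
}

#' Three-factor ANOVA gating of attention- and drug-modulated units
#'
#' Fixed-effects attention x drug x motion ANOVA on single-trial rates in
#' the pre-dimming epoch, per unit. A unit is attention-modulated if the
#' attention main effect or any interaction involving attention is
#' significant (p < alpha); drug-modulated analogously for the drug factor.
#'
#' @param rates [epoch_rates()] table restricted (internally) to the
#'   `pre_dim` epoch.
#' @param trials Filtered trial table supplying the factors.
#' @param alpha Significance level. Default 0.05.
#' @param min_trials Minimum trials per attention x motion x drug cell.
#' @return data.frame per unit: significance flags, p-values and partial
#'   eta squared for all terms.
#' @export
anova_gate <- function(rates, trials, alpha = 0.05, min_trials = 10L) {
  pre <- rates[rates$epoch == "pre_dim", ]
  units <- unique(pre$unit_id)
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[i]
    df <- merge(pre[pre$unit_id == u, ],
                trials[, c("trial_id", "attention", "motion", "drug")],
                by = "trial_id")
    cell_n <- table(df$attention, df$motion, df$drug)
    if (any(cell_n == 0)) { out[[i]] <- NULL; next }  # empty cell: exclude
    if (stats::var(df$rate) == 0) { out[[i]] <- NULL; next } # degenerate
    res <- anova_three_way(df)
    att_terms <- grepl("attention", res$term)
    drug_terms <- grepl("drug", res$term)
    out[[i]] <- data.frame(
      unit_id = u,
      attention_modulated = any(res$p[att_terms] < alpha),
      drug_modulated = any(res$p[drug_terms] < alpha),
      excluded = min(cell_n) < min_trials,
      p_attention = res$p[res$term == "attention"],
      p_drug = res$p[res$term == "drug"],
      p_motion = res$p[res$term == "motion"],
      p_att_x_drug = res$p[res$term == "attention:drug"],
      eta2p_attention = res$eta2p[res$term == "attention"],
      eta2p_drug = res$eta2p[res$term == "drug"],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Type II three-way fixed-effects ANOVA on `rate ~ attention*drug*motion`.
# The synthetic design is balanced by construction (imbalance only via error
# re-queueing), where Type I/II/III coincide; drop1-based Type II sums of
# squares keep mild imbalance honest.
anova_three_way <- function(df) {
  df$attention <- factor(df$attention); df$drug <- factor(df$drug)
  df$motion <- factor(df$motion)
  full <- stats::lm(rate ~ attention * drug * motion, data = df)
  ss_res <- sum(stats::residuals(full)^2)
  df_res <- full$df.residual
  terms_all <- attr(stats::terms(full), "term.labels")
  ss <- p <- dfn <- numeric(length(terms_all))
  for (j in seq_along(terms_all)) {
    tm <- terms_all[j]
    # Type II: compare against the model containing all terms that do not
    # include tm, of order <= containing relations
    others <- terms_all[!vapply(terms_all, function(o)
      all(strsplit(tm, ":")[[1]] %in% strsplit(o, ":")[[1]]), logical(1))]
    f_with <- stats::as.formula(paste("rate ~", paste(c(others, tm),
                                                      collapse = "+")))
    f_without <- if (length(others))
      stats::as.formula(paste("rate ~", paste(others, collapse = "+")))
    else stats::as.formula("rate ~ 1")
    m1 <- stats::lm(f_with, data = df); m0 <- stats::lm(f_without, data = df)
    ss[j] <- sum(stats::residuals(m0)^2) - sum(stats::residuals(m1)^2)
    dfn[j] <- m0$df.residual - m1$df.residual
    fstat <- (ss[j] / dfn[j]) / (ss_res / df_res)
    p[j] <- stats::pf(fstat, dfn[j], df_res, lower.tail = FALSE)
  }
  data.frame(term = terms_all, ss = ss, df = dfn, p = p,
             eta2p = ss / (ss + ss_res), stringsAsFactors = FALSE)
}

#' Classify a unit's response type from epoch rates
#'
#' Applies the 20-percent response-characteristic rules, in the order
#' visuo-attention, visual, attention, other:
#' \itemize{
#'   \item visuo-attention: at least 20% change upon stimulus onset, attend-RF
#'     pre-dimming rate at least 20% above baseline and at least as large as
#'     the stimulus transient;
#'   \item visual: at least 20% change upon stimulus onset, attend-RF
#'     pre-dimming rate at least 20% below the transient;
#'   \item attention: stimulus change below 20%, pre-dimming rate at least
#'     20% above baseline and at least as large as the transient;
#'   \item other: everything else.
#' }
#' Zero baselines are floored at `floor_rate` before computing percentages.
#'
#' @param baseline Pre-stimulus rate (spikes/s).
#' @param transient Post-stimulus (100-400 ms) rate.
#' @param predim_rf Attend-RF pre-dimming rate.
#' @param floor_rate Additive floor for zero baselines. Default 0.5.
#' @return One of `"visual"`, `"visuo-attention"`, `"attention"`, `"other"`.
#' @export
classify_response_type <- function(baseline, transient, predim_rf,
                                   floor_rate = 0.5) {
  b <- max(baseline, floor_rate)
  stim_change <- abs(transient - b) / b
  if (stim_change >= 0.2 && predim_rf >= 1.2 * b && predim_rf >= transient)
    return("visuo-attention")
  if (stim_change >= 0.2 && predim_rf <= 0.8 * transient)
    return("visual")
  if (stim_change < 0.2 && predim_rf >= 1.2 * b && predim_rf >= transient)
    return("attention")
  "other"
}

#' Peak-normalized population histogram
#'
#' Each unit's PSTH is divided by its own peak before averaging; the
#' population trace is the across-unit mean with SEM. All-zero units are
#' excluded with a warning.
#'
#' @param psths Numeric matrix, units x time bins (common bin grid).
#' @return List: `mean`, `sem` (per bin), `n_units`.
#' @export
population_histogram <- function(psths) {
  psths <- as.matrix(psths)
  peaks <- apply(psths, 1, max)
  if (any(peaks == 0)) {
    warning(sum(peaks == 0), " all-zero unit(s) excluded")
    psths <- psths[peaks > 0, , drop = FALSE]
    peaks <- peaks[peaks > 0]
  }
  norm <- sweep(psths, 1, peaks, "/")
  list(mean = colMeans(norm),
       sem = apply(norm, 2, stats::sd) / sqrt(nrow(norm)),
       n_units = nrow(norm))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjusted p-values (monotone); the rejection set at level
#' `q` is `adjusted <= q`.
#'
#' @param p P-values in [0, 1].
#' @param q FDR level. Default 0.05.
#' @return List: `adjusted`, `rejected`.
#' @export
fdr_adjust <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Per-unit attention/drug metrics table
#'
#' Computes, for every unit and epoch: AUROC (attend-RF versus pooled
#' attend-away) separately for no-drug and drug trials, flipped variants,
#' Cohen's D-prime for both drug states, and the DrugMI averaged across the
#' six attention x motion conditions. Pre-dimming ANOVA gating flags are
#' merged in.
#'
#' @param session A `fef_session`, or a list with `spikes` and `trials`.
#' @param windows Epoch windows. Default [epoch_windows()].
#' @return data.frame, one row per unit x epoch (`MetricsRow`).
#' @export
unit_metrics <- function(session, windows = epoch_windows(FALSE)) {
  trials <- filter_trials(session$trials)
  rates <- epoch_rates(session$spikes, trials, epoch_windows(TRUE))
  gate <- anova_gate(rates, trials)
  att_rf <- trials$trial_id[trials$attention == "RF"]
  drug_on <- trials$trial_id[trials$drug == "on"]
  combos <- expand.grid(unit_id = unique(rates$unit_id),
                        epoch = windows$epoch,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    u <- combos$unit_id[i]; ep <- combos$epoch[i]
    r <- rates[rates$unit_id == u & rates$epoch == ep, ]
    nd <- !r$trial_id %in% drug_on
    rf <- r$trial_id %in% att_rf
    a_nd <- auroc(r$rate[rf & nd], r$rate[!rf & nd])
    a_dr <- auroc(r$rate[rf & !nd], r$rate[!rf & !nd])
    d_nd <- cohens_dprime(r$rate[rf & nd], r$rate[!rf & nd])
    d_dr <- cohens_dprime(r$rate[rf & !nd], r$rate[!rf & !nd])
    # DrugMI per attention x motion condition, then averaged
    tt <- trials[match(r$trial_id, trials$trial_id), ]
    agg <- stats::aggregate(r$rate,
                            by = list(attention = tt$attention,
                                      motion = tt$motion, drug = tt$drug),
                            FUN = mean)
    wide <- merge(agg[agg$drug == "off", c("attention", "motion", "x")],
                  agg[agg$drug == "on", c("attention", "motion", "x")],
                  by = c("attention", "motion"),
                  suffixes = c("_nodrug", "_drug"))
    mi <- mean(drug_mi(wide$x_nodrug, wide$x_drug), na.rm = TRUE)
    data.frame(unit_id = u, epoch = ep,
               auroc_nodrug = a_nd, auroc_drug = a_dr,
               cohens_dprime_nodrug = d_nd, cohens_dprime_drug = d_dr,
               drug_mi = mi, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  fl <- auroc_flip(res$auroc_nodrug, res$auroc_drug)
  res$auroc_nodrug_flipped <- fl$auroc_nodrug
  res$auroc_drug_flipped <- fl$auroc_drug
  merge(res, gate, by = "unit_id", all.x = TRUE)
}

#' Population statistics over per-unit metrics
#'
#' Per group (cell class, cluster or response type): a paired t-test of
#' no-drug versus drug AUROC with Cohen's Dz and confidence interval; a
#' one-sample t-test of DrugMI against zero with Cohen's D and confidence
#' interval; plus one mixed between-within (split-plot) ANOVA on AUROC with
#' drug state as the within-unit factor and group as the between-unit
#' factor, reported with partial eta squared.
#'
#' @param metrics A [unit_metrics()] table (one epoch).
#' @param groups Named group label per unit (vector aligned with
#'   `metrics$unit_id` or named by unit id).
#' @param flipped Use the flipped AUROC convention. Default FALSE.
#' @return List: `per_group` (data.frame), `anova` (data.frame).
#' @export
population_tests <- function(metrics, groups, flipped = FALSE) {
  if (!is.null(names(groups))) groups <- groups[metrics$unit_id]
  stopifnot(length(groups) == nrow(metrics))
  a_nd <- if (flipped) metrics$auroc_nodrug_flipped else metrics$auroc_nodrug
  a_dr <- if (flipped) metrics$auroc_drug_flipped else metrics$auroc_drug
  per <- lapply(unique(groups), function(g) {
    i <- which(groups == g & is.finite(a_nd) & is.finite(a_dr))
    if (length(i) < 2) return(NULL)   # degenerate group skipped
    dif <- a_nd[i] - a_dr[i]
    tt <- stats::t.test(dif)
    dz <- mean(dif) / stats::sd(dif)
    mi <- metrics$drug_mi[groups == g]
    mi <- mi[is.finite(mi)]
    mt <- if (length(mi) >= 2) stats::t.test(mi) else NULL
    data.frame(group = g, n = length(i),
               auroc_diff_mean = mean(dif),
               auroc_t = unname(tt$statistic), auroc_p = tt$p.value,
               auroc_ci_lo = tt$conf.int[1], auroc_ci_hi = tt$conf.int[2],
               auroc_dz = dz,
               mi_mean = if (is.null(mt)) NA else mean(mi),
               mi_t = if (is.null(mt)) NA else unname(mt$statistic),
               mi_p = if (is.null(mt)) NA else mt$p.value,
               mi_ci_lo = if (is.null(mt)) NA else mt$conf.int[1],
               mi_ci_hi = if (is.null(mt)) NA else mt$conf.int[2],
               mi_cohens_d = if (is.null(mt)) NA else mean(mi) / stats::sd(mi),
               stringsAsFactors = FALSE)
  })
  long <- data.frame(unit = rep(metrics$unit_id, 2),
                     group = factor(rep(groups, 2)),
                     drugstate = factor(rep(c("nodrug", "drug"),
                                            each = nrow(metrics))),
                     auroc = c(a_nd, a_dr))
  long <- long[is.finite(long$auroc), ]
  anova <- mixed_anova(long, dv = "auroc", within = "drugstate",
                       between = "group", id = "unit")
  list(per_group = do.call(rbind, per), anova = anova)
}

# Classical between-within (split-plot) ANOVA with partial eta squared.
# Between factor tested against the subject stratum, within factor and the
# interaction against the subject:within stratum.
mixed_anova <- function(df, dv, within, between, id) {
  df[[id]] <- factor(df[[id]])
  f <- stats::as.formula(paste(dv, "~", between, "*", within,
                               "+ Error(", id, "/", within, ")"))
  fit <- stats::aov(f, data = df)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    res_i <- which(terms == "Residuals")
    if (!length(res_i)) next
    ss_err <- tab[res_i, "Sum Sq"]
    for (j in setdiff(seq_len(nrow(tab)), res_i)) {
      out[[length(out) + 1]] <- data.frame(
        term = terms[j], df = tab[j, "Df"], df_err = tab[res_i, "Df"],
        F = tab[j, "F value"], p = tab[j, "Pr(>F)"],
        eta2p = tab[j, "Sum Sq"] / (tab[j, "Sum Sq"] + ss_err),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
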