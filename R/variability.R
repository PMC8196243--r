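# Trial-to-trial rate variability: Fano factor and the negative-binomial
# gain-variance model.

#' Fano factor of spike counts
#'
#' `FF = var(counts) / mean(counts)` over trials of one condition (pre-dim
#' window counts). 1 for a Poisson process; under the gamma-gain model
#' `FF = 1 + sigma2g * mu`, increasing with the mean count.
#'
#' @param counts Spike counts (>= 2 trials).
#' @return FF, or NA when the mean is zero.
#' @export
fano_factor <- function(counts) {
  counts <- counts[is.finite(counts)]
  if (length(counts) < 2) return(NA_real_)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}

#' Negative-binomial gain-variance fit to spike counts
#'
#' Fits trial spike counts with a negative binomial parameterised as
#' `Var = mu + sigma2g * mu^2`, where `sigma2g` is the variance of a
#' trial-wise multiplicative excitability gain (gamma, mean 1). The mean is
#' estimated by the sample mean (its MLE); `sigma2g` by profile maximum
#' likelihood. The fit is not attempted (`valid = FALSE`) when the sample
#' variance is below the sample mean — the model cannot represent
#' under-dispersion. On optimisation failure the moment estimator
#' `(var - mean) / mean^2` is returned and flagged.
#'
#' @param counts Non-negative integer spike counts (>= 10 trials).
#' @param duration_s Window duration (s), carried through for rate
#'   conversion in reports. Default 0.5.
#' @return List: `mu` (mean count), `sigma2g`, `valid`, `method`
#'   (`"mle"`/`"moment"`/`NA`), `n_trials`, `rate` (spikes/s).
#' @export
fit_gain_variance <- function(counts, duration_s = 0.5) {
  counts <- counts[is.finite(counts)]
  if (length(counts) < 10) stop("need at least 10 trials")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  m <- mean(counts); v <- stats::var(counts)
  base <- list(mu = m, n_trials = length(counts), rate = m / duration_s)
  if (m == 0 || v < m)
    return(c(base, list(sigma2g = NA_real_, valid = FALSE, method = NA)))
  # profile negative log-likelihood in sigma2g (= 1/size)
  nll <- function(s2) {
    size <- 1 / s2
    -sum(stats::dnbinom(counts, size = size, mu = m, log = TRUE))
  }
  mom <- (v - m) / m^2
  fit <- tryCatch(
    stats::optimize(nll, interval = c(1e-8, max(10 * mom, 1)))$minimum,
    error = function(e) NULL)
  if (is.null(fit))
    return(c(base, list(sigma2g = mom, valid = TRUE, method = "moment")))
  c(base, list(sigma2g = fit, valid = TRUE, method = "mle"))
}

#' Per-unit gain-variance table over condition groups
#'
#' Fits the gain variance per stimulus condition and averages the fitted
#' terms across the two attend-RF conditions and, separately, across the
#' four attend-away conditions, per drug state. Conditions whose variance
#' falls below their mean are dropped from the average; a group with no
#' valid condition is flagged invalid.
#'
#' @param rates [epoch_rates()] table (pre-dim epoch used).
#' @param trials Filtered trial table.
#' @param epoch Epoch to analyse. Default `"pre_dim"`.
#' @return data.frame: `unit_id`, `attention_group`, `drug`, `ff`,
#'   `sigma2g`, `valid`, `n_trials`.
#' @export
gain_variance_table <- function(rates, trials, epoch = "pre_dim") {
  r <- rates[rates$epoch == epoch, ]
  tt <- trials[match(r$trial_id, trials$trial_id), ]
  r$attention_group <- ifelse(tt$attention == "RF", "attend_RF", "attend_away")
  r$condition <- paste(tt$attention, tt$motion)
  r$drug <- tt$drug
  groups <- unique(r[, c("unit_id", "attention_group", "drug")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- r[r$unit_id == g$unit_id & r$attention_group == g$attention_group &
               r$drug == g$drug, ]
    fits <- lapply(split(sub$spike_count, sub$condition), function(cnt) {
      if (length(cnt) < 10) return(NULL)
      fit_gain_variance(cnt, duration_s = sub$duration_s[1])
    })
    fits <- Filter(Negate(is.null), fits)
    s2 <- vapply(fits, function(f)
      if (isTRUE(f$valid)) f$sigma2g else NA_real_, numeric(1))
    data.frame(unit_id = g$unit_id, attention_group = g$attention_group,
               drug = g$drug,
               ff = fano_factor(sub$spike_count),
               sigma2g = if (all(is.na(s2))) NA_real_ else mean(s2, na.rm = TRUE),
               valid = any(!is.na(s2)),
               n_trials = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mixed ANOVA on variability measures
#'
#' Between-within ANOVA of a variability measure (FF or gain variance) with
#' attention group and drug state as within-unit factors and an optional
#' cell grouping as the between-unit factor; partial eta squared per term.
#' Per-group means and SEMs are returned alongside.
#'
#' @param vtab A [gain_variance_table()] (or compatible) data.frame.
#' @param measure Column to analyse: `"ff"` or `"sigma2g"`.
#' @param cell_groups Optional named (by unit id) group labels.
#' @return List: `anova` (term table), `means` (per-cell means +- SEM).
#' @export
variability_anova <- function(vtab, measure = "ff", cell_groups = NULL) {
  df <- vtab[is.finite(vtab[[measure]]), ]
  if (!nrow(df)) return(list(anova = data.frame(), means = data.frame()))
  df$y <- df[[measure]]
  df$unit <- factor(df$unit_id)
  df$attention_group <- factor(df$attention_group)
  df$drug <- factor(df$drug)
  if (!is.null(cell_groups)) {
    df$cellgroup <- factor(cell_groups[df$unit_id])
    keep <- stats::ave(seq_len(nrow(df)), df$cellgroup,
                       FUN = length) >= 2
    df <- df[keep & !is.na(df$cellgroup), ]
    f <- y ~ cellgroup * attention_group * drug +
      Error(unit / (attention_group * drug))
  } else {
    f <- y ~ attention_group * drug + Error(unit / (attention_group * drug))
  }
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
  by <- c("attention_group", "drug",
          if (!is.null(cell_groups)) "cellgroup")
  means <- stats::aggregate(df$y, by = df[by], FUN = function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  means <- do.call(data.frame, means)
  names(means) <- c(by, "mean", "sem", "n")
  list(anova = do.call(rbind, out), means = means)
}
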