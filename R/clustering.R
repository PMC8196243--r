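# Feature-based k-means cell classification with information-criterion
# model selection.

#' Interspike-interval irregularity measures
#'
#' Computes, from ISIs pooled across trials (ISIs never span trial
#' boundaries):
#' \itemize{
#'   \item CV: `sd(ISI) / mean(ISI)` (global irregularity; 1 for Poisson);
#'   \item CV2: mean of `2 * |ISI[i+1] - ISI[i]| / (ISI[i+1] + ISI[i])` over
#'     neighbouring ISI pairs within a trial;
#'   \item Lv: mean of `3 * (ISI[i] - ISI[i+1])^2 / (ISI[i] + ISI[i+1])^2`
#'     (local variation).
#' }
#' All three are 0 for a perfectly regular train. Fewer than 3 ISIs marks
#' the features missing (`NA`).
#'
#' @param spike_times List of numeric vectors, one per trial (ms), or a
#'   single numeric vector (one trial).
#' @return Named numeric vector `c(cv, cv2, lv)`.
#' @export
isi_irregularity <- function(spike_times) {
  if (is.numeric(spike_times)) spike_times <- list(spike_times)
  isis <- lapply(spike_times, function(s) if (length(s) >= 2) diff(sort(s)) else numeric(0))
  all_isi <- unlist(isis)
  if (length(all_isi) < 3)
    return(c(cv = NA_real_, cv2 = NA_real_, lv = NA_real_))
  cv <- stats::sd(all_isi) / mean(all_isi)
  pair_stats <- function(v) {
    if (length(v) < 2) return(NULL)
    a <- v[-length(v)]; b <- v[-1]
    cbind(cv2 = 2 * abs(b - a) / (b + a), lv = 3 * (a - b)^2 / (a + b)^2)
  }
  ps <- do.call(rbind, lapply(isis, pair_stats))
  if (is.null(ps) || nrow(ps) == 0)
    return(c(cv = cv, cv2 = NA_real_, lv = NA_real_))
  c(cv = cv, cv2 = mean(ps[, "cv2"]), lv = mean(ps[, "lv"]))
}

#' Build the per-unit clustering feature table
#'
#' Assembles the candidate features: P2T time, firing rate (FR, pre-dimming
#' window mean), Fano factor (FF, pre-dimming counts, no-drug trials),
#' ISI irregularity (CV, CV2, Lv; pooled pre-dimming ISIs), and attentional
#' AUROC (pre-dimming, no-drug).
#'
#' @param session A `fef_session`.
#' @param rates Optional precomputed [epoch_rates()] table.
#' @return data.frame with `unit_id` and feature columns.
#' @export
unit_features <- function(session, rates = NULL) {
  trials <- filter_trials(session$trials)
  if (is.null(rates)) rates <- epoch_rates(session$spikes, trials)
  pre <- rates[rates$epoch == "pre_dim", ]
  nd <- trials$trial_id[trials$drug == "off"]
  wm <- classify_waveforms(session$waveforms)
  units <- wm$unit_id
  f <- lapply(units, function(u) {
    pu <- pre[pre$unit_id == u & pre$trial_id %in% nd, ]
    fr <- mean(pu$rate)
    ff <- fano_factor(pu$spike_count)
    rf <- pu$rate[pu$trial_id %in% trials$trial_id[trials$attention == "RF"]]
    aw <- pu$rate[!pu$trial_id %in% trials$trial_id[trials$attention == "RF"]]
    au <- auroc(rf, aw)
    sp <- session$spikes[session$spikes$unit_id == u &
                           session$spikes$trial_id %in% nd, ]
    tt <- trials[match(sp$trial_id, trials$trial_id), ]
    inpre <- sp$spike_time_ms >= tt$t_dim1 - 500 & sp$spike_time_ms < tt$t_dim1
    irr <- isi_irregularity(split(sp$spike_time_ms[inpre], sp$trial_id[inpre]))
    c(p2t = wm$p2t_us[wm$unit_id == u], fr = fr, ff = ff, irr, auroc = au)
  })
  out <- data.frame(unit_id = units, do.call(rbind, f),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# min-max standardization of each column to [0, 1]
standardize01 <- function(x) {
  apply(as.matrix(x), 2, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  })
}

#' Greedy dissimilarity pre-screen of clustering features
#'
#' Standardizes features to [0, 1] and greedily retains, one at a time, the
#' feature that explains the most residual variance of the full standardized
#' matrix (variance explained via least-squares regression of every column
#' on the retained set), stopping once the retained set explains at least
#' `target` of the total variance. Deterministic given its input. Constant
#' features are excluded with a warning. Redundant near-duplicate features
#' (e.g. CV2 tracking CV) are dropped by construction.
#'
#' @param features Numeric matrix or data.frame (units x features); a
#'   `unit_id` column is ignored.
#' @param target Fraction of variance to explain. Default 0.9.
#' @return Character vector of retained feature names, with attribute
#'   `explained` (cumulative explained-variance fractions).
#' @export
prescreen_features <- function(features, target = 0.9) {
  if (is.data.frame(features))
    features <- features[, setdiff(names(features), "unit_id"), drop = FALSE]
  x <- as.matrix(features)
  stopifnot(ncol(x) >= 2, nrow(x) >= 10)
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning("constant feature(s) excluded: ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  z <- standardize01(x)
  z <- scale(z, center = TRUE, scale = FALSE)
  total <- sum(z^2)
  retained <- character(0)
  resid <- z
  expl <- numeric(0)
  repeat {
    cand <- setdiff(colnames(z), retained)
    gain <- vapply(cand, function(f) {
      v <- resid[, f]
      if (sum(v^2) == 0) return(0)
      # variance of the residual matrix explained by this feature
      sum(crossprod(resid, v)^2) / sum(v^2)
    }, numeric(1))
    best <- cand[which.max(gain)]
    retained <- c(retained, best)
    # orthogonalize the residual matrix against the chosen feature
    v <- resid[, best]
    if (sum(v^2) > 0)
      resid <- resid - outer(v, crossprod(resid, v)[, 1] / sum(v^2))
    expl <- c(expl, (total - sum(resid^2)) / total)
    if (expl[length(expl)] >= target || length(retained) == ncol(z)) break
  }
  structure(retained, explained = expl)
}

# Information criteria for a k-means solution via the classification
# likelihood of a diagonal-covariance Gaussian mixture with hard
# assignments and mixing proportions:
#   logL = sum_c [ m_c log(m_c/n)
#                  - (m_c / 2) sum_j (log(2 pi s2_cj) + 1) ],
# with per-cluster per-dimension variances s2_cj (floored against
# near-singleton degeneracy) and k(2d + 1) - 1 parameters (means,
# variances, proportions). The naive equal-variance spherical variant
# provably over-splits well-separated Gaussian clusters at these sample
# sizes — each split of an m-point cluster buys ~0.64 m in deviance
# against a fixed 2d (AIC) penalty, independent of separation — whereas
# per-cluster variances plus the proportion term make pure-noise splits
# pay for themselves.
kmeans_ic <- function(x, km, n, d, k) {
  floor2 <- max(km$tot.withinss / (n * d) * 1e-3, .Machine$double.eps)
  logl <- 0
  for (cc in seq_len(k)) {
    pts <- which(km$cluster == cc)
    mc <- length(pts)
    if (mc == 0) next
    dev <- sweep(x[pts, , drop = FALSE], 2, km$centers[cc, ])^2
    s2 <- pmax(colMeans(dev), floor2)
    logl <- logl + mc * log(mc / n) - (mc / 2) * sum(log(2 * pi * s2) + 1)
  }
  npar <- k * (2 * d + 1) - 1
  c(aic = -2 * logl + 2 * npar, bic = -2 * logl + log(n) * npar)
}

#' K-means clustering with AIC/BIC selection of the cluster number
#'
#' For each `k` in `k_range`, runs `realizations` seeded k-means
#' realizations, each taking the best of `replicas` random centroid
#' initialisations (centroids seeded uniformly from the data points) by
#' within-cluster sum of squares. Information criteria use the spherical
#' Gaussian equal-variance likelihood; the selected model minimises the
#' criteria (ties break to the smaller `k`). Units carrying missing
#' features must be excluded beforehand.
#'
#' @param features Numeric matrix standardized to [0, 1] (see
#'   [standardize01()]), or a data.frame whose non-`unit_id` columns are
#'   standardized internally.
#' @param k_range Candidate cluster numbers. Default 3:8.
#' @param realizations Realizations per k. Default 500.
#' @param replicas Random restarts per realization. Default 50.
#' @param seed Integer seed; required.
#' @return List of class `fef_cluster_model`: `k`, `assignments`,
#'   `centroids`, `wcss`, `criteria` (per-k table), `stability`
#'   (units x realizations assignment matrix for the selected k), `seed`.
#' @export
kmeans_select_k <- function(features, k_range = 3:8, realizations = 500L,
                            replicas = 50L, seed) {
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  ids <- NULL
  if (is.data.frame(features)) {
    ids <- features$unit_id
    features <- standardize01(
      features[, setdiff(names(features), "unit_id"), drop = FALSE])
  }
  x <- as.matrix(features)
  if (anyNA(x)) stop("missing feature values: exclude those units first")
  n <- nrow(x); d <- ncol(x)
  if (n < max(k_range)) stop("fewer units than max(k_range)")
  if (max(dist(x[seq_len(min(n, 200L)), , drop = FALSE])) == 0)
    stop("degenerate input: all feature vectors identical")

  run_k <- function(k, n_real) {
    best <- NULL
    assign_mat <- matrix(NA_integer_, n, n_real)
    for (r in seq_len(n_real)) {
      rbest <- NULL
      withr_rng(rng_stream(seed, paste0("km", k, "_", r)), {
        for (rep in seq_len(replicas)) {
          centers <- x[sample.int(n, k), , drop = FALSE]
          km <- tryCatch(
            suppressWarnings(stats::kmeans(x, centers, iter.max = 50L)),
            error = function(e) NULL)
          if (is.null(km)) next
          if (is.null(rbest) || km$tot.withinss < rbest$tot.withinss)
            rbest <- km
        }
      })
      assign_mat[, r] <- rbest$cluster
      if (is.null(best) || rbest$tot.withinss < best$tot.withinss) best <- rbest
    }
    list(km = best, assign = assign_mat)
  }

  crit <- data.frame(k = k_range, wcss = NA_real_, aic = NA_real_,
                     bic = NA_real_)
  models <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    res <- run_k(k, realizations)
    models[[i]] <- res
    ic <- kmeans_ic(x, res$km, n, d, k)
    crit$wcss[i] <- res$km$tot.withinss
    crit$aic[i] <- ic["aic"]; crit$bic[i] <- ic["bic"]
  }
  k_aic <- crit$k[which.min(crit$aic)]
  k_bic <- crit$k[which.min(crit$bic)]
  # argmin over both criteria; on disagreement the smaller selected k wins
  k_sel <- min(k_aic, k_bic)
  sel <- models[[match(k_sel, k_range)]]
  out <- list(k = k_sel, k_aic = k_aic, k_bic = k_bic,
              assignments = sel$km$cluster, centroids = sel$km$centers,
              wcss = sel$km$tot.withinss, criteria = crit,
              stability = sel$assign, unit_ids = ids, seed = seed)
  class(out) <- "fef_cluster_model"
  out
}

#' Stability (probability) thresholding of cluster membership
#'
#' For every unit, the fraction of realizations in which it co-clusters with
#' the majority of its final cluster's members. Units below `threshold` are
#' flagged unstable; stable membership is a subset of full membership.
#'
#' @param model A `fef_cluster_model`, or a units x realizations assignment
#'   matrix plus `assignments`.
#' @param threshold Minimum co-clustering probability. Default 0.9.
#' @param assignments Final cluster labels (matrix input only).
#' @return data.frame: `unit`, `cluster`, `stability`, `stable`.
#' @export
stability_threshold <- function(model, threshold = 0.9, assignments = NULL) {
  if (inherits(model, "fef_cluster_model")) {
    mat <- model$stability; assignments <- model$assignments
    ids <- if (is.null(model$unit_ids)) seq_along(assignments) else model$unit_ids
  } else {
    mat <- model
    ids <- seq_len(nrow(mat))
    if (is.null(assignments)) stop("assignments required with matrix input")
  }
  if (ncol(mat) < 2) stop("need at least 2 realizations")
  n <- nrow(mat)
  stab <- numeric(n)
  for (u in seq_len(n)) {
    mates <- which(assignments == assignments[u])
    co <- vapply(seq_len(ncol(mat)), function(r) {
      # majority of final-cluster mates in realization r
      maj <- as.integer(names(which.max(table(mat[mates, r]))))
      mat[u, r] == maj
    }, logical(1))
    stab[u] <- mean(co)
  }
  data.frame(unit = ids, cluster = assignments, stability = stab,
             stable = stab >= threshold, row.names = NULL)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index (1 = identical up to label permutation).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
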