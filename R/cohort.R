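#' Assign fitness scores to a patient cohort
#'
#' Maps each patient's mutation to the chosen component of a fitted
#' landscape. Patients whose mutation is not in the landscape are dropped
#' with a warning; a patient listed with several scored mutations keeps the
#' one with the highest free fitness (clonally dominant driver assumption).
#'
#' @param cohort data.frame with columns `patient_id`, `mutation`, `time`
#'   (> 0), `event` (0/1).
#' @param landscape A `freefit_landscape` from [free_fitness()].
#' @param component `"free"` (default), `"functional"` (`f_t`), `"immune"`
#'   (`f_i`) or `"intrinsic"`.
#' @return The cohort with a `score` column, one row per retained patient;
#'   attribute `n_dropped` counts unmapped patients.
#' @export
score_patients <- function(cohort, landscape,
                           component = c("free", "functional", "immune",
                                         "intrinsic")) {
  component <- match.arg(component)
  need <- c("patient_id", "mutation", "time", "event")
  if (!all(need %in% names(cohort))) {
    stop_input("cohort needs columns ", paste(need, collapse = ", "))
  }
  if (any(cohort$time <= 0)) stop_input("times must be positive")
  if (!all(cohort$event %in% c(0, 1))) stop_input("event must be 0/1")
  col <- switch(component, free = "free", functional = "f_t",
                immune = "f_i", intrinsic = "intrinsic")
  i <- match(cohort$mutation, landscape$mutation)
  dropped <- sum(is.na(i))
  if (dropped == nrow(cohort)) stop_input("no cohort mutation maps to the landscape")
  if (dropped > 0) {
    warning(sprintf("%d patient record(s) with unscored mutations dropped",
                    dropped), call. = FALSE)
  }
  out <- cohort[!is.na(i), , drop = FALSE]
  i <- i[!is.na(i)]
  out$score <- landscape[[col]][i]
  out$free_score <- landscape$free[i]
  # one row per patient: keep the mutation with the highest free fitness
  if (anyDuplicated(out$patient_id)) {
    ord <- order(out$patient_id, -out$free_score)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$patient_id), , drop = FALSE]
  }
  out$free_score <- NULL
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Median split of a score vector
#'
#' Low group: score strictly below the median; high group: at or above
#' (ties go high). Errors if either group would be empty, as when all
#' scores are identical.
#'
#' @param scores Numeric vector, length >= 2.
#' @return List `low`, `high` of indices, plus `median`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop_input("need at least 2 scores")
  med <- median(scores)
  low <- which(scores < med)
  high <- which(scores >= med)
  if (!length(low) || !length(high)) {
    stop_input("degenerate median split: a group is empty")
  }
  list(low = low, high = high, median = med)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via [survival::survfit()], returned as a tidy
#' step function. Censored times reduce the risk set without producing
#' steps.
#'
#' @param time Positive event/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (non-increasing, starts from 1).
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) stop_input("empty survival data")
  if (any(time <= 0)) stop_input("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Direct observed-minus-expected implementation over the pooled event
#' times (the relative-immune-weight scans call it thousands of times and
#' need a fixed, testable convention): at each distinct event time the
#' expected events in group A are `d * nA / n` with hypergeometric variance
#' `d (n - d) nA nB / (n^2 (n - 1))`; the statistic is
#' `(sum(O - E))^2 / sum(V)`, chi-square with 1 df.
#'
#' @param time_a,event_a Times and event indicators of group A.
#' @param time_b,event_b Times and event indicators of group B.
#' @return List `chisq`, `p`, `n_a`, `n_b`, `observed_a`, `expected_a`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop_input("both groups must be non-empty")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  if (!any(event == 1)) stop_input("no events in pooled data: test undefined")
  taus <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in taus) {
    at <- time >= t
    n <- sum(at); na <- sum(at & grp_a)
    d <- sum(time == t & event == 1)
    da <- sum(time == t & event == 1 & grp_a)
    o <- o + da
    e <- e + d * na / n
    if (n > 1) v <- v + d * (n - d) * na * (n - na) / (n^2 * (n - 1))
  }
  chisq <- if (v > 0) (o - e)^2 / v else 0
  list(chisq = chisq, p = pchisq(chisq, df = 1L, lower.tail = FALSE),
       n_a = length(time_a), n_b = length(time_b),
       observed_a = o, expected_a = e)
}

#' Log-rank score as a function of the relative immune weight
#'
#' For each `lambda` on the grid: refit the overall selection strength `s`
#' to the mutation counts (as in [weight_scan()]), rebuild the free-fitness
#' landscape at the fitted weights, score the cohort, median-split and run
#' the log-rank test. Grid points where the split degenerates (constant
#' scores) are kept with `NA` statistics and flagged.
#'
#' @param cohort Patient table as in [score_patients()].
#' @param counts,p,p_onc,p_pres Model inputs as in [fit_weights()].
#' @param mutation Mutation ids aligned with `p`.
#' @param lambda_grid Grid in `[0, 1]`.
#' @param component Landscape component used for scoring (default free).
#' @param sigma_max,tol Optimiser settings.
#' @return data.frame `lambda`, `s_hat`, `chisq`, `p`, `degenerate`, with
#'   attribute `lambda_star` (grid argmax of the statistic).
#' @export
survival_weight_scan <- function(cohort, counts, p, p_onc, p_pres, mutation,
                                 lambda_grid = seq(0, 1, by = 0.05),
                                 component = "free",
                                 sigma_max = 50, tol = 1e-8) {
  scan <- weight_scan(counts, p, p_onc, p_pres, lambda_grid = lambda_grid,
                      sigma_max = sigma_max, tol = tol)
  rows <- lapply(seq_len(nrow(scan)), function(j) {
    fl <- free_fitness(p, p_onc, p_pres, scan$sigma_t[j], scan$sigma_i[j],
                       mutation = mutation)
    scored <- score_patients(cohort, fl, component = component)
    res <- tryCatch({
      sp <- median_split(scored$score)
      lr <- logrank_test(scored$time[sp$low], scored$event[sp$low],
                         scored$time[sp$high], scored$event[sp$high])
      data.frame(lambda = scan$lambda[j], s_hat = scan$s_hat[j],
                 chisq = lr$chisq, p = lr$p, degenerate = FALSE)
    }, error = function(e) {
      data.frame(lambda = scan$lambda[j], s_hat = scan$s_hat[j],
                 chisq = NA_real_, p = NA_real_, degenerate = TRUE)
    })
    res
  })
  out <- do.call(rbind, rows)
  ok <- which(!out$degenerate)
  attr(out, "lambda_star") <-
    if (length(ok)) out$lambda[ok[which.max(out$chisq[ok])]] else NA_real_
  out
}

#' Compare mutation frequency distributions between two catalogs
#'
#' Restricts both catalogs to their shared mutations, renormalises counts
#' to frequencies within the shared support, and correlates them.
#'
#' @param catalog_a,catalog_b data.frames with columns `mutation`, `count`.
#' @return List `pearson_r`, `pearson_p`, `spearman_r`, `spearman_p`,
#'   `shared` (data.frame `mutation`, `freq_a`, `freq_b`, `delta`).
#' @export
dataset_comparison <- function(catalog_a, catalog_b) {
  shared <- intersect(catalog_a$mutation, catalog_b$mutation)
  if (length(shared) < 3L) stop_input("need >= 3 shared mutations")
  ca <- catalog_a$count[match(shared, catalog_a$mutation)]
  cb <- catalog_b$count[match(shared, catalog_b$mutation)]
  if (sum(ca) <= 0 || sum(cb) <= 0) stop_input("empty counts in shared support")
  fa <- ca / sum(ca); fb <- cb / sum(cb)
  if (sd(fa) == 0 || sd(fb) == 0) stop_input("zero variance: correlation undefined")
  pe <- cor.test(fa, fb, method = "pearson")
  sp <- suppressWarnings(cor.test(fa, fb, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
       shared = data.frame(mutation = shared, freq_a = fa, freq_b = fb,
                           delta = fb - fa, stringsAsFactors = FALSE))
}

#' Two-sided exact binomial enrichment test
#'
#' Exact binomial test of `k` successes in `n` trials against a reference
#' frequency, two-sided by the minimum-likelihood convention (sum the
#' probabilities of all outcomes no more likely than the observed one) —
#' stated explicitly because two-sided binomial conventions differ and the
#' p-values change.
#'
#' @param k Observed count.
#' @param n Total trials.
#' @param p0 Reference frequency, strictly inside (0, 1).
#' @return Two-sided p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (k < 0 || k > n) stop_input("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop_input("p0 must be strictly inside (0, 1)")
  binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Welch's unequal-variance t-test
#'
#' Two-sided comparison of two score distributions (e.g. free fitness of
#' hotspot vs non-hotspot mutations) with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param values_a,values_b Numeric samples, each of size >= 2.
#' @return List `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_compare <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop_input("both samples must have >= 2 values")
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    stop_input("zero variance in both samples: test undefined")
  }
  tt <- t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Read a patient cohort from CSV
#' @param path CSV with columns `patient_id`, `mutation`, `time`, `event`.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
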