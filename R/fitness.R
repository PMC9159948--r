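#' Free-fitness landscape of a mutation set
#'
#' Combines the background probability, the pro-oncogenic probability and
#' the haplotype-averaged presentation probability of each mutation into
#' \deqn{F_m = \log p_m + \sigma_T P^{onc}_m - \sigma_I \langle P^{pres}_m\rangle,}
#' the free fitness, together with its decomposition into intrinsic fitness
#' (`log p_m` plus functional fitness, `f_t`) and extrinsic immune fitness
#' (`f_i`, non-positive), and the predicted frequency `q_m` (softmax of F).
#' Entries with zero background probability are outside the model support
#' and are dropped with a warning.
#'
#' @param p Background probabilities (sum to 1 over candidates).
#' @param p_onc Pro-oncogenic probabilities in `[0, 1]`.
#' @param p_pres Haplotype-averaged presentation probabilities in `[0, 1]`.
#' @param sigma_t Functional weight (>= 0).
#' @param sigma_i Immune weight (>= 0).
#' @param mutation Optional mutation ids.
#' @param protein_pos Optional protein positions (enables per-position
#'   aggregation downstream).
#' @return A data.frame of class `freefit_landscape` with columns
#'   `mutation`, `p`, `p_onc`, `p_pres`, `f_t`, `f_i`, `intrinsic`,
#'   `extrinsic`, `free`, `q` (+ `protein_pos` when given); the weights are
#'   stored as attribute `weights`.
#' @export
#' @examples
#' fl <- free_fitness(c(0.5, 0.5), c(0.9, 0.1), c(0.2, 0.8), 4, 2)
#' sum(fl$q)
free_fitness <- function(p, p_onc, p_pres, sigma_t, sigma_i,
                         mutation = NULL, protein_pos = NULL) {
  stopifnot(length(p) == length(p_onc), length(p) == length(p_pres))
  if (sigma_t < 0 || sigma_i < 0) stop_input("weights must be non-negative")
  if (any(p < 0) || any(p_onc < 0 | p_onc > 1) || any(p_pres < 0 | p_pres > 1)) {
    stop_input("p must be non-negative and probabilities within [0, 1]")
  }
  mutation <- mutation %||% paste0("m", seq_along(p))
  keep <- p > 0
  if (!all(keep)) {
    warning(sprintf("%d mutation(s) with zero background probability excluded from support",
                    sum(!keep)), call. = FALSE)
  }
  out <- data.frame(mutation = mutation[keep], p = p[keep],
                    p_onc = p_onc[keep], p_pres = p_pres[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(protein_pos)) out$protein_pos <- protein_pos[keep]
  out$f_t <- sigma_t * out$p_onc
  out$f_i <- -sigma_i * out$p_pres
  out$intrinsic <- log(out$p) + out$f_t
  out$extrinsic <- out$f_i
  out$free <- out$intrinsic + out$extrinsic
  out$q <- predicted_frequencies(out$free)
  attr(out, "weights") <- c(sigma_t = sigma_t, sigma_i = sigma_i)
  class(out) <- c("freefit_landscape", "data.frame")
  out
}

#' Predicted mutation frequencies from free fitness
#'
#' Softmax of the free-fitness values, computed with log-sum-exp
#' stabilisation; invariant under adding a constant to all fitnesses.
#'
#' @param free Free-fitness vector (or a `freefit_landscape`).
#' @return Probabilities summing to 1.
#' @export
predicted_frequencies <- function(free) {
  if (inherits(free, "freefit_landscape")) free <- free$free
  if (!length(free)) stop_input("empty support")
  z <- free - max(free)
  e <- exp(z)
  e / sum(e)
}

#' Multinomial log-likelihood of observed counts
#'
#' The multinomial kernel `sum(n_m * log(q_m))`; the combinatorial constant
#' is dropped. If a category with observed counts has zero predicted
#' frequency the log-likelihood is `-Inf` (flagged with a warning).
#'
#' @param counts Observed non-negative counts.
#' @param q Predicted frequencies.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(counts, q) {
  stopifnot(length(counts) == length(q))
  if (any(counts < 0)) stop_input("negative counts")
  pos <- counts > 0
  if (any(q[pos] == 0)) {
    warning("observed counts on zero-probability categories: -Inf log-likelihood",
            call. = FALSE)
    return(-Inf)
  }
  sum(counts[pos] * log(q[pos]))
}

#' Kullback-Leibler divergence between observed and predicted frequencies
#'
#' `D(o || q) = sum(o * log(o / q))` in nats; zero-frequency observed
#' categories contribute nothing, and observed mass on a zero-probability
#' prediction yields `Inf` with a warning. With `aggregate = "position"`
#' both distributions are first summed per protein position, mirroring the
#' per-codon view of model fit.
#'
#' @param observed Observed frequencies (or counts; renormalised).
#' @param q Predicted frequencies (renormalised).
#' @param positions Protein positions, required for `aggregate = "position"`.
#' @param aggregate `"mutation"` (default) or `"position"`.
#' @return Non-negative scalar (nats).
#' @export
kl_divergence <- function(observed, q, positions = NULL,
                          aggregate = c("mutation", "position")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(observed) == length(q))
  if (any(observed < 0) || any(q < 0)) stop_input("negative frequencies")
  if (aggregate == "position") {
    if (is.null(positions)) stop_input("positions required for per-position KL")
    observed <- tapply(observed, positions, sum)
    q <- tapply(q, positions, sum)
  }
  o <- observed / sum(observed)
  qq <- q / sum(q)
  pos <- o > 0
  if (any(qq[pos] == 0)) {
    warning("observed mass on zero-probability categories: infinite KL",
            call. = FALSE)
    return(Inf)
  }
  sum(o[pos] * log(o[pos] / qq[pos]))
}

# Log-likelihood as a function of weights, for the optimiser.
ll_at <- function(sigma, counts, logp, p_onc, p_pres) {
  f <- logp + sigma[1] * p_onc - sigma[2] * p_pres
  z <- f - max(f)
  sum(counts * z) - sum(counts) * log(sum(exp(z)))
}

# Maximise the multinomial log-likelihood along free directions of
# (sigma_t, sigma_i). `direction` is a 2 x k matrix mapping k free
# parameters to the weight pair; multi-start box-constrained quasi-Newton.
fit_scaled <- function(counts, logp, p_onc, p_pres, direction, sigma_max,
                       tol, starts) {
  k <- ncol(direction)
  obj <- function(par) {
    -ll_at(as.vector(direction %*% par), counts, logp, p_onc, p_pres)
  }
  if (k == 0L) {
    return(list(par = numeric(0), value = -obj(numeric(0)), convergence = 0L,
                n_starts_converged = 1L))
  }
  best <- NULL
  conv <- 0L
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(pmin(starts[s, seq_len(k)], sigma_max), obj, method = "L-BFGS-B",
            lower = rep(0, k), upper = rep(sigma_max, k),
            control = list(factr = tol / .Machine$double.eps, maxit = 500L)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0L) conv <- conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop_input("weight optimisation failed from all starts")
  list(par = best$par, value = -best$value, convergence = best$convergence,
       n_starts_converged = conv)
}

default_starts <- function() {
  matrix(c(0, 0, 1, 1, 5, 5, 10, 1, 1, 10), ncol = 2L, byrow = TRUE)
}

#' Fit free-fitness weights by maximum likelihood
#'
#' Maximises the multinomial log-likelihood of the observed counts over the
#' weights of the requested model: `"background"` fixes both weights at 0,
#' `"function_only"` fits `sigma_t`, `"immune_only"` fits `sigma_i`, and
#' `"combined"` fits both. The search is box-constrained quasi-Newton
#' (L-BFGS-B) on `[0, sigma_max]` with five deterministic starts; the
#' log-likelihood is concave in the weights, so multi-start is a safeguard,
#' not a necessity.
#'
#' @param counts Observed counts per mutation.
#' @param p Background probabilities.
#' @param p_onc,p_pres Component probabilities per mutation.
#' @param model One of `"background"`, `"function_only"`, `"immune_only"`,
#'   `"combined"`.
#' @param sigma_max Upper bound of the weight box (default 50).
#' @param positions Optional protein positions (adds per-position KL).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @return A `freefit_fit` list: `weights`, `model`, `log_lik`, `k` (number
#'   of free weights), `kl` and `kl_position`, `q`, `convergence`,
#'   `n_starts_converged`, plus the data (`counts`, `p`, `p_onc`, `p_pres`)
#'   for downstream comparison.
#' @export
fit_weights <- function(counts, p, p_onc, p_pres,
                        model = c("combined", "background", "function_only",
                                  "immune_only"),
                        sigma_max = 50, positions = NULL, tol = 1e-8) {
  model <- match.arg(model)
  stopifnot(length(counts) == length(p))
  if (sum(p > 0) < 2L) stop_input("need >= 2 mutations with nonzero background")
  if (sum(counts) < 1) stop_input("need at least one observed occurrence")
  keep <- p > 0
  counts <- counts[keep]; p <- p[keep]
  p_onc <- p_onc[keep]; p_pres <- p_pres[keep]
  if (!is.null(positions)) positions <- positions[keep]
  logp <- log(p / sum(p))
  direction <- switch(model,
    background = matrix(numeric(0), nrow = 2L, ncol = 0L),
    function_only = matrix(c(1, 0), ncol = 1L),
    immune_only = matrix(c(0, 1), ncol = 1L),
    combined = diag(2)
  )
  fit <- fit_scaled(counts, logp, p_onc, p_pres, direction, sigma_max, tol,
                    default_starts())
  w <- as.vector(direction %*% fit$par)
  if (!length(w)) w <- c(0, 0)
  f <- logp + w[1] * p_onc - w[2] * p_pres
  q <- predicted_frequencies(f)
  obs <- counts / sum(counts)
  res <- list(
    weights = c(sigma_t = w[1], sigma_i = w[2]),
    model = model,
    log_lik = fit$value,
    k = ncol(direction),
    kl = kl_divergence(obs, q),
    kl_position = if (!is.null(positions)) {
      kl_divergence(obs, q, positions = positions, aggregate = "position")
    } else NA_real_,
    q = q,
    convergence = fit$convergence,
    n_starts_converged = fit$n_starts_converged,
    data = list(counts = counts, p = p, p_onc = p_onc, p_pres = p_pres)
  )
  class(res) <- "freefit_fit"
  res
}

#' @export
print.freefit_fit <- function(x, ...) {
  cat(sprintf("<freefit_fit: %s> sigma_t = %.4f, sigma_i = %.4f, logLik = %.3f, KL = %.4f\n",
              x$model, x$weights["sigma_t"], x$weights["sigma_i"],
              x$log_lik, x$kl))
  invisible(x)
}

#' Compare fitted free-fitness models
#'
#' Ranks a set of fits of the same data by AIC (`2k - 2 logLik`, with `k`
#' the number of free weights) and reports the log-likelihood gap to the
#' best model and likelihood-ratio statistics of each model against the
#' background-only null.
#'
#' @param fits List of `freefit_fit` objects on identical data.
#' @return data.frame ordered by AIC: `model`, `k`, `log_lik`, `delta_ll`,
#'   `aic`, `delta_aic`, `lr_vs_background`, `kl`.
#' @export
model_comparison <- function(fits) {
  if (!length(fits)) stop_input("no fits supplied")
  d0 <- fits[[1]]$data
  for (f in fits) {
    if (!isTRUE(all.equal(f$data, d0))) {
      stop_input("fits were not computed on identical data")
    }
  }
  ll <- vapply(fits, `[[`, 0, "log_lik")
  k <- vapply(fits, `[[`, 0L, "k")
  aic <- 2 * k - 2 * ll
  bg <- which(vapply(fits, `[[`, "", "model") == "background")
  lr <- if (length(bg)) 2 * (ll - ll[bg[1]]) else rep(NA_real_, length(ll))
  out <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    k = k, log_lik = ll, delta_ll = max(ll) - ll,
    aic = aic, delta_aic = aic - min(aic),
    lr_vs_background = lr,
    kl = vapply(fits, `[[`, 0, "kl"),
    stringsAsFactors = FALSE
  )
  out[order(out$aic), , drop = FALSE]
}

#' Scan the relative immune weight
#'
#' Reparametrises the weights as `sigma_t = s (1 - lambda)`,
#' `sigma_i = s lambda` and, for each `lambda` on the grid, fits the
#' overall selection strength `s >= 0` by maximum likelihood, reporting the
#' KL divergence of the fitted model. `lambda = 0` reproduces the
#' function-only fit and `lambda = 1` the immune-only fit exactly.
#'
#' @inheritParams fit_weights
#' @param lambda_grid Grid in `[0, 1]` (default `seq(0, 1, 0.05)`).
#' @return data.frame `lambda`, `s_hat`, `sigma_t`, `sigma_i`, `log_lik`,
#'   `kl`, with attribute `lambda_star` (the KL-minimising grid point).
#' @export
weight_scan <- function(counts, p, p_onc, p_pres,
                        lambda_grid = seq(0, 1, by = 0.05),
                        sigma_max = 50, tol = 1e-8) {
  if (length(lambda_grid) < 2L || any(lambda_grid < 0 | lambda_grid > 1)) {
    stop_input("lambda_grid must have >= 2 points within [0, 1]")
  }
  keep <- p > 0
  counts <- counts[keep]; pk <- p[keep]
  p_onc <- p_onc[keep]; p_pres <- p_pres[keep]
  logp <- log(pk / sum(pk))
  obs <- counts / sum(counts)
  rows <- lapply(lambda_grid, function(lam) {
    dir <- matrix(c(1 - lam, lam), ncol = 1L)
    fit <- fit_scaled(counts, logp, p_onc, p_pres, dir, sigma_max, tol,
                      default_starts())
    s <- fit$par[1]
    w <- as.vector(dir) * s
    q <- predicted_frequencies(logp + w[1] * p_onc - w[2] * p_pres)
    data.frame(lambda = lam, s_hat = s, sigma_t = w[1], sigma_i = w[2],
               log_lik = fit$value, kl = kl_divergence(obs, q))
  })
  out <- do.call(rbind, rows)
  attr(out, "lambda_star") <- out$lambda[which.min(out$kl)]
  out
}
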