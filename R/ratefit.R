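#' @title Time-dependent substitution-rate fitting
#' @description Conversion of phylogenetic node heights and ages into
#'   per-generation substitution rates and non-linear fitting of the
#'   time-dependent rate curve `Rate(t) = mu * exp(-lambda t) + k`, whose
#'   value at t = 0 supplies the mutation rate used to scale the
#'   demographic models.
#' @name ratefit
NULL

#' Node substitution rates from heights and ages
#'
#' For each dated node, the per-generation substitution rate is the node
#' height (substitutions/site) divided by the node age expressed in
#' generations; the rate per million generations is that times 1e6.
#'
#' @param table data frame with columns `node`, `height`
#'   (substitutions/site) and `age_my` (node age, million years).
#' @param generation_time generation time in years (default 15, the
#'   average of the 13- and 17-year cycles).
#' @return The table with `rate_per_gen` and `rate_pmg` (per site per
#'   million generations) columns appended.
#' @export
node_rates <- function(table, generation_time = 15) {
  req <- c("node", "height", "age_my")
  if (!all(req %in% names(table)))
    stop("table needs columns: ", paste(req, collapse = ", "))
  if (any(table$age_my <= 0)) stop("node ages must be > 0")
  if (any(table$height <= 0)) stop("node heights must be > 0")
  gens <- table$age_my * 1e6 / generation_time
  table$rate_per_gen <- table$height / gens
  table$rate_pmg <- table$rate_per_gen * 1e6
  table
}

#' Fit the time-dependent rate curve
#'
#' Non-linear least squares of `rate = mu * exp(-lambda * t) + k` on the
#' raw rate scale with non-negativity bounds on all three parameters,
#' where `t` is node age in million years and rates are per site per
#' million generations.  Multi-start: the heuristic start
#' `(max - min rate, 1 / median age, min rate)` plus jittered restarts;
#' the lowest residual sum of squares wins.
#'
#' @param rates output of [node_rates()] (>= 3 rows), or any data frame
#'   with `age_my` and `rate_pmg`.
#' @param n_starts number of jittered restarts (default 10).
#' @param seed optional integer seed for the restarts.
#' @return A `rate_fit` with `mu`, `lambda`, `k`, `rss`, `converged`.
#' @export
fit_rate_curve <- function(rates, n_starts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(rates) < 3) stop("need at least 3 dated nodes")
  t <- rates$age_my
  y <- rates$rate_pmg
  start0 <- c(mu = max(y) - min(y), lambda = 1 / stats::median(t),
              k = min(y))
  start0["mu"] <- max(start0["mu"], 1e-8)
  starts <- list(start0)
  for (i in seq_len(n_starts - 1)) {
    starts[[i + 1]] <- start0 * stats::runif(3, 0.2, 5)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ mu * exp(-lambda * t) + k,
                        start = as.list(st),
                        lower = c(0, 0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  # flat-curve fallback (mu = 0): exact solution k = mean(y); covers the
  # degenerate constant-rate limit where the exponential model is singular
  flat <- list(mu = 0, lambda = 0, k = mean(y),
               rss = sum((y - mean(y))^2))
  if (is.null(best) || flat$rss <= best$rss) {
    return(structure(c(flat, list(converged = TRUE, n_points = nrow(rates))),
                     class = "rate_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(mu = unname(cf["mu"]), lambda = unname(cf["lambda"]),
                 k = unname(cf["k"]), rss = best$rss,
                 converged = best$fit$convInfo$isConv,
                 n_points = nrow(rates)),
            class = "rate_fit")
}

#' Evaluate the time-dependent rate curve
#'
#' `Rate(t) = mu * exp(-lambda t) + k`; at t = 0 this is the instantaneous
#' mutation rate `mu + k`, and the asymptote for large t is `k`.
#'
#' @param fit a `rate_fit`, or any list with `mu`, `lambda`, `k` (per site
#'   per million generations, t in million years).
#' @param t time (million years); vectorised.
#' @return Rate(t), per site per million generations.
#' @export
rate_at <- function(fit, t) {
  fit$mu * exp(-fit$lambda * t) + fit$k
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("rate_fit: mu = ", format(x$mu, digits = 4),
      ", lambda = ", format(x$lambda, digits = 4),
      ", k = ", format(x$k, digits = 4),
      " (per site per million generations); Rate(0) = ",
      format(x$mu + x$k, digits = 4), "; RSS = ",
      format(x$rss, digits = 3),
      if (!isTRUE(x$converged)) "  [not converged]", "\n", sep = "")
  invisible(x)
}

#' Convert a rate per million generations to a per-generation rate
#' @param rate_pmg rate per site per million generations.
#' @return Rate per site per generation (divided by 1e6).
#' @export
rate_per_generation <- function(rate_pmg) rate_pmg / 1e6
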