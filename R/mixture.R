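# k-means++ style seeding: spread initial means out with probability
# proportional to squared distance from the nearest chosen centre
kmeanspp_centers <- function(values, k) {
  centers <- numeric(k)
  centers[1] <- values[sample.int(length(values), 1L)]
  if (k > 1L) {
    d2 <- (values - centers[1])^2
    for (j in 2:k) {
      centers[j] <- if (sum(d2) <= 0) {
        values[sample.int(length(values), 1L)]
      } else {
        values[sample.int(length(values), 1L, prob = d2)]
      }
      d2 <- pmin(d2, (values - centers[j])^2)
    }
  }
  centers
}

#' Fit a univariate normal mixture by EM
#'
#' Expectation-maximisation from `n_restarts` k-means++-seeded starts;
#' the best-log-likelihood restart is returned. Component standard
#' deviations are floored at `1e-4` so no component can degenerate into
#' a spike on a single observation. Either all components share one
#' variance (`"equal"`) or each has its own (`"unequal"`). The reported
#' BIC is the minimised form `-2 * loglik + p * log(n)` with
#' `p = (k - 1) + k + 1` (equal) or `(k - 1) + 2k` (unequal).
#'
#' @param values numeric observations (`length(values) > k`).
#' @param k number of components.
#' @param variance_mode `"unequal"` or `"equal"`.
#' @param n_restarts independent EM starts.
#' @param seed optional integer seed (restarts are reproducible).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @return A `normal_mixture` object: components sorted by mean, with
#'   `weights`, `means`, `sds`, `loglik`, `bic`, `loglik_trace` of the
#'   winning restart, `n_iter`, `converged`.
#' @export
fit_normal_mixture <- function(values, k, variance_mode = c("unequal", "equal"),
                               n_restarts = 20L, seed = NULL,
                               tol = 1e-7, max_iter = 500L) {
  variance_mode <- match.arg(variance_mode)
  values <- as.numeric(values)
  if (any(!is.finite(values))) abort("`values` must be finite")
  n <- length(values)
  if (n <= k) abort("need more observations than components")
  if (var(values) == 0) abort("all values identical: zero variance")
  sd_floor <- 1e-4
  with_seed_if(seed, {
    s0 <- max(sd(values), sd_floor)
    if (k == 1L) {
      # closed form: single component has an exact MLE
      mu <- mean(values)
      s <- max(sqrt(mean((values - mu)^2)), sd_floor)
      ll <- sum(dnorm(values, mu, s, log = TRUE))
      best <- list(weights = 1, means = mu, sds = s, loglik = ll,
                   loglik_trace = ll, n_iter = 1L, converged = TRUE)
    } else {
      # screen restarts with a short burn-in, then run the best start to
      # full convergence (standard multi-start EM economy)
      burn <- as.integer(min(max_iter, 50L))
      starts <- lapply(seq_len(n_restarts), function(r) {
        sort(kmeanspp_centers(values, k))
      })
      fits <- lapply(starts, function(mu0) {
        .em_normal_mixture(values, mu0, rep(s0 / sqrt(k), k), rep(1 / k, k),
                           variance_mode == "equal", sd_floor, burn, tol)
      })
      best0 <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
      best <- if (best0$converged) best0 else {
        .em_normal_mixture(values, best0$means, best0$sds, best0$weights,
                           variance_mode == "equal", sd_floor,
                           as.integer(max_iter), tol)
      }
    }
    p <- if (variance_mode == "equal") (k - 1) + k + 1 else (k - 1) + 2 * k
    ord <- order(best$means)
    structure(
      list(k = as.integer(k),
           weights = best$weights[ord],
           means = best$means[ord],
           sds = best$sds[ord],
           loglik = best$loglik,
           bic = -2 * best$loglik + p * log(n),
           variance_mode = variance_mode,
           n = n,
           seed = seed,
           loglik_trace = best$loglik_trace,
           n_iter = best$n_iter,
           converged = best$converged),
      class = "normal_mixture"
    )
  })
}

#' Select a normal mixture by BIC over component counts and variance modes
#'
#' Fits every combination of `k_range` and `variance_modes` and returns
#' the minimum-BIC model; ties break toward fewer components, then the
#' equal-variance family. Individual fit failures are skipped with a
#' warning.
#'
#' @param values numeric observations.
#' @param k_range candidate component counts.
#' @param variance_modes variance families to try.
#' @param seed optional integer seed.
#' @param n_restarts EM restarts per candidate fit.
#' @param tol EM convergence tolerance used during model screening (the
#'   looser default follows common mixture-selection practice; refit the
#'   winner with [fit_normal_mixture()] for tighter parameter estimates).
#' @param ... passed to [fit_normal_mixture()].
#' @return The winning `normal_mixture`.
#' @export
select_model_bic <- function(values, k_range = 1:8,
                             variance_modes = c("equal", "unequal"),
                             seed = NULL, n_restarts = 5L, tol = 1e-5, ...) {
  grid <- expand.grid(k = sort(k_range), mode = variance_modes,
                      stringsAsFactors = FALSE)
  # order so ties on BIC resolve to smaller k, then equal variance
  grid <- grid[order(grid$k, grid$mode != "equal"), , drop = FALSE]
  seeds <- derive_seeds(seed %||% 1L, nrow(grid))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      fit_normal_mixture(values, grid$k[i], variance_mode = grid$mode[i],
                         n_restarts = n_restarts, seed = seeds[i],
                         tol = tol, ...),
      error = function(e) {
        warn(sprintf("fit with k=%d (%s) failed: %s",
                     grid$k[i], grid$mode[i], conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(fit) && (is.null(best) || fit$bic < best$bic)) best <- fit
  }
  if (is.null(best)) abort("all mixture fits failed")
  best
}

#' Split mixture components into small-scale-duplication and WGD peaks
#'
#' Components whose mean falls below `ssd_mean_threshold` are attributed
#' to recent small-scale duplications; the rest are WGD peaks, reported
#' in ascending mean order.
#'
#' @param model a fitted `normal_mixture`.
#' @param ssd_mean_threshold corrected-4DTv boundary between SSD and WGD
#'   components.
#' @return A `wgd_peaks` tibble (`component`, `mean`, `sd`, `weight`,
#'   `type`) with attribute `n_wgd`; see [n_wgd_peaks()].
#' @export
classify_wgd_peaks <- function(model, ssd_mean_threshold = 0.1) {
  if (!inherits(model, "normal_mixture") || model$k < 1) {
    abort("`model` must be a fitted normal_mixture")
  }
  out <- tibble(
    component = seq_len(model$k),
    mean = model$means, sd = model$sds, weight = model$weights,
    type = ifelse(model$means < ssd_mean_threshold, "ssd", "wgd")
  ) %>% arrange(.data$mean)
  attr(out, "n_wgd") <- sum(out$type == "wgd")
  class(out) <- c("wgd_peaks", class(out))
  out
}

#' Number of WGD peaks in a peak report
#' @param peaks a `wgd_peaks` tibble.
#' @return Integer count of WGD-classified components.
#' @export
n_wgd_peaks <- function(peaks) {
  sum(peaks$type == "wgd")
}

#' @export
print.normal_mixture <- function(x, ...) {
  cat(sprintf("Normal mixture: k = %d (%s variance), n = %d, loglik = %.2f, BIC = %.2f\n",
              x$k, x$variance_mode, x$n, x$loglik, x$bic))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.normal_mixture <- function(x, ...) {
  tibble(component = seq_len(x$k), weight = x$weights,
         mean = x$means, sd = x$sds)
}

#' @export
glance.normal_mixture <- function(x, ...) {
  tibble(k = x$k, variance_mode = x$variance_mode, loglik = x$loglik,
         bic = x$bic, n = x$n, n_iter = x$n_iter, converged = x$converged)
}
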