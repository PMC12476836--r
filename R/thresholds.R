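#' Expected-minimum curve by subsampling a non-binder score pool
#'
#' For each requested subsample size n, draws n MiniPAE scores from the
#' non-binder pool (without replacement by default), records the minimum,
#' and repeats `iterations` times; the mean of these minima estimates the
#' best score expected among n non-binders, i.e. the noise floor a screen
#' of size n must beat. Fully reproducible: each size uses an RNG stream
#' derived deterministically from `seed`, so adding or reordering sizes
#' does not perturb the others.
#'
#' @param scores Numeric vector of non-binder MiniPAE values (the pool).
#' @param sizes Integer vector of subsample sizes; default a log-spaced
#'   grid `{1, 2, 5, 10, 25, 50, 100, 250, 500, 1000}` capped at pool size.
#' @param iterations Subsamplings per size (default 100).
#' @param seed Master integer seed.
#' @param replace Sample with replacement instead of without.
#' @return A data frame of class `minima_curve` with columns `n`,
#'   `avg_min`, `iterations`, `sd`.
#' @export
subsample_minima <- function(scores, sizes = NULL, iterations = 100L,
                             seed = 1L, replace = FALSE) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L || anyNA(scores)) {
    stop_slimpae("score pool must be non-empty and free of NA",
                 "slimpae_degenerate_input_error")
  }
  if (is.null(sizes)) {
    sizes <- c(1L, 2L, 5L, 10L, 25L, 50L, 100L, 250L, 500L, 1000L)
    sizes <- sizes[sizes <= length(scores)]
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) {
    stop_slimpae("subsample sizes must be >= 1", "slimpae_domain_error")
  }
  if (!replace && any(sizes > length(scores))) {
    stop_slimpae("subsample size %d exceeds pool size %d",
                 "slimpae_sampling_error", max(sizes), length(scores))
  }
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)

  rows <- lapply(seq_along(sizes), function(k) {
    n <- sizes[k]
    minima <- with_seed(derive_seed(seed, k), {
      vapply(seq_len(iterations), function(i) {
        min(sample(scores, n, replace = replace))
      }, numeric(1))
    })
    data.frame(n = n, avg_min = mean(minima), iterations = iterations,
               sd = stats::sd(minima))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("minima_curve", "data.frame")
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Fit the power-law threshold model to an expected-minimum curve
#'
#' Fits y = a x^-b + c by nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nlsLM()]), where x is the subsample
#' size and y the average minimum MiniPAE. Starting values: a = range of
#' y, b = 0.3, c = min(y). The fitted model predicts the adaptive
#' threshold for any screen size.
#'
#' @param points A `minima_curve` (or data frame with columns `n`,
#'   `avg_min`), at least 4 points over at least 3 distinct sizes.
#' @return An object of class `threshold_model` with fields `a`, `b`, `c`,
#'   `fit_points`, `rss`, `converged` and `seed` (carried over from the
#'   curve when present).
#' @export
fit_power_law <- function(points) {
  stopifnot(is.data.frame(points), all(c("n", "avg_min") %in% names(points)))
  if (nrow(points) < 4L || length(unique(points$n)) < 3L) {
    stop_slimpae(
      "need >= 4 points over >= 3 distinct sizes to fit 3 parameters",
      "slimpae_underdetermined_error")
  }
  x <- as.numeric(points$n)
  y <- as.numeric(points$avg_min)
  if (diff(range(y)) < 1e-10) {
    # flat curve: the power law degenerates to a = 0, threshold = constant
    out <- threshold_model(0, 0.3, mean(y))
    out$fit_points <- as.data.frame(points)
    out$rss <- sum((y - mean(y))^2)
    out$converged <- TRUE
    out$seed <- attr(points, "seed")
    return(out)
  }
  start <- list(a = max(y) - min(y), b = 0.3, c = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^(-b) + c, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop_slimpae("power-law fit failed to converge: %s",
                   "slimpae_fit_failure_error", conditionMessage(e))
    }
  )
  cf <- stats::coef(fit)
  structure(
    list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
         fit_points = as.data.frame(points),
         rss = sum(stats::resid(fit)^2),
         converged = fit$convInfo$isConv %||% TRUE,
         seed = attr(points, "seed")),
    class = "threshold_model"
  )
}

#' Construct a threshold model from known constants
#'
#' @param a,b,c Power-law parameters of threshold(n) = a n^-b + c.
#' @return An object of class `threshold_model`.
#' @export
threshold_model <- function(a, b, c) {
  assert_scalar_number(a, "a"); assert_scalar_number(b, "b")
  assert_scalar_number(c, "c")
  structure(list(a = a, b = b, c = c, fit_points = NULL, rss = NA_real_,
                 converged = NA, seed = NULL),
            class = "threshold_model")
}

#' Predict the MiniPAE threshold for a screen of size n
#'
#' @param model A `threshold_model`.
#' @param n Screen size (>= 1), vectorized.
#' @return Threshold(s) in Angstrom: a n^-b + c.
#' @export
predict_threshold <- function(model, n) {
  stopifnot(inherits(model, "threshold_model"))
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop_slimpae("screen size n must be >= 1", "slimpae_domain_error")
  }
  model$a * n^(-model$b) + model$c
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> threshold(n) = %.4g * n^-%.4g + %.4g\n",
              x$a, x$b, x$c))
  if (!is.null(x$fit_points)) {
    cat(sprintf("  fitted on %d points, RSS %.4g\n", nrow(x$fit_points), x$rss))
  }
  invisible(x)
}
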