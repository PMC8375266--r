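# The random-walk stochastic optimizer. Derivative-free minimization by
# repeated random steps of shrinking length; simple, and hard to trap in a
# poor local minimum because the direction is resampled fresh every trial.

#' Random-walk optimizer configuration
#'
#' @param lambda0 initial step length (> 0).
#' @param epsilon control accuracy: the walk ends once the step length
#'   shrinks below this value (0 < epsilon < lambda0).
#' @param nTries consecutive failed trials before the step length is
#'   halved.
#' @param maxEvals global budget of objective evaluations.
#' @param dim embedding dimension per gene (used by [encodeNetwork()]).
#' @param seed RNG seed; a fixed seed makes the walk deterministic.
#' @return validated list of class "RwConfig".
#' @export
rwConfig <- function(lambda0 = 1, epsilon = 1e-4, nTries = 30L,
                     maxEvals = 100000L, dim = 16L, seed = 1L) {
  stopifnot(lambda0 > 0, epsilon > 0, nTries >= 1, maxEvals >= 1, dim >= 1)
  if (epsilon >= lambda0)
    stop("epsilon must be smaller than lambda0")
  structure(list(lambda0 = lambda0, epsilon = epsilon,
                 nTries = as.integer(nTries),
                 maxEvals = as.integer(maxEvals), dim = as.integer(dim),
                 seed = as.integer(seed)),
            class = "RwConfig")
}

#' Minimize a function by random walk with shrinking step length
#'
#' From the current point x, a direction u is drawn uniformly from
#' (-1, 1)^n and normalized to unit length, and the candidate
#' x1 = x + lambda * u' is evaluated. A candidate is accepted iff it is
#' strictly better (f(x1) < f(x)); acceptance resets the failure counter.
#' After \code{nTries} consecutive failures the optimum is taken to lie
#' inside the sphere of radius lambda around x, so lambda is halved and a
#' new round starts; the walk terminates when lambda drops below
#' \code{epsilon} (or the evaluation budget runs out, in which case the
#' best point so far is returned with attribute \code{truncated = TRUE}).
#' After r failed rounds lambda equals lambda0 / 2^r exactly, so at most
#' ceiling(log2(lambda0 / epsilon)) rounds are possible and termination is
#' guaranteed.
#'
#' @param f objective: function of a numeric vector returning a scalar.
#' @param x0 numeric start vector; f(x0) must be finite.
#' @param cfg an [rwConfig()].
#' @return list with \code{x} (best point), \code{f} (best value, never
#'   worse than f(x0)), \code{evals} (candidate evaluations used) and
#'   \code{lambda} (final step length); attribute \code{truncated} flags
#'   budget exhaustion.
#' @examples
#' r <- rwMinimize(function(x) sum(x^2), c(3, 4),
#'                 rwConfig(lambda0 = 1, epsilon = 1e-4, seed = 7))
#' r$f  # < 1e-4
#' @export
rwMinimize <- function(f, x0, cfg = rwConfig()) {
  stopifnot(inherits(cfg, "RwConfig"))
  x <- as.numeric(x0)
  fx <- f(x)
  if (!is.finite(fx)) stop("objective is not finite at x0")
  withSeed(cfg$seed, {
    lambda <- cfg$lambda0
    k <- 1L
    evals <- 0L
    truncated <- FALSE
    n <- length(x)
    repeat {
      if (evals >= cfg$maxEvals) { truncated <- TRUE; break }
      u <- stats::runif(n, -1, 1)
      nu <- sqrt(sum(u^2))
      while (nu == 0) {           # degenerate draw: resample
        u <- stats::runif(n, -1, 1)
        nu <- sqrt(sum(u^2))
      }
      x1 <- x + lambda * (u / nu)
      f1 <- f(x1)
      evals <- evals + 1L
      if (is.finite(f1) && f1 < fx) {   # strict improvement only
        x <- x1; fx <- f1; k <- 1L
      } else {
        k <- k + 1L
        if (k > cfg$nTries) {           # round failed: shrink the step
          lambda <- lambda / 2
          k <- 1L
          if (lambda < cfg$epsilon) break
        }
      }
    }
    structure(list(x = x, f = fx, evals = evals, lambda = lambda),
              truncated = truncated)
  })
}
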