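#' Unidirectionally coupled Henon maps
#'
#' Generates a driver--response pair of Henon-map trajectories. The driver is
#' the standard map `x[n+1] = 1.4 - x[n]^2 + 0.3 x[n-1]`; the response has the
#' driver mixed into its quadratic term with weight `coupling`:
#' `y[n+1] = 1.4 - (c x[n] + (1 - c) y[n]) y[n] + 0.3 y[n-1]`. At `coupling = 0`
#' the two maps are independent; as `coupling` grows the response becomes
#' generalized-synchronized with the driver, which is the regime the
#' synchronization-likelihood estimator is designed to detect.
#'
#' @param n Number of samples to return (after discarding transients).
#' @param coupling Coupling constant in `[0, 1]`.
#' @param seed Integer seed for the random initial conditions.
#' @param transient Samples discarded from the start (default 200).
#' @return A list with numeric vectors `x` (driver) and `y` (response).
#' @examples
#' h <- henon_pair(1000, coupling = 0.6, seed = 1)
#' @export
henon_pair <- function(n, coupling = 0, seed = 1, transient = 200L) {
  stopifnot(n >= 1, coupling >= 0, coupling <= 1)
  ntot <- n + transient
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # restart from fresh initial conditions if a trajectory escapes to infinity
  repeat {
    x <- numeric(ntot); y <- numeric(ntot)
    x[1:2] <- runif(2, -0.5, 0.5)
    y[1:2] <- runif(2, -0.5, 0.5)
    ok <- TRUE
    for (i in 3:ntot) {
      x[i] <- 1.4 - x[i - 1]^2 + 0.3 * x[i - 2]
      y[i] <- 1.4 - (coupling * x[i - 1] + (1 - coupling) * y[i - 1]) * y[i - 1] +
        0.3 * y[i - 2]
      if (!is.finite(x[i]) || !is.finite(y[i]) || abs(x[i]) > 10 || abs(y[i]) > 10) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  list(x = x[(transient + 1):ntot], y = y[(transient + 1):ntot])
}
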