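# Poisson-Gaussian corruption of test radiographs at named severity
# levels, modeling photon (quantum) noise and detector/readout
# electronic noise.

#' Named noise severity levels
#'
#' A level couples a Poisson photon-count scale \code{lam} (rate
#' parameter: the expected count at unit intensity, so relative photon
#' noise shrinks as lam grows) with a Gaussian standard deviation
#' \code{sigma} on the [0, 1] intensity scale. The shipped defaults span
#' visibly mild to severe corruption at 224 x 224 scale: low
#' (lam 200, sigma 0.01), medium (lam 50, sigma 0.03), high
#' (lam 10, sigma 0.08). All are configurable.
#'
#' @param name "low", "medium", "high", or any label when \code{lam} and
#'   \code{sigma} are given explicitly.
#' @param lam Poisson rate scale, > 0.
#' @param sigma Gaussian standard deviation, >= 0.
#' @return a classed list with elements name, lam, sigma.
#' @export
noiseLevel <- function(name = c("low", "medium", "high"), lam = NULL,
                       sigma = NULL) {
  if (is.null(lam) || is.null(sigma)) {
    name <- match.arg(name)
    preset <- switch(name,
                     low = c(200, 0.01),
                     medium = c(50, 0.03),
                     high = c(10, 0.08))
    if (is.null(lam)) lam <- preset[1]
    if (is.null(sigma)) sigma <- preset[2]
  }
  if (!is.finite(lam) || lam <= 0) stop("lam must be > 0")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(name = as.character(name)[1], lam = lam, sigma = sigma),
            class = "NoiseLevel")
}

#' Add Poisson-Gaussian noise to a normalized image
#'
#' Simulates photon noise by drawing per-pixel Poisson counts at rate
#' \code{v * lam} and rescaling by \code{1 / lam}, then adds zero-mean
#' Gaussian noise of standard deviation \code{sigma}, and clips to
#' [0, 1]:
#' \code{out = clip(Poisson(v * lam) / lam + N(0, sigma^2), 0, 1)}.
#' Reproducible under \code{seed}.
#'
#' @param image numeric matrix with values in [0, 1].
#' @param level a [noiseLevel()].
#' @param seed integer seed.
#' @return corrupted image, same shape, values in [0, 1].
#' @export
addPoissonGaussian <- function(image, level = noiseLevel("medium"),
                               seed = 1L) {
  stopifnot(inherits(level, "NoiseLevel"))
  if (!is.numeric(image))
    stop("image must be numeric")
  if (any(!is.finite(image)) || min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image must be normalized to [0, 1] before noise injection")
  d <- dim(image)
  out <- .with_seed(as.integer(seed), {
    counts <- stats::rpois(length(image), as.vector(image) * level$lam)
    counts / level$lam + stats::rnorm(length(image), 0, level$sigma)
  })
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- d
  out
}
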