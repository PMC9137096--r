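## internal helpers shared across modules

## run `code` under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so simulation calls do not perturb
## user-level randomness. seed = NULL uses (and advances) the ambient stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## snap intensities onto the 16-bit grid k/65535 (the camera bit depth the
## stacks are stored at), so TIFF round trips are bit-identical.
quantize16 <- function(x) {
  d <- dim(x)
  out <- round(as.numeric(x) * 65535) / 65535
  dim(out) <- d
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Default detection threshold for the green (live) channel
#'
#' Objects whose mean green intensity exceeds this value count as labeled.
#' The default sits three noise standard deviations above the baseline
#' background of the default optical model, so an unstained well scores 0
#' percent and any labeled object (intensity of order 1) clears it easily.
#'
#' @param optics an [OpticalModel-class]; defaults to [opticalModel()].
#' @return numeric threshold on mean green intensity.
#' @export
#' @examples
#' defaultGreenThreshold()
defaultGreenThreshold <- function(optics = opticalModel()) {
  optics@backgroundBase + 3 * optics@noiseSd
}
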