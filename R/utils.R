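# Internal helpers shared across modules.

# Run code under a local RNG stream without disturbing the caller's RNG.
withLocalSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed; stays below 2^31.
childSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 1009) %% 2147483647
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# ITU-R BT.709 luminance for an RGB array (rows x cols x 3).
toGray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3 && d[3] >= 3)
    return(0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3])
  if (length(d) == 3 && d[3] == 1) return(img[, , 1])
  stop("expected a matrix or an RGB array")
}

# Euclidean distance between rows of a and a single point p.
distToPoint <- function(coords, p) {
  sqrt((coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2)
}
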