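#' @importFrom rlang %||%
#' @importFrom stats rnorm runif median setNames
#' @importFrom utils head tail
NULL

ARENA_SIZE <- 40

vec3 <- function(x = 0, y = 0, z = 0) list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))

as_vec3 <- function(v) {
  if (is.list(v)) return(vec3(v$x %||% 0, v$y %||% 0, v$z %||% 0))
  if (is.numeric(v) && length(v) == 3) return(vec3(v[1], v[2], v[3]))
  if (is.numeric(v) && length(v) == 1) return(vec3(v, v, v))
  stop("cannot interpret value as a 3-vector", call. = FALSE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180

# heading unit vector on the x-z plane; yaw 0 points along +z, positive yaw
# turns clockwise when viewed from above (right)
heading_vec <- function(yaw) {
  a <- deg2rad(yaw)
  c(sin(a), cos(a))
}

norm_yaw <- function(yaw) ((yaw %% 360) + 360) %% 360

# signed smallest angle from yaw `from` to yaw `to`, in (-180, 180]
yaw_diff <- function(from, to) {
  d <- norm_yaw(to - from)
  if (d > 180) d <- d - 360
  d
}

## ---- deterministic RNG streams --------------------------------------------
## A mutable RNG handle isolated from the global .Random.seed, so that
## simulator randomness is a pure function of the seed it was created with and
## never perturbs (or is perturbed by) user code.

rng_new <- function(seed) {
  h <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  h$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(h) <- "arenalab_rng"
  h
}

rng_do <- function(rng, fn) {
  stopifnot(inherits(rng, "arenalab_rng"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

rng_runif <- function(rng, n = 1, min = 0, max = 1) rng_do(rng, function() runif(n, min, max))
rng_rnorm <- function(rng, n = 1, mean = 0, sd = 1) rng_do(rng, function() rnorm(n, mean, sd))
rng_sample <- function(rng, x, size = 1, prob = NULL) {
  rng_do(rng, function() {
    if (length(x) == 1 && is.numeric(x)) x <- seq_len(x)
    x[sample.int(length(x), size = size, replace = TRUE, prob = prob)]
  })
}

# derive a well-separated child seed (kept below 2^31)
derive_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  h <- 0
  for (v in ix) h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h)
}
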