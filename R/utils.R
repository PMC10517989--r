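# Physical constants shared across the package.
C_LIGHT <- 299792458      # speed of light, m/s
EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Derive a stage seed from a master seed
#'
#' A single master seed fans out to per-stage seeds by stable hashing of the
#' stage name, so that adding a stage never perturbs the random stream of
#' another. The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"train"`, `"sample3"`).
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @export
seed_for <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(master) + h) %% 2147483647)
}

# Evaluate `expr` under a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

l2norm <- function(x) sqrt(sum(Mod(x)^2))

stop_validation <- function(...) stop(..., call. = FALSE)

# Complex values round-trip through JSON as a list of re/im arrays.
complex_to_json <- function(z) list(re = Re(z), im = Im(z), dim = dim(z))

complex_from_json <- function(obj) {
  z <- complex(real = unlist(obj$re), imaginary = unlist(obj$im))
  if (!is.null(obj$dim) && length(obj$dim)) dim(z) <- unlist(obj$dim)
  z
}
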