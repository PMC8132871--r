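#' @useDynLib desp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif prcomp setNames
#' @importFrom utils read.delim write.table modifyList
NULL

TWO_PI <- 2 * pi

#' Wrap angles to the interval (-pi, pi]
#'
#' @param x numeric vector or matrix of angles in radians.
#' @return object of the same shape with every value in (-pi, pi].
#' @export
wrap_angle <- function(x) {
  x - TWO_PI * ceiling((x - pi) / TWO_PI)
}

stop_desp <- function(..., class = "desp_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_desp(name, " must be a single finite number", class = "desp_config_error")
  if (integer && x != round(x))
    stop_desp(name, " must be an integer", class = "desp_config_error")
  if (x < lower || x > upper)
    stop_desp(name, " must be in [", lower, ", ", upper, "]",
              class = "desp_config_error")
  invisible(x)
}

## Independent, reproducible RNG streams.  One global seed fans out to named
## component streams (dynamics, vae, reps, synthetic, ...) so that, e.g., VAE
## retraining never perturbs the dynamics noise sequence.  Streams are plain
## .Random.seed snapshots swapped in and out around each use.

rng_stream_new <- function(seed) {
  old <- get_rs()
  on.exit(set_rs(old))
  set.seed(as.integer(seed))
  get_rs()
}

get_rs <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rs <- function(state) {
  if (is.null(state)) return(invisible(NULL))
  assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

## Evaluate expr with the given stream state active; returns list(value, state).
with_stream <- function(state, expr) {
  old <- get_rs()
  set_rs(state)
  value <- force(expr)
  new_state <- get_rs()
  set_rs(old)
  list(value = value, state = new_state)
}

#' Derive a per-component seed from a global run seed
#'
#' One global seed fans out to named component streams (dynamics noise, VAE
#' initialization/shuffling, representative sampling, ...) so that components
#' are independently reproducible. The derivation is a fixed hash kept below
#' 2^31.
#'
#' @param seed integer global seed.
#' @param component character label of the consuming component.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, component) {
  base <- as.double(seed %% 2147483647L)
  off <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((base * 69069 + off) %% 2147483647)
}
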