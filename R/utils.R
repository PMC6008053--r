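`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's random stream so that
#' seeded helpers do not perturb surrounding code. All stochastic functions in
#' the package draw through this helper.
#'
#' @param seed integer seed, or `NULL` to leave the stream untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

msg <- function(fmt, ...) message("[dynasilac] ", sprintf(fmt, ...))

stop_format <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# sample-sd by column of a matrix, used by resampling code
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}
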