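#' @import data.table
#' @importFrom stats rnbinom rpois rbinom runif median var pchisq pnorm pt
#'   dhyper p.adjust setNames complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name, min, max)
  invisible(x)
}

#' Deterministic sub-seed derivation
#'
#' Derives a stream-specific 32-bit seed from a base seed and a label so that
#' independent generator stages draw from independent, reproducible streams.
#'
#' @param seed integer base seed.
#' @param label character stream label.
#' @return integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, label) {
  # polynomial rolling hash of the label (exact in double arithmetic)
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147480009
  as.integer((as.numeric(seed) * 69069 + h) %% 2147480009)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# md5 of an R object via its canonical JSON serialization (content hashing for
# the pipeline cache; structure, not attribute order, determines the hash)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
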