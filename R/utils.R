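#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib molimage, .registration = TRUE
NULL

# Stable content hash used for image provenance and manifests.
content_hash <- function(x) rlang::hash(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Derive a child seed from a base seed and a stream label, kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- utf8ToInt(content_hash(list(as.integer(seed), as.character(stream))))
  as.integer((sum(h * seq_along(h)) + as.integer(seed)) %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
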