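# internal helpers shared across modules

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed and an index, kept
# within the 32-bit integer range R requires of set.seed().
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1000003) %% 2147483629)
}

#' Names of the seven analysis variables
#'
#' The four texture variables and three structure variables retained after
#' correlation filtering that every statistical stage operates on.
#'
#' @return Character vector of length 7.
#' @export
analysis_variables <- function() {
  c("kappa", "diagonal_moment", "entropy", "cluster_shade",
    "lend", "l220", "l250")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
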