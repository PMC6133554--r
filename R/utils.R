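#' @keywords internal
"_PACKAGE"

# Compartment names, innermost first. The order is load-bearing: boundary
# ties in cell assignment resolve to the innermost containing compartment.
COMPARTMENTS <- c("TU_CORE", "MARG_500_IN", "MARG_500_OUT")

TOPO_LEVELS <- c("cold", "excluded", "hot")

UM2_PER_MM2 <- 1e6

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

# Deterministic per-patient substream seed derived from a master seed, so a
# cohort can be extended without reshuffling already-generated patients.
# Kept strictly below 2^31 - 1.
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + as.double(index) * 7919) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
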