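`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so seeded helpers do not
#' perturb the surrounding random stream. With `seed = NULL` the expression
#' is evaluated unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Fan one master seed out to independent per-stage child seeds (kept below
# .Machine$integer.max so they remain valid R integer seeds).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Geometric mean with a floor on each factor; the floor prevents a single
# zero from annihilating the product (log(0) = -Inf). Length-1 input is
# returned directly so singleton aggregation is exact, not exp(log(x)).
geo_mean_floored <- function(x, eps = 1e-12) {
  x <- pmax(x, eps)
  if (length(x) == 1L) return(unname(x))
  exp(mean(log(x)))
}
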