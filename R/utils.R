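#' @useDynLib bwsportrait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test fft filter kruskal.test wilcox.test
#'   friedman.test median quantile rnorm runif sd setNames aggregate
#'   p.adjust pnorm pchisq var predict
#' @importFrom graphics barplot
#' @importFrom utils head write.csv read.csv
NULL

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers are unaffected.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Hashes the master seed together with arbitrary character labels
#' (stage names, participant ids, ...) into a 31-bit integer, so that any
#' pipeline stage can be re-run in isolation with the same stream.
#'
#' @param master_seed integer master seed.
#' @param ... character or numeric labels identifying the stream.
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42, "design", "P01")
derive_seed <- function(master_seed, ...) {
  labels <- paste(c(as.character(master_seed), as.character(unlist(list(...)))),
                  collapse = "\x1f")
  bytes <- utf8ToInt(labels)
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (b in bytes) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bws <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "bws_error")))
}
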