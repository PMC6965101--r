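#' @importFrom stats rnorm runif rexp rbinom qnorm pnorm qchisq pchisq cor
#'   cor.test sd median setNames complete.cases coef ks.test quantile var
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Derive a deterministic per-stage seed from a global seed
#'
#' Stage seeds are a fixed arithmetic function of the global seed and the
#' stage name so that any stage can be re-run in isolation and reproduce the
#' run-pipeline result bit for bit.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 10007) %% 2147483647)
}

## internal: consistent error helper with a class so tests can target it
grpmError <- function(msg, class) {
  stop(structure(
    class = c(class, "grpmError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## internal: permutation-style P estimate with the (k+1)/(n+1) floor
permP <- function(k, n) (k + 1) / (n + 1)

## internal: check a scalar probability-like argument
checkProb <- function(x, name, open0 = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)) ||
      any(x > 1) || any(if (open0) x <= 0 else x < 0)) {
    grpmError(sprintf("'%s' must lie in %s", name,
                      if (open0) "(0, 1]" else "[0, 1]"),
              "invalidConfigError")
  }
  invisible(TRUE)
}
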