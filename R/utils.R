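#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named RNG substream seed from a master seed
#'
#' Every stochastic operation in the package draws its seed from the master
#' seed plus a stable hash of the operation name, so that stages can be rerun
#' independently without replaying the whole stream.
#'
#' @param seed master seed (integer).
#' @param name substream label.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h) %% 2147483647L
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

## z-score over non-missing values; degenerate SD -> zeros
zscore <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(ifelse(is.na(x), NA_real_, 0))
  (x - m) / s
}

stop_sibscore <- function(msg, class) {
  stop(structure(class = c(class, "sibscore_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
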