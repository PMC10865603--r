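#' @useDynLib insightsleep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sigmoid <- function(z) 1 / (1 + exp(-z))

relu <- function(z) {
  z[z < 0] <- 0
  z
}

next_pow2 <- function(n) as.integer(2^ceiling(log2(n)))

#' Column-wise softmax
#'
#' Overflow-safe softmax over the rows of each column (classes in rows,
#' epochs in columns).
#'
#' @param z numeric matrix of scores, classes x time.
#' @return matrix of the same shape with columns summing to one.
#' @keywords internal
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_insight <- function(..., class = "insightsleep_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
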