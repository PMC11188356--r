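#' Inverse-logit (expit) transform
#'
#' Maps a logit-scale value to a probability, `1 / (1 + exp(-x))`. This is the
#' link inverse used throughout the package to turn the structural linear
#' predictor `E0 + Edrug (+ eta)` into a response probability.
#'
#' @param x numeric vector of logit-scale values (must be finite).
#' @return numeric vector of probabilities in (0, 1).
#' @seealso [logit()], [response_probability()]
#' @export
#' @examples
#' inverse_logit(0)      # 0.5
#' inverse_logit(-2.22)  # ~0.098
inverse_logit <- function(x) {
  if (any(!is.finite(x))) stop("inverse_logit() requires finite input")
  stats::plogis(x)
}

#' Logit transform
#'
#' @param p numeric vector of probabilities in (0, 1).
#' @return numeric vector of logit-scale values.
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("logit() requires p strictly in (0, 1)")
  stats::qlogis(p)
}

# Gauss-Hermite nodes and weights for weight function exp(-x^2), computed by
# the Golub-Welsch eigen-decomposition of the Jacobi matrix. Exact for
# polynomials up to degree 2n - 1.
.gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  out <- if (n == 1L) list(nodes = 0, weights = sqrt(pi)) else {
    i <- seq_len(n - 1)
    J <- matrix(0, n, n)
    off <- sqrt(i / 2)
    J[cbind(i, i + 1)] <- off
    J[cbind(i + 1, i)] <- off
    e <- eigen(J, symmetric = TRUE)
    list(nodes = rev(e$values), weights = rev(sqrt(pi) * e$vectors[1, ]^2))
  }
  .gh_cache[[key]] <- out
  out
}

# numerically stable log(sum(exp(x))) by rows of a matrix
.row_logsumexp <- function(m) {
  mx <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clip probabilities away from 0/1 for log terms; B ~ -39 at week 0 underflows
.floor_prob <- function(p, floor = 1e-8) pmin(pmax(p, floor), 1 - floor)
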