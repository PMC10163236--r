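#' @useDynLib gpcrmsm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif kmeans dist sd cutree hclust as.dist aggregate
#' @importFrom utils write.csv read.csv head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gpcrmsm <- function(category, msg, ...) {
  stop(structure(
    class = c(paste0("gpcrmsm_", category), "gpcrmsm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_stochastic <- function(T, tol = 1e-8) {
  if (!is.matrix(T) || nrow(T) != ncol(T))
    stop_gpcrmsm("validation", "transition matrix must be square")
  if (any(T < -tol))
    stop_gpcrmsm("validation", "transition matrix has negative entries")
  rs <- rowSums(T)
  if (any(abs(rs - 1) > tol))
    stop_gpcrmsm("validation", "transition matrix rows must sum to 1 (max deviation %.3g)",
                 max(abs(rs - 1)))
  T[T < 0] <- 0
  T / rowSums(T)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves pi = pi T by the leading left eigenvector, normalised to sum 1.
#'
#' @param T row-stochastic square matrix.
#' @return numeric vector summing to 1.
#' @export
stationary_distribution <- function(T) {
  T <- check_stochastic(T)
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# Shared-bin histogram probabilities with pseudocount, over a pooled range.
# Used by the KL estimators so divergences stay finite. The default of half
# a count per bin (Jeffreys-style) keeps the null divergence of two finite
# samples from the same distribution near zero; a vanishing pseudocount
# would let single-count tail bins contribute O(log(1/eps)) spikes.
hist_probs <- function(x, breaks, pseudocount = 0.5) {
  x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts + pseudocount
  h / sum(h)
}

shared_breaks <- function(..., bins = 30) {
  pooled <- unlist(list(...), use.names = FALSE)
  rng <- range(pooled, finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = bins + 1)
}

kl_divergence <- function(p, q) sum(p * log(p / q))

symmetric_kl <- function(p, q) 0.5 * (kl_divergence(p, q) + kl_divergence(q, p))

# frames x 3N coordinate row -> atoms x 3 matrix
row_to_coords <- function(x) matrix(x, ncol = 3, byrow = TRUE)
coords_to_row <- function(m) as.numeric(t(m))
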