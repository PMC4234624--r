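#' Confusion matrix between two partitions
#'
#' Cross-tabulates the nodes common to both partitions: entry
#' \eqn{N_{kl}} is the number of overlapping nodes placed in module
#' \eqn{k} of the first partition and module \eqn{l} of the second.
#' Modules with no overlapping nodes are retained as zero rows/columns,
#' so row and column counts equal the module counts of the inputs.
#'
#' @param px,py named membership vectors (node -> community id) or
#'   \code{partition} objects. Node sets may differ; the matrix is built
#'   on their overlap ("reduced groupings").
#' @return integer matrix with \code{dimnames} the module ids;
#'   attribute \code{n_overlap} carries the overlap size.
#' @export
confusion_matrix <- function(px, py) {
  px <- partition_vector(px)
  py <- partition_vector(py)
  common <- intersect(names(px), names(py))
  if (length(common) == 0L) stop("partitions share no nodes", call. = FALSE)
  fx <- factor(px[common], levels = sort(unique(px)))
  fy <- factor(py[common], levels = sort(unique(py)))
  m <- table(fx, fy, dnn = NULL)
  m <- matrix(as.integer(m), nrow = nrow(m),
              dimnames = dimnames(m))
  attr(m, "n_overlap") <- length(common)
  m
}

partition_vector <- function(x) {
  if (inherits(x, "partition")) x <- x$membership
  if (is.null(names(x))) stop("partition must be a named vector", call. = FALSE)
  x
}

#' Variation of information between two partitions
#'
#' The metric distance \eqn{VI = H(X) + H(Y) - 2 I(X;Y)} in bits,
#' computed from the confusion matrix restricted to the overlapping
#' nodes, with base-2 logarithms and \eqn{0 \log 0 = 0}. It is 0 exactly
#' when the partitions agree on the overlap and never exceeds
#' \eqn{\log_2 n} for \eqn{n} overlapping nodes.
#'
#' @param px,py named membership vectors or \code{partition} objects.
#' @return distance in bits.
#' @export
variation_of_information <- function(px, py) {
  N <- confusion_matrix(px, py)
  n <- attr(N, "n_overlap")
  pxy <- N / n
  pr <- rowSums(pxy)
  pc <- colSums(pxy)
  hx <- -sum(plogp(pr))
  hy <- -sum(plogp(pc))
  hxy <- -sum(plogp(pxy))
  mi <- hx + hy - hxy
  max(hx + hy - 2 * mi, 0)
}

#' Upper bound on the variation of information
#'
#' For partitions of \eqn{n} overlapping nodes the distance cannot exceed
#' \eqn{\log_2 n} bits.
#'
#' @param n_overlap number of overlapping nodes (>= 1).
#' @return bound in bits.
#' @export
vi_upper_bound <- function(n_overlap) {
  if (any(n_overlap < 1)) stop("n_overlap must be >= 1", call. = FALSE)
  log2(n_overlap)
}
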