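#' Truncated Katz baseline
#'
#' Scores every gene-disease pair by a damped count of heterogeneous walks of
#' length at most 3 from the gene to the disease:
#' \deqn{S = \beta P + \beta^2 (G P + P Q)
#'         + \beta^3 (P P^T P + G^2 P + G P Q + P Q^2),}
#' where \eqn{G} is the gene-gene matrix, \eqn{P} the gene-disease matrix,
#' \eqn{Q} the disease-disease matrix, and \eqn{0 < \beta < 1} punishes long
#' walks. This equals the gene x disease block of
#' \eqn{\sum_{l=1}^3 \beta^l M^l} for the block heterogeneous adjacency
#' matrix \eqn{M = [[G, P], [P^T, Q]]}. Matrices are used as loaded
#' (weighted, no binarization).
#'
#' @param G m x m gene-gene matrix.
#' @param P m x n gene-disease matrix.
#' @param Q n x n disease-disease matrix.
#' @param beta damping constant in (0, 1); default 0.01.
#' @return dense m x n matrix of Katz scores.
#' @export
katz_scores <- function(G, P, Q, beta = 0.01) {
  if (beta < 0 || beta >= 1) stopf("beta must lie in [0, 1) (got %g)", beta)
  if (nrow(G) != ncol(G) || nrow(Q) != ncol(Q) ||
      nrow(P) != nrow(G) || ncol(P) != nrow(Q)) {
    stopf("dimension mismatch: G %dx%d, P %dx%d, Q %dx%d",
          nrow(G), ncol(G), nrow(P), ncol(P), nrow(Q), ncol(Q))
  }
  GP <- G %*% P
  PQ <- P %*% Q
  S <- beta * P +
    beta^2 * (GP + PQ) +
    beta^3 * (P %*% Matrix::t(P) %*% P + G %*% GP + GP %*% Q + PQ %*% Q)
  out <- as.matrix(S)
  dimnames(out) <- dimnames(P)
  out
}
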