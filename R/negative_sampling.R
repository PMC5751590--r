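#' Random-walk propensity of unlabeled gene-disease pairs
#'
#' Scores every gene-disease pair by the probability that a one-step
#' heterogeneous walk reaches the disease from the gene: out of gene g along
#' the gene similarity network, across a known association, and along the
#' disease similarity network into disease d,
#' \deqn{P = \tilde S_g \, I_{GD} \, \tilde S_d,}
#' where \eqn{\tilde S_g} is the row-stochastic gene similarity and
#' \eqn{\tilde S_d} the column-stochastic disease similarity (the default
#' realization of the normalization \eqn{1/(|S_g||S_d|)}; a Frobenius-norm
#' division is available with \code{norm = "frobenius"}). With stochastic
#' normalization and a binary association matrix every entry lies in [0, 1];
#' zero-sum rows/columns contribute zeros.
#'
#' @param gene_sim m x m gene similarity matrix.
#' @param assoc m x n binary association matrix.
#' @param disease_sim n x n disease similarity matrix.
#' @param norm \code{"stochastic"} (default) or \code{"frobenius"}.
#' @return dense m x n matrix of walk propensities.
#' @export
walk_propensity <- function(gene_sim, assoc, disease_sim,
                            norm = c("stochastic", "frobenius")) {
  norm <- match.arg(norm)
  if (nrow(gene_sim) != ncol(gene_sim) || nrow(disease_sim) != ncol(disease_sim) ||
      nrow(assoc) != nrow(gene_sim) || ncol(assoc) != nrow(disease_sim)) {
    stopf("dimension mismatch: S_g %dx%d, I_GD %dx%d, S_d %dx%d",
          nrow(gene_sim), ncol(gene_sim), nrow(assoc), ncol(assoc),
          nrow(disease_sim), ncol(disease_sim))
  }
  P <- if (norm == "stochastic") {
    row_normalize(gene_sim) %*% assoc %*% col_normalize(disease_sim)
  } else {
    (gene_sim %*% assoc %*% disease_sim) /
      (frobenius_norm(methods::as(gene_sim, "CsparseMatrix")) *
         frobenius_norm(methods::as(disease_sim, "CsparseMatrix")))
  }
  out <- as.matrix(P)
  dimnames(out) <- dimnames(assoc)
  out
}

#' Sampling configuration for the negative set
#'
#' The positive-unlabeled problem is converted to supervised learning by
#' drawing a negative set \eqn{NS = \{NS_{\le\theta}, NS_{>\theta}\}} from
#' the unlabeled pairs: most negatives come from pairs with walk propensity
#' at or below the threshold \eqn{\theta} (likely true negatives), and a
#' small share \code{high_fraction} from above it, which guards the model's
#' generalizability since most unlabeled pairs are negative anyway.
#'
#' @param theta_percentile percentile (in [0, 100]) of the unlabeled
#'   propensities used as \eqn{\theta} (default 90).
#' @param n_negatives total negatives to draw, or \code{"auto"} for one per
#'   positive.
#' @param high_fraction share of negatives drawn from above \eqn{\theta};
#'   must be below 0.5 (the above-threshold stratum is meant to stay small).
#' @param seed RNG seed.
#' @param norm propagated to \code{\link{walk_propensity}}.
#' @return a \code{pcfm_sampling_config} list.
#' @export
sampling_config <- function(theta_percentile = 90, n_negatives = "auto",
                            high_fraction = 0.1, seed = 1L,
                            norm = c("stochastic", "frobenius")) {
  stopifnot(theta_percentile >= 0, theta_percentile <= 100,
            high_fraction >= 0, high_fraction < 0.5)
  if (!identical(n_negatives, "auto")) stopifnot(n_negatives >= 1)
  structure(list(theta_percentile = theta_percentile,
                 n_negatives = n_negatives, high_fraction = high_fraction,
                 seed = as.integer(seed), norm = match.arg(norm)),
            class = "pcfm_sampling_config")
}

#' Draw the negative sample set
#'
#' Returns the positives (label 1) plus \code{n_negatives} label-0 pairs
#' drawn uniformly without replacement from the unlabeled pairs:
#' \eqn{\lceil (1 - high\_fraction) \cdot n \rceil} from the stratum with
#' propensity \eqn{\le \theta} and the remainder from above \eqn{\theta}.
#' If a stratum cannot supply its quota the deficit is filled from the other
#' side (with a message). Reproducible under the configured seed.
#'
#' @param P propensity matrix from \code{\link{walk_propensity}}.
#' @param positives binary association matrix of known links.
#' @param config a \code{\link{sampling_config}}.
#' @param theta explicit threshold; by default the configured percentile of
#'   the unlabeled propensities.
#' @return a \code{\link{labeled_pairs}} data frame; the chosen
#'   \eqn{\theta} is attached as attribute \code{"theta"}.
#' @export
select_negatives <- function(P, positives, config = sampling_config(),
                             theta = NULL) {
  stopifnot(all(dim(P) == dim(positives)))
  pos_idx <- which(as.matrix(positives) != 0)
  n_pos <- length(pos_idx)
  n_neg <- if (identical(config$n_negatives, "auto")) n_pos else
    as.integer(config$n_negatives)
  unl_idx <- setdiff(seq_along(P), pos_idx)
  if (n_neg > length(unl_idx)) {
    stopf("n_negatives (%d) exceeds the %d unlabeled pairs", n_neg,
          length(unl_idx))
  }
  pv <- P[unl_idx]
  if (is.null(theta)) {
    theta <- as.numeric(quantile(pv, config$theta_percentile / 100,
                                 names = FALSE, type = 7))
  }
  low <- unl_idx[pv <= theta]
  high <- unl_idx[pv > theta]
  n_low <- ceiling((1 - config$high_fraction) * n_neg)
  if (n_low > length(low)) {
    message(sprintf("NS_<=theta can supply only %d of %d draws; filling from NS_>theta",
                    length(low), n_low))
    n_low <- length(low)
  }
  n_high <- n_neg - n_low
  if (n_high > length(high)) {  # deficit: fall back to the low stratum
    message(sprintf("NS_>theta can supply only %d of %d draws; filling from NS_<=theta",
                    length(high), n_high))
    n_high <- length(high)
    n_low <- n_neg - n_high
  }
  set.seed(config$seed)
  draw <- function(pool, k) if (k == 0) integer(0) else
    pool[sample.int(length(pool), k)]
  neg <- c(draw(low, n_low), draw(high, n_high))
  m <- nrow(P)
  all_idx <- c(pos_idx, neg)
  out <- labeled_pairs(gene = ((all_idx - 1L) %% m) + 1L,
                       disease = ((all_idx - 1L) %/% m) + 1L,
                       label = rep(c(1, 0), c(n_pos, length(neg))))
  attr(out, "theta") <- theta
  out
}
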