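#' Ortholog-profile gene similarities
#'
#' Gene-gene similarities are computed from binary ortholog-disease profiles:
#' row i of the incidence matrix records which nonhuman-species diseases the
#' orthologs of gene i are linked to. Two metrics are offered:
#' \describe{
#'   \item{VSS}{vector-space (cosine) similarity between the binary profiles.}
#'   \item{PCC}{Pearson correlation between the profiles, mapped to [0,1]
#'     with \eqn{f(x) = (x+1)/2}.}
#' }
#' Both are then degree-scaled by \eqn{|I(i)| / \max_j |I(j)|}, the profile
#' size of gene i relative to the largest profile, which down-weights genes
#' with little cross-species evidence (and makes the matrix mildly
#' asymmetric, by exactly the ratio of profile sizes).
#'
#' The printed similarity formulas restrict the denominator sums to the
#' profile intersection \eqn{I(i) \cap I(g)}; on strictly binary profiles
#' that collapses cosine to 1 and Pearson to a sign whenever the intersection
#' is non-empty. The default therefore takes denominators over each gene's
#' full profile (standard cosine/Pearson); the literal intersection reading
#' remains available via \code{denominator = "intersection"} for fidelity
#' experiments.
#'
#' @param profiles binary genes x nonhuman-diseases incidence matrix
#'   (see \code{\link{read_ortholog_profiles}}).
#' @param i,g gene index or identifier.
#' @param denominator \code{"full_profile"} (default) or
#'   \code{"intersection"} (the formulas as printed).
#' @return a similarity in [0, 1]; degenerate profiles (empty, or constant
#'   for PCC) never yield NaN.
#' @export
vss_similarity <- function(profiles, i, g,
                           denominator = c("full_profile", "intersection")) {
  denominator <- match.arg(denominator)
  ri <- profile_row(profiles, i); rg <- profile_row(profiles, g)
  num <- sum(ri * rg)
  if (num == 0) return(0)
  den <- if (denominator == "full_profile") {
    sqrt(sum(ri^2)) * sqrt(sum(rg^2))
  } else {
    inter <- ri * rg
    sqrt(sum(ri[inter != 0]^2)) * sqrt(sum(rg[inter != 0]^2))
  }
  if (den == 0) return(0)
  degree_scale(profiles, i) * num / den
}

#' @rdname vss_similarity
#' @export
pcc_similarity <- function(profiles, i, g,
                           denominator = c("full_profile", "intersection")) {
  denominator <- match.arg(denominator)
  ri <- profile_row(profiles, i); rg <- profile_row(profiles, g)
  ci <- ri - mean(ri); cg <- rg - mean(rg)
  if (denominator == "intersection") {
    sel <- (ri * rg) != 0
    num <- sum(ci[sel] * cg[sel])
    den <- sqrt(sum(ci[sel]^2)) * sqrt(sum(cg[sel]^2))
  } else {
    num <- sum(ci * cg)
    den <- sqrt(sum(ci^2)) * sqrt(sum(cg^2))
  }
  raw <- if (den == 0) 0 else num / den  # zero-variance profiles: r := 0
  degree_scale(profiles, i) * (raw + 1) / 2
}

profile_row <- function(profiles, i) {
  if (is.character(i)) i <- index_of(i, rownames(profiles))
  as.numeric(profiles[i, ])
}

degree_scale <- function(profiles, i) {
  sizes <- Matrix::rowSums(profiles != 0)
  mx <- max(sizes)
  if (mx == 0) return(0)
  if (is.character(i)) i <- index_of(i, rownames(profiles))
  unname(sizes[i]) / mx
}

#' Full gene-gene similarity matrix from ortholog profiles
#'
#' Dense-matrix evaluation of \code{\link{vss_similarity}} /
#' \code{\link{pcc_similarity}} over all gene pairs. The diagonal is zero
#' (self-similarity is never used downstream).
#'
#' @inheritParams vss_similarity
#' @param metric \code{"vss"} or \code{"pcc"}.
#' @return sparse genes x genes similarity matrix with entries in [0, 1].
#' @export
ortholog_similarity <- function(profiles, metric = c("vss", "pcc"),
                                denominator = c("full_profile", "intersection")) {
  metric <- match.arg(metric)
  denominator <- match.arg(denominator)
  m <- nrow(profiles)
  R <- as.matrix(profiles)
  sizes <- rowSums(R != 0)
  mx <- max(sizes, 1)
  if (denominator == "full_profile") {
    if (metric == "vss") {
      C <- tcrossprod(R)
      den <- sqrt(sizes) %o% sqrt(sizes)
      raw <- ifelse(den > 0, C / den, 0)
    } else {
      Rc <- R - rowMeans(R)
      C <- tcrossprod(Rc)
      sd2 <- rowSums(Rc^2)
      den <- sqrt(sd2) %o% sqrt(sd2)
      raw <- (ifelse(den > 0, C / den, 0) + 1) / 2
    }
  } else {
    fun <- if (metric == "vss") vss_similarity else pcc_similarity
    raw <- matrix(0, m, m)
    for (i in seq_len(m)) for (g in seq_len(m)) {
      raw[i, g] <- fun(profiles, i, g, denominator = "intersection")
    }
    diag(raw) <- 0
    dimnames(raw) <- dimnames(profiles)[c(1L, 1L)]
    return(Matrix::drop0(methods::as(raw, "CsparseMatrix")))
  }
  S <- (sizes / mx) * raw  # recycles column-wise: scales row i by |I(i)|/max
  S <- pmin(pmax(S, 0), 1) # guard 1 + eps from the sqrt products
  diag(S) <- 0
  dimnames(S) <- dimnames(profiles)[c(1L, 1L)]
  Matrix::drop0(methods::as(S, "CsparseMatrix"))
}

#' Combine ortholog-derived and functional-network gene similarities
#'
#' Implements \eqn{S_g = S_g' + \omega \cdot \mathrm{normal}\{S_g''\}}: the
#' functional network weights are min-max normalized over their observed
#' nonzero values, scaled by \eqn{\omega > 1} (the functional network is
#' treated as the more reliable evidence), added to the ortholog-derived
#' similarities, and the result is rescaled by its global maximum so all
#' entries lie in [0, 1] for the downstream regularizers and random walk.
#'
#' @param S_prime ortholog-derived gene similarity (entries in [0,1]).
#' @param S_doubleprime weighted functional gene network (HumanNet-style).
#' @param omega combination weight, must exceed 1.
#' @return symmetricized sparse similarity matrix with entries in [0, 1].
#' @export
combine_gene_similarity <- function(S_prime, S_doubleprime, omega = 2) {
  if (omega <= 1) stopf("omega must be larger than 1 (got %g)", omega)
  if (!identical(rownames(S_prime), rownames(S_doubleprime))) {
    stopf("gene identifier maps of the two similarity layers differ")
  }
  N <- minmax_normalize(S_doubleprime)
  S <- methods::as(S_prime + omega * N, "CsparseMatrix")
  mx <- if (length(S@x)) max(S@x) else 0
  if (mx > 1) S <- S / mx  # omega > 1 can push sums past 1; cap at [0,1]
  Matrix::drop0(S)
}

# Min-max normalization of the nonzero weights to [0,1]; structural zeros
# stay zero. A constant nonzero weight set maps to 1.
minmax_normalize <- function(M) {
  M <- methods::as(M, "CsparseMatrix")
  if (length(M@x) == 0) return(M)
  lo <- min(M@x); hi <- max(M@x)
  M@x <- if (hi > lo) (M@x - lo) / (hi - lo) else rep(1, length(M@x))
  Matrix::drop0(M)
}

#' Top-k neighbor sets for the graph regularizers
#'
#' For each gene the neighbor set G(i) holds its \code{k} most similar genes
#' (similarity descending, ties by index), excluding itself and
#' zero-similarity entries; likewise D(j) for diseases. The sets are stored
#' as sparse directed weight matrices: \code{gene[i, g] = S_ig} for
#' \code{g} in G(i).
#'
#' @param gene_sim,disease_sim symmetric similarity matrices in [0, 1].
#' @param k neighbor count (default 5).
#' @return object of class \code{pcfm_neighbors} with sparse components
#'   \code{gene} (m x m) and \code{disease} (n x n).
#' @export
build_neighbor_sets <- function(gene_sim, disease_sim, k = 5L) {
  stopifnot(k >= 1)
  structure(list(gene = topk_rows(gene_sim, k),
                 disease = topk_rows(disease_sim, k),
                 k = as.integer(k)),
            class = "pcfm_neighbors")
}

topk_rows <- function(S, k) {
  S <- methods::as(S, "CsparseMatrix")
  n <- nrow(S)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    row <- S[i, ]
    cand <- which(row != 0)
    cand <- cand[cand != i]
    if (!length(cand)) next
    o <- order(-row[cand], cand)
    take <- cand[o][seq_len(min(k, length(cand)))]
    ii <- c(ii, rep.int(i, length(take))); jj <- c(jj, take)
    xx <- c(xx, row[take])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = dim(S),
                       dimnames = dimnames(S))
}

#' @rdname build_neighbor_sets
#' @param neighbors a \code{pcfm_neighbors} object.
#' @param side \code{"gene"} or \code{"disease"}.
#' @param i node index.
#' @return \code{neighbors_of}: data frame (\code{index}, \code{sim}) ordered
#'   by decreasing similarity, ties by index.
#' @export
neighbors_of <- function(neighbors, side = c("gene", "disease"), i) {
  side <- match.arg(side)
  row <- neighbors[[side]][i, ]
  idx <- which(row != 0)
  o <- order(-row[idx], idx)
  data.frame(index = idx[o], sim = row[idx][o])
}

#' @export
print.pcfm_neighbors <- function(x, ...) {
  cat(sprintf("pcfm neighbor sets: %d genes, %d diseases, k = %d\n",
              nrow(x$gene), nrow(x$disease), x$k))
  invisible(x)
}
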