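#' Cross-validation folds over the known positives
#'
#' The known positive links (not the diseases) are partitioned into
#' near-equal seeded random folds; each fold serves once as the test set.
#' Splitting positives is what creates test diseases with zero remaining
#' training links (the "single known gene" stratum).
#'
#' @param assoc binary association matrix.
#' @param n_folds number of folds (default 3).
#' @param seed RNG seed.
#' @return data frame (\code{gene}, \code{disease}, \code{fold}) with one
#'   row per positive; fold sizes differ by at most one.
#' @export
threefold_split <- function(assoc, n_folds = 3L, seed = 1L) {
  nz <- nonzeros(assoc)
  if (nrow(nz) < n_folds) {
    stopf("only %d positives but %d folds requested", nrow(nz), n_folds)
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), nrow(nz)))
  data.frame(gene = rownames(assoc)[nz$i], disease = colnames(assoc)[nz$j],
             fold = fold)
}

#' Stratify test diseases by remaining training support
#'
#' With fold \code{test_fold} held out, each disease's positives visible in
#' training are counted: diseases with none left fall in the
#' \code{"single"} (no known genes) stratum, diseases with at least one in
#' \code{"many"}. Diseases with no links at all are excluded (nothing to
#' retrieve).
#'
#' @param assoc binary association matrix.
#' @param split fold assignment from \code{\link{threefold_split}}.
#' @param test_fold the held-out fold.
#' @return named character vector over diseases that have at least one
#'   positive: \code{"single"} or \code{"many"}.
#' @export
stratify_diseases <- function(assoc, split, test_fold) {
  train <- split[split$fold != test_fold, , drop = FALSE]
  counts <- table(factor(train$disease, levels = colnames(assoc)))
  linked <- Matrix::colSums(assoc != 0) > 0
  out <- ifelse(counts[linked] == 0, "single", "many")
  stats::setNames(as.character(out), colnames(assoc)[linked])
}

#' Top-k retrieval curve
#'
#' For each cutoff k, the fraction of held-out positive (gene, disease)
#' pairs whose gene appears within the top k of its disease's ranking. The
#' curve is non-decreasing in k by construction.
#'
#' @param rankings named list mapping disease identifiers to character
#'   vectors of candidate genes in rank order (training positives already
#'   excluded).
#' @param truth data frame (\code{gene}, \code{disease}) of held-out
#'   positives; every disease must have a ranking.
#' @param k_grid strictly increasing cutoffs.
#' @return data frame (\code{k}, \code{probability}).
#' @export
topk_curve <- function(rankings, truth, k_grid) {
  if (!length(k_grid) || is.unsorted(k_grid, strictly = TRUE)) {
    stopf("k_grid must be non-empty and strictly increasing")
  }
  pos <- vapply(seq_len(nrow(truth)), function(r) {
    rk <- rankings[[truth$disease[r]]]
    if (is.null(rk)) stopf("no ranking for disease %s", truth$disease[r])
    match(truth$gene[r], rk) %||% NA_integer_
  }, 0L)
  if (anyNA(pos)) stopf("held-out gene missing from its disease's candidates")
  data.frame(k = k_grid,
             probability = vapply(k_grid, function(k) mean(pos <= k), 0))
}

# Ranked candidate genes for each requested disease, excluding that
# disease's training positives from the candidate set.
disease_rankings <- function(model, diseases, train_assoc) {
  S <- score_matrix(model)
  genes <- rownames(S)
  out <- lapply(diseases, function(d) {
    j <- index_of(d, colnames(S))
    cand <- which(train_assoc[, j] == 0)
    o <- order(-S[cand, j], genes[cand], method = "radix")
    genes[cand][o]
  })
  stats::setNames(out, diseases)
}

#' Cross-validated evaluation of a model variant
#'
#' Runs the full protocol: positives are split into folds; per fold, the
#' held-out positives are removed, negatives are drawn by random-walk
#' sampling on the training network, the model is trained, every test
#' disease is ranked over all genes minus its training positives, and
#' held-out retrieval is accumulated per disease stratum. The per-fold seed
#' is \code{seed + fold} for both sampling and training.
#'
#' @param assoc binary association matrix.
#' @param gene_sim,disease_sim similarity layers.
#' @param config a \code{\link{train_config}}.
#' @param samp a \code{\link{sampling_config}}.
#' @param n_folds folds (default 3).
#' @param k_grid retrieval cutoffs (default 1..100, capped at the gene
#'   count).
#' @param neighbor_k neighbor-set size for the regularizers.
#' @param seed base seed for splitting, sampling and training.
#' @return list with \code{per_pair} (one row per held-out positive:
#'   \code{gene}, \code{disease}, \code{fold}, \code{stratum}, \code{rank},
#'   \code{n_candidates}) and \code{curves} (pooled over folds:
#'   \code{stratum} including \code{"all"}, \code{k}, \code{probability}).
#' @export
evaluate_cv <- function(assoc, gene_sim, disease_sim,
                        config = train_config(), samp = sampling_config(),
                        n_folds = 3L, k_grid = NULL, neighbor_k = 5L,
                        seed = 1L) {
  m <- nrow(assoc)
  if (is.null(k_grid)) k_grid <- seq_len(min(100L, m))
  split <- threefold_split(assoc, n_folds, seed)
  neighbors <- build_neighbor_sets(gene_sim, disease_sim, neighbor_k)
  per_pair <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- split[split$fold == f, , drop = FALSE]
    train_assoc <- assoc
    train_assoc[cbind(index_of(test$gene, rownames(assoc)),
                      index_of(test$disease, colnames(assoc)))] <- 0
    train_assoc <- Matrix::drop0(train_assoc)

    P <- walk_propensity(gene_sim, train_assoc, disease_sim, samp$norm)
    samp_f <- samp; samp_f$seed <- samp$seed + f
    pairs <- select_negatives(P, train_assoc, samp_f)
    cfg_f <- config; cfg_f$seed <- config$seed + f
    model <- pcfm_train(pairs, rownames(assoc), colnames(assoc),
                        neighbors, cfg_f)

    strata <- stratify_diseases(assoc, split, f)
    S <- score_matrix(model)
    res <- lapply(unique(test$disease), function(d) {
      j <- index_of(d, colnames(assoc))
      cand <- which(train_assoc[, j] == 0)
      sc <- S[cand, j]
      ids <- rownames(assoc)[cand]
      o <- order(-sc, ids, method = "radix")
      ranked <- ids[o]
      genes_d <- test$gene[test$disease == d]
      data.frame(gene = genes_d, disease = d, fold = f,
                 stratum = unname(strata[d]),
                 rank = match(genes_d, ranked),
                 n_candidates = length(cand))
    })
    per_pair[[f]] <- do.call(rbind, res)
  }
  per_pair <- do.call(rbind, per_pair)
  curves <- pool_curves(per_pair, k_grid)
  list(per_pair = per_pair, curves = curves)
}

pool_curves <- function(per_pair, k_grid) {
  strata <- c("all", sort(unique(per_pair$stratum)))
  do.call(rbind, lapply(strata, function(s) {
    sel <- if (s == "all") per_pair else per_pair[per_pair$stratum == s, ]
    data.frame(stratum = s, k = k_grid,
               probability = vapply(k_grid, function(k) mean(sel$rank <= k), 0))
  }))
}

#' Sweep the regularization weights over a grid
#'
#' One full cross-validated evaluation per (alpha, beta) cell, reporting the
#' pooled top-k probability for both disease strata at every cutoff.
#'
#' @inheritParams evaluate_cv
#' @param alphas,betas non-empty grids of regularization weights.
#' @return data frame (\code{model}, \code{alpha}, \code{beta},
#'   \code{stratum}, \code{k}, \code{probability}).
#' @export
parameter_grid <- function(assoc, gene_sim, disease_sim, alphas, betas,
                           config = train_config(variant = "model2"),
                           samp = sampling_config(), n_folds = 3L,
                           k_grid = NULL, neighbor_k = 5L, seed = 1L) {
  if (!length(alphas) || !length(betas)) stopf("alpha/beta grids must be non-empty")
  cells <- expand.grid(alpha = alphas, beta = betas, KEEP.OUT.ATTRS = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    cfg <- config
    cfg$alpha <- cells$alpha[r]; cfg$beta <- cells$beta[r]
    ev <- evaluate_cv(assoc, gene_sim, disease_sim, cfg, samp, n_folds,
                      k_grid, neighbor_k, seed)
    cbind(model = cfg$variant, alpha = cells$alpha[r], beta = cells$beta[r],
          ev$curves)
  }))
}
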