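#' Synthetic heterogeneous gene-disease data with planted latent structure
#'
#' Generates all four network layers from the model's own generative
#' assumptions so every pipeline stage is testable without downloads. Genes
#' and diseases are assigned round-robin to shared clusters; planted factors
#' \eqn{U^*, V^*} are drawn around seeded cluster centers with spread
#' \code{cluster_spread} and globally rescaled so the mean association
#' probability \eqn{p^*_{ij} = e^{-(\|U^*_i - V^*_j\|^2/2 + \vartheta)}}
#' equals \code{density_target}. Associations are Bernoulli\eqn{(p^*)} draws;
#' the gene and disease similarity layers derive from the planted-factor
#' distances (\eqn{e^{-d^2}} plus seeded symmetric noise, clipped to [0,1]),
#' so neighborhoods carry information about held-out links; ortholog profiles
#' share nonhuman diseases within clusters (in-block incidence 0.7 vs 0.05
#' outside), giving higher within-cluster than between-cluster profile
#' overlap.
#'
#' @param m,n gene and disease counts.
#' @param D_true planted latent dimensionality.
#' @param n_clusters shared cluster count.
#' @param cluster_spread standard deviation of factors around their center.
#' @param n_nonhuman number of nonhuman-species diseases in the ortholog
#'   layer.
#' @param similarity_noise standard deviation of the noise added to the
#'   similarity layers.
#' @param density_target mean of \eqn{p^*} after rescaling, in (0, 1).
#' @param vartheta distance offset of the generative probability map.
#' @param seed RNG seed; every emitted artifact is reproducible under it.
#' @return a \code{pcfm_synthetic_config} list.
#' @export
synthetic_config <- function(m = 300L, n = 150L, D_true = 5L,
                             n_clusters = 6L, cluster_spread = 0.5,
                             n_nonhuman = 120L, similarity_noise = 0.05,
                             density_target = 0.01, vartheta = 1e-4,
                             seed = 1L) {
  stopifnot(m >= 1, n >= 1, D_true >= 1, n_clusters >= 1, cluster_spread > 0,
            n_nonhuman >= 1, similarity_noise >= 0,
            density_target > 0, density_target < 1, vartheta > 0)
  structure(list(m = as.integer(m), n = as.integer(n),
                 D_true = as.integer(D_true), n_clusters = as.integer(n_clusters),
                 cluster_spread = cluster_spread,
                 n_nonhuman = as.integer(n_nonhuman),
                 similarity_noise = similarity_noise,
                 density_target = density_target, vartheta = vartheta,
                 seed = as.integer(seed)),
            class = "pcfm_synthetic_config")
}

#' @rdname synthetic_config
#' @param config a \code{synthetic_config}.
#' @return \code{generate_synthetic_data}: list of class
#'   \code{pcfm_synthetic} with components \code{assoc}, \code{gene_sim},
#'   \code{disease_sim}, \code{ortholog}, \code{truth} (matrix of
#'   \eqn{p^*_{ij}}), \code{U_star}, \code{V_star}, \code{gene_cluster},
#'   \code{disease_cluster}, \code{config}.
#' @export
generate_synthetic_data <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  gene_ids <- sprintf("g%0*d", nchar(cfg$m), seq_len(cfg$m))
  disease_ids <- sprintf("d%0*d", nchar(cfg$n), seq_len(cfg$n))
  nonhuman_ids <- sprintf("nd%0*d", nchar(cfg$n_nonhuman),
                          seq_len(cfg$n_nonhuman))

  centers <- matrix(rnorm(cfg$n_clusters * cfg$D_true), cfg$n_clusters)
  gc <- rep_len(seq_len(cfg$n_clusters), cfg$m)
  dc <- rep_len(seq_len(cfg$n_clusters), cfg$n)
  U <- centers[gc, , drop = FALSE] +
    matrix(rnorm(cfg$m * cfg$D_true, sd = cfg$cluster_spread), cfg$m)
  V <- centers[dc, , drop = FALSE] +
    matrix(rnorm(cfg$n * cfg$D_true, sd = cfg$cluster_spread), cfg$n)

  # global scale s so that mean of exp(-(s^2 d^2/2 + vartheta)) hits the
  # density target (monotone in s, so a root always brackets if reachable)
  D2 <- outer(rowSums(U^2), rowSums(V^2), `+`) - 2 * tcrossprod(U, V)
  D2[D2 < 0] <- 0
  dens <- function(s) mean(exp(-(s^2 * D2 / 2 + cfg$vartheta)))
  if (dens(1e4) > cfg$density_target || dens(1e-8) < cfg$density_target) {
    stopf("density_target %g unreachable with this cluster geometry",
          cfg$density_target)
  }
  s <- uniroot(function(s) dens(s) - cfg$density_target,
               c(1e-8, 1e4), tol = 1e-12)$root
  U <- s * U; V <- s * V
  rownames(U) <- gene_ids; rownames(V) <- disease_ids
  p_star <- exp(-(s^2 * D2 / 2 + cfg$vartheta))
  dimnames(p_star) <- list(gene_ids, disease_ids)

  y <- matrix(rbinom(length(p_star), 1L, p_star), cfg$m,
              dimnames = dimnames(p_star))
  assoc <- Matrix::drop0(methods::as(y * 1, "CsparseMatrix"))

  gene_sim <- planted_similarity(U, cfg$similarity_noise)
  disease_sim <- planted_similarity(V, cfg$similarity_noise)

  block <- rep_len(seq_len(cfg$n_clusters), cfg$n_nonhuman)
  inblock <- outer(gc, block, `==`)
  prob <- ifelse(inblock, 0.7, 0.05)
  R <- matrix(rbinom(length(prob), 1L, prob), cfg$m,
              dimnames = list(gene_ids, nonhuman_ids))
  ortholog <- Matrix::drop0(methods::as(R * 1, "CsparseMatrix"))

  structure(list(assoc = assoc, gene_sim = gene_sim,
                 disease_sim = disease_sim, ortholog = ortholog,
                 truth = p_star, U_star = U, V_star = V,
                 gene_cluster = gc, disease_cluster = dc, config = cfg),
            class = "pcfm_synthetic")
}

planted_similarity <- function(X, noise_sd) {
  S <- exp(-as.matrix(stats::dist(X))^2)
  if (noise_sd > 0) {
    E <- matrix(rnorm(length(S), sd = noise_sd), nrow(S))
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 0
  dimnames(S) <- list(rownames(X), rownames(X))
  Matrix::drop0(methods::as(S, "CsparseMatrix"))
}

#' @export
print.pcfm_synthetic <- function(x, ...) {
  cat(sprintf(paste0("pcfm synthetic dataset: %d genes x %d diseases, ",
                     "%d positives (density %.4f), D_true = %d\n"),
              nrow(x$assoc), ncol(x$assoc), length(x$assoc@x),
              length(x$assoc@x) / prod(dim(x$assoc)), x$config$D_true))
  invisible(x)
}

#' Write the synthetic layers as TSV edge lists
#'
#' Emits \code{associations.tsv}, \code{gene_sim.tsv},
#' \code{disease_sim.tsv}, \code{ortholog.tsv} and \code{truth.tsv}
#' (gene, disease, generative probability) into \code{dir}; the first four
#' load back through the network readers without loss.
#'
#' @param dataset a \code{pcfm_synthetic}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_associations(dataset$assoc, file.path(dir, "associations.tsv"))
  write_similarity(dataset$gene_sim, file.path(dir, "gene_sim.tsv"))
  write_similarity(dataset$disease_sim, file.path(dir, "disease_sim.tsv"))
  write_ortholog_profiles(dataset$ortholog, file.path(dir, "ortholog.tsv"))
  tr <- expand.grid(g = rownames(dataset$truth), d = colnames(dataset$truth),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tr$p <- as.vector(dataset$truth)
  tr$p <- format_double(tr$p)
  write_edges(file.path(dir, "truth.tsv"), tr)
  invisible(dir)
}

#' Structure-recovery report for a trained model
#'
#' Measures how well a trained model recovers the planted structure:
#' \describe{
#'   \item{truth_rank_cor}{Spearman correlation between the predicted
#'     association probability \eqn{e^{-f}} and the generative \eqn{p^*}
#'     over unlabeled (non-positive) pairs.}
#'   \item{holdout_auc}{probability that a held-out positive pair outscores
#'     a seeded sampled unlabeled pair (rank-sum AUC; 0.5 is chance).}
#'   \item{topk}{top-k retrieval curve of the held-out positives against the
#'     per-disease rankings (training positives excluded from candidates),
#'     with the uniform-random expectation at each k for comparison.}
#' }
#'
#' @param dataset a \code{pcfm_synthetic}.
#' @param model a trained \code{pcfm_model} over the same identifiers.
#' @param heldout data frame (\code{gene}, \code{disease}) of positive pairs
#'   that were withheld from training (identifiers).
#' @param k_grid cutoffs for the retrieval curve.
#' @param seed seed for the negative draw of the AUC.
#' @return list with \code{truth_rank_cor}, \code{holdout_auc}, \code{topk}.
#' @export
recovery_report <- function(dataset, model, heldout, k_grid = 1:50,
                            seed = 1L) {
  S <- score_matrix(model)
  pos <- as.matrix(dataset$assoc) != 0
  unl <- which(!pos)
  rank_cor <- cor(S[unl], dataset$truth[unl], method = "spearman")

  held_idx <- cbind(index_of(heldout$gene, rownames(S)),
                    index_of(heldout$disease, colnames(S)))
  set.seed(seed)
  neg_pool <- unl[!(unl %in% ((held_idx[, 2L] - 1L) * nrow(S) + held_idx[, 1L]))]
  neg_idx <- sample(neg_pool, min(length(neg_pool), max(1000L, nrow(held_idx))))
  sp <- S[held_idx]; sn <- S[neg_idx]
  auc <- (sum(outer(sp, sn, `>`)) + 0.5 * sum(outer(sp, sn, `==`))) /
    (length(sp) * length(sn))

  train_assoc <- dataset$assoc
  train_assoc[held_idx] <- 0
  train_assoc <- Matrix::drop0(train_assoc)
  rankings <- disease_rankings(model, unique(heldout$disease), train_assoc)
  topk <- topk_curve(rankings, heldout, k_grid)
  topk$random <- vapply(topk$k, function(k) {
    mean(pmin(k / (nrow(S) - Matrix::colSums(train_assoc != 0)[heldout$disease]), 1))
  }, 0)
  list(truth_rank_cor = rank_cor, holdout_auc = auc, topk = topk)
}

# Full m x n matrix of association probabilities e^{-f}.
score_matrix <- function(model) {
  D2 <- outer(rowSums(model$U^2), rowSums(model$V^2), `+`) -
    2 * tcrossprod(model$U, model$V)
  D2[D2 < 0] <- 0
  S <- exp(-(D2 / 2 + model$vartheta))
  dimnames(S) <- list(rownames(model$U), rownames(model$V))
  S
}
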