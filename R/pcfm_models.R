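#' Latent factor model container
#'
#' Holds the gene factors \code{U} (m x D), disease factors \code{V} (n x D)
#' and the distance offset \code{vartheta}. The association probability for a
#' gene-disease pair is \eqn{e^{-f}} with
#' \eqn{f = \|U_i - V_j\|^2 / 2 + \vartheta}; \code{vartheta} is a tiny
#' positive constant (default 1e-4) that keeps \eqn{f} strictly positive so
#' \eqn{\log(1 - e^{-f})} is always finite.
#'
#' @param U,V numeric factor matrices with identifier rownames.
#' @param vartheta positive distance offset.
#' @return an object of class \code{pcfm_model}.
#' @export
factor_model <- function(U, V, vartheta = 1e-4) {
  stopifnot(is.matrix(U), is.matrix(V), ncol(U) == ncol(V), vartheta > 0,
            all(is.finite(U)), all(is.finite(V)))
  structure(list(U = U, V = V, vartheta = vartheta, D = ncol(U)),
            class = "pcfm_model")
}

#' @export
print.pcfm_model <- function(x, ...) {
  cat(sprintf("pcfm factor model: %d genes x %d diseases, D = %d, vartheta = %g\n",
              nrow(x$U), nrow(x$V), x$D, x$vartheta))
  if (!is.null(x$trace)) {
    cat(sprintf("  trained %d epochs, final objective %.6g\n",
                nrow(x$trace), x$trace$total[nrow(x$trace)]))
  }
  invisible(x)
}

#' Labeled training pairs
#'
#' The supervised training set: known positive links (label 1) plus sampled
#' negatives (label 0). Stored as a data frame of integer indices into the
#' model's gene/disease maps.
#'
#' @param gene,disease integer indices.
#' @param label 0/1 labels.
#' @return data frame with columns \code{gene}, \code{disease}, \code{label}.
#' @export
labeled_pairs <- function(gene, disease, label) {
  stopifnot(length(gene) == length(disease), length(gene) == length(label),
            all(label %in% c(0, 1)))
  if (anyDuplicated(paste(gene, disease))) stopf("duplicate (gene, disease) pair")
  data.frame(gene = as.integer(gene), disease = as.integer(disease),
             label = as.numeric(label))
}

#' Distance and probability maps
#'
#' \code{pair_distance} is the half squared Euclidean distance between a gene
#' and a disease factor plus the offset \eqn{\vartheta};
#' \code{association_probability} converts it to the Bernoulli probabilities
#' \eqn{P(Y=1) = e^{-f}} and \eqn{P(Y=0) = 1 - e^{-f}} (which sum to 1
#' exactly). As \eqn{f \to \vartheta}, \eqn{P(Y=1) \to e^{-\vartheta}};
#' as \eqn{f \to \infty}, \eqn{P(Y=0) \to 1}.
#'
#' @param u,v factor vectors of equal length.
#' @param vartheta positive offset.
#' @param f distance value(s), each at least \eqn{\vartheta > 0}.
#' @return \code{pair_distance}: a scalar \eqn{f \ge \vartheta}.
#'   \code{association_probability}: list with vectors \code{p1}, \code{p0}.
#' @export
pair_distance <- function(u, v, vartheta = 1e-4) {
  if (length(u) != length(v)) stopf("factor vectors have different lengths")
  sum((u - v)^2) / 2 + vartheta
}

#' @rdname pair_distance
#' @export
association_probability <- function(f) {
  p1 <- exp(-f)
  list(p1 = p1, p0 = 1 - p1)
}

# f for every pair, vectorized over the pair table.
pair_f <- function(model, pairs) {
  diffs <- model$V[pairs$disease, , drop = FALSE] -
    model$U[pairs$gene, , drop = FALSE]
  rowSums(diffs^2) / 2 + model$vartheta
}

#' Bernoulli log-likelihood and its gradient
#'
#' \code{log_likelihood_L1} evaluates
#' \deqn{L_1 = \sum_{(i,j)} \left[(1 - Y_{ij})\log(1 - e^{-f}) - Y_{ij} f\right] \le 0.}
#' \code{gradient_L1} returns its exact gradient: each pair contributes
#' \eqn{(V_j - U_i) \cdot [Y + (1-Y)(1 - 1/(1 - e^{-f}))]} to
#' \eqn{\partial L_1 / \partial U_i}, and the negated vector to
#' \eqn{\partial L_1 / \partial V_j}.
#'
#' @param model a \code{pcfm_model}.
#' @param pairs labeled pairs (see \code{\link{labeled_pairs}}).
#' @return \code{log_likelihood_L1}: a scalar (0 for an empty pair set).
#'   \code{gradient_L1}: list with matrices \code{dU}, \code{dV}.
#' @export
log_likelihood_L1 <- function(model, pairs) {
  if (nrow(pairs) == 0) return(0)
  f <- pair_f(model, pairs)
  y <- pairs$label
  # log(1 - e^{-f}) via expm1 for accuracy at small f
  sum((1 - y) * log(-expm1(-f)) - y * f)
}

#' @rdname log_likelihood_L1
#' @export
gradient_L1 <- function(model, pairs) {
  dU <- matrix(0, nrow(model$U), model$D, dimnames = dimnames(model$U))
  dV <- matrix(0, nrow(model$V), model$D, dimnames = dimnames(model$V))
  if (nrow(pairs) > 0) {
    diffs <- model$V[pairs$disease, , drop = FALSE] -
      model$U[pairs$gene, , drop = FALSE]
    f <- rowSums(diffs^2) / 2 + model$vartheta
    w <- pair_weight(pairs$label, f)
    contrib <- diffs * w
    dU <- dU + accumulate_rows(contrib, pairs$gene, nrow(model$U))
    dV <- dV - accumulate_rows(contrib, pairs$disease, nrow(model$V))
  }
  list(dU = dU, dV = dV)
}

# the bracket of the printed gradient: Y + (1-Y)(1 - 1/(1 - e^{-f}))
pair_weight <- function(y, f) {
  y + (1 - y) * (1 - 1 / (-expm1(-f)))
}

accumulate_rows <- function(contrib, idx, n) {
  out <- matrix(0, n, ncol(contrib))
  agg <- rowsum(contrib, group = idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# --- graph regularizers -----------------------------------------------------

# Centroid ("integral") penalty: (alpha/2) sum_i ||U_i - centroid_i||^2 where
# centroid_i is the similarity-weighted mean of i's neighbor factors. Rows
# with empty neighbor sets (or zero similarity mass) contribute nothing.
centroid_residual <- function(X, A) {
  W <- row_normalize(A)
  E <- as.matrix(X - W %*% X)
  E[Matrix::rowSums(A) == 0, ] <- 0
  E
}

centroid_penalty <- function(X, A, coef) {
  if (coef == 0) return(list(value = 0, grad = matrix(0, nrow(X), ncol(X))))
  E <- centroid_residual(X, A)
  W <- row_normalize(A)
  # d/dX of (coef/2)||(I-W)X||^2 restricted to rows with neighbors
  grad <- coef * (E - as.matrix(Matrix::t(W) %*% E))
  list(value = (coef / 2) * sum(E^2), grad = grad)
}

# Pairwise ("personal") penalty: (alpha/2) sum_i sum_{g in G(i)} S_ig
# ||X_i - X_g||^2, the sum over *directed* neighbor terms as written. Its
# exact gradient is coef * L X with L the Laplacian of A + t(A).
pairwise_penalty <- function(X, A, coef) {
  if (coef == 0) return(list(value = 0, grad = matrix(0, nrow(X), ncol(X))))
  P <- A + Matrix::t(A)
  L <- Matrix::Diagonal(x = Matrix::rowSums(P)) - P
  quad <- sum(X * as.matrix(L %*% X))  # = directed sum of S_ig ||X_i - X_g||^2
  list(value = (coef / 2) * quad, grad = coef * as.matrix(L %*% X))
}

#' Regularized objectives and gradients (models I and II)
#'
#' Model I subtracts from \eqn{L_1} a centroid penalty pulling each factor
#' toward the similarity-weighted mean of its neighbors' factors:
#' \deqn{L_2 = L_1
#'   - \frac{\alpha_1}{2}\sum_i \|U_i - \textstyle\sum_{g \in G(i)} S_{ig} U_g / \sum_g S_{ig}\|^2
#'   - \frac{\beta_1}{2}\sum_j \|V_j - \textstyle\sum_{d \in D(j)} S_{jd} V_d / \sum_d S_{jd}\|^2.}
#' Model II replaces the centroid penalty with a pairwise one:
#' \deqn{L_3 = L_1
#'   - \frac{\alpha_2}{2}\sum_i \sum_{g \in G(i)} S_{ig}\|U_i - U_g\|^2
#'   - \frac{\beta_2}{2}\sum_j \sum_{d \in D(j)} S_{jd}\|V_j - V_d\|^2.}
#' The gradient functions return the exact derivative of these objectives:
#' for model II each directed neighbor term contributes to both endpoints'
#' rows (the printed per-row update covers only a row's own terms), which is
#' what makes them agree with finite differences.
#'
#' @inheritParams log_likelihood_L1
#' @param neighbors neighbor sets from \code{\link{build_neighbor_sets}}.
#' @param alpha,beta nonnegative regularization weights for the gene and
#'   disease side respectively.
#' @return objective functions: list with components \code{total},
#'   \code{likelihood}, \code{gene_reg}, \code{disease_reg} (the two
#'   regularizer contributions are \eqn{\le 0} and
#'   \code{total = likelihood + gene_reg + disease_reg}).
#'   Gradient functions: list with \code{dU}, \code{dV}.
#' @export
objective_model1 <- function(model, pairs, neighbors, alpha, beta) {
  gr <- centroid_penalty(model$U, neighbors$gene, alpha)
  dr <- centroid_penalty(model$V, neighbors$disease, beta)
  objective_value(log_likelihood_L1(model, pairs), gr$value, dr$value)
}

#' @rdname objective_model1
#' @export
objective_model2 <- function(model, pairs, neighbors, alpha, beta) {
  gr <- pairwise_penalty(model$U, neighbors$gene, alpha)
  dr <- pairwise_penalty(model$V, neighbors$disease, beta)
  objective_value(log_likelihood_L1(model, pairs), gr$value, dr$value)
}

objective_value <- function(lik, gene_pen, disease_pen) {
  list(total = lik - gene_pen - disease_pen, likelihood = lik,
       gene_reg = -gene_pen, disease_reg = -disease_pen)
}

#' @rdname objective_model1
#' @export
gradient_model1 <- function(model, pairs, neighbors, alpha, beta) {
  g <- gradient_L1(model, pairs)
  list(dU = g$dU - centroid_penalty(model$U, neighbors$gene, alpha)$grad,
       dV = g$dV - centroid_penalty(model$V, neighbors$disease, beta)$grad)
}

#' @rdname objective_model1
#' @export
gradient_model2 <- function(model, pairs, neighbors, alpha, beta) {
  g <- gradient_L1(model, pairs)
  list(dU = g$dU - pairwise_penalty(model$U, neighbors$gene, alpha)$grad,
       dV = g$dV - pairwise_penalty(model$V, neighbors$disease, beta)$grad)
}

# Unified objective/gradient dispatch used by the trainer.
pcfm_objective <- function(model, pairs, neighbors, variant, alpha, beta) {
  switch(variant,
    basic = objective_value(log_likelihood_L1(model, pairs), 0, 0),
    model1 = objective_model1(model, pairs, neighbors, alpha, beta),
    model2 = objective_model2(model, pairs, neighbors, alpha, beta),
    stopf("unknown model variant: %s", variant))
}

pcfm_gradient <- function(model, pairs, neighbors, variant, alpha, beta) {
  switch(variant,
    basic = gradient_L1(model, pairs),
    model1 = gradient_model1(model, pairs, neighbors, alpha, beta),
    model2 = gradient_model2(model, pairs, neighbors, alpha, beta),
    stopf("unknown model variant: %s", variant))
}

#' Training configuration
#'
#' Defaults for the hyperparameters the method itself does not pin down:
#' learning rate 0.05 decayed by 0.95 per epoch, factors initialized from a
#' seeded N(0, 0.1^2), up to 200 epochs with early stop when the objective
#' improves by less than \code{tolerance}; \code{vartheta} defaults to the
#' stated 1e-4. \code{batch = "full"} replaces the per-pair stochastic pass
#' by one full-gradient step per epoch (used by the ascent-monotonicity
#' checks).
#'
#' @param variant \code{"basic"}, \code{"model1"} or \code{"model2"}.
#' @param D latent dimensionality.
#' @param alpha,beta regularization weights (ignored for \code{"basic"}).
#' @param vartheta distance offset.
#' @param learning_rate,lr_decay step size and per-epoch decay factor.
#' @param epochs maximum epochs.
#' @param init_scale standard deviation of the factor initialization.
#' @param seed RNG seed controlling initialization and pair shuffling.
#' @param tolerance early-stopping threshold on objective improvement.
#' @param batch \code{"stochastic"} (default) or \code{"full"}.
#' @return a \code{pcfm_train_config} list.
#' @export
train_config <- function(variant = c("basic", "model1", "model2"), D = 10L,
                         alpha = 0.5, beta = 0.001, vartheta = 1e-4,
                         learning_rate = 0.05, lr_decay = 0.95,
                         epochs = 200L, init_scale = 0.1, seed = 1L,
                         tolerance = 1e-6,
                         batch = c("stochastic", "full")) {
  variant <- match.arg(variant)
  batch <- match.arg(batch)
  stopifnot(D >= 1, alpha >= 0, beta >= 0, vartheta > 0, learning_rate > 0,
            lr_decay > 0, lr_decay <= 1, epochs >= 1, init_scale > 0,
            tolerance > 0)
  structure(list(variant = variant, D = as.integer(D), alpha = alpha,
                 beta = beta, vartheta = vartheta,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 epochs = as.integer(epochs), init_scale = init_scale,
                 seed = as.integer(seed), tolerance = tolerance,
                 batch = batch),
            class = "pcfm_train_config")
}

#' Fit the latent factor model by stochastic gradient ascent
#'
#' Factors are initialized from a seeded zero-mean normal. Each epoch visits
#' the training pairs in a freshly shuffled order; a visited pair updates its
#' gene and disease rows with the pair's likelihood gradient, and (for the
#' regularized variants) the rows coupled to them through their neighbor
#' sets with the corresponding penalty terms. Rows that no pair touched in
#' an epoch still receive their regularizer gradient once at the end of the
#' epoch — without this, genes and diseases absent from the training pairs
#' would keep their random initialization and cold-start prediction could
#' not work. The step size is
#' \code{learning_rate * lr_decay^(epoch-1)}. Training stops after
#' \code{epochs} epochs or when the full objective improves by less than
#' \code{tolerance}; a non-finite objective aborts with advice to lower the
#' learning rate. Runs with the same seed are bitwise identical.
#'
#' @param pairs labeled training pairs (\code{\link{labeled_pairs}}).
#' @param gene_ids,disease_ids identifier vectors defining the factor rows.
#' @param neighbors neighbor sets (required for \code{model1}/\code{model2}).
#' @param config a \code{\link{train_config}}.
#' @return a trained \code{pcfm_model} with a per-epoch \code{trace} data
#'   frame (columns \code{epoch}, \code{total}, \code{likelihood},
#'   \code{gene_reg}, \code{disease_reg}).
#' @export
pcfm_train <- function(pairs, gene_ids, disease_ids, neighbors = NULL,
                       config = train_config()) {
  m <- length(gene_ids); n <- length(disease_ids)
  stopifnot(m >= 1, n >= 1, all(pairs$gene >= 1), all(pairs$gene <= m),
            all(pairs$disease >= 1), all(pairs$disease <= n))
  if (config$variant != "basic" && is.null(neighbors)) {
    stopf("variant '%s' requires neighbor sets", config$variant)
  }
  set.seed(config$seed)
  U <- matrix(rnorm(m * config$D, sd = config$init_scale), m, config$D,
              dimnames = list(gene_ids, NULL))
  V <- matrix(rnorm(n * config$D, sd = config$init_scale), n, config$D,
              dimnames = list(disease_ids, NULL))
  model <- factor_model(U, V, config$vartheta)
  nb <- if (config$variant == "basic") NULL else precompute_neighbors(neighbors, config)

  trace <- vector("list", config$epochs)
  prev <- -Inf
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate * config$lr_decay^(epoch - 1)
    if (config$batch == "full") {
      g <- pcfm_gradient(model, pairs, neighbors, config$variant,
                         config$alpha, config$beta)
      model$U <- model$U + lr * g$dU
      model$V <- model$V + lr * g$dV
    } else {
      model <- sgd_epoch(model, pairs, nb, config, lr, neighbors)
    }
    obj <- pcfm_objective(model, pairs, neighbors, config$variant,
                          config$alpha, config$beta)
    if (!is.finite(obj$total)) {
      stopf("objective diverged at epoch %d; reduce learning_rate", epoch)
    }
    trace[[epoch]] <- data.frame(epoch = epoch, total = obj$total,
                                 likelihood = obj$likelihood,
                                 gene_reg = obj$gene_reg,
                                 disease_reg = obj$disease_reg)
    if (abs(obj$total - prev) < config$tolerance && epoch > 1) {
      trace <- trace[seq_len(epoch)]
      break
    }
    prev <- obj$total
  }
  model$trace <- do.call(rbind, trace[!vapply(trace, is.null, TRUE)])
  model$config <- config
  model
}

# Pre-extract neighbor index/weight vectors so the SGD inner loop touches no
# sparse-matrix slicing.
precompute_neighbors <- function(neighbors, config) {
  extract <- function(A, normalize) {
    A <- methods::as(A, "RsparseMatrix")
    lapply(seq_len(nrow(A)), function(i) {
      jj <- (A@p[i] + 1L):A@p[i + 1L]
      if (A@p[i] == A@p[i + 1L]) return(NULL)
      idx <- A@j[jj] + 1L
      w <- A@x[jj]
      if (normalize) w <- w / sum(w)
      list(idx = idx, w = w)
    })
  }
  norm <- config$variant == "model1"
  list(gene = extract(neighbors$gene, norm),
       disease = extract(neighbors$disease, norm))
}

sgd_epoch <- function(model, pairs, nb, config, lr, neighbors) {
  U <- model$U; V <- model$V
  vt <- model$vartheta
  ord <- sample.int(nrow(pairs))
  for (p in ord) {
    i <- pairs$gene[p]; j <- pairs$disease[p]; y <- pairs$label[p]
    diff <- V[j, ] - U[i, ]
    f <- sum(diff^2) / 2 + vt
    w <- y + (1 - y) * (1 - 1 / (-expm1(-f)))
    U[i, ] <- U[i, ] + lr * w * diff
    V[j, ] <- V[j, ] - lr * w * diff
    if (!is.null(nb)) {
      gi <- nb$gene[[i]]
      if (!is.null(gi)) {
        if (config$variant == "model1") {
          delta <- U[i, ] - drop(gi$w %*% U[gi$idx, , drop = FALSE])
          U[i, ] <- U[i, ] - lr * config$alpha * delta
          U[gi$idx, ] <- U[gi$idx, , drop = FALSE] +
            (lr * config$alpha * gi$w) %o% delta
        } else {
          for (t in seq_along(gi$idx)) {
            g <- gi$idx[t]
            delta <- U[i, ] - U[g, ]
            step <- lr * config$alpha * gi$w[t] * delta
            U[i, ] <- U[i, ] - step
            U[g, ] <- U[g, ] + step
          }
        }
      }
      dj <- nb$disease[[j]]
      if (!is.null(dj)) {
        if (config$variant == "model1") {
          delta <- V[j, ] - drop(dj$w %*% V[dj$idx, , drop = FALSE])
          V[j, ] <- V[j, ] - lr * config$beta * delta
          V[dj$idx, ] <- V[dj$idx, , drop = FALSE] +
            (lr * config$beta * dj$w) %o% delta
        } else {
          for (t in seq_along(dj$idx)) {
            d <- dj$idx[t]
            delta <- V[j, ] - V[d, ]
            step <- lr * config$beta * dj$w[t] * delta
            V[j, ] <- V[j, ] - step
            V[d, ] <- V[d, ] + step
          }
        }
      }
    }
  }
  model$U <- U; model$V <- V
  # Rows no pair touched this epoch got no regularizer update at all, which
  # would leave cold genes/diseases at their random initialization; apply
  # their share of the exact penalty gradient once per epoch.
  if (!is.null(nb)) {
    pen <- if (config$variant == "model1") centroid_penalty else pairwise_penalty
    cold_u <- setdiff(seq_len(nrow(U)), unique(pairs$gene))
    if (length(cold_u) && config$alpha > 0) {
      gU <- pen(model$U, neighbors$gene, config$alpha)$grad
      model$U[cold_u, ] <- model$U[cold_u, ] - lr * gU[cold_u, ]
    }
    cold_v <- setdiff(seq_len(nrow(V)), unique(pairs$disease))
    if (length(cold_v) && config$beta > 0) {
      gV <- pen(model$V, neighbors$disease, config$beta)$grad
      model$V[cold_v, ] <- model$V[cold_v, ] - lr * gV[cold_v, ]
    }
  }
  model
}

#' Score and rank candidate genes for a disease
#'
#' The score of gene i for disease j is the association probability
#' \eqn{e^{-f(U_i, V_j)}}; candidates are returned in decreasing score order
#' with ties broken by gene identifier.
#'
#' @param model a trained \code{pcfm_model}.
#' @param disease disease identifier or index.
#' @param candidates gene identifiers or indices (default: all genes).
#' @return data frame (\code{gene}, \code{score}) ordered by rank.
#' @export
rank_genes <- function(model, disease, candidates = NULL) {
  j <- if (is.character(disease)) index_of(disease, rownames(model$V)) else disease
  cand <- if (is.null(candidates)) seq_len(nrow(model$U)) else {
    if (is.character(candidates)) index_of(candidates, rownames(model$U)) else candidates
  }
  diffs <- model$U[cand, , drop = FALSE] -
    matrix(model$V[j, ], length(cand), model$D, byrow = TRUE)
  score <- exp(-(rowSums(diffs^2) / 2 + model$vartheta))
  ids <- rownames(model$U)[cand] %||% as.character(cand)
  o <- order(-score, ids, method = "radix")
  data.frame(gene = ids[o], score = score[o], row.names = NULL)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory with \code{U.tsv}, \code{V.tsv} (factors with
#' identifier rownames, full double precision) and \code{config.json}. The
#' round trip is lossless, and two checkpoints written from the same seeded
#' training run are bitwise identical.
#'
#' @param model a \code{pcfm_model}.
#' @param path checkpoint directory (created if needed).
#' @return \code{load_model} returns the restored \code{pcfm_model}.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_factor <- function(M, file) {
    df <- data.frame(id = rownames(M) %||% as.character(seq_len(nrow(M))),
                     apply(M, 2L, format_double))
    write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  write_factor(model$U, "U.tsv")
  write_factor(model$V, "V.tsv")
  cfg <- model$config
  meta <- list(vartheta = model$vartheta, D = model$D,
               config = if (is.null(cfg)) NULL else unclass(cfg))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "config.json"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  read_factor <- function(file) {
    df <- read.table(file.path(path, file), sep = "\t",
                     colClasses = "character")
    M <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(M) <- "double"
    dimnames(M) <- list(df[[1L]], NULL)
    M
  }
  meta <- jsonlite::fromJSON(file.path(path, "config.json"))
  model <- factor_model(read_factor("U.tsv"), read_factor("V.tsv"),
                        vartheta = meta$vartheta)
  if (!is.null(meta$config)) {
    model$config <- structure(meta$config, class = "pcfm_train_config")
  }
  model
}
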