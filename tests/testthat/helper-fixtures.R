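# Shared fixture builders; everything is generated in code at test time.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
# withr is not a declared dependency; fall back to plain tempfiles
if (!requireNamespace("withr", quietly = TRUE)) {
  write_lines_tmp <- function(lines) {
    path <- tempfile(fileext = ".tsv")
    writeLines(lines, path)
    path
  }
}

# binary profile matrix from a named list of character vectors
make_profiles <- function(sets, diseases) {
  m <- length(sets)
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(m), lengths(sets)),
    j = match(unlist(sets), diseases),
    x = 1, dims = c(m, length(diseases)),
    dimnames = list(names(sets), diseases))
  M
}

# random symmetric similarity in [0,1] with zero diagonal
random_similarity <- function(ids) {
  n <- length(ids)
  S <- matrix(runif(n * n), n)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  dimnames(S) <- list(ids, ids)
  methods::as(S, "CsparseMatrix")
}

# small random model + labeled pairs + neighbor sets, for gradient tests
random_instance <- function(seed, m_max = 6L, n_max = 6L, D_max = 4L,
                            vartheta = 1e-4) {
  set.seed(seed)
  m <- sample(3:m_max, 1); n <- sample(2:n_max, 1); D <- sample(2:D_max, 1)
  gid <- sprintf("g%02d", seq_len(m)); did <- sprintf("d%02d", seq_len(n))
  model <- factor_model(
    matrix(rnorm(m * D), m, dimnames = list(gid, NULL)),
    matrix(rnorm(n * D), n, dimnames = list(did, NULL)), vartheta)
  np <- sample(2:(m * n), 1)
  idx <- sample(m * n, np)
  pairs <- labeled_pairs(((idx - 1) %% m) + 1, ((idx - 1) %/% m) + 1,
                         rbinom(np, 1, 0.5))
  neighbors <- build_neighbor_sets(random_similarity(gid),
                                   random_similarity(did), 3L)
  list(model = model, pairs = pairs, neighbors = neighbors, m = m, n = n,
       D = D)
}

# central finite differences of a scalar objective in the factor entries
finite_diff <- function(model, objective, h = 1e-6) {
  grad_of <- function(field) {
    G <- model[[field]] * 0
    for (r in seq_len(nrow(G))) for (c in seq_len(ncol(G))) {
      up <- model; up[[field]][r, c] <- up[[field]][r, c] + h
      dn <- model; dn[[field]][r, c] <- dn[[field]][r, c] - h
      G[r, c] <- (objective(up) - objective(dn)) / (2 * h)
    }
    G
  }
  list(dU = grad_of("U"), dV = grad_of("V"))
}

max_rel_err <- function(analytic, fd) {
  scale <- max(abs(fd$dU), abs(fd$dV), 1)
  max(abs(analytic$dU - fd$dU), abs(analytic$dV - fd$dV)) / scale
}

# brute-force Katz oracle: enumerate all heterogeneous walks of length <= 3
katz_oracle <- function(G, P, Q, beta) {
  m <- nrow(P); n <- ncol(P)
  M <- rbind(cbind(as.matrix(G), as.matrix(P)),
             cbind(t(as.matrix(P)), as.matrix(Q)))
  nn <- nrow(M)
  S <- matrix(0, m, n)
  for (u in seq_len(m)) for (v in seq_len(n)) {
    vv <- m + v
    s <- beta * M[u, vv]
    for (w in seq_len(nn)) {
      s <- s + beta^2 * M[u, w] * M[w, vv]
      for (x in seq_len(nn)) {
        s <- s + beta^3 * M[u, w] * M[w, x] * M[x, vv]
      }
    }
    S[u, v] <- s
  }
  S
}
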