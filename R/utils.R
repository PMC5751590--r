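# Internal helpers shared across modules.

# Deterministic identifier ordering: C-locale (radix) sort so index maps are
# stable across platforms and locales.
index_map <- function(ids) {
  sort(unique(as.character(ids)), method = "radix")
}

index_of <- function(ids, universe) {
  idx <- match(ids, universe)
  if (anyNA(idx)) {
    stop("unknown identifier(s): ", paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  idx
}

# Row-stochastic scaling; all-zero rows stay zero.
row_normalize <- function(M) {
  rs <- Matrix::rowSums(M)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% M
}

# Column-stochastic scaling; all-zero columns stay zero.
col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

frobenius_norm <- function(M) sqrt(sum(M@x^2))

# Doubles serialized with %.17g round-trip exactly through text.
format_double <- function(x) formatC(x, format = "g", digits = 17)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
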