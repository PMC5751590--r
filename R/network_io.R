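#' Read and write heterogeneous network layers
#'
#' The four layers of the heterogeneous gene-disease network are exchanged as
#' tab-separated edge lists (UTF-8, \code{#} comments). Identifiers are mapped
#' to indices in C-locale sorted order, so loading the same file twice always
#' yields the same index assignment. Internally every layer is a sparse
#' \code{\link[Matrix]{dgCMatrix}} whose dimnames carry the identifier maps:
#' \itemize{
#'   \item associations: binary genes x diseases matrix (entries exactly 1),
#'   \item similarity: symmetric nonnegative entities x entities matrix,
#'   \item ortholog profiles: binary genes x nonhuman-diseases incidence.
#' }
#'
#' @param path file to read or write.
#' @param gene_col,disease_col 1-based columns holding the gene and disease
#'   identifier (defaults 1 and 2).
#' @return \code{read_associations}: a sparse binary genes x diseases matrix.
#' @name network_io
NULL

# Shared edge-list reader: drops comments/blank lines, enforces a minimum
# field count, reports 1-based line numbers of the original file on error.
read_edge_lines <- function(path, min_fields) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stopf("no records in %s", path)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    bad <- which(keep)[which(nf < min_fields)[1]]
    stopf("parse error at line %d of %s: expected >= %d tab-separated fields",
          bad, path, min_fields)
  }
  list(fields = fields, lines = which(keep))
}

#' @rdname network_io
#' @export
read_associations <- function(path, gene_col = 1L, disease_col = 2L) {
  rec <- read_edge_lines(path, max(gene_col, disease_col))
  g <- vapply(rec$fields, `[[`, "", gene_col)
  d <- vapply(rec$fields, `[[`, "", disease_col)
  genes <- index_map(g)
  diseases <- index_map(d)
  # duplicates collapse to a single unit entry
  M <- Matrix::sparseMatrix(i = index_of(g, genes), j = index_of(d, diseases),
                            x = 1, dims = c(length(genes), length(diseases)),
                            dimnames = list(genes, diseases), use.last.ij = TRUE)
  M@x[] <- 1
  Matrix::drop0(M)
}

#' @rdname network_io
#' @return \code{read_similarity}: a symmetric sparse similarity matrix; when
#'   a pair is listed twice with different weights the maximum is kept, and
#'   self-similarities are dropped.
#' @export
read_similarity <- function(path) {
  rec <- read_edge_lines(path, 3L)
  a <- vapply(rec$fields, `[[`, "", 1L)
  b <- vapply(rec$fields, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(rec$fields, `[[`, "", 3L)))
  bad <- which(is.na(w) | !is.finite(w) | w < 0)
  if (length(bad)) {
    stopf("parse error at line %d of %s: weight must be a finite nonnegative number",
          rec$lines[bad[1]], path)
  }
  ids <- index_map(c(a, b))
  keep <- a != b
  i <- index_of(a[keep], ids); j <- index_of(b[keep], ids); w <- w[keep]
  if (!length(i)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(ids), length(ids)),
                                dimnames = list(ids, ids)))
  }
  # max-weight duplicate policy, applied across both orientations
  key <- paste(c(i, j), c(j, i))
  agg <- tapply(rep(w, 2L), key, max)
  ij <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  M <- Matrix::sparseMatrix(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                            x = as.numeric(agg),
                            dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids))
  Matrix::drop0(M)
}

#' @rdname network_io
#' @param genes optional full gene universe; genes absent from the file get an
#'   empty profile row (useful when the functional network covers more genes
#'   than the ortholog layer).
#' @return \code{read_ortholog_profiles}: a binary genes x nonhuman-diseases
#'   incidence matrix. A third column, if present, is a species tag and is
#'   namespaced into the disease identifier as \code{"species:disease"} so the
#'   eight species' vocabularies never collide.
#' @export
read_ortholog_profiles <- function(path, genes = NULL) {
  rec <- read_edge_lines(path, 2L)
  g <- vapply(rec$fields, `[[`, "", 1L)
  d <- vapply(rec$fields, function(f) {
    if (length(f) >= 3L && nzchar(f[[3L]])) paste0(f[[3L]], ":", f[[2L]]) else f[[2L]]
  }, "")
  gene_ids <- index_map(c(g, genes))
  dis_ids <- index_map(d)
  M <- Matrix::sparseMatrix(i = index_of(g, gene_ids), j = index_of(d, dis_ids),
                            x = 1, dims = c(length(gene_ids), length(dis_ids)),
                            dimnames = list(gene_ids, dis_ids), use.last.ij = TRUE)
  M@x[] <- 1
  Matrix::drop0(M)
}

#' @rdname network_io
#' @param profiles a binary incidence matrix as returned by
#'   \code{read_ortholog_profiles}.
#' @return \code{profile_sets}: named list mapping each gene to the character
#'   vector of nonhuman diseases in its profile (the support of its row).
#'   \code{profile_means}: named numeric vector of row means (profile size
#'   over the number of nonhuman diseases).
#' @export
profile_sets <- function(profiles) {
  apply_names <- rownames(profiles)
  sets <- lapply(seq_len(nrow(profiles)), function(i) {
    colnames(profiles)[profiles[i, ] != 0]
  })
  stats::setNames(sets, apply_names)
}

#' @rdname network_io
#' @export
profile_means <- function(profiles) {
  Matrix::rowSums(profiles != 0) / ncol(profiles)
}

# (row, col, value) triplets of the nonzeros, sorted row-major.
nonzeros <- function(M) {
  TM <- as(as(M, "generalMatrix"), "TsparseMatrix")
  o <- order(TM@i, TM@j)
  data.frame(i = TM@i[o] + 1L, j = TM@j[o] + 1L, x = TM@x[o])
}

write_edges <- function(path, df) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname network_io
#' @param assoc binary genes x diseases association matrix.
#' @export
write_associations <- function(assoc, path) {
  nz <- nonzeros(assoc)
  write_edges(path, data.frame(g = rownames(assoc)[nz$i],
                               d = colnames(assoc)[nz$j]))
}

#' @rdname network_io
#' @param sim symmetric similarity matrix.
#' @export
write_similarity <- function(sim, path) {
  nz <- nonzeros(sim)
  nz <- nz[nz$i < nz$j, , drop = FALSE]
  write_edges(path, data.frame(a = rownames(sim)[nz$i],
                               b = colnames(sim)[nz$j],
                               w = format_double(nz$x)))
}

#' @rdname network_io
#' @export
write_ortholog_profiles <- function(profiles, path) {
  nz <- nonzeros(profiles)
  write_edges(path, data.frame(g = rownames(profiles)[nz$i],
                               d = colnames(profiles)[nz$j]))
}

#' Write and read ranked prediction tables
#'
#' Serializes per-disease gene rankings as a TSV with columns
#' \code{disease_id}, \code{gene_id}, \code{score}, \code{rank}. Ranks are
#' 1-based within each disease, ordered by decreasing score with ties broken
#' by gene identifier (C-locale). Scores round-trip losslessly.
#'
#' @param rankings data frame with columns \code{disease_id}, \code{gene_id},
#'   \code{score} (rank, if present, is recomputed).
#' @param path output file.
#' @return \code{write_ranked_predictions} invisibly returns \code{path};
#'   \code{read_ranked_predictions} returns the table with numeric scores.
#' @export
write_ranked_predictions <- function(rankings, path) {
  stopifnot(all(c("disease_id", "gene_id", "score") %in% names(rankings)))
  if (nrow(rankings) && any(!is.finite(rankings$score))) {
    stopf("non-finite score in rankings")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("disease_id\tgene_id\tscore\trank", con)
  if (nrow(rankings)) {
    o <- order(rankings$disease_id, -rankings$score, rankings$gene_id,
               method = "radix")
    rankings <- rankings[o, , drop = FALSE]
    rk <- stats::ave(seq_len(nrow(rankings)), rankings$disease_id,
                     FUN = seq_along)
    writeLines(paste(rankings$disease_id, rankings$gene_id,
                     format_double(rankings$score), rk, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_ranked_predictions
#' @export
read_ranked_predictions <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = c(
    disease_id = "character", gene_id = "character",
    score = "numeric", rank = "integer"))
  df
}
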