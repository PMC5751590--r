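diseases5 <- c("dA", "dB", "dC", "dD", "dE")

test_that("VSS matches hand-derived values", {
  R <- make_profiles(list(g1 = c("dA", "dB"), g2 = c("dA", "dB")),
                     c("dA", "dB"))
  expect_equal(vss_similarity(R, "g1", "g2"), 1.0)

  R2 <- make_profiles(list(g1 = c("dA", "dB"), g2 = "dC"),
                      c("dA", "dB", "dC"))
  expect_equal(vss_similarity(R2, "g1", "g2"), 0)

  # raw cosine 1/sqrt(2*2) = 0.5, degree scale 2/2
  R3 <- make_profiles(list(g1 = c("dA", "dB"), g2 = c("dA", "dC")),
                      c("dA", "dB", "dC"))
  expect_equal(vss_similarity(R3, "g1", "g2"), 0.5)
})

test_that("PCC matches the mapped Pearson correlation", {
  R <- make_profiles(list(g1 = c("dA", "dB"), g2 = c("dA", "dB")),
                     c("dA", "dB", "dC"))
  expect_equal(pcc_similarity(R, "g1", "g2"), 1.0)

  comp <- make_profiles(list(g1 = "dA", g2 = "dB"), c("dA", "dB"))
  expect_equal(pcc_similarity(comp, "g1", "g2"), 0)

  # brute-force Pearson over the explicit 0/1 vectors
  R3 <- make_profiles(list(g1 = c("dA", "dB"), g2 = "dA"),
                      c("dA", "dB", "dC"))
  ri <- c(1, 1, 0); rg <- c(1, 0, 0)
  raw <- sum((ri - mean(ri)) * (rg - mean(rg))) /
    (sqrt(sum((ri - mean(ri))^2)) * sqrt(sum((rg - mean(rg))^2)))
  expect_equal(pcc_similarity(R3, "g1", "g2"), (raw + 1) / 2 * (2 / 2))
})

test_that("both metrics agree with a dense-vector oracle on random profiles", {
  set.seed(101)
  sets <- lapply(1:20, function(i) sample(diseases5, sample(0:5, 1)))
  names(sets) <- sprintf("g%02d", 1:20)
  sets[[3]] <- character(0)       # force a degenerate empty profile
  sets[[7]] <- diseases5          # and a constant-1 profile
  R <- make_profiles(sets, diseases5)
  sizes <- unname(lengths(sets))
  scale_i <- sizes / max(sizes)
  Svss <- ortholog_similarity(R, "vss")
  Spcc <- ortholog_similarity(R, "pcc")
  for (i in 1:20) for (g in 1:20) {
    ri <- as.numeric(R[i, ]); rg <- as.numeric(R[g, ])
    den <- sqrt(sum(ri^2)) * sqrt(sum(rg^2))
    cos_raw <- if (den == 0) 0 else sum(ri * rg) / den
    pden <- sqrt(sum((ri - mean(ri))^2)) * sqrt(sum((rg - mean(rg))^2))
    pcc_raw <- if (pden == 0) 0 else
      sum((ri - mean(ri)) * (rg - mean(rg))) / pden
    if (i != g) {
      expect_equal(Svss[i, g], scale_i[i] * cos_raw, tolerance = 1e-12)
      expect_equal(Spcc[i, g], scale_i[i] * (pcc_raw + 1) / 2,
                   tolerance = 1e-12)
      expect_equal(vss_similarity(R, i, g), scale_i[i] * cos_raw,
                   tolerance = 1e-12)
      expect_equal(pcc_similarity(R, i, g), scale_i[i] * (pcc_raw + 1) / 2,
                   tolerance = 1e-12)
    }
  }
  expect_true(all(Svss@x >= 0 & Svss@x <= 1))
  expect_true(all(Spcc@x >= 0 & Spcc@x <= 1))
  expect_false(anyNA(as.matrix(Svss)))
  expect_false(anyNA(as.matrix(Spcc)))
})

test_that("degree scaling is the only source of asymmetry", {
  set.seed(7)
  sets <- lapply(1:10, function(i) sample(diseases5, sample(1:5, 1)))
  names(sets) <- sprintf("g%02d", 1:10)
  R <- make_profiles(sets, diseases5)
  sizes <- lengths(sets)
  for (i in 1:9) for (g in (i + 1):10) {
    sig <- vss_similarity(R, i, g); sgi <- vss_similarity(R, g, i)
    if (sgi > 0) expect_equal(sig / sgi, sizes[[i]] / sizes[[g]],
                              tolerance = 1e-12)
  }
})

test_that("the literal intersection denominator is degenerate on binary data", {
  R <- make_profiles(list(g1 = c("dA", "dB"), g2 = c("dA", "dC")),
                     c("dA", "dB", "dC"))
  # cosine over the intersection support is identically 1 before scaling
  expect_equal(vss_similarity(R, "g1", "g2", denominator = "intersection"), 1)
  S <- ortholog_similarity(R, "vss", denominator = "intersection")
  expect_equal(S["g1", "g2"], 1)
  expect_false(anyNA(as.matrix(
    ortholog_similarity(R, "pcc", denominator = "intersection"))))
})

test_that("combine_gene_similarity min-max normalizes, combines, rescales", {
  ids <- c("g1", "g2", "g3")
  Sp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(3, 3), dimnames = list(ids, ids))
  Sdp <- Matrix::sparseMatrix(i = c(1, 2, 1, 3), j = c(2, 1, 3, 1),
                              x = c(2, 2, 4, 4), dims = c(3, 3),
                              dimnames = list(ids, ids))
  S <- combine_gene_similarity(Sp, Sdp, omega = 2)
  expect_equal(S["g1", "g3"], 1)   # weight 4 -> normal 1 -> 2 -> rescaled 1
  expect_equal(S["g1", "g2"], 0)   # weight 2 -> normal 0

  # empty functional layer: output equals S' exactly
  Sp2 <- Matrix::sparseMatrix(i = 1, j = 2, x = 0.3, dims = c(3, 3),
                              dimnames = list(ids, ids), symmetric = FALSE)
  empty <- Sp * 0
  expect_equal(as.matrix(combine_gene_similarity(Sp2, empty, 2)),
               as.matrix(Sp2))
  expect_equal(sum(combine_gene_similarity(empty, empty, 2)), 0)
  expect_error(combine_gene_similarity(Sp, Sdp, omega = 1), "omega")
  expect_true(all(combine_gene_similarity(Sp2, Sdp, 5)@x <= 1))
})

test_that("neighbor sets keep the top-k nonzero similarities", {
  ids <- c("a", "b", "c", "d")
  S <- matrix(0, 4, 4, dimnames = list(ids, ids))
  S["a", "b"] <- S["b", "a"] <- 0.9
  S["a", "c"] <- S["c", "a"] <- 0.3
  nb <- build_neighbor_sets(S, S, k = 5)
  expect_equal(neighbors_of(nb, "gene", 1)$index, c(2L, 3L))
  nb1 <- build_neighbor_sets(S, S, k = 1)
  expect_equal(neighbors_of(nb1, "gene", 1)$index, 2L)
  expect_equal(neighbors_of(nb1, "gene", 1)$sim, 0.9)
  # all-zero row has an empty neighbor set; i never neighbors itself
  expect_equal(nrow(neighbors_of(nb, "gene", 4)), 0L)
  for (i in 1:4) expect_false(i %in% neighbors_of(nb, "gene", i)$index)
})
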