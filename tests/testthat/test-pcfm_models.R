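test_that("pair distance and probability conversion follow the stated maps", {
  expect_equal(pair_distance(c(1, 0), c(1, 0)), 1e-4)
  expect_equal(pair_distance(c(1, 0), c(0, 0), vartheta = 1e-12), 0.5,
               tolerance = 1e-9)
  expect_equal(pair_distance(c(1, 2), c(3, 4)), 4.0001)
  expect_error(pair_distance(c(1, 2), c(1, 2, 3)), "length")

  p <- association_probability(log(2))
  expect_equal(p$p1, 0.5)
  expect_equal(p$p0, 0.5)
  expect_gte(association_probability(50)$p0, 1 - 1e-20)
})

test_that("the log-likelihood matches closed forms", {
  U <- matrix(c(1, 0), 1, dimnames = list("g1", NULL))
  mod <- factor_model(U, matrix(c(1, 0), 1, dimnames = list("d1", NULL)))
  expect_equal(log_likelihood_L1(mod, labeled_pairs(1, 1, 1)), -1e-4)
  expect_equal(log_likelihood_L1(mod, labeled_pairs(integer(0), integer(0),
                                                    numeric(0))), 0)

  # Y = 0 at f = log 2: contribution log(1 - 1/2)
  v <- c(sqrt(2 * (log(2) - 1e-4)), 0)
  mod2 <- factor_model(matrix(0, 1, 2, dimnames = list("g1", NULL)),
                       matrix(v, 1, byrow = TRUE,
                              dimnames = list("d1", NULL)))
  expect_equal(log_likelihood_L1(mod2, labeled_pairs(1, 1, 0)), -log(2))
  expect_lte(log_likelihood_L1(mod2, labeled_pairs(1, 1, 0)), 0)
})

test_that("gradients vanish and saturate where the formulas say they must", {
  U <- matrix(c(0.3, -0.2), 1, dimnames = list("g1", NULL))
  mod <- factor_model(U, U * 1, 1e-4)
  rownames(mod$V) <- "d1"
  g <- gradient_L1(mod, labeled_pairs(1, 1, 1))
  expect_equal(unname(g$dU), matrix(0, 1, 2))  # V_j - U_i = 0

  # Y = 0 with large f: the bracket tends to 0
  far <- factor_model(U, U + 100, 1e-4)
  g0 <- gradient_L1(far, labeled_pairs(1, 1, 0))
  expect_lt(max(abs(g0$dU)), 1e-12)
})

test_that("all three analytic gradients match central finite differences", {
  for (s in 1:10) {
    inst <- random_instance(s)
    a <- runif(1, 0.1, 1); b <- runif(1, 0.1, 1)
    checks <- list(
      list(g = gradient_L1(inst$model, inst$pairs),
           o = function(M) log_likelihood_L1(M, inst$pairs)),
      list(g = gradient_model1(inst$model, inst$pairs, inst$neighbors, a, b),
           o = function(M) objective_model1(M, inst$pairs, inst$neighbors,
                                            a, b)$total),
      list(g = gradient_model2(inst$model, inst$pairs, inst$neighbors, a, b),
           o = function(M) objective_model2(M, inst$pairs, inst$neighbors,
                                            a, b)$total))
    for (ch in checks) {
      expect_lt(max_rel_err(ch$g, finite_diff(inst$model, ch$o)), 1e-5)
    }
  }
})

test_that("regularizers match hand evaluations and vanish on identical rows", {
  gid <- c("g1", "g2"); did <- c("d1", "d2")
  U <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE, dimnames = list(gid, NULL))
  V <- matrix(0, 2, 2, dimnames = list(did, NULL))
  mod <- factor_model(U, V)
  Sg <- matrix(c(0, 1, 1, 0), 2, dimnames = list(gid, gid))
  Sd <- matrix(0, 2, 2, dimnames = list(did, did))
  nb <- build_neighbor_sets(Sg, Sd, 2)
  pairs <- labeled_pairs(integer(0), integer(0), numeric(0))

  # centroid: (alpha/2) * ||(1,0) - (0,0)||^2 summed over both directed rows
  o1 <- objective_model1(mod, pairs, nb, alpha = 2, beta = 1)
  expect_equal(o1$gene_reg, -(2 / 2) * (1 + 1))
  expect_equal(o1$disease_reg, 0)
  expect_equal(o1$total, o1$likelihood + o1$gene_reg + o1$disease_reg)

  # pairwise: (alpha/2) * S * ||U_i - U_g||^2 per directed term
  Sg2 <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(gid, gid))
  U2 <- matrix(c(2, 0, 0, 0), 2, byrow = TRUE, dimnames = list(gid, NULL))
  nb2 <- build_neighbor_sets(Sg2, Sd, 2)
  o2 <- objective_model2(factor_model(U2, V), pairs, nb2, alpha = 1, beta = 1)
  expect_equal(o2$gene_reg, -(1 / 2) * 0.5 * 4 * 2)

  # identical rows: both regularizers vanish, objectives reduce to L1
  same <- factor_model(matrix(1, 2, 2, dimnames = list(gid, NULL)),
                       matrix(2, 2, 2, dimnames = list(did, NULL)))
  pr <- labeled_pairs(c(1, 2), c(1, 2), c(1, 0))
  o3 <- objective_model1(same, pr, nb, 1, 1)
  o4 <- objective_model2(same, pr, nb2, 1, 1)
  expect_equal(o3$total, log_likelihood_L1(same, pr))
  expect_equal(o4$total, log_likelihood_L1(same, pr))

  # empty neighbor sets: gradients reduce to the likelihood gradient
  inst <- random_instance(3)
  gL1 <- gradient_L1(inst$model, inst$pairs)
  nbe <- build_neighbor_sets(
    matrix(0, inst$m, inst$m, dimnames = list(rownames(inst$model$U),
                                              rownames(inst$model$U))),
    matrix(0, inst$n, inst$n, dimnames = list(rownames(inst$model$V),
                                              rownames(inst$model$V))), 3)
  expect_equal(gradient_model1(inst$model, inst$pairs, nbe, 1, 1), gL1)
  expect_equal(gradient_model2(inst$model, inst$pairs, nbe, 1, 1), gL1)
})

test_that("training is deterministic, converges on one pair, ascends full-batch", {
  gid <- c("g1", "g2"); did <- c("d1", "d2")
  pr <- labeled_pairs(1, 1, 1)
  cfg <- train_config(variant = "basic", D = 2, epochs = 50, seed = 4)
  m1 <- pcfm_train(pr, gid, did, config = cfg)
  m2 <- pcfm_train(pr, gid, did, config = cfg)
  expect_identical(m1$U, m2$U)
  expect_identical(m1$V, m2$V)

  # a single positive pair: f decreases monotonically toward vartheta
  fs <- numeric(0)
  for (ep in 1:30) {
    mm <- pcfm_train(pr, gid, did, config = train_config(
      variant = "basic", D = 2, epochs = ep, seed = 4, tolerance = 1e-15))
    fs <- c(fs, pair_distance(mm$U[1, ], mm$V[1, ], mm$vartheta))
  }
  expect_true(all(diff(fs) < 1e-12))
  expect_lt(fs[length(fs)], fs[1])

  # full-batch ascent with a tiny step never decreases the objective
  inst <- random_instance(11)
  for (variant in c("basic", "model1", "model2")) {
    tr <- pcfm_train(inst$pairs, rownames(inst$model$U),
                     rownames(inst$model$V), inst$neighbors,
                     train_config(variant = variant, D = 3, alpha = 0.3,
                                  beta = 0.3, learning_rate = 1e-3,
                                  lr_decay = 1, epochs = 40, seed = 8,
                                  tolerance = 1e-15, batch = "full"))$trace
    expect_true(all(diff(tr$total) >= -1e-10))
  }

  # divergence is reported as an actionable error
  bad <- labeled_pairs(c(1, 1), c(1, 2), c(1, 1))
  expect_error(
    pcfm_train(bad, gid, did, config = train_config(
      variant = "basic", D = 2, learning_rate = 1e6, epochs = 50, seed = 1,
      init_scale = 1e-4)),
    "learning_rate")
})

test_that("rank_genes orders by probability with identifier tie-breaks", {
  U <- rbind(g2 = c(0, 0), g1 = c(3, 0), g3 = c(0, 0))
  V <- rbind(d1 = c(0, 0))
  mod <- factor_model(U, V)
  rk <- rank_genes(mod, "d1")
  expect_equal(rk$gene, c("g2", "g3", "g1"))  # tie 0-distance: id order
  expect_equal(rk$score[1], exp(-1e-4))
  expect_true(all(diff(rk$score) <= 0))
  rk2 <- rank_genes(mod, 1, candidates = c("g1", "g3"))
  expect_equal(rk2$gene, c("g3", "g1"))
})

test_that("cold-start diseases get finite scores and move toward neighbors", {
  set.seed(21)
  gid <- sprintf("g%02d", 1:8); did <- sprintf("d%02d", 1:4)
  # d04 has no training pairs at all but is a strong neighbor of d01
  pr <- labeled_pairs(c(1, 2, 3, 4, 5), c(1, 1, 2, 3, 2), c(1, 1, 1, 0, 0))
  Sd <- matrix(0, 4, 4, dimnames = list(did, did))
  Sd["d01", "d04"] <- Sd["d04", "d01"] <- 0.9
  Sg <- matrix(0, 8, 8, dimnames = list(gid, gid))
  nb <- build_neighbor_sets(Sg, Sd, 3)
  dist_after <- function(epochs) {
    mm <- pcfm_train(pr, gid, did, nb, train_config(
      variant = "model2", D = 3, alpha = 0, beta = 0.5, epochs = epochs,
      seed = 5, tolerance = 1e-15))
    sqrt(sum((mm$V["d04", ] - mm$V["d01", ])^2))
  }
  d_start <- dist_after(1)
  d_later <- dist_after(15)
  expect_lt(d_later, d_start)
  mm <- pcfm_train(pr, gid, did, nb, train_config(
    variant = "model2", D = 3, alpha = 0, beta = 0.5, epochs = 15, seed = 5))
  expect_true(all(is.finite(rank_genes(mm, "d04")$score)))
})

test_that("model checkpoints round-trip bitwise", {
  inst <- random_instance(2)
  cfg <- train_config(variant = "basic", D = 2, epochs = 5, seed = 3)
  mod <- pcfm_train(inst$pairs, rownames(inst$model$U),
                    rownames(inst$model$V), config = cfg)
  d1 <- tempfile(); d2 <- tempfile()
  save_model(mod, d1)
  back <- load_model(d1)
  expect_identical(back$U, mod$U)
  expect_identical(back$V, mod$V)
  expect_equal(back$vartheta, mod$vartheta)
  save_model(back, d2)
  for (f in c("U.tsv", "V.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
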