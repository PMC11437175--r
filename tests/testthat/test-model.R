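test_that("leaf softmax matches closed forms", {
  expect_equal(leaf_softmax(5), 1)
  expect_equal(leaf_softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(leaf_softmax(c(log(3), 0)), c(0.75, 0.25))
  expect_equal(sum(leaf_softmax(c(1000, 1001, 999))), 1)  # stabilized
})

test_that("likelihood aggregation sums descendant leaves bottom-up", {
  tr <- tiny_tree()
  q <- aggregate_likelihoods(c(0.7, 0.3), tr)
  expect_equal(unname(q["root"]), 1)
  expect_equal(unname(q["A;B"]), 1)
  expect_equal(unname(q["A"]), 1)
  expect_equal(unname(q["A;B;C"]), 0.7)

  two_dom <- build_taxtree(annotation_set(list(x = c("A", "C"),
                                               y = c("Aprime", "D"))))
  q2 <- aggregate_likelihoods(c(0.7, 0.3), two_dom)
  expect_equal(unname(q2["A"]), 0.7)
  expect_equal(unname(q2["Aprime"]), 0.3)
})

test_that("likelihood conservation holds on random trees and logits", {
  set.seed(7)
  for (i in 1:100) {
    tr <- random_tree(50)
    p <- leaf_softmax(rnorm(tr$n_leaves, sd = 3))
    q <- aggregate_likelihoods(p, tr)
    expect_lt(abs(sum(p) - 1), 1e-6)
    expect_lt(abs(q["root"] - 1), 1e-6)
    for (id in tr$nodes$id) {
      ch <- tr$children[[as.character(id)]]
      if (length(ch) > 0)
        expect_lt(abs(q[id + 1] - sum(q[ch + 1])), 1e-6)
    }
  }
})

test_that("hierarchical loss matches closed forms", {
  single <- build_taxtree(annotation_set(list(x = "A")))
  expect_equal(hierarchical_loss(1, single, "A"), 0)

  two_dom <- build_taxtree(annotation_set(list(x = "A", y = "Aprime")))
  p <- leaf_softmax(c(0, 0))
  expect_equal(hierarchical_loss(p, two_dom, "A"), -log(0.5),
               tolerance = 1e-9)

  tr <- tiny_tree()
  expect_equal(hierarchical_loss(c(0.5, 0.5), tr, "A;B"), 0)
  # loss is nonnegative and zero iff the whole path has likelihood 1
  expect_gt(hierarchical_loss(c(0.4, 0.6), tr, "A;B;C"), 0)
})

test_that("loss gradient matches a central-difference oracle", {
  set.seed(11)
  tr <- build_taxtree(annotation_set(list(
    a = c("A", "B", "C"), b = c("A", "B", "D"), c = c("E", "F"),
    d = c("A", "B"))))
  logits <- matrix(rnorm(3 * tr$n_leaves), 3)
  paths <- lapply(list(c("A", "B", "C"), c("E", "F"), c("A", "B")),
                  function(l) node_path(tr, lineage_node(tr, l)))
  got <- taxrefiner:::hier_loss_grad(logits, paths, tr$incidence)
  h <- 1e-6
  num <- matrix(0, nrow(logits), ncol(logits))
  for (i in seq_len(nrow(logits))) for (j in seq_len(ncol(logits))) {
    up <- logits; up[i, j] <- up[i, j] + h
    dn <- logits; dn[i, j] <- dn[i, j] - h
    num[i, j] <- (taxrefiner:::hier_loss_grad(up, paths, tr$incidence,
                                              want_grad = FALSE)$loss -
                    taxrefiner:::hier_loss_grad(dn, paths, tr$incidence,
                                                want_grad = FALSE)$loss) / (2 * h)
  }
  expect_lt(max(abs(num - got$grad)), 1e-7)
})

test_that("training separates a well-separated two-species community", {
  comm <- two_species_community(seed = 21)
  feats <- compute_features(comm$sequences, comm$depths)
  truth <- comm$truth

  # logistic-regression oracle first: the fixture must be linearly separable
  y <- as.integer(comm$species_of[feats$contig_ids] ==
                    unique(comm$species_of)[1])
  oracle <- suppressWarnings(
    stats::glm(y ~ ., family = binomial(),
               data = data.frame(y = y, feats$values[, c(1:10, 104:107)])))
  expect_gt(mean((stats::fitted(oracle) > 0.5) == y), 0.95)

  model <- train_refiner(feats, truth, config = fast_config(seed = 2))
  expect_lt(model$loss_trace[length(model$loss_trace)], model$loss_trace[1])
  preds <- predict(model, feats)
  sp <- preds[preds$rank == "species", ]
  acc <- sum(comm$species_of[sp$contig_id] == sp$path) / length(feats$contig_ids)
  expect_gte(acc, 0.95)
})

test_that("degenerate trees make training a no-op with zero loss", {
  comm <- default_community(seed = 3, n_species = 1, n_genera = 1,
                            n_families = 1, contigs_per_species = 8)
  feats <- compute_features(comm$sequences, comm$depths)
  model <- train_refiner(feats, comm$truth,
                         config = fast_config(seed = 1, epochs = 3))
  expect_equal(model$loss_trace, rep(0, 3))

  # annotations all at domain level in a one-domain tree
  dom_only <- annotation_set(lapply(comm$truth$lineages, function(l) l[1]))
  model2 <- train_refiner(feats, dom_only,
                          config = fast_config(seed = 1, epochs = 3))
  expect_equal(model2$loss_trace, rep(0, 3))
})

test_that("training validates its inputs", {
  comm <- default_community(seed = 5, contigs_per_species = 3)
  feats <- compute_features(comm$sequences, comm$depths)
  empty <- annotation_set(setNames(
    rep(list(character(0)), length(feats$contig_ids)), feats$contig_ids))
  expect_error(train_refiner(feats, empty), "no annotated")
  stray <- annotation_set(list(nonexistent = c("A", "B")))
  expect_error(train_refiner(feats, stray), "missing from the feature")
})

test_that("greedy decoding applies the strict 0.5 rule down the tree", {
  two_dom <- build_taxtree(annotation_set(list(x = "A", y = "Aprime")))
  Q <- matrix(c(0.5, 0.5), 1)
  expect_identical(nrow(taxrefiner:::decode_greedy(Q, two_dom, "c1")), 0L)

  Q <- matrix(c(0.7, 0.3), 1)
  out <- taxrefiner:::decode_greedy(Q, two_dom, "c1")
  expect_identical(out$label, "A")
  expect_equal(out$score, 0.7)

  tr <- tiny_tree()                       # nodes A, A;B, A;B;C, A;B;D
  Q <- matrix(c(1.0, 1.0, 0.4, 0.6), 1)
  out <- taxrefiner:::decode_greedy(Q, tr, "c1")
  expect_identical(out$path, c("A", "A;B", "A;B;D"))
  expect_equal(out$score, c(1.0, 1.0, 0.6))
})

test_that("prediction scores are in (0.5, 1], non-increasing, contiguous", {
  comm <- default_community(seed = 8, contigs_per_species = 10)
  feats <- compute_features(comm$sequences, comm$depths)
  model <- train_refiner(feats, comm$truth, config = fast_config(seed = 4))
  preds <- predict(model, feats)
  expect_gt(nrow(preds), 0)
  expect_true(all(preds$score > 0.5 & preds$score <= 1 + 1e-12))
  rank_depth <- match(preds$rank, TAX_RANKS)
  for (id in unique(preds$contig_id)) {
    sel <- preds$contig_id == id
    d <- rank_depth[sel]
    expect_identical(sort(d), seq_along(d))           # contiguous prefix
    expect_true(all(diff(preds$score[sel][order(d)]) <= 1e-9))
  }
})

test_that("prediction rejects mismatched feature width", {
  comm <- default_community(seed = 9, contigs_per_species = 5, n_samples = 2)
  feats <- compute_features(comm$sequences, comm$depths)
  model <- train_refiner(feats, comm$truth,
                         config = fast_config(seed = 1, epochs = 2))
  wrong <- feats
  wrong$values <- wrong$values[, -1]
  expect_error(predict(model, wrong), "width")
})

test_that("score filtering keeps a contiguous high-confidence prefix", {
  preds <- structure(data.frame(
    contig_id = "c1", rank = c("domain", "phylum", "class"),
    label = c("A", "B", "C"), path = c("A", "A;B", "A;B;C"),
    score = c(1.0, 0.96, 0.80)), class = c("prediction_set", "data.frame"))
  expect_identical(nrow(filter_predictions(preds, 0.5)), 3L)
  expect_identical(filter_predictions(preds, 0.95)$label, c("A", "B"))
  expect_identical(filter_predictions(preds, 1.0)$label, "A")
})
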