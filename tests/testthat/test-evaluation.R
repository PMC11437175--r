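make_preds <- function(rows) {
  structure(rows, class = c("prediction_set", "data.frame"))
}

# Predictions/reference pair with configurable overlap at one rank.
paired_fixture <- function(n_ref = 10, n_pred = 10, n_equal = 10) {
  ref <- annotation_set(setNames(
    lapply(seq_len(n_ref), function(i)
      if (i <= n_equal) c("A", "B") else c("A", "Z")),
    paste0("c", seq_len(n_ref))))
  preds <- make_preds(data.frame(
    contig_id = paste0("c", seq_len(n_pred)),
    rank = "phylum", label = "B", path = "A;B", score = 0.9,
    stringsAsFactors = FALSE))
  list(ref = ref, preds = preds)
}

test_that("confusion counts follow the benchmark's definitions", {
  fx <- paired_fixture(10, 10, 10)
  cc <- confusion_counts(fx$preds, fx$ref, "phylum")
  expect_equal(unlist(cc[c("TP", "FP", "FN")]), c(TP = 10, FP = 0, FN = 0))

  fx <- paired_fixture(10, 9, 8)          # pred misses c10; c9 disagrees
  cc <- confusion_counts(fx$preds, fx$ref, "phylum")
  expect_equal(unlist(cc[c("TP", "FP", "FN")]), c(TP = 8, FP = 1, FN = 1))

  empty <- make_preds(data.frame(contig_id = character(0),
                                 rank = character(0), label = character(0),
                                 path = character(0), score = numeric(0)))
  cc <- confusion_counts(empty, fx$ref, "phylum")
  expect_equal(unlist(cc[c("TP", "FP", "FN")]), c(TP = 0, FP = 0, FN = 10))
})

test_that("equality is full-path identity, not bare-name identity", {
  ref <- annotation_set(list(c1 = c("A", "F1", "G")))
  pred_wrong_parent <- make_preds(data.frame(
    contig_id = "c1", rank = "class", label = "G", path = "A;F2;G",
    score = 0.9, stringsAsFactors = FALSE))
  cc <- confusion_counts(pred_wrong_parent, ref, "class")
  expect_equal(cc$FP, 1)
  expect_equal(cc$TP, 0)
})

test_that("precision/recall/F1 use FP in the recall denominator", {
  m <- precision_recall_f1(list(TP = 8, FP = 1, FN = 1))
  expect_equal(unname(m["precision"]), 0.8889, tolerance = 1e-4)
  expect_equal(unname(m["recall"]), 0.8000, tolerance = 1e-4)
  expect_equal(unname(m["f1"]), 0.8421, tolerance = 1e-4)

  expect_equal(unname(precision_recall_f1(list(TP = 0, FP = 0, FN = 0))),
               c(0, 0, 0))
  expect_equal(unname(precision_recall_f1(list(TP = 10, FP = 0, FN = 0))),
               c(1, 1, 1))
})

test_that("this recall is bounded by the textbook recall and metrics are monotone in TP", {
  set.seed(13)
  for (i in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    m <- precision_recall_f1(list(TP = tp, FP = fp, FN = fn))
    textbook <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_lte(m["recall"], textbook + 1e-12)
    m2 <- precision_recall_f1(list(TP = tp + 1, FP = fp, FN = fn))
    expect_true(all(m2 >= m - 1e-12))
  }
})

test_that("k-fold split is balanced, disjoint and seed-deterministic", {
  f <- kfold_split(paste0("c", 1:10), k = 5, seed = 3)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  f11 <- kfold_split(paste0("c", 1:11), k = 5, seed = 3)
  expect_equal(sort(unname(table(f11))), c(2L, 2L, 2L, 2L, 3L),
               ignore_attr = TRUE)
  expect_identical(f, kfold_split(paste0("c", 1:10), k = 5, seed = 3))
  expect_false(identical(f, kfold_split(paste0("c", 1:10), k = 5, seed = 4)))
  expect_error(kfold_split(paste0("c", 1:3), k = 5), "at least")
})

test_that("k-fold consistency covers each annotated contig exactly once", {
  comm <- default_community(seed = 17, contigs_per_species = 8)
  feats <- compute_features(comm$sequences, comm$depths)
  ann <- corrupt_annotations(comm$truth, drop_rate = 0.2, seed = 18)
  rep <- kfold_consistency(feats, ann, config = fast_config(seed = 5), k = 5)
  ann_ids <- names(ann$lineages)[lengths(ann$lineages) > 0]
  expect_true(all(rep$predictions$contig_id %in% ann_ids))
  per_rank <- table(rep$predictions$contig_id, rep$predictions$rank)
  expect_true(all(per_rank <= 1))         # one prediction per contig-rank
  expect_true(all(c("TP", "FP", "FN", "precision", "recall", "f1") %in%
                    names(rep$metrics)))
})

test_that("k-fold completes when every fold is a single contig", {
  comm <- default_community(seed = 19, n_species = 5, n_genera = 5,
                            n_families = 5, contigs_per_species = 1)
  feats <- compute_features(comm$sequences, comm$depths)
  rep <- kfold_consistency(feats, comm$truth,
                           config = fast_config(seed = 1, epochs = 2), k = 5)
  expect_s3_class(rep$predictions, "prediction_set")
})

test_that("permuted annotations score near the majority-class baseline", {
  comm <- default_community(seed = 23)
  feats <- compute_features(comm$sequences, comm$depths)
  lin <- comm$truth$lineages
  set.seed(24)
  permuted <- annotation_set(setNames(lin[sample(length(lin))], names(lin)))
  rep <- kfold_consistency(feats, permuted, config = fast_config(seed = 6))
  prec <- rep$metrics$precision[rep$metrics$rank == "species"]
  # analytic baseline: predicting any fixed species i is correct with
  # frequency p_i; the best fixed guess scores max(p_i), here 1/8
  freqs <- table(vapply(lin, paste, character(1), collapse = ";"))
  baseline <- max(freqs) / sum(freqs)
  expect_lt(prec, baseline + 0.15)
})

test_that("ground-truth threshold sweep is monotone in FP", {
  comm <- default_community(seed = 29, contigs_per_species = 10)
  feats <- compute_features(comm$sequences, comm$depths)
  model <- train_refiner(feats, comm$truth, config = fast_config(seed = 7))
  preds <- predict(model, feats)
  rep <- ground_truth_report(preds, comm$truth)
  expect_true(any(rep$is_default))
  for (r in unique(rep$rank)) {
    sub <- rep[rep$rank == r, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$FP) <= 0))   # raising the threshold never adds FP
  }
  # all-1.0 scores: constant PR across thresholds <= 1
  const <- make_preds(data.frame(contig_id = "c1", rank = "domain",
                                 label = "A", path = "A", score = 1))
  truth1 <- annotation_set(list(c1 = "A"))
  rep1 <- ground_truth_report(const, truth1, thresholds = c(0.5, 0.9, 1.0))
  expect_true(all(rep1$precision == 1))
})

test_that("species deletion reassigns contigs within the surviving tree", {
  comm <- default_community(seed = 31)
  feats <- compute_features(comm$sequences, comm$depths)
  del <- "Species1"                       # sibling species share its genus
  out <- species_deletion_experiment(feats, comm$truth,
                                     config = fast_config(seed = 8),
                                     species = del)
  s <- out$summary
  expect_identical(nrow(s), 1L)
  expect_equal(s$n_contigs, 50)
  expect_gte(s$frac_correct_genus, 0.5)
  # the deleted species cannot be re-assigned: it left the output space
  if (s$frac_species_assigned > 0)
    expect_false(grepl(";Species1$", s$top_assigned_species))
  expect_error(
    species_deletion_experiment(feats, comm$truth,
                                config = fast_config(seed = 8),
                                species = "NoSuchSpecies"),
    "unknown species")
})

test_that("near-identical sibling absorbs a deleted species' contigs", {
  # two species, same genus, nearly identical composition and abundance
  comm <- generate_community(community_spec(
    n_species = 2, n_genera = 1, n_families = 1, n_samples = 3,
    contigs_per_species = 60, composition_alpha = 2,
    hierarchy_concentration = 1e5, abundance_sigma = 0.05,
    contig_depth_sigma = 0.05, seed = 33))
  feats <- compute_features(comm$sequences, comm$depths)
  # nearest-centroid oracle on raw projected TNF: the centroids of the two
  # species must sit closer together than the within-species scatter,
  # i.e. the species are not separable by composition
  proj <- project_tnf(count_tetramers(comm$sequences))
  sp <- comm$species_of
  mu1 <- colMeans(proj[sp == unique(sp)[1], ])
  mu2 <- colMeans(proj[sp == unique(sp)[2], ])
  within <- mean(sqrt(rowSums(sweep(proj[sp == unique(sp)[1], ], 2, mu1)^2)))
  expect_lt(sqrt(sum((mu1 - mu2)^2)), within)
  out <- species_deletion_experiment(feats, comm$truth,
                                     config = fast_config(seed = 9),
                                     species = "Species1")
  s <- out$summary
  expect_gt(s$frac_species_assigned, 0.5)  # sibling absorbs the contigs
  expect_match(s$top_assigned_species, "Species2")
})

test_that("classifier ranking reports per-rank precision and Spearman", {
  comm <- default_community(seed = 37, contigs_per_species = 12)
  feats <- compute_features(comm$sequences, comm$depths)
  sets <- list(good = corrupt_annotations(comm$truth, error_rate = 0.05,
                                          seed = 38),
               bad = corrupt_annotations(comm$truth, error_rate = 0.5,
                                         seed = 39))
  rep <- benchmark_classifiers(feats, sets, config = fast_config(seed = 10),
                               truth = comm$truth)
  expect_setequal(unique(rep$precision$classifier), c("good", "bad"))
  expect_true("species" %in% names(rep$spearman))
  expect_error(benchmark_classifiers(feats, sets["good"]), ">= 2")
})
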