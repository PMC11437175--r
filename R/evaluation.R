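# Reference label of each contig at a given rank depth (full path string),
# restricted to contigs annotated at least that deep.
ref_paths_at_rank <- function(annotations, rank_depth) {
  lin <- annotations$lineages[lengths(annotations$lineages) >= rank_depth]
  vapply(lin, function(lab) paste(lab[seq_len(rank_depth)], collapse = ";"),
         character(1))
}

#' Per-rank confusion counts between predictions and reference annotations
#'
#' Counted over the contigs where the reference has a label at the rank:
#' TP = prediction present and identical (full-path identity, so a correct
#' species under a wrong genus cannot count), FP = present and different,
#' FN = reference present but prediction missing.
#'
#' @param preds A `prediction_set`.
#' @param ref An `annotation_set` (classifier annotations or ground truth).
#' @param rank Rank name (one of [TAX_RANKS]) or depth 1-7.
#' @return List of class `confusion_counts`: `TP`, `FP`, `FN`, `rank`.
#' @export
confusion_counts <- function(preds, ref, rank) {
  depth <- if (is.character(rank)) match(rank, TAX_RANKS) else as.integer(rank)
  stopifnot(!is.na(depth), depth >= 1, depth <= length(TAX_RANKS))
  ref_paths <- ref_paths_at_rank(ref, depth)
  p <- preds[preds$rank == TAX_RANKS[depth], , drop = FALSE]
  pred_paths <- stats::setNames(p$path, p$contig_id)
  hit <- pred_paths[names(ref_paths)]
  tp <- sum(!is.na(hit) & hit == ref_paths)
  fp <- sum(!is.na(hit) & hit != ref_paths)
  fn <- sum(is.na(hit))
  structure(list(TP = tp, FP = fp, FN = fn, rank = TAX_RANKS[depth]),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' Uses the benchmark's definitions: `precision = TP / (TP + FP)` and
#' `recall = TP / (TP + FP + FN)` — note that FP appears in the recall
#' denominator, unlike the textbook definition, so this recall is never
#' larger than the textbook one. `f1` is the harmonic mean. Any 0/0 is 0.
#'
#' @param counts A `confusion_counts` (or list with `TP`, `FP`, `FN`).
#' @return Named numeric vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  div0 <- function(a, b) if (b == 0) 0 else a / b
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fp + fn)
  f1 <- div0(2 * precision * recall, precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

# Per-rank metric table for a prediction/reference pair.
metric_table <- function(preds, ref, ranks = TAX_RANKS) {
  rows <- lapply(ranks, function(r) {
    cc <- confusion_counts(preds, ref, r)
    if (cc$TP + cc$FP + cc$FN == 0) return(NULL)  # rank absent from ref
    m <- precision_recall_f1(cc)
    data.frame(rank = r, TP = cc$TP, FP = cc$FP, FN = cc$FN,
               precision = m["precision"], recall = m["recall"],
               f1 = m["f1"], row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Random balanced k-fold assignment
#'
#' @param contig_ids Character vector of ids to split.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Object of class `fold_assignment`: named integer vector of folds
#'   in `0..k-1`, with attributes `k` and `seed`. Fold sizes differ by at
#'   most 1.
#' @export
kfold_split <- function(contig_ids, k = 5, seed = 1L) {
  stopifnot(k >= 2)
  if (length(contig_ids) < k)
    stop(sprintf("need at least k = %d ids, got %d", k, length(contig_ids)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold <- (seq_along(contig_ids) - 1L) %% k
  fold <- fold[sample.int(length(fold))]
  structure(stats::setNames(fold, contig_ids), k = k, seed = seed,
            class = "fold_assignment")
}

#' K-fold annotation self-consistency benchmark
#'
#' The ground-truth-free evaluation: the annotated contigs are split into
#' `k` folds; for each fold the refiner is trained on the other `k - 1` folds
#' (with the taxonomy tree rebuilt from the training annotations only) and
#' predicts the held-out fold at score threshold 0.5. The concatenated
#' held-out predictions are scored against the classifier's own annotations
#' per rank. A held-out label absent from the training-fold tree cannot be
#' emitted and is scored as a false negative. High consistency precision
#' indicates reproducible (feature-supported) annotations.
#'
#' @param features A `feature_matrix` covering the annotated contigs.
#' @param annotations The classifier `annotation_set` under evaluation.
#' @param config A [network_config()]; fold seeds are derived from its seed.
#' @param k Number of folds (default 5).
#' @return List of class `kfold_report`: `metrics` (per-rank data.frame),
#'   `predictions` (the concatenated held-out `prediction_set`), `folds`.
#' @export
kfold_consistency <- function(features, annotations, config = network_config(),
                              k = 5) {
  ann_ids <- names(annotations$lineages)[lengths(annotations$lineages) > 0]
  if (length(ann_ids) < k)
    stop(sprintf("need >= %d annotated contigs for %d-fold evaluation", k, k))
  folds <- kfold_split(ann_ids, k = k, seed = config$seed)
  all_preds <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    train_ids <- ann_ids[folds != f]
    test_ids <- ann_ids[folds == f]
    ann_train <- annotation_set(annotations$lineages[train_ids],
                                source_name = annotations$source_name)
    tree_f <- build_taxtree(ann_train)
    feats_train <- subset_features(features, train_ids)
    model <- tryCatch(
      train_refiner(feats_train, ann_train, tree = tree_f, config = config),
      error = function(e) stop(sprintf("fold %d training failed: %s", f,
                                       conditionMessage(e))))
    preds <- predict(model, subset_features(features, test_ids))
    # labels unreachable by this fold's tree are forced to count as FN
    preds <- drop_out_of_tree(preds, annotations, test_ids, tree_f)
    all_preds[[f + 1]] <- preds
  }
  preds <- structure(do.call(rbind, all_preds),
                     class = c("prediction_set", "data.frame"))
  rownames(preds) <- NULL
  structure(list(metrics = metric_table(preds, annotations),
                 predictions = preds, folds = folds),
            class = "kfold_report")
}

# Remove emissions at ranks where the held-out reference label does not
# exist in the training-fold tree (those contigs are FN at that rank).
drop_out_of_tree <- function(preds, annotations, test_ids, tree) {
  keep <- rep(TRUE, nrow(preds))
  for (depth in seq_along(TAX_RANKS)) {
    ref_paths <- ref_paths_at_rank(
      annotation_set(annotations$lineages[test_ids],
                     source_name = annotations$source_name), depth)
    unreachable <- names(ref_paths)[!(ref_paths %in% tree$nodes$path)]
    keep <- keep & !(preds$rank == TAX_RANKS[depth] &
                       preds$contig_id %in% unreachable)
  }
  out <- preds[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("prediction_set", "data.frame"))
}

subset_features <- function(features, ids) {
  row_of <- match(ids, features$contig_ids)
  if (anyNA(row_of))
    stop("contig(s) missing from the feature matrix: ",
         paste(utils::head(ids[is.na(row_of)], 5), collapse = ", "))
  structure(list(values = features$values[row_of, , drop = FALSE],
                 contig_ids = ids, n_samples = features$n_samples,
                 blocks = features$blocks),
            class = "feature_matrix")
}

#' Ground-truth comparison with a threshold sweep
#'
#' Filters the predictions at each threshold and reports per-rank precision
#' and recall pairs (the PR curve table), marking the default 0.95 operating
#' point. Ranks with no ground-truth labels are omitted.
#'
#' @param preds A `prediction_set` (unfiltered, threshold 0.5 decode).
#' @param truth A non-empty ground-truth `annotation_set`.
#' @param thresholds Score grid to sweep (always augmented with
#'   `default_threshold`).
#' @param default_threshold Marked operating point (default 0.95).
#' @return Data.frame `rank, threshold, TP, FP, FN, precision, recall, f1,
#'   is_default`.
#' @export
ground_truth_report <- function(preds, truth,
                                thresholds = seq(0.5, 1, by = 0.05),
                                default_threshold = 0.95) {
  if (sum(lengths(truth$lineages) > 0) == 0)
    stop("ground-truth annotation set is empty")
  thresholds <- sort(unique(c(thresholds, default_threshold)))
  rows <- lapply(thresholds, function(th) {
    m <- metric_table(filter_predictions(preds, th), truth)
    if (is.null(m)) return(NULL)
    m$threshold <- th
    m$is_default <- th == default_threshold
    m
  })
  out <- do.call(rbind, rows)
  out[, c("rank", "threshold", "TP", "FP", "FN", "precision", "recall",
          "f1", "is_default")]
}

#' Novel-taxon (species-deletion) experiment
#'
#' Emulates species missing from the reference database: the annotations of
#' all contigs of each named species are truncated to the genus rank, the
#' refiner is retrained on the modified annotations (tree rebuilt, so the
#' deleted species leaves the output space), and the affected contigs are
#' re-predicted. For each deleted species the report gives the fraction of
#' its contigs that recover the correct genus, the fraction that are
#' (incorrectly) assigned some species label — the false-positive share,
#' with `1 - FP` being the share of correctly missing labels — the most
#' frequently assigned species, and the Pearson correlation of mean feature
#' vectors between the deleted and that assigned species.
#'
#' @param features A `feature_matrix`.
#' @param annotations The classifier `annotation_set`.
#' @param config A [network_config()].
#' @param species Character vector of species to delete (full paths or bare
#'   species names present in the annotations).
#' @return List of class `deletion_report`: `summary` (one row per deleted
#'   species), `predictions` (for the affected contigs), `model`.
#' @export
species_deletion_experiment <- function(features, annotations,
                                        config = network_config(), species) {
  lin <- annotations$lineages
  sp_path_of <- vapply(lin, function(lab)
    if (length(lab) == 7) paste(lab, collapse = ";") else NA_character_,
    character(1))
  resolve <- function(s) {
    if (s %in% sp_path_of) return(s)
    hits <- unique(sp_path_of[!is.na(sp_path_of) &
                                endsWith(sp_path_of, paste0(";", s))])
    if (length(hits) == 0) stop("unknown species: ", s)
    if (length(hits) > 1) stop("ambiguous species name: ", s)
    hits
  }
  del_paths <- vapply(species, resolve, character(1))

  modified <- lin
  affected <- lapply(del_paths, function(p) names(lin)[!is.na(sp_path_of) &
                                                         sp_path_of == p])
  for (ids in affected)
    modified[ids] <- lapply(modified[ids], function(lab) lab[1:6])
  ann_mod <- annotation_set(modified, source_name = annotations$source_name)
  tree <- build_taxtree(ann_mod)
  model <- train_refiner(features, ann_mod, tree = tree, config = config)

  all_affected <- unlist(affected, use.names = FALSE)
  preds <- predict(model, subset_features(features, all_affected))

  summary_rows <- lapply(seq_along(del_paths), function(i) {
    ids <- affected[[i]]
    genus_true <- sub(";[^;]+$", "", del_paths[i])
    pg <- preds[preds$rank == "genus" & preds$contig_id %in% ids, ]
    ps <- preds[preds$rank == "species" & preds$contig_id %in% ids, ]
    frac_genus <- sum(pg$path == genus_true) / length(ids)
    frac_species_assigned <- nrow(ps) / length(ids)
    top <- if (nrow(ps) > 0) names(sort(table(ps$path), decreasing = TRUE))[1]
      else NA_character_
    corr <- if (!is.na(top)) {
      top_ids <- names(lin)[!is.na(sp_path_of) & sp_path_of == top]
      if (length(top_ids) > 0) {
        mu_del <- colMeans(features$values[match(ids, features$contig_ids),
                                           , drop = FALSE])
        mu_top <- colMeans(features$values[match(top_ids, features$contig_ids),
                                           , drop = FALSE])
        stats::cor(mu_del, mu_top)
      } else NA_real_
    } else NA_real_
    data.frame(species = del_paths[i], n_contigs = length(ids),
               frac_correct_genus = frac_genus,
               frac_species_assigned = frac_species_assigned,
               top_assigned_species = top %||% NA_character_,
               feature_correlation = corr,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, summary_rows), predictions = preds,
                 model = model),
            class = "deletion_report")
}

#' Rank classifiers by k-fold self-consistency precision
#'
#' Runs [kfold_consistency()] for each annotation set over the shared
#' features and tabulates per-classifier per-rank precision. When ground
#' truth is supplied, each classifier's own annotations are also scored
#' against the truth and the Spearman rank correlation between
#' consistency-based and truth-based precision is reported per rank.
#'
#' @param features Shared `feature_matrix`.
#' @param annotation_sets Named list of >= 2 `annotation_set`s.
#' @param config A [network_config()].
#' @param k Folds.
#' @param truth Optional ground-truth `annotation_set`.
#' @return List of class `benchmark_report`: `precision` (classifier x rank
#'   data.frame), `reports` (per-classifier `kfold_report`s), and, with
#'   truth, `truth_precision` and `spearman` (per rank).
#' @export
benchmark_classifiers <- function(features, annotation_sets,
                                  config = network_config(), k = 5,
                                  truth = NULL) {
  if (length(annotation_sets) < 2)
    stop("ranking needs >= 2 annotation sets")
  if (is.null(names(annotation_sets)))
    names(annotation_sets) <- paste0("classifier", seq_along(annotation_sets))
  reports <- lapply(annotation_sets, function(a)
    kfold_consistency(features, a, config = config, k = k))
  prec <- do.call(rbind, lapply(names(reports), function(nm) {
    m <- reports[[nm]]$metrics
    data.frame(classifier = nm, rank = m$rank, precision = m$precision,
               recall = m$recall, f1 = m$f1, stringsAsFactors = FALSE)
  }))
  out <- list(precision = prec, reports = reports)
  if (!is.null(truth)) {
    truth_prec <- do.call(rbind, lapply(names(annotation_sets), function(nm) {
      p <- annotations_as_predictions(annotation_sets[[nm]])
      m <- metric_table(p, truth)
      data.frame(classifier = nm, rank = m$rank, precision = m$precision,
                 stringsAsFactors = FALSE)
    }))
    spearman <- vapply(unique(prec$rank), function(r) {
      x <- prec$precision[prec$rank == r][match(names(annotation_sets),
                                                prec$classifier[prec$rank == r])]
      y <- truth_prec$precision[truth_prec$rank == r][
        match(names(annotation_sets),
              truth_prec$classifier[truth_prec$rank == r])]
      if (sum(stats::complete.cases(x, y)) < 2) return(NA_real_)
      suppressWarnings(stats::cor(x, y, method = "spearman",
                                  use = "complete.obs"))
    }, numeric(1))
    out$truth_precision <- truth_prec
    out$spearman <- stats::setNames(spearman, unique(prec$rank))
  }
  structure(out, class = "benchmark_report")
}

# View an annotation set as a prediction set (score 1 at every rank), so it
# can be scored against another annotation set with the same machinery.
annotations_as_predictions <- function(annotations) {
  lin <- annotations$lineages[lengths(annotations$lineages) > 0]
  rows <- lapply(names(lin), function(id) {
    lab <- lin[[id]]
    data.frame(contig_id = id, rank = TAX_RANKS[seq_along(lab)],
               label = lab,
               path = vapply(seq_along(lab), function(r)
                 paste(lab[1:r], collapse = ";"), character(1)),
               score = 1, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("prediction_set", "data.frame"))
}
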