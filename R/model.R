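#' Refiner network configuration
#'
#' Defaults follow the published training regime: four fully connected hidden
#' layers of 512 units with leaky ReLU (negative slope 0.01), batch
#' normalization (eps 1e-5, momentum 0.1) and dropout (p = 0.2) on each, 100
#' epochs at batch size 1024, Adam. The learning rate is fixed at 1e-3; the
#' batch size is reduced automatically when the training set is smaller.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param leaky_slope Negative slope of the leaky ReLU.
#' @param batchnorm_eps,batchnorm_momentum Batch-normalization parameters.
#' @param dropout_p Dropout probability in `[0, 1)`.
#' @param epochs Number of passes over the annotated training set.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param clamp Likelihood floor applied before taking logs in the loss.
#' @param seed Integer seed controlling weight init, shuffling and dropout.
#' @return A list of class `network_config`.
#' @export
network_config <- function(hidden_sizes = c(512, 512, 512, 512),
                           leaky_slope = 0.01,
                           batchnorm_eps = 1e-5,
                           batchnorm_momentum = 0.1,
                           dropout_p = 0.2,
                           epochs = 100,
                           batch_size = 1024,
                           learning_rate = 1e-3,
                           clamp = 1e-12,
                           seed = 1L) {
  stopifnot(all(hidden_sizes > 0), dropout_p >= 0, dropout_p < 1,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 leaky_slope = leaky_slope, batchnorm_eps = batchnorm_eps,
                 batchnorm_momentum = batchnorm_momentum,
                 dropout_p = dropout_p, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, clamp = clamp,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Softmax over leaf logits
#' @param logits Numeric vector (or matrix, row-wise) of one logit per leaf.
#' @return Leaf likelihoods summing to 1 (per row).
#' @export
leaf_softmax <- function(logits) {
  if (is.null(dim(logits))) as.vector(softmax_rows(matrix(logits, 1)))
  else softmax_rows(logits)
}

#' Aggregate leaf likelihoods bottom-up over the taxonomy tree
#'
#' A node's likelihood is the sum of the softmax leaf likelihoods over its
#' descendant leaves; the root aggregates all leaves and always has
#' likelihood 1 for a normalized input.
#'
#' @param leaf_probs Numeric vector of leaf likelihoods in leaf-index order.
#' @param tree A `taxtree`.
#' @return Named numeric vector: `root` followed by one entry per node, named
#'   by full path.
#' @export
aggregate_likelihoods <- function(leaf_probs, tree) {
  stopifnot(length(leaf_probs) == tree$n_leaves)
  q <- as.vector(matrix(leaf_probs, 1) %*% tree$incidence)
  stats::setNames(c(sum(leaf_probs), q), c("root", tree$nodes$path))
}

#' Hierarchical negative log-likelihood of a true node
#'
#' The loss is the sum, over the true node and all its ancestors (root
#' excluded), of the negative log of the aggregated node likelihood.
#'
#' @param leaf_probs Numeric vector of leaf likelihoods (sums to 1).
#' @param tree A `taxtree`.
#' @param true_node Node id or full path string of the annotated taxon.
#' @param clamp Likelihood floor before the log.
#' @return Nonnegative scalar; 0 iff every node on the path has likelihood 1.
#' @export
hierarchical_loss <- function(leaf_probs, tree, true_node, clamp = 1e-12) {
  path <- node_path(tree, if (is.character(true_node))
    unname(tree$path_to_id[true_node]) else true_node)
  if (length(path) == 0) return(0)
  q <- as.vector(matrix(leaf_probs, 1) %*% tree$incidence)
  sum(-log(pmax(q[path], clamp)))
}

#' Train the taxonomy refiner on the annotated contigs
#'
#' Trains the MLP on the subset of contigs with a non-empty lineage, using
#' the hierarchical softmax loss: each contig contributes the negative
#' log-likelihood summed along its annotated ancestor path, so partial
#' (rank-truncated) annotations train the network at exactly the depth they
#' reach. Unannotated contigs are excluded from training but can be predicted
#' afterwards.
#'
#' @param features A `feature_matrix` covering (at least) all annotated
#'   contigs.
#' @param annotations An `annotation_set`.
#' @param tree The output-space `taxtree`; defaults to the tree built from
#'   `annotations`.
#' @param config A [network_config()].
#' @return Object of class `trained_refiner` with the learned weights, the
#'   tree, the config, and the per-epoch mean training-loss trace.
#' @export
train_refiner <- function(features, annotations, tree = NULL,
                          config = network_config()) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(annotations, "annotation_set"))
  ann <- annotations$lineages[lengths(annotations$lineages) > 0]
  if (length(ann) == 0) stop("no annotated contigs to train on")
  if (is.null(tree)) tree <- build_taxtree(annotations)
  missing <- setdiff(names(ann), features$contig_ids)
  if (length(missing) > 0)
    stop("annotated contig(s) missing from the feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  target_node <- vapply(ann, function(lab) lineage_node(tree, lab), integer(1))
  if (anyNA(target_node))
    stop("annotation(s) not resolvable in the supplied tree: ",
         paste(utils::head(names(ann)[is.na(target_node)], 5), collapse = ", "))
  row_of <- match(names(ann), features$contig_ids)
  Xt <- t(features$values[row_of, , drop = FALSE])  # features x contigs
  paths <- lapply(target_node, function(nid) node_path(tree, nid))

  n <- ncol(Xt)
  batch_size <- min(config$batch_size, n)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  params <- nn_init(nrow(Xt), config$hidden_sizes, tree$n_leaves)
  state <- adam_init(params)
  loss_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      fwd <- nn_forward(params, Xt[, idx, drop = FALSE], config,
                        training = TRUE)
      params <- fwd$params          # running BN statistics were updated
      lg <- hier_loss_grad(fwd$logits, paths[idx], tree$incidence,
                           clamp = config$clamp)
      grads <- nn_backward(params, fwd, lg$grad, config)
      stepped <- adam_step(params, grads, state, lr = config$learning_rate)
      params <- stepped$params
      state <- stepped$state
      epoch_loss <- epoch_loss + lg$loss * length(idx)
    }
    loss_trace[epoch] <- epoch_loss / n
  }
  structure(list(params = params, tree = tree, config = config,
                 feature_dim = nrow(Xt), blocks = features$blocks,
                 n_train = n, loss_trace = loss_trace),
            class = "trained_refiner")
}

#' @export
print.trained_refiner <- function(x, ...) {
  cat(sprintf(paste0("trained_refiner: %d features -> [%s] -> %d leaves; ",
                     "%d contigs, %d epochs (loss %.4f -> %.4f)\n"),
              x$feature_dim, paste(x$config$hidden_sizes, collapse = ","),
              x$tree$n_leaves, x$n_train, x$config$epochs,
              x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Predict per-rank taxonomic labels with likelihood scores
#'
#' Runs the network in inference mode (dropout off, batch normalization using
#' running statistics), aggregates leaf likelihoods bottom-up, and decodes
#' greedily from the root: at each rank the child of the current node with
#' the highest likelihood is selected and emitted if its likelihood is
#' strictly greater than 0.5; otherwise decoding stops and that rank and all
#' deeper ranks are left unannotated. Emitted scores therefore lie in
#' (0.5, 1] and are non-increasing with depth.
#'
#' @param object A `trained_refiner`.
#' @param features A `feature_matrix` with the same column layout used in
#'   training.
#' @param batch_rows Number of contigs scored per forward pass.
#' @param ... Unused.
#' @return A `prediction_set`: data.frame with columns `contig_id`, `rank`,
#'   `label`, `path`, `score`, one row per emitted (contig, rank) label.
#' @export
predict.trained_refiner <- function(object, features, batch_rows = 8192, ...) {
  stopifnot(inherits(features, "feature_matrix"))
  if (ncol(features$values) != object$feature_dim)
    stop(sprintf("feature width %d does not match the model's %d",
                 ncol(features$values), object$feature_dim))
  tree <- object$tree
  n <- nrow(features$values)
  out <- vector("list", ceiling(n / batch_rows))
  for (bi in seq_along(out)) {
    idx <- ((bi - 1) * batch_rows + 1):min(bi * batch_rows, n)
    fwd <- nn_forward(object$params, t(features$values[idx, , drop = FALSE]),
                      object$config, training = FALSE)
    P <- softmax_rows(fwd$logits)
    Q <- as.matrix(P %*% tree$incidence)
    out[[bi]] <- decode_greedy(Q, tree, features$contig_ids[idx])
  }
  preds <- do.call(rbind, out)
  rownames(preds) <- NULL
  structure(preds, class = c("prediction_set", "data.frame"))
}

# Greedy thresholded top-down decoding of aggregated node likelihoods.
decode_greedy <- function(Q, tree, contig_ids, threshold = 0.5) {
  rows <- vector("list", nrow(Q))
  for (i in seq_len(nrow(Q))) {
    node <- 0L
    emitted_id <- integer(0)
    emitted_q <- numeric(0)
    repeat {
      ch <- tree$children[[as.character(node)]]
      if (length(ch) == 0) break
      q_ch <- Q[i, ch]
      best <- ch[which.max(q_ch)]       # ties: first in path order
      if (!(Q[i, best] > threshold)) break
      emitted_id <- c(emitted_id, best)
      emitted_q <- c(emitted_q, Q[i, best])
      node <- best
    }
    if (length(emitted_id) > 0)
      rows[[i]] <- data.frame(contig_id = contig_ids[i],
                              rank = TAX_RANKS[tree$nodes$rank[emitted_id]],
                              label = tree$nodes$name[emitted_id],
                              path = tree$nodes$path[emitted_id],
                              score = emitted_q,
                              stringsAsFactors = FALSE)
  }
  got <- !vapply(rows, is.null, logical(1))
  if (!any(got))
    return(data.frame(contig_id = character(0), rank = character(0),
                      label = character(0), path = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows[got])
}

#' Filter predictions by score threshold
#'
#' Drops every emitted label whose score is below `threshold`. Because scores
#' are non-increasing along each contig's rank path, the surviving ranks are
#' automatically a contiguous prefix.
#'
#' @param preds A `prediction_set`.
#' @param threshold Score threshold in `[0.5, 1]`; the published default for
#'   ground-truth comparison is 0.95.
#' @return The filtered `prediction_set`.
#' @export
filter_predictions <- function(preds, threshold) {
  stopifnot(threshold >= 0.5, threshold <= 1)
  out <- preds[preds$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("prediction_set", "data.frame"))
}

#' Write a prediction set as CSV
#'
#' Long format (`contig_id, rank, label, path, score`), plus optionally a
#' wide per-rank variant with one row per contig.
#' @param preds A `prediction_set`.
#' @param path Output CSV path.
#' @param wide Also write a `*_wide.csv` with one label column per rank.
#' @export
write_predictions <- function(preds, path, wide = FALSE) {
  data.table::fwrite(as.data.frame(preds), path)
  if (wide) {
    dt <- data.table::as.data.table(as.data.frame(preds))
    w <- data.table::dcast(dt, contig_id ~ factor(rank, levels = TAX_RANKS),
                           value.var = "label")
    data.table::fwrite(w, sub("\\.csv$", "_wide.csv", path))
  }
  invisible(path)
}
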