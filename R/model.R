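#' Model architecture specification
#'
#' Hyperparameters of the ontology-structured convolutional classifier. The
#' defaults are the published architecture: trigram embedding size 128 over a
#' vocabulary of 8000 trigrams plus padding index 0, a single 1D convolution
#' with 32 filters of size 128 (valid, stride 1), temporal max-pooling with
#' window 64 and stride 32 (so 26 windows x 32 filters = an 832-long flattened
#' feature vector), fusion with a 256-dimensional network embedding, a dense
#' ReLU layer of 1024 units with dropout, and one sigmoid classification
#' layer per selected term with recursive max-merge for internal terms.
#'
#' @param embedding_dim trigram embedding size.
#' @param vocab_size embedding rows including the padding index (8001).
#' @param seq_positions trigram positions per sequence (1000).
#' @param conv_filters,conv_kernel 1D convolution filters and kernel length.
#' @param pool_window,pool_stride temporal max-pooling geometry.
#' @param net_dim network-embedding dimension.
#' @param dense_units width of the shared fully connected layer.
#' @param variant `"deepgo"` (sequence + network, hierarchical),
#'   `"deepgoseq"` (sequence only, hierarchical) or `"deepgoflat"`
#'   (sequence + network, one flat sigmoid layer, no merge).
#' @param hierarchy_wiring `"shared-input"` (every class layer reads the
#'   shared dense features) or `"cascade"` (a class layer additionally reads
#'   its induced parents' activations).
#' @param dropout_rate dropout after the dense layer (training only).
#' @param class_layer_units width of each per-class layer; 1 means the layer
#'   is the sigmoid output neuron itself.
#' @return A `model_spec` list with a `shapes` element (embedded matrix,
#'   pooled/flattened length, fused feature length).
#' @export
model_spec <- function(embedding_dim = 128L, vocab_size = 8001L,
                       seq_positions = 1000L, conv_filters = 32L,
                       conv_kernel = 128L, pool_window = 64L,
                       pool_stride = 32L, net_dim = 256L,
                       dense_units = 1024L,
                       variant = c("deepgo", "deepgoseq", "deepgoflat"),
                       hierarchy_wiring = c("shared-input", "cascade"),
                       dropout_rate = 0.2, class_layer_units = 1L) {
  variant <- match.arg(variant)
  hierarchy_wiring <- match.arg(hierarchy_wiring)
  conv_len <- seq_positions - conv_kernel + 1L
  if (conv_len <= 0) stop("convolution output length is non-positive")
  pooled_windows <- (conv_len - pool_window) %/% pool_stride + 1L
  if (pooled_windows <= 0) stop("pooled output length is non-positive")
  flat <- conv_filters * pooled_windows
  use_net <- variant != "deepgoseq"
  spec <- list(embedding_dim = as.integer(embedding_dim),
               vocab_size = as.integer(vocab_size),
               seq_positions = as.integer(seq_positions),
               conv_filters = as.integer(conv_filters),
               conv_kernel = as.integer(conv_kernel),
               pool_window = as.integer(pool_window),
               pool_stride = as.integer(pool_stride),
               net_dim = as.integer(net_dim),
               dense_units = as.integer(dense_units),
               variant = variant, hierarchy_wiring = hierarchy_wiring,
               dropout_rate = dropout_rate,
               class_layer_units = as.integer(class_layer_units),
               shapes = list(embedded = c(seq_positions, embedding_dim),
                             conv_length = conv_len,
                             pooled_windows = pooled_windows,
                             flattened = flat,
                             fused = flat + if (use_net) net_dim else 0L))
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> variant ", x$variant, " (", x$hierarchy_wiring, ")\n",
      "  embedding ", x$shapes$embedded[1], " x ", x$shapes$embedded[2],
      ", conv ", x$conv_filters, " x ", x$conv_kernel,
      " -> pool ", x$pool_window, "/", x$pool_stride,
      " -> flattened ", x$shapes$flattened,
      " -> fused ", x$shapes$fused,
      " -> dense ", x$dense_units, "\n", sep = "")
  invisible(x)
}

#' Training configuration
#'
#' @param batch_size minibatch size (128).
#' @param learning_rate RMSprop learning rate (0.01).
#' @param rho,epsilon RMSprop decay and stabiliser.
#' @param validation_fraction fraction of the training samples held out for
#'   per-epoch validation; the weights of the best-validation-loss epoch are
#'   the ones retained.
#' @param max_epochs number of training epochs.
#' @param seed integer seed driving initialisation, shuffling, the
#'   train/validation split and dropout.
#' @param verbose print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 128L, learning_rate = 0.01,
                         rho = 0.9, epsilon = 1e-7,
                         validation_fraction = 0.2, max_epochs = 12L,
                         seed = 1L, verbose = FALSE) {
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 validation_fraction = validation_fraction,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# wiring passed to the C++ core: 1-based index lists over termset order
.model_wiring <- function(termset, dag) {
  terms <- termset$terms
  cl <- descendant_closure(dag, termset)
  pa <- induced_parents(dag, termset)
  topo_cf <- topological_order(dag, termset)        # children first
  list(closure = lapply(terms, function(t) unname(termset$index[cl[[t]]] + 1L)),
       parents = lapply(terms, function(t) unname(termset$index[pa[[t]]] + 1L)),
       topo_pf = unname(termset$index[rev(topo_cf)] + 1L))
}

.cxx_spec <- function(spec) {
  list(vocab_size = spec$vocab_size - 1L,   # trigram count, excl. padding row
       embedding_dim = spec$embedding_dim,
       seq_positions = spec$seq_positions,
       conv_filters = spec$conv_filters,
       conv_kernel = spec$conv_kernel,
       pool_window = spec$pool_window,
       pool_stride = spec$pool_stride,
       net_dim = spec$net_dim,
       dense_units = spec$dense_units,
       class_layer_units = spec$class_layer_units,
       use_net = spec$variant != "deepgoseq",
       use_merge = spec$variant != "deepgoflat",
       cascade = spec$hierarchy_wiring == "cascade",
       dropout_rate = spec$dropout_rate)
}

#' Build an untrained model over a selected term set
#'
#' Validates the shape arithmetic and freezes the ontology wiring (the
#' selected-descendant closure of every term, the induced parent lists and a
#' children-before-parents order) into the model object, so that prediction
#' and max-merging never need the ontology again.
#'
#' @param spec a `model_spec`.
#' @param termset a `term_set`.
#' @param dag the `ontology_dag` the term set was selected from.
#' @return An untrained `deepgo_model`.
#' @export
build_model <- function(spec, termset, dag) {
  stopifnot(inherits(spec, "model_spec"), inherits(termset, "term_set"))
  if (!length(termset$terms)) stop("empty term set")
  wiring <- .model_wiring(termset, dag)
  structure(list(spec = spec, termset = termset, wiring = wiring,
                 weights = NULL, history = NULL, config = NULL),
            class = "deepgo_model")
}

#' @export
print.deepgo_model <- function(x, ...) {
  cat("<deepgo_model> ", x$spec$variant, ", ", length(x$termset$terms),
      " terms (", length(x$termset$leaves), " leaves), ",
      if (is.null(x$weights)) "untrained" else
        paste0("trained ", nrow(x$history), " epochs (best ",
               which.min(x$history[, "val_loss"]), ")"),
      "\n", sep = "")
  invisible(x)
}

# instantiate the C++ network for a model, optionally loading stored weights
.model_net <- function(model, seed = 0L) {
  net <- .net_new(.cxx_spec(model$spec), model$wiring, as.integer(seed))
  if (!is.null(model$weights)) .net_set_weights(net, model$weights)
  net
}

.check_samples <- function(model, samples) {
  stopifnot(inherits(samples, "encoded_samples"))
  if (ncol(samples$indices) != model$spec$seq_positions)
    stop("sample index width ", ncol(samples$indices),
         " does not match seq_positions ", model$spec$seq_positions)
  if (!is.null(samples$labels) &&
      ncol(samples$labels) != length(model$termset$terms))
    stop("label width does not match the model's term set")
  if (model$spec$variant != "deepgoseq" &&
      ncol(samples$net) != model$spec$net_dim)
    stop("network-embedding dimension ", ncol(samples$net),
         " does not match net_dim ", model$spec$net_dim)
}

#' Train a model
#'
#' Minimises mean multi-output binary cross-entropy with RMSprop. The
#' samples are shuffled once under the configured seed and split into an
#' internal train/validation partition; per-epoch training and validation
#' losses are recorded and the weights of the best-validation epoch are
#' restored at the end. Dropout is active during training only. Gradients
#' flow through the max-merge layers, so the hierarchy participates in
#' optimisation.
#'
#' @param model an (untrained or trained) `deepgo_model`.
#' @param samples an `encoded_samples` object with labels.
#' @param config a `train_config`.
#' @return The trained `deepgo_model` with `weights`, `history` (matrix with
#'   columns train_loss / val_loss) and `best_epoch`.
#' @export
train_model <- function(model, samples, config = train_config()) {
  stopifnot(inherits(model, "deepgo_model"), inherits(config, "train_config"))
  .check_samples(model, samples)
  if (is.null(samples$labels)) stop("samples carry no labels")
  net <- .net_new(.cxx_spec(model$spec), model$wiring, config$seed)
  cfg <- list(max_epochs = config$max_epochs, batch_size = config$batch_size,
              learning_rate = config$learning_rate, rho = config$rho,
              epsilon = config$epsilon,
              validation_fraction = config$validation_fraction,
              seed = config$seed, verbose = config$verbose)
  hist <- .net_train(net, samples$indices, samples$net, samples$labels, cfg)
  colnames(hist) <- c("train_loss", "val_loss")
  model$weights <- .net_get_weights(net)
  model$history <- hist
  model$best_epoch <- which.min(hist[, "val_loss"])
  model$config <- config
  model
}

#' Predict term scores for encoded samples
#'
#' Runs the forward pass sample by sample (so batched and single-sample
#' execution are bit-identical) and, for hierarchical variants, applies the
#' recursive max-merge so that every ancestor scores at least as high as any
#' of its selected descendants.
#'
#' @param object a trained `deepgo_model`.
#' @param samples an `encoded_samples` object.
#' @param ... unused.
#' @return A `prediction_matrix` over the model's term set.
#' @export
predict.deepgo_model <- function(object, samples, ...) {
  if (is.null(object$weights)) stop("model is untrained")
  .check_samples(object, samples)
  net <- .model_net(object)
  raw <- .net_forward(net, samples$indices, samples$net)
  rownames(raw) <- samples$ids
  if (object$spec$variant != "deepgoflat")
    raw <- .merge_matrix(raw, object$wiring$closure)
  prediction_matrix(raw, object$termset$terms)
}

# closure-max merge of a score matrix given 1-based closure index lists
.merge_matrix <- function(m, closure) {
  out <- m
  for (j in seq_along(closure)) {
    cl <- closure[[j]]
    out[, j] <- if (length(cl) > 1L)
      do.call(pmax, lapply(cl, function(i) m[, i])) else m[, cl]
  }
  out
}

#' Max-merge raw class scores into hierarchically consistent scores
#'
#' In children-before-parents order, a term's merged score is the maximum of
#' its own raw score and the merged scores of its selected direct children;
#' equivalently, the maximum raw score over its selected-descendant closure
#' (itself included). Leaves pass through unchanged. The result is reported
#' in term-set index order.
#'
#' @param raw named numeric vector of raw sigmoid scores (names = term ids),
#'   or a matrix with one column per term in term-set order.
#' @param termset a `term_set`.
#' @param dag the `ontology_dag`.
#' @return Merged scores with the same shape as `raw`.
#' @export
merge_scores <- function(raw, termset, dag) {
  cl <- descendant_closure(dag, termset)
  if (is.matrix(raw)) {
    stopifnot(ncol(raw) == length(termset$terms))
    idx <- lapply(termset$terms, function(t) unname(termset$index[cl[[t]]] + 1L))
    return(.merge_matrix(raw, idx))
  }
  stopifnot(all(termset$terms %in% names(raw)))
  out <- raw[termset$terms]
  for (t in termset$terms) out[t] <- max(raw[cl[[t]]])
  out
}

#' Find ancestor-descendant score inversions
#'
#' Flags every (protein, ancestor, descendant) triple where a selected
#' descendant outscores its ancestor — impossible for merged hierarchical
#' predictions, but expected for the flat variant.
#'
#' @param pred a `prediction_matrix`.
#' @param termset a `term_set`.
#' @param dag the `ontology_dag`.
#' @param tol numeric slack.
#' @return data.frame with columns protein, ancestor, descendant,
#'   ancestor_score, descendant_score (zero rows if consistent).
#' @export
check_hierarchy <- function(pred, termset, dag, tol = 0) {
  cl <- descendant_closure(dag, termset)
  rows <- list()
  for (a in termset$terms) {
    for (d in setdiff(cl[[a]], a)) {
      bad <- which(pred$scores[, d] > pred$scores[, a] + tol)
      if (length(bad))
        rows[[length(rows) + 1L]] <- data.frame(
          protein = pred$ids[bad], ancestor = a, descendant = d,
          ancestor_score = pred$scores[bad, a],
          descendant_score = pred$scores[bad, d])
    }
  }
  if (!length(rows)) return(data.frame(protein = character(0),
                                       ancestor = character(0),
                                       descendant = character(0),
                                       ancestor_score = numeric(0),
                                       descendant_score = numeric(0)))
  do.call(rbind, rows)
}

#' Bundle encoded inputs for training or prediction
#'
#' @param seqs named character vector of validated sequences.
#' @param termset a `term_set`; `NULL` for unlabelled samples.
#' @param annotations propagated annotations (named list); `NULL` for
#'   unlabelled samples.
#' @param embeddings an `embedding_table` or `NULL` (zero vectors).
#' @param net_dim embedding dimension used when `embeddings` is `NULL`.
#' @param seq_positions encoded index length.
#' @return An `encoded_samples` object: list with `ids`, `indices` (n x
#'   1000 integer), `net` (n x net_dim numeric) and `labels` (n x |terms|
#'   integer or `NULL`).
#' @export
encode_dataset <- function(seqs, termset = NULL, annotations = NULL,
                           embeddings = NULL, net_dim = 256L,
                           seq_positions = SEQ_POSITIONS) {
  ids <- names(seqs)
  idx <- encode_sequences(seqs, positions = seq_positions)
  net <- if (is.null(embeddings)) {
    matrix(0, nrow = length(ids), ncol = net_dim, dimnames = list(ids, NULL))
  } else embedding_vectors(embeddings, ids)
  labels <- NULL
  if (!is.null(termset) && !is.null(annotations)) {
    labels <- t(vapply(ids, function(p) encode_labels(annotations[[p]], termset),
                       integer(length(termset$terms))))
    rownames(labels) <- ids
  }
  structure(list(ids = ids, indices = idx, net = net, labels = labels),
            class = "encoded_samples")
}

#' @export
print.encoded_samples <- function(x, ...) {
  cat("<encoded_samples> ", length(x$ids), " proteins, ",
      ncol(x$indices), " index positions, net dim ", ncol(x$net),
      if (!is.null(x$labels)) paste0(", ", ncol(x$labels), " labels"),
      "\n", sep = "")
  invisible(x)
}

#' Subset encoded samples by protein id
#'
#' @param samples an `encoded_samples` object.
#' @param ids protein ids to keep (in this order).
#' @return An `encoded_samples` object.
#' @export
subset_samples <- function(samples, ids) {
  stopifnot(all(ids %in% samples$ids))
  i <- match(ids, samples$ids)
  structure(list(ids = ids,
                 indices = samples$indices[i, , drop = FALSE],
                 net = samples$net[i, , drop = FALSE],
                 labels = if (!is.null(samples$labels))
                   samples$labels[i, , drop = FALSE]),
            class = "encoded_samples")
}

#' Persist / load a trained model
#'
#' The single-file container embeds the architecture spec, the term set and
#' the frozen ontology wiring, so a loaded model predicts without re-parsing
#' any ontology.
#'
#' @param model a `deepgo_model`.
#' @param path file path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deepgo_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "deepgo_model")) stop("not a saved model: ", path)
  model
}
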