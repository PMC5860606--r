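#' Run configuration for the pipeline commands
#'
#' Reads a YAML configuration and applies flag-style overrides (overrides
#' win). Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file, or `NULL` to start from defaults.
#' @param ... overrides of individual keys.
#' @return A `run_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    ontology = NULL, sequences = NULL, annotations = NULL, embeddings = NULL,
    queries = NULL,
    out_dir = ".", branch = "BP", top_k = 1000L, min_count = 1L,
    evidence = EXPERIMENTAL_EVIDENCE,
    variant = "deepgo", hierarchy_wiring = "shared-input",
    dropout_rate = 0.2, class_layer_units = 1L,
    batch_size = 128L, learning_rate = 0.01, validation_fraction = 0.2,
    max_epochs = 12L, report_threshold = 0.0, identity_threshold = 50,
    train_fraction = 0.8, seed = 1L)
  cfg <- defaults
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    bad <- setdiff(names(y), names(defaults))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(y)] <- y
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(defaults))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "run_config")
}

.cfg_hash <- function(cfg) {
  s <- paste(vapply(cfg[order(names(cfg))], function(v)
    paste(format(v), collapse = ","), ""), collapse = ";")
  # small deterministic FNV-style hash; enough to fingerprint a manifest
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

.write_manifest <- function(cfg, counts, path) {
  jsonlite::write_json(list(config_hash = .cfg_hash(cfg), seed = cfg$seed,
                            counts = counts),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Prepare an encoded dataset from ontology, sequences and annotations
#'
#' Applies, in order: evidence-code filtering, sequence validation (length
#' and alphabet), alt-id rewriting and annotation propagation, the
#' at-least-one-selected-term filter, term selection and trigram encoding.
#' Writes the term set, the encoded dataset (id + 1000 indices), the label
#' matrix and a manifest with per-filter attrition counts.
#'
#' @param cfg a `run_config` with `ontology`, `sequences`, `annotations` and
#'   `out_dir` set.
#' @return Invisibly, a list with the in-memory artefacts (`dag`, `termset`,
#'   `samples`, `annotations`, `counts`).
#' @export
cmd_prepare <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dag <- parse_obo(cfg$ontology)
  seqs <- read_fasta(cfg$sequences)
  ann <- read_annotations(cfg$annotations, evidence = cfg$evidence)

  counts <- list(input_proteins = length(seqs),
                 annotated_after_evidence_filter = length(ann))
  val <- validate_proteins(seqs)
  counts$dropped_by_validation <- nrow(val$dropped)
  counts$validation_reasons <- as.list(table(val$dropped$reason))
  keep <- intersect(names(val$records), names(ann))
  counts$validated_and_annotated <- length(keep)
  if (!length(keep))
    stop("zero proteins survive filtering; attrition: ",
         jsonlite::toJSON(counts, auto_unbox = TRUE))
  ann <- propagate_annotations(dag, ann[keep], lenient = TRUE)
  termset <- select_terms(dag, ann, branch = cfg$branch,
                          top_k = cfg$top_k, min_count = cfg$min_count)
  has_sel <- vapply(ann, function(ts) any(ts %in% termset$terms), TRUE)
  counts$with_selected_term <- sum(has_sel)
  if (!any(has_sel)) stop("no protein is annotated with a selected term")
  keep <- names(ann)[has_sel]

  emb <- if (!is.null(cfg$embeddings)) load_embeddings(cfg$embeddings) else NULL
  samples <- encode_dataset(val$records[keep], termset, ann[keep], emb)
  counts$encoded <- length(samples$ids)

  utils::write.table(
    data.frame(term = termset$terms, index = termset$index[termset$terms],
               leaf = termset$terms %in% termset$leaves,
               count = if (is.null(termset$counts)) NA else
                 as.integer(termset$counts)),
    file.path(cfg$out_dir, "termset.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(id = samples$ids, samples$indices),
                     file.path(cfg$out_dir, "dataset.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(id = samples$ids, samples$labels),
                     file.path(cfg$out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  .write_manifest(cfg, counts, file.path(cfg$out_dir, "manifest.json"))
  invisible(list(dag = dag, termset = termset, samples = samples,
                 annotations = ann[keep], counts = counts))
}

#' Train a model on a prepared dataset
#'
#' @param cfg a `run_config`.
#' @param prepared the list returned by [cmd_prepare()]; if `NULL` it is
#'   recomputed from the config paths.
#' @return Invisibly, the trained `deepgo_model` (also written to
#'   `out_dir/model_<branch>.rds` with its history).
#' @export
cmd_train <- function(cfg, prepared = NULL) {
  if (is.null(prepared)) prepared <- cmd_prepare(cfg)
  spec <- model_spec(variant = cfg$variant,
                     hierarchy_wiring = cfg$hierarchy_wiring,
                     dropout_rate = cfg$dropout_rate,
                     class_layer_units = cfg$class_layer_units)
  model <- build_model(spec, prepared$termset, prepared$dag)
  tc <- train_config(batch_size = cfg$batch_size,
                     learning_rate = cfg$learning_rate,
                     validation_fraction = cfg$validation_fraction,
                     max_epochs = cfg$max_epochs, seed = cfg$seed)
  model <- train_model(model, prepared$samples, tc)
  save_model(model, file.path(cfg$out_dir, paste0("model_", cfg$branch, ".rds")))
  utils::write.table(model$history,
                     file.path(cfg$out_dir, paste0("history_", cfg$branch, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(model)
}

#' Predict annotations for a FASTA file with a trained model
#'
#' @param cfg a `run_config` (`sequences`, optional `embeddings`, `out_dir`).
#' @param model a `deepgo_model`, or `NULL` to load
#'   `out_dir/model_<branch>.rds`.
#' @return Invisibly, the `prediction_matrix` (also written as a TSV of
#'   protein / term / score rows at or above `report_threshold`).
#' @export
cmd_predict <- function(cfg, model = NULL) {
  if (is.null(model))
    model <- load_model(file.path(cfg$out_dir, paste0("model_", cfg$branch, ".rds")))
  seqs <- read_fasta(cfg$sequences)
  val <- validate_proteins(seqs)
  emb <- if (!is.null(cfg$embeddings)) load_embeddings(cfg$embeddings) else NULL
  samples <- encode_dataset(val$records, embeddings = emb,
                            net_dim = model$spec$net_dim)
  pred <- predict(model, samples)
  write_predictions(pred, file.path(cfg$out_dir, "predictions.tsv"),
                    min_score = cfg$report_threshold)
  invisible(pred)
}

#' Evaluate a prediction TSV against truth annotations
#'
#' Prints the protein-centric metric row (Fmax, AvgPr, AvgRc at the
#' maximising threshold, global AUC, MCC) and writes it as TSV.
#'
#' @param cfg a `run_config` (`annotations` = truth, `ontology`, `out_dir`).
#' @param pred a `prediction_matrix`, or `NULL` to read
#'   `out_dir/predictions.tsv`.
#' @param grouping optional named character vector protein -> group.
#' @return Invisibly, the `evaluation_report` (or a list of per-group
#'   reports).
#' @export
cmd_evaluate <- function(cfg, pred = NULL, grouping = NULL) {
  if (is.null(pred))
    pred <- read_predictions(file.path(cfg$out_dir, "predictions.tsv"))
  dag <- parse_obo(cfg$ontology)
  truth <- propagate_annotations(
    dag, read_annotations(cfg$annotations, evidence = cfg$evidence),
    lenient = TRUE)
  rep <- evaluate_predictions(pred, truth)
  print(rep)
  utils::write.table(
    data.frame(branch = cfg$branch, fmax = rep$fmax, avgpr = rep$avgpr,
               avgrc = rep$avgrc, auc = rep$auc, mcc = rep$mcc,
               t_max = rep$t_max, n = rep$n),
    file.path(cfg$out_dir, "evaluation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  out <- rep
  if (!is.null(grouping))
    out <- list(overall = rep,
                groups = evaluate_grouped(pred, truth, grouping))
  invisible(out)
}

#' Run the best-hit annotation-transfer baseline
#'
#' @param cfg a `run_config` (used for `out_dir`).
#' @param queries named character vector of query sequences.
#' @param train_seqs named character vector of annotated training sequences.
#' @param train_ann propagated training annotations.
#' @param termset a `term_set` (prediction universe).
#' @param backend alignment backend.
#' @return Invisibly, the baseline `prediction_matrix` (written to
#'   `out_dir/baseline_predictions.tsv`).
#' @export
cmd_baseline <- function(cfg, queries, train_seqs, train_ann, termset,
                         backend = sw_backend()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pred <- baseline_predictions(queries, train_seqs, train_ann, termset, backend)
  write_predictions(pred, file.path(cfg$out_dir, "baseline_predictions.tsv"),
                    min_score = 1)
  invisible(pred)
}

#' Split sequences into homology-reduced train/test id lists
#'
#' @param cfg a `run_config` (`sequences`, `identity_threshold`,
#'   `train_fraction`, `out_dir`).
#' @param backend alignment backend.
#' @return Invisibly, the `identity_split`; id lists are written to
#'   `out_dir/train_ids.txt` and `out_dir/test_ids.txt`.
#' @export
cmd_split <- function(cfg, backend = sw_backend()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- read_fasta(cfg$sequences)
  sp <- identity_split(seqs, threshold = cfg$identity_threshold,
                       train_fraction = cfg$train_fraction, backend = backend)
  writeLines(sp$train, file.path(cfg$out_dir, "train_ids.txt"))
  writeLines(sp$test, file.path(cfg$out_dir, "test_ids.txt"))
  invisible(sp)
}

#' Write a complete synthetic dataset in standard formats
#'
#' Generates the toy ontology, motif-planted proteins and class-correlated
#' embeddings and writes them as OBO, FASTA, annotation TSV and embedding
#' TSV under `out_dir`, so the synthetic fixtures double as format
#' round-trip tests for the whole pipeline.
#'
#' @param cfg a `run_config` (`seed`, `out_dir`).
#' @param spec optional `synthetic_spec` (defaults to the standard one with
#'   the config seed).
#' @return Invisibly, the dataset list from [make_synthetic_dataset()].
#' @export
cmd_synth <- function(cfg, spec = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) spec <- synthetic_spec(seed = cfg$seed)
  ds <- make_synthetic_dataset(spec)
  write_obo(ds$dag, file.path(cfg$out_dir, "ontology.obo"))
  write_fasta(ds$proteins, file.path(cfg$out_dir, "proteins.fasta"))
  # written annotations are the asserted (leaf) terms; propagation is
  # recomputed downstream from the ontology
  leaves <- dag_leaves(ds$dag)
  asserted <- lapply(ds$annotations, intersect, x = leaves)
  write_annotations(asserted[lengths(asserted) > 0],
                    file.path(cfg$out_dir, "annotations.tsv"))
  write_embeddings(ds$embeddings, file.path(cfg$out_dir, "embeddings.tsv"))
  invisible(ds)
}
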