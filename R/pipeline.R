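#' End-to-end pipeline: split, normalize, align, train, evaluate
#'
#' Applies the standard experimental protocol: stratified 80/20 development/
#' test split (development further split 80/20 into training/validation),
#' per-gene standardization with training-set statistics, alignment of the
#' expression columns to the pathway mask, model initialization and training,
#' and test-set evaluation.
#'
#' @param dataset a `spin_dataset` (raw expression).
#' @param mask a `pathway_mask` (e.g. from [build_mask()] or the simulator).
#' @param config a `spin_config` whose task matches the dataset.
#' @param split_seed seed for the stratified split (defaults to the
#'   configuration seed).
#' @return list with `model`, `report`, `metrics` (test-set), `splits`
#'   (aligned, normalized train/validation/test datasets), `normalizer`.
#' @export
spin_pipeline <- function(dataset, mask, config, split_seed = NULL) {
  splits <- stratified_split(dataset, seed = split_seed %||% config$seed)
  normalizer <- fit_normalizer(splits$train$expression)
  sets <- lapply(splits[c("train", "validation", "test")], function(d)
    apply_normalizer(normalizer, d))
  if (!all(mask$gene_ids %in% colnames(sets$train$expression))) {
    keep <- mask$gene_ids %in% colnames(sets$train$expression)
    mask$matrix <- mask$matrix[keep, , drop = FALSE]
    mask$gene_ids <- mask$gene_ids[keep]
  }
  sets <- lapply(sets, align_dataset, mask = mask)
  model <- spin_model(mask, config)
  fit <- spin_train(model, sets$train, sets$validation)
  metrics <- evaluate_model(fit$model, sets$test)
  list(model = fit$model, report = fit$report, metrics = metrics,
       splits = sets, normalizer = normalizer, indices = splits$indices)
}
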