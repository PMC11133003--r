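#' Model configuration
#'
#' @param task `"survival"` (Cox prognostic-index head, no output bias) or
#'   `"risk"` (sigmoid posterior-probability head).
#' @param hidden_sizes integer vector of hidden-layer widths after the
#'   pathway layer; default a single hidden layer of 8 nodes.
#' @param activation elementwise nonlinearity; only `"relu"` is implemented.
#' @param seed integer seed controlling weight initialization.
#' @param sex_specific logical; `TRUE` gives the sex-routed pathway layer
#'   (separate male/female gene-to-pathway weights). `FALSE` is the
#'   sex-combined ablation: one shared pathway layer for all samples.
#' @param learning_rate,max_epochs,patience,l2 optimizer settings used by
#'   [spin_train()]: Adam step size, epoch cap, early-stopping patience on
#'   validation loss, and L2 weight penalty.
#' @param n_restarts independent random initializations trained by
#'   [spin_train()]; the restart with the lowest validation loss is kept.
#' @param sparsity_grid candidate pruning fractions for the hidden-layer
#'   masks, selected on validation loss by [sparse_code_masks()].
#' @param finetune_epochs brief re-training budget after pruning.
#' @return an object of class `spin_config`.
#' @export
spin_config <- function(task = c("survival", "risk"), hidden_sizes = 8L,
                        activation = "relu", seed = 1L, sex_specific = TRUE,
                        learning_rate = 0.003, max_epochs = 500L,
                        patience = 60L, l2 = 0.05, n_restarts = 3L,
                        sparsity_grid = c(0, 0.2, 0.4, 0.6, 0.8),
                        finetune_epochs = 60L) {
  task <- match.arg(task)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) == 0 || any(hidden_sizes < 1))
    stopf("hidden_sizes must be a non-empty vector of positive integers")
  if (!identical(activation, "relu"))
    stopf("only the 'relu' activation is implemented")
  structure(list(task = task, hidden_sizes = hidden_sizes,
                 activation = activation, seed = as.integer(seed),
                 sex_specific = isTRUE(sex_specific),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), l2 = l2,
                 n_restarts = as.integer(n_restarts),
                 sparsity_grid = sparsity_grid,
                 finetune_epochs = as.integer(finetune_epochs)),
            class = "spin_config")
}

# uniform init scaled by the masked fan-in of each target node
init_masked <- function(nr, nc, mask = NULL) {
  fan <- if (is.null(mask)) rep(nr, nc) else pmax(colSums(mask), 1)
  lim <- rep(sqrt(6 / fan), each = nr)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# pathway-enrichment initialization of the gene-to-pathway weights: each
# pathway node starts as the scaled mean of its member genes (weight
# 1/sqrt(m_j) per member, jittered), so nodes begin as pathway scores and
# training fine-tunes gene loadings from there
init_pathway_mean <- function(mask, jitter = 0.1) {
  scl <- sweep(mask, 2, sqrt(pmax(colSums(mask), 1)), `/`)
  scl * (1 + matrix(stats::runif(length(mask), -jitter, jitter),
                    nrow(mask), ncol(mask)))
}

#' Initialize a sex-routed pathway-masked model
#'
#' Builds the four-layer architecture: gene layer -> sex-specific masked
#' pathway layers (weights `W_G` per sex, shared gene-pathway mask `M_G`) ->
#' hidden layers with prunable masks (shared across sexes) -> output head.
#' Weights use uniform initialization scaled by each node's masked fan-in;
#' hidden masks start dense (all ones) and are sparsified during training.
#'
#' @param mask a `pathway_mask` (the gene-pathway bi-adjacency matrix).
#' @param config a `spin_config`.
#' @return an object of class `spin_model`.
#' @export
spin_model <- function(mask, config) {
  stopifnot(inherits(mask, "pathway_mask"), inherits(config, "spin_config"))
  q <- length(mask$gene_ids); r <- length(mask$pathway_ids)
  sizes <- c(r, config$hidden_sizes)
  with_seed(config$seed, {
    model <- list(
      config = config, mask = mask,
      W_G_male = init_pathway_mean(mask$matrix),
      W_G_female = init_pathway_mean(mask$matrix),
      # unit bias keeps the ReLU mostly linear around the initial pathway
      # scores (standardized inputs give the scores unit variance)
      b_G_male = rep(1, r), b_G_female = rep(1, r),
      hidden = lapply(seq_along(config$hidden_sizes), function(l) {
        list(W = init_masked(sizes[l], sizes[l + 1]),
             M = matrix(1, sizes[l], sizes[l + 1]),
             b = rep(0, sizes[l + 1]))
      }),
      W_H = init_masked(sizes[length(sizes)], 1L),
      b_H = if (config$task == "risk") 0 else NULL)
    if (!config$sex_specific) {
      model$W_G_female <- model$W_G_male
      model$b_G_female <- model$b_G_male
    }
    structure(model, class = "spin_model")
  })
}

#' @export
print.spin_model <- function(x, ...) {
  cat(sprintf(
    "spin_model (%s%s): %d genes -> %d pathways -> [%s] hidden -> 1\n",
    x$config$task, if (x$config$sex_specific) ", sex-routed" else ", sex-combined",
    length(x$mask$gene_ids), length(x$mask$pathway_ids),
    paste(x$config$hidden_sizes, collapse = ", ")))
  invisible(x)
}

relu <- function(x) pmax(x, 0)

#' Effective (masked) weights of every masked layer
#'
#' Returns the elementwise product `W * M` for the male and female
#' gene-to-pathway layers and each hidden layer; these are the weights the
#' forward pass actually applies.
#'
#' @param model a `spin_model`.
#' @return named list of matrices: `W_G_male`, `W_G_female`, then
#'   `hidden1`, `hidden2`, ...
#' @export
masked_effective_weights <- function(model) {
  out <- list(W_G_male = model$W_G_male * model$mask$matrix,
              W_G_female = model$W_G_female * model$mask$matrix)
  for (l in seq_along(model$hidden))
    out[[paste0("hidden", l)]] <- model$hidden[[l]]$W * model$hidden[[l]]$M
  out
}

route_labels <- function(n, sex, route_as) {
  if (!is.null(route_as)) {
    route_as <- match.arg(route_as, c("male", "female"))
    rep(route_as, n)
  } else check_sex(sex)
}

#' Forward pass
#'
#' Routes each sample through its sex's gene-to-pathway weights (or through
#' the branch named by `route_as` — the cross-sex counterfactual, which never
#' alters stored parameters), then through the shared hidden layers to the
#' output head: a prognostic index for the survival task (no output bias) or
#' a sigmoid risk score in (0, 1) for the risk task.
#'
#' @param model a `spin_model`.
#' @param expression numeric matrix (samples x genes) aligned to
#'   `model$mask$gene_ids`.
#' @param sex sex label per row (ignored when `route_as` is given).
#' @param route_as optional `"male"` or `"female"`: force every row through
#'   that branch.
#' @return an object of class `spin_trace`: list with `pathway` (n x r node
#'   values), `hidden` (list of n x s matrices), `output` (length-n vector)
#'   and `routed_sex`.
#' @export
spin_forward <- function(model, expression, sex = NULL, route_as = NULL) {
  expression <- as.matrix(expression)
  q <- length(model$mask$gene_ids)
  if (ncol(expression) != q)
    stopf("expression has %d columns; model expects %d genes",
          ncol(expression), q)
  n <- nrow(expression)
  if (is.null(route_as) && is.null(sex))
    stopf("supply `sex` labels or a `route_as` override")
  routing <- route_labels(n, sex, route_as)
  if (!model$config$sex_specific) routing <- rep("male", n)

  P <- matrix(0, n, length(model$mask$pathway_ids),
              dimnames = list(rownames(expression), model$mask$pathway_ids))
  for (s in c("male", "female")) {
    rows <- which(routing == s)
    if (length(rows) == 0) next
    Wg <- (if (s == "male") model$W_G_male else model$W_G_female) *
      model$mask$matrix
    bg <- if (s == "male") model$b_G_male else model$b_G_female
    P[rows, ] <- relu(sweep(expression[rows, , drop = FALSE] %*% Wg, 2, bg, `+`))
  }
  hidden <- vector("list", length(model$hidden))
  A <- P
  for (l in seq_along(model$hidden)) {
    h <- model$hidden[[l]]
    A <- relu(sweep(A %*% (h$W * h$M), 2, h$b, `+`))
    hidden[[l]] <- A
  }
  z <- drop(A %*% model$W_H)
  if (model$config$task == "risk") z <- stats::plogis(z + model$b_H)
  structure(list(pathway = P, hidden = hidden, output = z,
                 routed_sex = if (is.null(route_as)) routing
                              else rep(route_as, n)),
            class = "spin_trace")
}

#' Predict from a spin_model
#'
#' @param object a `spin_model`.
#' @param dataset a `spin_dataset` aligned to the model's genes.
#' @param route_as optional counterfactual routing.
#' @param ... unused.
#' @return numeric vector: prognostic index (survival) or risk score (risk).
#' @export
predict.spin_model <- function(object, dataset, route_as = NULL, ...) {
  spin_forward(object, dataset$expression, dataset$sex, route_as)$output
}

#' Export pathway-layer activations
#'
#' Writes the n x r table of sex-routed pathway node values together with
#' sample identifiers, sex and outcome columns, for downstream embedding or
#' visualization. Values are written with 17 significant digits so a
#' round-trip read reproduces them bit-identically.
#'
#' @param model a trained `spin_model`.
#' @param dataset a `spin_dataset` aligned to the model.
#' @param path output TSV path.
#' @return (invisibly) the data.frame written.
#' @export
export_pathway_activations <- function(model, dataset, path) {
  trace <- spin_forward(model, dataset$expression, dataset$sex)
  meta <- data.frame(sample_id = dataset$sample_ids, sex = dataset$sex,
                     stringsAsFactors = FALSE)
  if (dataset$task == "survival") {
    meta$time <- format_full(dataset$time); meta$event <- dataset$event
  } else meta$label <- dataset$label
  act <- as.data.frame(apply(trace$pathway, 2, format_full),
                       stringsAsFactors = FALSE)
  if (nrow(trace$pathway) == 1) act <- as.data.frame(t(act))
  colnames(act) <- model$mask$pathway_ids
  df <- cbind(meta, act)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# ---- checkpoint (plain-text JSON) ----

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON archive holding all weights, biases,
#' masks, the configuration and the gene/pathway identifier lists, plus a
#' format version string.
#'
#' @param model a `spin_model`.
#' @param path checkpoint path (JSON).
#' @return `save_spin_model` returns `path` invisibly; `load_spin_model`
#'   returns the restored `spin_model`.
#' @export
save_spin_model <- function(model, path) {
  payload <- list(
    format = "spinr-checkpoint-1",
    config = unclass(model$config),
    gene_ids = model$mask$gene_ids,
    pathway_ids = model$mask$pathway_ids,
    mask = model$mask$matrix,
    W_G_male = model$W_G_male, W_G_female = model$W_G_female,
    b_G_male = model$b_G_male, b_G_female = model$b_G_female,
    hidden = lapply(model$hidden, function(h)
      list(W = h$W, M = h$M, b = h$b)),
    W_H = model$W_H, b_H = model$b_H)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_spin_model
#' @export
load_spin_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "spinr-checkpoint-1"))
    stopf("unrecognized checkpoint format: %s", p$format %||% "<missing>")
  cfg <- do.call(spin_config, p$config[setdiff(names(p$config), NULL)])
  mask <- structure(list(
    matrix = matrix(as.numeric(p$mask), length(p$gene_ids),
                    length(p$pathway_ids),
                    dimnames = list(p$gene_ids, p$pathway_ids)),
    gene_ids = p$gene_ids, pathway_ids = p$pathway_ids),
    class = "pathway_mask")
  as_mat <- function(x) {
    x <- as.matrix(x); dimnames(x) <- NULL; storage.mode(x) <- "double"; x
  }
  model <- list(
    config = cfg, mask = mask,
    W_G_male = as_mat(p$W_G_male), W_G_female = as_mat(p$W_G_female),
    b_G_male = as.numeric(p$b_G_male), b_G_female = as.numeric(p$b_G_female),
    hidden = lapply(seq_len(nrow_or_len(p$hidden)), function(l) {
      h <- extract_hidden(p$hidden, l)
      list(W = as_mat(h$W), M = as_mat(h$M), b = as.numeric(h$b))
    }),
    W_H = as_mat(p$W_H),
    b_H = if (is.null(p$b_H)) NULL else as.numeric(p$b_H))
  structure(model, class = "spin_model")
}

# jsonlite may simplify a list of layer records to a data.frame
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
extract_hidden <- function(x, l) {
  if (is.data.frame(x)) list(W = x$W[[l]], M = x$M[[l]], b = x$b[[l]])
  else x[[l]]
}
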