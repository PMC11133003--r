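#' Construct an expression dataset with sex labels and outcome
#'
#' Bundles a samples x genes expression matrix with per-sample sex labels and
#' either a survival outcome (`time`, `event`) or a binary disease `label`.
#'
#' @param expression numeric matrix, samples in rows, genes in columns; row
#'   names are sample identifiers, column names gene identifiers (or supply
#'   `sample_ids` / `gene_ids`).
#' @param sex character vector, `"male"` or `"female"` per sample.
#' @param time,event survival outcome: positive times and 0/1 event
#'   indicators (survival task).
#' @param label 0/1 disease labels (binary risk task).
#' @param sample_ids,gene_ids optional identifier vectors overriding dimnames.
#' @return an object of class `spin_dataset` with a `task` field
#'   (`"survival"` or `"risk"`).
#' @export
spin_dataset <- function(expression, sex, time = NULL, event = NULL,
                         label = NULL, sample_ids = NULL, gene_ids = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  sample_ids <- sample_ids %||% rownames(expression) %||% paste0("S", seq_len(n))
  gene_ids <- gene_ids %||% colnames(expression) %||%
    paste0("G", seq_len(ncol(expression)))
  dimnames(expression) <- list(sample_ids, gene_ids)
  if (anyNA(expression)) stopf("expression contains missing values")
  sex <- check_sex(sex)
  if (length(sex) != n) stopf("`sex` must have one label per sample")
  has_surv <- !is.null(time) && !is.null(event)
  has_bin <- !is.null(label)
  if (has_surv == has_bin)
    stopf("supply exactly one outcome: (time, event) or label")
  if (has_surv) {
    time <- as.numeric(time); event <- as.numeric(event)
    if (length(time) != n || length(event) != n)
      stopf("outcome length must equal sample count")
    if (any(time <= 0)) stopf("survival times must be positive")
    if (!all(event %in% c(0, 1))) stopf("event indicators must be 0/1")
    task <- "survival"
  } else {
    label <- as.numeric(label)
    if (length(label) != n) stopf("outcome length must equal sample count")
    if (!all(label %in% c(0, 1))) stopf("labels must be 0/1")
    task <- "risk"
  }
  structure(list(expression = expression, sex = sex, time = time,
                 event = event, label = label, sample_ids = sample_ids,
                 gene_ids = gene_ids, task = task),
            class = "spin_dataset")
}

#' @export
print.spin_dataset <- function(x, ...) {
  out <- if (x$task == "survival")
    sprintf("%d events, %.0f%% censored", sum(x$event),
            100 * mean(1 - x$event))
  else sprintf("%d cases / %d controls", sum(x$label), sum(1 - x$label))
  cat(sprintf("spin_dataset (%s): %d samples (%d male, %d female) x %d genes; %s\n",
              x$task, length(x$sample_ids), sum(x$sex == "male"),
              sum(x$sex == "female"), length(x$gene_ids), out))
  invisible(x)
}

#' Subset a spin_dataset by sample index
#' @param dataset a `spin_dataset`.
#' @param idx integer or logical index over samples.
#' @return the subsetted `spin_dataset`.
#' @export
subset_samples <- function(dataset, idx) {
  dataset$expression <- dataset$expression[idx, , drop = FALSE]
  dataset$sex <- dataset$sex[idx]
  dataset$sample_ids <- dataset$sample_ids[idx]
  for (f in c("time", "event", "label"))
    if (!is.null(dataset[[f]])) dataset[[f]] <- dataset[[f]][idx]
  dataset
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of gene identifiers and a first column of sample
#' identifiers; the delimiter is inferred from the file extension
#' (`.csv` gives comma, anything else tab).
#'
#' @param path file path.
#' @return numeric matrix, samples x genes.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read a clinical table from delimited text
#'
#' Columns: `sample_id`, `sex`, and either `time` + `event` or `label`.
#'
#' @param path file path.
#' @return a data.frame with one row per sample.
#' @export
read_clinical <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex")
  if (!all(need %in% names(df)))
    stopf("clinical table must contain columns: %s", paste(need, collapse = ", "))
  if (!(("time" %in% names(df) && "event" %in% names(df)) ||
        "label" %in% names(df)))
    stopf("clinical table must contain either time+event or label")
  df
}

#' Assemble a spin_dataset from expression and clinical files
#'
#' @param expression_path,clinical_path paths accepted by
#'   [read_expression()] / [read_clinical()].
#' @return a `spin_dataset`; samples are matched by identifier and must agree.
#' @export
load_dataset <- function(expression_path, clinical_path) {
  x <- read_expression(expression_path)
  clin <- read_clinical(clinical_path)
  missing <- setdiff(rownames(x), clin$sample_id)
  if (length(missing) > 0)
    stopf("samples without clinical rows: %s", paste(missing, collapse = ", "))
  clin <- clin[match(rownames(x), clin$sample_id), ]
  if ("time" %in% names(clin) && !all(is.na(clin$time)))
    spin_dataset(x, clin$sex, time = clin$time, event = clin$event)
  else
    spin_dataset(x, clin$sex, label = clin$label)
}
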