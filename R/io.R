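# CSV interchange in the public fetal-health dialect (21 numeric feature
# columns + a trailing fetal_health label column coded 1.0/2.0/3.0) and
# versioned JSON model checkpoints.

MODEL_FORMAT <- "it2fnn-model"
MODEL_VERSION <- 1L

#' Read a dataset CSV
#'
#' Expects a header row, numeric feature columns and a label column (named
#' `fetal_health` if present, otherwise the last column) with class codes
#' `{1, 2, 3, ...}` (decimal forms such as `"2.0"` are accepted). Empty cells
#' become missing-mask entries.
#'
#' @param path Path to a CSV file.
#' @return An `fh_dataset` with `X`, `y`, `feature_names` and a
#'   `missing_mask` when any cell is empty.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("schema error: need features and a label column",
                         call. = FALSE)
  label_col <- if ("fetal_health" %in% names(df)) "fetal_health" else names(df)[ncol(df)]
  for (j in names(df)) {
    if (!is.numeric(df[[j]])) {
      v <- df[[j]]
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) {
        stop(sprintf("parse error: non-numeric cell at row %d, column '%s'",
                     bad[1], j), call. = FALSE)
      }
      df[[j]] <- num
    }
  }
  y <- df[[label_col]]
  if (anyNA(y) || any(y != round(y))) {
    stop("schema error: label column must hold integral class codes",
         call. = FALSE)
  }
  X <- as.matrix(df[setdiff(names(df), label_col)])
  mask <- is.na(X)
  new_dataset(X, as.integer(y), colnames(X),
              missing_mask = if (any(mask)) mask else NULL)
}

#' Write a dataset CSV
#'
#' Inverse of [read_dataset_csv()]: features in column order, a trailing
#' `fetal_health` label column, missing cells written as empty fields.
#'
#' @param dataset An `fh_dataset`.
#' @param path Output path.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "fh_dataset"))
  X <- dataset$X
  # 17 significant digits guarantee an exact write -> read round trip
  cells <- matrix(ifelse(is.na(X), "", sprintf("%.17g", X)), nrow(X), ncol(X))
  lines <- c(paste(c(colnames(X), "fetal_health"), collapse = ","),
             paste(apply(cbind(cells, as.character(dataset$y)), 1L,
                         paste, collapse = ","),
                   collapse = "\n"))
  if (nrow(X) == 0L) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

#' Write the missing-cell mask as a sidecar CSV of (row, column) pairs
#'
#' @param mask Logical matrix of missing positions.
#' @param path Output path.
#' @export
write_mask_csv <- function(mask, path) {
  pos <- which(mask, arr.ind = TRUE)
  df <- data.frame(row = pos[, 1], column = pos[, 2])
  df <- df[order(df$row, df$column), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

model_to_list <- function(model) {
  list(format = MODEL_FORMAT, version = MODEL_VERSION,
       shape = c(m = model$m, n_rules = model$n_rules, n_out = model$n_out),
       tnorm = model$tnorm,
       p_coef = fmt_num(model$p_coef), q_coef = fmt_num(model$q_coef),
       c1 = apply(model$c1, c(1, 2), fmt_num),
       c2 = apply(model$c2, c(1, 2), fmt_num),
       sigma = apply(model$sigma, c(1, 2), fmt_num),
       V = apply(model$V, c(1, 2), fmt_num),
       W = apply(model$W, c(1, 2), fmt_num),
       scaler = if (is.null(model$scaler)) NULL else {
         list(min = fmt_num(model$scaler$min), max = fmt_num(model$scaler$max),
              feature_names = model$scaler$feature_names)
       })
}

#' Save / load a model as versioned JSON
#'
#' Checkpoints every trainable parameter (centers, widths, consequent
#' weights, type-reduction coefficients) plus any carried scaler state in a
#' human-diffable JSON format. Floats are written with 17 significant digits,
#' so `save -> load -> forward` is bit-exact and two saves of the same model
#' are byte-identical.
#'
#' @param model An `it2fnn` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "it2fnn"))
  json <- jsonlite::toJSON(model_to_list(model), auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

num_mat <- function(x, nr, nc, what) {
  m <- matrix(as.numeric(x), nr, nc)
  if (anyNA(m) || length(x) != nr * nc) {
    stop("load error: corrupt ", what, " block", call. = FALSE)
  }
  m
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("load error: not valid JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop("load error: not an it2fnn model file", call. = FALSE)
  }
  if (!identical(as.integer(obj$version), MODEL_VERSION)) {
    stop("load error: unsupported model format version ", obj$version,
         call. = FALSE)
  }
  shape <- as.integer(obj$shape)
  if (length(shape) != 3 || anyNA(shape) || any(shape < 1)) {
    stop("load error: schema error in shape field", call. = FALSE)
  }
  m <- shape[1]; n <- shape[2]; p <- shape[3]
  sizes <- c(length(obj$c1), length(obj$c2), length(obj$sigma))
  if (any(sizes != n * m) || length(obj$V) != m * n || length(obj$W) != n * p) {
    stop("load error: schema error, parameter blocks do not match shape",
         call. = FALSE)
  }
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- structure(list(min = as.numeric(obj$scaler$min),
                             max = as.numeric(obj$scaler$max),
                             feature_names = obj$scaler$feature_names),
                        class = "minmax_scaler")
  }
  new_it2fnn(num_mat(obj$c1, n, m, "c1"), num_mat(obj$c2, n, m, "c2"),
             num_mat(obj$sigma, n, m, "sigma"), num_mat(obj$V, m, n, "V"),
             num_mat(obj$W, n, p, "W"),
             p_coef = as.numeric(obj$p_coef), q_coef = as.numeric(obj$q_coef),
             tnorm = obj$tnorm, scaler = scaler)
}

#' Write a training history as a tidy CSV
#'
#' Columns `epoch, fold, split, rmse`, one row per recorded RMSE, with fixed
#' float formatting so identical runs produce byte-identical files.
#'
#' @param fit An `it2fnn_fit`.
#' @param path Output path.
#' @export
write_history_csv <- function(fit, path) {
  stopifnot(inherits(fit, "it2fnn_fit"))
  h <- fit$history
  lines <- c("epoch,fold,split,rmse",
             sprintf("%d,%d,%s,%s", h$epoch, h$fold, h$split, fmt_num(h$rmse)))
  writeLines(lines, path)
  invisible(path)
}
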