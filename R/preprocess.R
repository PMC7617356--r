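# Preprocessing: complete-case filtering, binary/one-hot encoding,
# min-max scaling fitted on a reference set, outcome-stratified splitting.

#' Drop patients with any missing value
#'
#' @param table Cohort data.frame.
#' @return `list(table = filtered table, excluded_count = rows removed)`.
#' @export
complete_case_filter <- function(table) {
  if ("death_1y" %in% names(table) && anyNA(table$death_1y))
    stop("schema error: outcome 'death_1y' must never be missing")
  keep <- stats::complete.cases(table)
  if (!any(keep)) stop("empty cohort after filtering")
  list(table = table[keep, , drop = FALSE],
       excluded_count = sum(!keep))
}

#' Encode a complete-case cohort as a numeric feature matrix
#'
#' Binary features become 0/1 columns; categorical features (sex, ethnicity,
#' surgical specialty) become one indicator column per declared level — no
#' reference level is dropped, since the downstream genetic-programming
#' search performs its own feature selection and is indifferent to
#' collinearity. Continuous features pass through unscaled. Column
#' provenance (source feature, level) is retained.
#'
#' @param table Complete-case cohort data.frame with `death_1y`.
#' @param schema Feature schema; acts as the frozen encoding schema —
#'   values outside a declared level set are an error.
#' @return An object of class `feature_matrix`: list with `X` (numeric
#'   matrix), `y` (integer outcome), `info` (column provenance), `row_ids`,
#'   `scaling` (NULL until [scale_apply()]).
#' @export
encode_features <- function(table, schema = cohort_schema()) {
  if (anyNA(table)) stop("encode_features requires a complete-case table")
  feats <- schema$feature[schema$feature %in% names(table)]
  cols <- list(); info <- list()
  for (f in feats) {
    cls <- schema$class[schema$feature == f]
    x <- table[[f]]
    if (cls == "continuous") {
      cols[[f]] <- as.numeric(x)
      info[[f]] <- data.frame(column = f, source = f, level = NA_character_,
                              type = "continuous", stringsAsFactors = FALSE)
    } else if (cls == "binary") {
      if (!all(x %in% c(0, 1)))
        stop(sprintf("binary feature '%s' contains non-0/1 value '%s'",
                     f, x[!(x %in% c(0, 1))][1]))
      cols[[f]] <- as.numeric(x)
      info[[f]] <- data.frame(column = f, source = f, level = NA_character_,
                              type = "binary", stringsAsFactors = FALSE)
    } else {
      lv <- strsplit(schema$levels[schema$feature == f], ",")[[1]]
      bad <- setdiff(unique(x), lv)
      if (length(bad))
        stop(sprintf("unseen category '%s' for feature '%s'", bad[1], f))
      for (l in lv) {
        cn <- paste(f, l, sep = "_")
        cols[[cn]] <- as.numeric(x == l)
        info[[cn]] <- data.frame(column = cn, source = f, level = l,
                                 type = "onehot", stringsAsFactors = FALSE)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  structure(list(
    X = X,
    y = if ("death_1y" %in% names(table)) as.integer(table$death_1y) else NULL,
    info = do.call(rbind, c(info, list(make.row.names = FALSE))),
    row_ids = if ("patient_id" %in% names(table)) table$patient_id
              else as.character(seq_len(nrow(table))),
    scaling = NULL), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d columns (%d source features)%s\n",
              nrow(x$X), ncol(x$X), length(unique(x$info$source)),
              if (is.null(x$scaling)) "" else ", scaled"))
  invisible(x)
}

#' Fit min-max scaling parameters
#'
#' @param fm A `feature_matrix`.
#' @param columns Columns to fit; default every continuous column.
#' @return data.frame with `column`, `min`, `max` observed on `fm`.
#' @export
scale_fit <- function(fm, columns = NULL) {
  if (is.null(columns)) columns <- fm$info$column[fm$info$type == "continuous"]
  missing_cols <- setdiff(columns, colnames(fm$X))
  if (length(missing_cols)) stop("unknown column: ", missing_cols[1])
  data.frame(column = columns,
             min = apply(fm$X[, columns, drop = FALSE], 2, min),
             max = apply(fm$X[, columns, drop = FALSE], 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply min-max scaling parameters
#'
#' Maps fitted column x to (x - min)/(max - min). A constant fitted column
#' (max == min) maps to 0. Values from outside the fitting set may land
#' outside [0, 1]; they are deliberately not clipped, preserving ordering.
#'
#' @param fm A `feature_matrix`.
#' @param params Parameters from [scale_fit()] (possibly fitted on another
#'   matrix, e.g. training parameters applied to test data).
#' @return The scaled `feature_matrix` with `scaling` recorded.
#' @export
scale_apply <- function(fm, params) {
  missing_cols <- setdiff(params$column, colnames(fm$X))
  if (length(missing_cols))
    stop("scaling parameters refer to absent column: ", missing_cols[1])
  for (i in seq_len(nrow(params))) {
    cn <- params$column[i]
    rng <- params$max[i] - params$min[i]
    fm$X[, cn] <- if (rng == 0) 0 else (fm$X[, cn] - params$min[i]) / rng
  }
  fm$scaling <- params
  fm
}

#' Outcome-stratified train/test split
#'
#' Training size is `round(fraction * n)`. Per-class training counts are
#' `floor(fraction * class size)`, with remaining seats (to reach the
#' rounded total) granted to the largest class first. For a 1190-patient
#' cohort with 66 events at fraction 0.8 this yields 952 training / 238
#' test patients with 52 / 14 events.
#'
#' @param table Data.frame (or `feature_matrix`) to split.
#' @param fraction Training fraction, in (0, 1); default 0.8.
#' @param outcome Outcome column name (default `death_1y`); ignored for a
#'   `feature_matrix`, which carries `y`.
#' @param seed Integer seed; the split is seed-reproducible.
#' @return list with `train`, `test` (same class as input) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
stratified_split <- function(table, fraction = 0.8, outcome = "death_1y",
                             seed = 1) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  y <- if (inherits(table, "feature_matrix")) table$y else table[[outcome]]
  n <- length(y)
  counts <- sort(table(y), decreasing = TRUE)   # largest class first
  if (any(counts < 2) || length(counts) < 2)
    stop("cannot stratify: each outcome class needs at least 2 members")
  n_train <- round(fraction * n)
  alloc <- floor(fraction * as.numeric(counts))
  seats <- n_train - sum(alloc)
  k <- 1L
  while (seats > 0) {                            # largest class first, cycling
    if (alloc[k] < counts[k]) { alloc[k] <- alloc[k] + 1L; seats <- seats - 1L }
    k <- if (k == length(counts)) 1L else k + 1L
  }
  train_idx <- integer(0)
  for (j in seq_along(counts)) {
    cls <- names(counts)[j]
    idx <- which(as.character(y) == cls)
    idx <- with_seed(substream_seed(seed, paste0("split_", cls)), shuffle_(idx))
    train_idx <- c(train_idx, idx[seq_len(alloc[j])])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  subset_rows <- function(x, idx) {
    if (inherits(x, "feature_matrix")) {
      x$X <- x$X[idx, , drop = FALSE]; x$y <- x$y[idx]
      x$row_ids <- x$row_ids[idx]; x
    } else x[idx, , drop = FALSE]
  }
  list(train = subset_rows(table, train_idx),
       test = subset_rows(table, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Write / read an encoded feature matrix with its provenance sidecar
#'
#' The matrix goes to `<path>.csv` (row ids + outcome + columns); column
#' provenance and any scaling parameters go to `<path>.json`.
#'
#' @param fm A `feature_matrix`.
#' @param path Path stem (no extension).
#' @return The path stem, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient_id = fm$row_ids, death_1y = fm$y,
                   fm$X, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- list(info = fm$info, scaling = fm$scaling)
  jsonlite::write_json(meta, paste0(path, ".json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(df[, setdiff(names(df), c("patient_id", "death_1y")),
                    drop = FALSE])
  structure(list(X = X, y = as.integer(df$death_1y),
                 info = as.data.frame(meta$info, stringsAsFactors = FALSE),
                 row_ids = df$patient_id,
                 scaling = if (is.null(meta$scaling)) NULL
                           else as.data.frame(meta$scaling)),
            class = "feature_matrix")
}
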