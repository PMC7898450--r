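#' Assemble a measurement set for one cellular context
#'
#' A `measurement_set` holds, for one context (cell line), the experimental
#' design (one row per condition assigning an activity in \[0, 1\] to every
#' input node — stimulator present = 1, absent = 0, drug applied = 1) and the
#' measured activities of the output nodes, scaled to \[0, 1\], with optional
#' standard errors of the mean (SEM).
#'
#' @param context Context (cell line) identifier.
#' @param conditions Data frame: column `condition` (unique names) plus one
#'   numeric column per input node, values in \[0, 1\].
#' @param values Data frame: column `condition` plus one numeric column per
#'   output node, values in \[0, 1\] (`NA` allowed: masked from fitting).
#' @param sem Optional data frame shaped like `values` with nonnegative SEMs.
#' @param network A [logic_network()] used to check column names.
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(context, conditions, values, sem = NULL,
                            network = NULL) {
  conditions <- as_tibble(conditions)
  values <- as_tibble(values)
  if (!"condition" %in% names(conditions) || !"condition" %in% names(values)) {
    abort("`conditions` and `values` need a 'condition' column")
  }
  if (anyDuplicated(conditions$condition)) abort("condition names must be unique")
  if (!identical(as.character(conditions$condition), as.character(values$condition))) {
    abort("`conditions` and `values` must list the same conditions in the same order")
  }
  in_cols <- setdiff(names(conditions), "condition")
  out_cols <- setdiff(names(values), "condition")
  check_unit_range(conditions[in_cols], "input assignment", allow_na = FALSE)
  check_unit_range(values[out_cols], "measured activity", allow_na = TRUE)
  if (!is.null(sem)) {
    sem <- as_tibble(sem)
    if (!identical(sort(names(sem)), sort(names(values)))) {
      abort("`sem` must have the same columns as `values`")
    }
    sem <- sem[, names(values)]
    if (any(vapply(sem[out_cols], function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
      abort("SEMs must be nonnegative")
    }
  }
  if (!is.null(network)) {
    miss_in <- setdiff(input_nodes(network), in_cols)
    if (length(miss_in) > 0) {
      abort(paste0("missing input-node column(s): ", paste(miss_in, collapse = ", ")))
    }
    extra_out <- setdiff(out_cols, output_nodes(network))
    if (length(extra_out) > 0) {
      abort(paste0("measured column(s) not output nodes of the network: ",
                   paste(extra_out, collapse = ", ")))
    }
  }
  structure(
    list(context = as.character(context), conditions = conditions,
         values = values, sem = sem),
    class = "measurement_set"
  )
}

check_unit_range <- function(df, what, allow_na) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (!is.numeric(x)) abort(paste0(what, " column '", nm, "' is not numeric"))
    if (!allow_na && anyNA(x)) abort(paste0(what, " column '", nm, "' has NA"))
    if (any(x < 0 | x > 1, na.rm = TRUE)) {
      abort(paste0(what, " column '", nm, "' outside [0, 1]"))
    }
  }
  invisible(df)
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set> context '", x$context, "': ",
      nrow(x$conditions), " conditions, ",
      ncol(x$values) - 1, " output node(s)",
      if (!is.null(x$sem)) ", with SEMs" else "", "\n", sep = "")
  invisible(x)
}

#' Read / write a measurement table
#'
#' Tab-separated, UTF-8, `#` comments, one row per condition: a `condition`
#' column, one column per input node (0/1 or fractional), one column per
#' output node, and optional `<node>__sem` columns. Column roles are resolved
#' against the network.
#'
#' @param file Path to the TSV file.
#' @param network A [logic_network()].
#' @param context Context identifier recorded in the returned object.
#' @return `read_measurements` returns a [measurement_set()];
#'   `write_measurements` returns `file` invisibly.
#' @export
read_measurements <- function(file, network, context) {
  df <- readr::read_tsv(file, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  parse_measurements(df, network, context)
}

#' @rdname read_measurements
#' @param table Data frame laid out like the measurement file.
#' @export
parse_measurements <- function(table, network, context) {
  df <- as_tibble(table)
  if (!"condition" %in% names(df)) abort("measurement table needs a 'condition' column")
  ins <- input_nodes(network)
  outs <- output_nodes(network)
  miss_in <- setdiff(ins, names(df))
  if (length(miss_in) > 0) {
    abort(paste0("missing input-node column(s): ", paste(miss_in, collapse = ", ")))
  }
  sem_cols <- grep("__sem$", names(df), value = TRUE)
  data_cols <- setdiff(names(df), c("condition", ins, sem_cols))
  unknown <- setdiff(data_cols, outs)
  if (length(unknown) > 0) {
    abort(paste0("column(s) not input or output nodes of the network: ",
                 paste(unknown, collapse = ", ")))
  }
  for (nm in setdiff(names(df), "condition")) {
    if (!is.numeric(df[[nm]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))) & !is.na(df[[nm]]))[1]
      abort(paste0("non-numeric cell at row ", bad_row %||% 1, ", column '", nm, "'"))
    }
  }
  conditions <- df[, c("condition", ins)]
  values <- df[, c("condition", data_cols)]
  sem <- NULL
  if (length(sem_cols) > 0) {
    base <- sub("__sem$", "", sem_cols)
    unknown_sem <- setdiff(base, data_cols)
    if (length(unknown_sem) > 0) {
      abort(paste0("SEM column(s) without matching output column: ",
                   paste(unknown_sem, collapse = ", ")))
    }
    sem <- values
    for (o in data_cols) {
      sem[[o]] <- if (o %in% base) df[[paste0(o, "__sem")]] else NA_real_
    }
  }
  measurement_set(context, conditions, values, sem = sem, network = network)
}

#' @rdname read_measurements
#' @param dataset A [measurement_set()].
#' @export
write_measurements <- function(dataset, file) {
  stopifnot(inherits(dataset, "measurement_set"))
  df <- dplyr::inner_join(dataset$conditions, dataset$values, by = "condition")
  if (!is.null(dataset$sem)) {
    sem <- dataset$sem
    names(sem)[-1] <- paste0(names(sem)[-1], "__sem")
    df <- dplyr::inner_join(df, sem, by = "condition")
  }
  readr::write_tsv(df, file, progress = FALSE)
  invisible(file)
}

#' Normalize immunoblot intensity series to model-ready activities
#'
#' Reproduces the quantification chain used for phosphoprotein read-outs:
#' (1) per lane, the ratio of phosphorylated-protein to total-protein signal
#' intensity; (2) per blot, division by the mean ratio of that blot, making
#' blots comparable across technical day-to-day variability; (3) per series
#' (one output node in one context), min–max scaling of the blot-normalized
#' values onto \[0, 1\].
#'
#' @param data Data frame with numeric columns `phospho` and `total`
#'   (strictly positive intensities), a `blot` column identifying the blot
#'   each lane comes from, and optionally a `series` column; scaling
#'   (step 3) is done within each series.
#' @return The input tibble with columns `ratio`, `blot_norm` and `activity`
#'   appended; `activity` is in \[0, 1\]. A degenerate series whose values
#'   are all equal maps to `activity = 0.5`.
#' @examples
#' normalize_blots(data.frame(
#'   blot = c(1, 1), phospho = c(2, 4), total = c(1, 1)
#' ))
#' @export
normalize_blots <- function(data) {
  df <- as_tibble(data)
  for (nm in c("phospho", "total", "blot")) {
    if (!nm %in% names(df)) abort(paste0("`data` needs a '", nm, "' column"))
  }
  if (any(!is.finite(df$total)) || any(df$total <= 0)) {
    abort("total intensities must be strictly positive")
  }
  if (any(!is.finite(df$phospho)) || any(df$phospho <= 0)) {
    abort("phospho intensities must be strictly positive")
  }
  df$ratio <- df$phospho / df$total
  df <- dplyr::mutate(df, blot_norm = .data$ratio / mean(.data$ratio),
                      .by = "blot")
  grp <- if ("series" %in% names(df)) "series" else character(0)
  scale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
  }
  if (length(grp) == 0) {
    df$activity <- scale01(df$blot_norm)
  } else {
    df <- dplyr::mutate(df, activity = scale01(.data$blot_norm), .by = "series")
  }
  df
}
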