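#' Construct a curve matrix for one individual
#'
#' A `curve_matrix` holds all replicate stress-response curves measured on a
#' single individual: an `R x T` matrix of response values (rows = replicate
#' curves in collection order, columns = timepoints on a shared time grid).
#' Missing observations are stored as `NA` and mirrored in `missing_mask`.
#' Replicate order is preserved exactly as supplied; it is semantically
#' meaningful for the order-sensitive metrics (KL divergence, HPA
#' flexibility).
#'
#' @param individual_id Single character or numeric label for the individual.
#' @param times Strictly increasing numeric vector of sampling times
#'   (minutes), length `T >= 2`.
#' @param values Numeric `R x T` matrix of response values (e.g. plasma
#'   corticosterone in ng/mL), `R >= 2` replicate curves. `NA` marks a
#'   missing cell.
#' @param replicate_ids Optional labels for the replicate rows; defaults to
#'   `1:R`.
#'
#' @return An object of class `curve_matrix` with elements `individual_id`,
#'   `times`, `values`, `missing_mask` and `replicate_ids`.
#'
#' @details Invariants enforced at construction:
#' * `times` strictly increasing, `T >= 2`, `R >= 2`;
#' * every replicate row has at least one present value;
#' * every timepoint column has at least two present values (so a
#'   cross-replicate variance is computable after interpolation).
#'
#' @examples
#' cm <- curve_matrix("A", times = c(0, 30),
#'                    values = rbind(c(5, 20), c(6, 24)))
#' cm$missing_mask
#' @export
curve_matrix <- function(individual_id, times, values, replicate_ids = NULL) {
  if (length(individual_id) != 1L || is.na(individual_id)) {
    stop("'individual_id' must be a single non-missing label", call. = FALSE)
  }
  individual_id <- as.character(individual_id)
  times <- as.numeric(times)
  if (length(times) < 2L || anyNA(times)) {
    stop("'times' must be a numeric vector of length >= 2 with no NA",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing (individual ", individual_id,
         ")", call. = FALSE)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) {
    stop("individual ", individual_id, ": fewer than 2 replicate curves",
         call. = FALSE)
  }
  if (ncol(values) != length(times)) {
    stop("individual ", individual_id, ": 'values' has ", ncol(values),
         " columns but 'times' has length ", length(times), call. = FALSE)
  }
  if (is.null(replicate_ids)) replicate_ids <- as.character(seq_len(nrow(values)))
  replicate_ids <- as.character(replicate_ids)
  if (length(replicate_ids) != nrow(values) || anyDuplicated(replicate_ids)) {
    stop("individual ", individual_id,
         ": 'replicate_ids' must be unique and match the row count",
         call. = FALSE)
  }
  mask <- is.na(values)
  if (any(rowSums(!mask) < 1L)) {
    stop("individual ", individual_id,
         ": every replicate must have at least one present value",
         call. = FALSE)
  }
  if (any(colSums(!mask) < 2L)) {
    stop("individual ", individual_id,
         ": every timepoint must have at least two present values",
         call. = FALSE)
  }
  dimnames(values) <- NULL
  structure(
    list(individual_id = individual_id, times = times, values = values,
         missing_mask = mask, replicate_ids = replicate_ids),
    class = "curve_matrix"
  )
}

#' @export
print.curve_matrix <- function(x, ...) {
  cat("<curve_matrix> individual ", x$individual_id, ": ",
      nrow(x$values), " replicates x ", length(x$times), " timepoints (",
      sum(x$missing_mask), " missing)\n", sep = "")
  invisible(x)
}

#' Construct a dataset of replicated stress-response curves
#'
#' A `stress_curve_dataset` collects `curve_matrix` objects for several
#' individuals sharing one time grid and one replicate count, the unit on
#' which metrics are compared (rankings are only comparable between
#' individuals scored on the same design).
#'
#' @param curves List of [curve_matrix] objects.
#' @param name Dataset label.
#'
#' @return An object of class `stress_curve_dataset` with elements `name`,
#'   `curves` (named by individual id), `times` and `n_replicates`.
#' @export
stress_curve_dataset <- function(curves, name = "dataset") {
  if (!is.list(curves) || length(curves) == 0L ||
      !all(vapply(curves, inherits, logical(1), "curve_matrix"))) {
    stop("'curves' must be a non-empty list of curve_matrix objects",
         call. = FALSE)
  }
  ids <- vapply(curves, function(cm) cm$individual_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  times <- curves[[1L]]$times
  nrep <- nrow(curves[[1L]]$values)
  for (cm in curves) {
    if (length(cm$times) != length(times) ||
        any(abs(cm$times - times) > 1e-9)) {
      stop("individual ", cm$individual_id,
           " has a different time grid than the rest of the dataset",
           call. = FALSE)
    }
    if (nrow(cm$values) != nrep) {
      stop("individual ", cm$individual_id, " has ", nrow(cm$values),
           " replicates; dataset requires ", nrep, call. = FALSE)
    }
  }
  names(curves) <- ids
  structure(
    list(name = name, curves = curves, times = times, n_replicates = nrep),
    class = "stress_curve_dataset"
  )
}

#' @export
print.stress_curve_dataset <- function(x, ...) {
  cat("<stress_curve_dataset> '", x$name, "': ", length(x$curves),
      " individuals, ", x$n_replicates, " replicates x ",
      length(x$times), " timepoints\n", sep = "")
  invisible(x)
}

#' Number of individuals in a dataset
#' @param x A `stress_curve_dataset`.
#' @return Integer count.
#' @export
n_individuals <- function(x) {
  stopifnot(inherits(x, "stress_curve_dataset"))
  length(x$curves)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read replicated curves from a long-format delimited file
#'
#' The one supported dialect is a "tidy" long table with a header row
#' `individual,replicate,time,value` (comma- or tab-delimited, UTF-8,
#' decimal point `.`). Each row is one observation; an empty or `NA` value
#' field, or an absent (individual, replicate, time) combination, becomes a
#' missing cell. Replicate rows are ordered by the first appearance of each
#' replicate identifier in the file (collection order), not lexically;
#' times are sorted ascending.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @param name Dataset label; defaults to the file name.
#'
#' @return A validated [stress_curve_dataset].
#' @export
read_curves <- function(path, sep = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           blank.lines.skip = TRUE, quote = "\"",
                           fill = FALSE, encoding = "UTF-8")
  need <- c("individual", "replicate", "time", "value")
  if (!all(need %in% names(raw))) {
    stop("missing required column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  time_num <- suppressWarnings(as.numeric(raw$time))
  bad <- which(is.na(time_num) & nzchar(raw$time))
  if (length(bad)) {
    stop("non-numeric 'time' at line ", bad[1L] + 1L, ": '",
         raw$time[bad[1L]], "'", call. = FALSE)
  }
  if (anyNA(time_num)) {
    stop("empty 'time' at line ", which(is.na(time_num))[1L] + 1L,
         call. = FALSE)
  }
  value_num <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value_num) & nzchar(raw$value) &
               !raw$value %in% c("NA", "na"))
  if (length(bad)) {
    stop("non-numeric 'value' at line ", bad[1L] + 1L, ": '",
         raw$value[bad[1L]], "'", call. = FALSE)
  }
  df <- data.frame(individual = raw$individual, replicate = raw$replicate,
                   time = time_num, value = value_num,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)

  curves <- lapply(split(df, factor(df$individual, unique(df$individual))),
                   function(d) {
    rep_ids <- unique(d$replicate)           # first-appearance order
    times <- sort(unique(d$time))
    vals <- matrix(NA_real_, length(rep_ids), length(times),
                   dimnames = list(rep_ids, NULL))
    i <- match(d$replicate, rep_ids)
    j <- match(d$time, times)
    dup <- duplicated(cbind(i, j))
    if (any(dup)) {
      stop("individual ", d$individual[1L],
           ": duplicate (replicate, time) observation for replicate '",
           d$replicate[dup][1L], "' at time ", d$time[dup][1L],
           call. = FALSE)
    }
    vals[cbind(i, j)] <- d$value
    curve_matrix(d$individual[1L], times, vals, replicate_ids = rep_ids)
  })
  if (is.null(name)) name <- basename(path)
  stress_curve_dataset(unname(curves), name = name)
}

#' Convert a dataset back to the long tidy format
#'
#' @param x A `stress_curve_dataset`.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data.frame with columns `individual`, `replicate`, `time`,
#'   `value` (missing cells as `NA`), one row per cell, replicates in
#'   collection order.
#' @export
as.data.frame.stress_curve_dataset <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  out <- do.call(rbind, lapply(x$curves, function(cm) {
    R <- nrow(cm$values); T <- length(cm$times)
    data.frame(individual = cm$individual_id,
               replicate = rep(cm$replicate_ids, each = T),
               time = rep(cm$times, times = R),
               value = as.vector(t(cm$values)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a tidy result table to a delimited text file
#'
#' Writes comma-separated text that round-trips through [utils::read.csv]
#' without loss at (better than) 12 significant digits; numerics are
#' serialized at full double precision.
#'
#' @param x Non-empty data.frame.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, sep = ",") {
  if (!is.data.frame(x)) stop("'x' must be a data.frame", call. = FALSE)
  if (nrow(x) == 0L) stop("refusing to write an empty table", call. = FALSE)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(col) {
    ifelse(is.na(col), NA_character_,
           formatC(col, digits = 15, format = "g"))
  })
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Write a dataset of curves in the long input format
#'
#' Emits the same `individual,replicate,time,value` dialect that
#' [read_curves] accepts, so datasets round-trip.
#'
#' @param ds A `stress_curve_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curves <- function(ds, path) {
  stopifnot(inherits(ds, "stress_curve_dataset"))
  write_table(as.data.frame(ds), path)
}
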