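#' Competition-rank individuals by repeatability score
#'
#' Converts per-individual metric scores into repeatability rankings: rank 1
#' is the most repeatable individual (highest PR; lowest KL or RMSSD). Ties
#' use competition ("min") ranking: `k` individuals tied at the best
#' unassigned position `p` all receive rank `p`, and the next distinct score
#' receives rank `p + k` — the pattern seen in published score tables
#' (e.g. a three-way tie at rank 5 followed by rank 8).
#'
#' @param scores A `metric_score_table` from [score_dataset], or any
#'   data.frame with columns `individual`, `metric`, `score` where `metric`
#'   is one of `PR`, `KL`, `RMSSD`.
#' @param tie_decimals Optional number of decimal places to round scores to
#'   before ranking (ties then mean equality after rounding). Default
#'   `NULL`: rank at full precision. Published tables often print rounded
#'   scores but rank on unrounded ones, so full precision is the default.
#' @return A `rank_table`: data.frame with columns `individual`, `column`
#'   (the metric name) and `rank` (positive integer).
#' @export
rank_scores <- function(scores, tie_decimals = NULL) {
  stopifnot(is.data.frame(scores),
            all(c("individual", "metric", "score") %in% names(scores)))
  if (!all(is.finite(scores$score))) {
    stop("non-finite score(s) for individual(s): ",
         paste(scores$individual[!is.finite(scores$score)], collapse = ", "),
         call. = FALSE)
  }
  dirs <- metric_directions()
  unknown <- setdiff(unique(scores$metric), names(dirs))
  if (length(unknown)) {
    stop("unknown metric(s) without direction metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pieces <- lapply(split(scores, scores$metric), function(d) {
    if (nrow(d) < 2L) {
      stop("metric ", d$metric[1L], ": need >= 2 individuals to rank",
           call. = FALSE)
    }
    s <- d$score
    if (!is.null(tie_decimals)) s <- round(s, tie_decimals)
    if (dirs[[d$metric[1L]]] == "higher") s <- -s
    data.frame(individual = d$individual, column = d$metric,
               rank = as.integer(rank(s, ties.method = "min")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  # restore the input's individual order within each metric block
  out <- out[order(match(out$column, unique(scores$metric)),
                   match(out$individual, unique(scores$individual))), ]
  rownames(out) <- NULL
  structure(out, class = c("rank_table", "data.frame"))
}

#' Attach an externally supplied ranking column
#'
#' Human visual rankings (e.g. a "majority" or "minority" rank) are supplied
#' as a two-column table or file (`individual`, `rank`) and merged by
#' individual id. The ranking itself is never computed here.
#'
#' @param ranks A `rank_table` from [rank_scores].
#' @param external Either a data.frame with columns `individual` and `rank`,
#'   or a path to a delimited file with those columns.
#' @param column_name Name for the new rank column (e.g. `"majority"`).
#' @return The extended `rank_table`.
#' @export
add_external_ranks <- function(ranks, external, column_name) {
  stopifnot(inherits(ranks, "rank_table"), is.character(column_name))
  if (is.character(external)) {
    if (!file.exists(external)) {
      stop("external rank file not found: ", external, call. = FALSE)
    }
    external <- utils::read.table(external, header = TRUE,
                                  sep = sniff_sep(external),
                                  stringsAsFactors = FALSE)
  }
  if (!all(c("individual", "rank") %in% names(external))) {
    stop("external ranks need columns 'individual' and 'rank'",
         call. = FALSE)
  }
  external$individual <- as.character(external$individual)
  ids <- unique(ranks$individual)
  if (!setequal(external$individual, ids)) {
    stop("external rank individuals do not match the dataset: missing [",
         paste(setdiff(ids, external$individual), collapse = ", "),
         "], extra [",
         paste(setdiff(external$individual, ids), collapse = ", "), "]",
         call. = FALSE)
  }
  extra <- data.frame(individual = external$individual,
                      column = column_name,
                      rank = as.integer(external$rank),
                      stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(ranks), extra)
  rownames(out) <- NULL
  structure(out, class = c("rank_table", "data.frame"))
}

star_code <- function(p, alpha_codes) {
  if (is.na(p)) return(NA_character_)
  for (s in names(alpha_codes)) if (p < alpha_codes[[s]]) return(s)
  ""
}

#' Pairwise Pearson correlation of rank columns with significance coding
#'
#' Because the metrics live on incomparable scales (PR on \[0,1\], KL and
#' RMSSD unbounded with opposite orientation), metrics are compared through
#' their rank vectors: a Pearson coefficient is computed on the integer
#' ranks for every unordered pair of columns. Two-sided p-values come from
#' the t transform `t = r * sqrt((n-2) / (1-r^2))` on `n - 2` degrees of
#' freedom, coded as `***` (p < 0.001), `**` (< 0.01), `*` (< 0.05),
#' `.` (< 0.10), `""` otherwise. No multiple-testing correction is applied.
#'
#' @param ranks A `rank_table` (all columns must cover the same set of at
#'   least 3 individuals).
#' @param alpha_codes Named numeric vector of star thresholds, most
#'   stringent first.
#' @return A `correlation_matrix`: data.frame with columns `metric_a`,
#'   `metric_b`, `r`, `p`, `stars`, one row per unordered pair (a < b in
#'   column order; the diagonal is omitted, being identically `r = 1`). A
#'   zero-variance column (all individuals tied) yields `NA` with a
#'   warning, not an error.
#' @export
correlate_ranks <- function(ranks,
                            alpha_codes = c("***" = 0.001, "**" = 0.01,
                                            "*" = 0.05, "." = 0.10)) {
  stopifnot(inherits(ranks, "rank_table") || is.data.frame(ranks))
  stopifnot(all(c("individual", "column", "rank") %in% names(ranks)))
  if (is.unsorted(rev(alpha_codes))) {
    alpha_codes <- sort(alpha_codes)
  }
  cols <- unique(ranks$column)
  ids <- unique(ranks$individual)
  if (length(ids) < 3L) {
    stop("need >= 3 individuals for rank correlation", call. = FALSE)
  }
  wide <- sapply(cols, function(cl) {
    d <- ranks[ranks$column == cl, ]
    if (!setequal(d$individual, ids) || nrow(d) != length(ids)) {
      stop("rank column '", cl,
           "' does not cover the same individuals as the others",
           call. = FALSE)
    }
    d$rank[match(ids, d$individual)]
  })
  n <- length(ids)
  pairs <- utils::combn(cols, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- wide[, pr[1L]]; y <- wide[, pr[2L]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("rank column '", pr[c(stats::sd(x) == 0, TRUE)][1L],
              "' has zero variance (all tied); correlation undefined",
              call. = FALSE)
      r <- NA_real_; p <- NA_real_
    } else {
      r <- stats::cor(x, y)
      if (abs(r) >= 1) {
        p <- 0
      } else {
        tval <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(tval), df = n - 2)
      }
    }
    data.frame(metric_a = pr[1L], metric_b = pr[2L], r = r, p = p,
               stars = star_code(p, alpha_codes), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n = n, class = c("correlation_matrix", "data.frame"))
}
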