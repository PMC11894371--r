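# local-RNG helper: run expr under set.seed(seed) without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Enumerate or sample replicate subsets of a given size
#'
#' If the number of `k`-subsets of `1:n` is at most `cap`, all of them are
#' returned in lexicographic order. Otherwise exactly `cap` distinct subsets
#' are drawn uniformly without replacement (rejection of duplicate designs),
#' reproducibly for a given `seed`. Each subset is a sorted index vector, so
#' restricting a curve matrix to it preserves the original replicate
#' collection order — this matters for the order-sensitive metrics.
#'
#' @param n Number of replicates available.
#' @param k Subset size, `2 <= k <= n`.
#' @param cap Maximum number of subsets to score (default 100).
#' @param seed Integer seed; required when sampling kicks in.
#' @return List of sorted integer vectors, each of length `k`.
#' @examples
#' length(enumerate_or_sample_subsets(4, 2))  # 6
#' length(enumerate_or_sample_subsets(4, 3))  # 4
#' @export
enumerate_or_sample_subsets <- function(n, k, cap = 100L, seed = NULL) {
  if (k < 2L || k > n) {
    stop("subset size k must satisfy 2 <= k <= n (got k = ", k,
         ", n = ", n, ")", call. = FALSE)
  }
  total <- choose(n, k)
  if (total <= cap) {
    return(utils::combn(n, k, simplify = FALSE))
  }
  if (is.null(seed)) {
    stop("choose(", n, ", ", k, ") = ", total, " exceeds cap = ", cap,
         "; a seed is required for subset sampling", call. = FALSE)
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- vector("list", cap)
    got <- 0L
    while (got < cap) {
      s <- sort(sample.int(n, k))
      key <- paste(s, collapse = "+")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- s
      }
    }
    out
  })
}

subset_curve <- function(cm, idx) {
  curve_matrix(cm$individual_id, cm$times, cm$values[idx, , drop = FALSE],
               replicate_ids = cm$replicate_ids[idx])
}

# one RNG stream per (individual index, k), derived from the master seed so
# adding individuals does not perturb other individuals' subset draws
derive_seed <- function(seed, i, k) {
  ((as.double(seed %% 100003L) * 9973 + i * 1009 + k * 7) %% 2147483629) + 1
}

#' Replicate-subsampling ("combination") analysis against the consensus
#'
#' For every individual and every subset size `k` from 2 up to the full
#' replicate count, scores each subset of replicate curves with each metric
#' (all subsets when there are at most `cap` of them, otherwise a seeded
#' uniform sample of `cap` distinct subsets) and attaches the consensus
#' score — the score computed on all available replicates (`k = R`). This
#' quantifies how representative scores from few replicates are of the
#' consensus, and in which direction they are biased.
#'
#' @param ds A complete [stress_curve_dataset] (no missing cells when KL or
#'   RMSSD are requested).
#' @param metrics Character subset of `c("PR", "KL", "RMSSD")`.
#' @param cap Maximum subsets per (individual, k); default 100.
#' @param seed Integer master seed for subset sampling.
#' @return A `combination_result` list with:
#'   * `scores`: data.frame `individual`, `metric`, `k`, `subset_id`
#'     ("+"-joined 1-based replicate indices), `score`, `consensus_score`;
#'   * `summary`: data.frame `individual`, `metric`, `k`, `n_subsets`,
#'     `median`, `mean`, `variance`, `IQR`, `consensus_score`.
#' @export
combination_analysis <- function(ds, metrics = c("PR", "KL", "RMSSD"),
                                 cap = 100L, seed = 1L) {
  stopifnot(inherits(ds, "stress_curve_dataset"))
  metrics <- match.arg(metrics, c("PR", "KL", "RMSSD"), several.ok = TRUE)
  R <- ds$n_replicates
  rows <- list()
  for (i in seq_along(ds$curves)) {
    cm <- ds$curves[[i]]
    for (k in 2:R) {
      subsets <- enumerate_or_sample_subsets(R, k, cap = cap,
                                             seed = derive_seed(seed, i, k))
      for (s in subsets) {
        sub <- subset_curve(cm, s)
        for (mname in metrics) {
          sc <- tryCatch(metric_functions[[mname]](sub), error = function(e) {
            stop("metric ", mname, " failed for individual ",
                 cm$individual_id, ", k = ", k, ", subset ",
                 paste(s, collapse = "+"), ": ", conditionMessage(e),
                 call. = FALSE)
          })
          rows[[length(rows) + 1L]] <- data.frame(
            individual = cm$individual_id, metric = mname, k = k,
            subset_id = paste(s, collapse = "+"), score = sc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  scores <- do.call(rbind, rows)
  consensus <- scores[scores$k == R,
                      c("individual", "metric", "score")]
  names(consensus)[3L] <- "consensus_score"
  scores <- merge(scores, consensus, by = c("individual", "metric"),
                  sort = FALSE)
  scores <- scores[order(match(scores$individual, names(ds$curves)),
                         match(scores$metric, metrics), scores$k,
                         scores$subset_id), ]
  rownames(scores) <- NULL

  grp <- interaction(scores$individual, scores$metric, scores$k,
                     drop = TRUE, lex.order = TRUE)
  summ <- do.call(rbind, lapply(split(scores, grp), function(d) {
    data.frame(individual = d$individual[1L], metric = d$metric[1L],
               k = d$k[1L], n_subsets = nrow(d),
               median = stats::median(d$score), mean = mean(d$score),
               variance = if (nrow(d) > 1L) stats::var(d$score) else 0,
               IQR = stats::IQR(d$score),
               consensus_score = d$consensus_score[1L],
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(match(summ$individual, names(ds$curves)),
                     match(summ$metric, metrics), summ$k), ]
  rownames(summ) <- NULL
  structure(list(scores = scores, summary = summ),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat("<combination_result> ", nrow(x$scores), " subset scores, ",
      nrow(x$summary), " (individual, metric, k) summaries\n", sep = "")
  invisible(x)
}
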