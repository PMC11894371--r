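#' Fill missing replicate values by interpolation in replicate-index space
#'
#' For each missing cell the value is linearly interpolated at its fixed
#' timepoint between the nearest present replicate below and above, in
#' replicate-index space: the curve at timepoint `t` is interpolated along
#' the collection order, not along the time axis. When a boundary replicate
#' is missing (no present replicate below, or above), the index space is
#' treated cyclically, interpolating between the last present and next
#' present replicate — for a single missing boundary replicate the fill is
#' their arithmetic mean. Interpolating along the time axis here would be
#' wrong: it fills a replicate's value from unrelated timepoints.
#'
#' @param curve A [curve_matrix]; every timepoint must retain at least two
#'   present values.
#' @return A list with `curve` (a complete `curve_matrix`, empty mask) and
#'   `n_interpolated` (the number of cells filled, the `m` entering the
#'   profile-repeatability interpolation penalty).
#' @export
fill_missing_replicates <- function(curve) {
  stopifnot(inherits(curve, "curve_matrix"))
  vals <- curve$values
  R <- nrow(vals)
  m <- 0L
  for (t in seq_along(curve$times)) {
    col <- vals[, t]
    present <- which(!is.na(col))
    if (length(present) < 2L) {
      stop("individual ", curve$individual_id, ": timepoint ",
           curve$times[t], " has fewer than 2 present values", call. = FALSE)
    }
    for (r in which(is.na(col))) {
      below <- present[present < r]
      above <- present[present > r]
      if (length(below) && length(above)) {
        r_prev <- max(below); r_next <- min(above)
        d_prev <- r - r_prev
        d_next <- r_next - r
      } else if (length(above)) {
        # first replicate(s) missing: wrap to the last present replicate
        r_prev <- max(present); r_next <- min(above)
        d_prev <- r + (R - r_prev)
        d_next <- r_next - r
      } else {
        # last replicate(s) missing: wrap forward to the first present
        r_prev <- max(below); r_next <- min(present)
        d_prev <- r - r_prev
        d_next <- (R - r) + r_next
      }
      w <- d_prev / (d_prev + d_next)
      vals[r, t] <- col[r_prev] + w * (col[r_next] - col[r_prev])
      m <- m + 1L
    }
  }
  filled <- curve_matrix(curve$individual_id, curve$times, vals,
                         replicate_ids = curve$replicate_ids)
  list(curve = filled, n_interpolated = m)
}

#' Count replicate curve crossings
#'
#' A crossing is an event where, for an unordered pair of replicate curves
#' and an adjacent time interval, the difference between the two curves has
#' strictly opposite signs at the interval's endpoints. Touching (a zero
#' difference at an endpoint) is not counted, so a curve that meets another
#' and retreats contributes nothing.
#'
#' @param curve A complete [curve_matrix] (no missing cells).
#' @return Integer crossing count `C`, with
#'   `0 <= C <= (T-1) * R * (R-1) / 2`.
#' @export
count_crossings <- function(curve) {
  stopifnot(inherits(curve, "curve_matrix"))
  if (any(curve$missing_mask)) {
    stop("individual ", curve$individual_id,
         ": crossings require a complete matrix; fill missing values first",
         call. = FALSE)
  }
  vals <- curve$values
  R <- nrow(vals)
  C <- 0L
  for (i in seq_len(R - 1L)) {
    for (j in (i + 1L):R) {
      d <- vals[i, ] - vals[j, ]
      C <- C + sum(d[-length(d)] * d[-1L] < 0)
    }
  }
  as.integer(C)
}

#' Profile repeatability (PR) of one individual's replicate curves
#'
#' PR is a bounded score in \[0, 1\] (1 = perfectly repeatable) built from
#' the spread of the replicate curves: per-timepoint variances across
#' replicates (normalized by the squared grand mean, so the score is
#' invariant to the measurement scale), the maximum such variance, the
#' number of curve crossings, and a penalty for interpolated cells (since
#' interpolation artificially inflates apparent repeatability, it is
#' corrected for here). Missing cells are first filled with
#' [fill_missing_replicates].
#'
#' The raw dispersion is
#' `S = (mean(v) + max(v)) * (1 + C/C_max) * (1 + m/(R*T))`
#' where `v_t` is the sample variance at timepoint `t` divided by the grand
#' mean squared, `C` the crossing count, `C_max = (T-1)*R*(R-1)/2` its
#' maximum, and `m` the number of interpolated cells; `PR = 1/(1 + S)`.
#'
#' @param curve A [curve_matrix]; missing cells allowed.
#' @return A list with `score` (PR in \[0,1\]) and `detail`, a
#'   `profile_repeatability_detail` with `per_time_variance`,
#'   `max_variance`, `crossings`, `max_crossings`, `n_interpolated`,
#'   `raw_dispersion` and `score`.
#' @examples
#' cm <- curve_matrix("A", c(0, 30), rbind(c(4, 4), c(6, 6)))
#' profile_repeatability(cm)$score  # 1/1.16 = 0.862...
#' @export
profile_repeatability <- function(curve) {
  stopifnot(inherits(curve, "curve_matrix"))
  filled <- fill_missing_replicates(curve)
  vals <- filled$curve$values
  m <- filled$n_interpolated
  R <- nrow(vals)
  T <- ncol(vals)
  G <- mean(vals)
  if (abs(G) < .Machine$double.eps) {
    stop("individual ", curve$individual_id,
         ": grand mean is zero, scale-normalized variance undefined",
         call. = FALSE)
  }
  v <- apply(vals, 2L, stats::var) / G^2
  C <- count_crossings(filled$curve)
  C_max <- (T - 1L) * R * (R - 1L) / 2
  S <- (mean(v) + max(v)) * (1 + C / C_max) * (1 + m / (R * T))
  score <- 1 / (1 + S)
  detail <- structure(
    list(per_time_variance = v, max_variance = max(v), crossings = C,
         max_crossings = as.integer(C_max), n_interpolated = m,
         raw_dispersion = S, score = score),
    class = "profile_repeatability_detail"
  )
  list(score = score, detail = detail)
}

generalized_kl <- function(p, q) sum(p * log(p / q) - p + q)

#' Generalized KL divergence score of ordered replicate curves
#'
#' Computes the generalized (unnormalized, I-) Kullback-Leibler divergence
#' between each ordered pair of successive replicate curves,
#' `D(p || q) = sum_t [ p_t * ln(p_t / q_t) - p_t + q_t ]`,
#' and returns their mean over the `R - 1` successive pairs. The curves are
#' used as-is, without conversion to probability distributions; the
#' `- p + q` correction keeps each divergence nonnegative on unnormalized
#' data. A score of 0 means high repeatability (all successive curves
#' identical); there is no upper bound. The score depends on replicate
#' order and is asymmetric under order reversal.
#'
#' @param curve A complete [curve_matrix] with all values strictly positive.
#'   Missing cells are an error: this metric cannot handle missing data.
#' @return A list with `score` (mean divergence, `>= 0`) and `detail`, a
#'   `kl_detail` with `pairwise_divergences` (length `R - 1`) and `score`.
#' @export
kl_divergence_score <- function(curve) {
  stopifnot(inherits(curve, "curve_matrix"))
  if (any(curve$missing_mask)) {
    bad <- which(curve$missing_mask, arr.ind = TRUE)[1L, ]
    stop("individual ", curve$individual_id,
         ": KL divergence cannot handle missing datapoints (replicate ",
         curve$replicate_ids[bad[1L]], ", time ", curve$times[bad[2L]], ")",
         call. = FALSE)
  }
  vals <- curve$values
  if (any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)[1L, ]
    stop("individual ", curve$individual_id,
         ": KL divergence requires strictly positive values (replicate ",
         curve$replicate_ids[bad[1L]], ", time ", curve$times[bad[2L]],
         " is ", vals[bad[1L], bad[2L]], ")", call. = FALSE)
  }
  R <- nrow(vals)
  d <- vapply(seq_len(R - 1L), function(r) {
    generalized_kl(vals[r, ], vals[r + 1L, ])
  }, numeric(1))
  score <- mean(d)
  detail <- structure(list(pairwise_divergences = d, score = score),
                      class = "kl_detail")
  list(score = score, detail = detail)
}

#' HPA flexibility (RMSSD of per-curve means)
#'
#' Each replicate curve is collapsed to its unweighted mean over timepoints,
#' giving the series `M_1, ..., M_R` in collection order; the score is the
#' root mean square of successive differences,
#' `RMSSD = sqrt( mean( (M_(r+1) - M_r)^2 ) )` (denominator `R - 1`).
#' Borrowed from heart-rate-variability analysis, it measures how flexible
#' (variable) the axis output is across successive occasions: low RMSSD =
#' repeatable. Order-sensitive by construction.
#'
#' @param curve A complete [curve_matrix] (no missing cells), `R >= 2`.
#' @return A list with `score` (`>= 0`) and `detail`, an `rmssd_detail`
#'   with `replicate_means` (length `R`, collection order) and `score`.
#' @export
hpa_flexibility_score <- function(curve) {
  stopifnot(inherits(curve, "curve_matrix"))
  if (any(curve$missing_mask)) {
    stop("individual ", curve$individual_id,
         ": HPA flexibility (RMSSD) cannot handle missing datapoints",
         call. = FALSE)
  }
  M <- rowMeans(curve$values)
  score <- sqrt(mean(diff(M)^2))
  detail <- structure(list(replicate_means = M, score = score),
                      class = "rmssd_detail")
  list(score = score, detail = detail)
}

metric_functions <- list(
  PR = function(cm) profile_repeatability(cm)$score,
  KL = function(cm) kl_divergence_score(cm)$score,
  RMSSD = function(cm) hpa_flexibility_score(cm)$score
)

#' Score direction of each repeatability metric
#'
#' @return Named character vector: `"higher"` if a higher score means more
#'   repeatable (PR), `"lower"` if lower means more repeatable (KL, RMSSD).
#' @export
metric_directions <- function() {
  c(PR = "higher", KL = "lower", RMSSD = "lower")
}

#' Score every individual in a dataset with the selected metrics
#'
#' @param ds A [stress_curve_dataset].
#' @param metrics Character subset of `c("PR", "KL", "RMSSD")`.
#' @return A `metric_score_table`: data.frame with columns `individual`,
#'   `metric`, `score`, one row per (individual, metric), individuals in
#'   dataset order; metric directionality attached as attribute
#'   `directions`.
#' @export
score_dataset <- function(ds, metrics = c("PR", "KL", "RMSSD")) {
  stopifnot(inherits(ds, "stress_curve_dataset"))
  metrics <- match.arg(metrics, c("PR", "KL", "RMSSD"), several.ok = TRUE)
  rows <- lapply(ds$curves, function(cm) {
    scores <- vapply(metrics, function(mname) {
      tryCatch(metric_functions[[mname]](cm), error = function(e) {
        stop("metric ", mname, " failed for individual ", cm$individual_id,
             ": ", conditionMessage(e), call. = FALSE)
      })
    }, numeric(1))
    data.frame(individual = cm$individual_id, metric = metrics,
               score = unname(scores), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, directions = metric_directions()[metrics],
            class = c("metric_score_table", "data.frame"))
}
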