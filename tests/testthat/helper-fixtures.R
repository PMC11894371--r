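# shared fixture builders and independent oracles

cm2x2 <- function(a, b, id = "X", times = c(0, 30)) {
  curve_matrix(id, times, rbind(a, b))
}

random_curve <- function(R, T, id = "X", positive = TRUE) {
  vals <- matrix(stats::runif(R * T, if (positive) 0.5 else -5, 10), R, T)
  curve_matrix(id, seq(0, by = 15, length.out = T), vals)
}

# exhaustive pair x interval sign-change enumeration, independent of
# count_crossings' loop structure
crossings_oracle <- function(vals) {
  R <- nrow(vals); T <- ncol(vals)
  n <- 0L
  for (i in seq_len(R)) for (j in seq_len(R)) for (t in seq_len(T - 1L)) {
    if (i < j) {
      d1 <- vals[i, t] - vals[j, t]
      d2 <- vals[i, t + 1L] - vals[j, t + 1L]
      if ((d1 < 0 && d2 > 0) || (d1 > 0 && d2 < 0)) n <- n + 1L
    }
  }
  n
}

rmssd_oracle <- function(m) {
  m <- unname(m)
  sq <- 0
  for (r in seq_len(length(m) - 1L)) sq <- sq + (m[r + 1L] - m[r])^2
  sqrt(sq / (length(m) - 1L))
}

reference_scores <- function() {
  utils::read.csv(system.file("extdata", "reference_scores.csv",
                              package = "stressrep"),
                  stringsAsFactors = FALSE)
}

# long-format file from a matrix spec, for read_curves tests
write_long_fixture <- function(path, individuals, sep = ",") {
  rows <- list()
  for (id in names(individuals)) {
    spec <- individuals[[id]]
    vals <- spec$values
    for (r in seq_len(nrow(vals))) for (t in seq_along(spec$times)) {
      v <- vals[r, t]
      rows[[length(rows) + 1L]] <- data.frame(
        individual = id, replicate = r, time = spec$times[t],
        value = if (is.na(v)) "" else as.character(v))
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
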