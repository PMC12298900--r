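# Internal helpers.

# 31-bit polynomial rolling hash of a string; used to key per-report RNG
# substreams so that reconstruction of any subset of reports reproduces the
# corresponding rows of a full run.
.hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

.substream_seed <- function(seed, id) {
  (.hash31(id) + as.numeric(seed) * 7919) %% 2147483647
}

#' Pool per-report summary moments
#'
#' Combines report-level (mean, SD, n) summaries into the overall mean and SD
#' of the underlying individuals, using the exact pooled-variance identity
#' (within-report sums of squares plus between-report dispersion of means).
#'
#' @param mean,sd,n Numeric vectors of per-report sample means, SDs and sizes.
#' @return Named numeric vector with elements `mean`, `sd` and `n`.
#' @export
pooled_moments <- function(mean, sd, n) {
  stopifnot(length(mean) == length(sd), length(mean) == length(n))
  keep <- is.finite(mean) & is.finite(sd) & is.finite(n) & n >= 1
  mean <- mean[keep]; sd <- sd[keep]; n <- n[keep]
  if (length(mean) == 0) stop("no usable (mean, sd, n) triples", call. = FALSE)
  N <- sum(n)
  M <- sum(n * mean) / N
  ss <- sum((n - 1) * sd^2) + sum(n * (mean - M)^2)
  c(mean = M, sd = if (N > 1) sqrt(ss / (N - 1)) else 0, n = N)
}

#' Pooled mercury moments by feeding habit
#'
#' @param db A `fish_reports` database.
#' @return Data frame with one row per feeding habit and pooled `hg_mean`,
#'   `hg_sd` and total `n` across the reports that provide an SD.
#' @export
pooled_hg_by_habit <- function(db) {
  stopifnot(inherits(db, "fish_reports"))
  habits <- sort(unique(db$feeding_habit))
  out <- do.call(rbind, lapply(habits, function(h) {
    sub <- db[db$feeding_habit == h & !is.na(db$hg_sd), , drop = FALSE]
    if (nrow(sub) == 0) stop("no reports with SD for habit ", h, call. = FALSE)
    pm <- pooled_moments(sub$hg_mean, sub$hg_sd, sub$n_samples)
    data.frame(feeding_habit = h, hg_mean = pm[["mean"]], hg_sd = pm[["sd"]],
               n = pm[["n"]])
  }))
  rownames(out) <- NULL
  out
}
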