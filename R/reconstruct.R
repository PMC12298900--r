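#' Reconstruct individual-level pseudo-observations from report summaries
#'
#' The meta-analytic device at the heart of the pipeline: each report only
#' publishes the sample mean, SD and size of muscle Hg, so a dataset with the
#' same first two moments is regenerated by drawing `n_samples` values from
#' `Normal(hg_mean, hg_sd)` per report. This propagates both the within-study
#' spread (via the SD) and the between-study differences (via the means) into
#' the downstream linear models.
#'
#' Because the models are fitted on log concentrations, a normal draw at or
#' below zero is undefined downstream. Under `positivity = "redraw"` (the
#' default) non-positive draws are redrawn, i.e. the per-report distribution
#' is the normal truncated at zero; `positivity = "raw"` keeps the literal
#' normal draws for fidelity checks.
#'
#' Per-report RNG substreams are keyed by `(seed, report_id)`, so
#' reconstructing any subset of reports reproduces exactly the corresponding
#' rows of a full run, and report order never changes the values.
#'
#' @param db A `fish_reports` database.
#' @param seed Integer seed.
#' @param positivity `"redraw"` (truncate at zero by redrawing) or `"raw"`.
#' @return An `hg_pseudo` data frame with one row per pseudo-observation:
#'   `report_id`, `pseudo_value` (ug/g w.w.) and all report covariates copied
#'   through. Reports lacking an SD are excluded and listed, with reasons, in
#'   the `"excluded"` attribute.
#' @export
reconstruct <- function(db, seed = 1L, positivity = c("redraw", "raw")) {
  stopifnot(inherits(db, "fish_reports"))
  positivity <- match.arg(positivity)
  if (nrow(db) == 0) stop("empty database: nothing to reconstruct", call. = FALSE)

  has_sd <- !is.na(db$hg_sd)
  excluded <- data.frame(report_id = db$report_id[!has_sd],
                         reason = rep("missing hg_sd", sum(!has_sd)),
                         stringsAsFactors = FALSE)
  use <- db[has_sd, , drop = FALSE]
  if (nrow(use) == 0) {
    stop("nothing to reconstruct: all reports lack an SD", call. = FALSE)
  }

  pieces <- vector("list", nrow(use))
  for (i in seq_len(nrow(use))) {
    r <- use[i, ]
    set.seed(.substream_seed(seed, r$report_id))
    if (r$hg_sd == 0) {
      v <- rep(r$hg_mean, r$n_samples)
    } else {
      v <- stats::rnorm(r$n_samples, r$hg_mean, r$hg_sd)
      if (positivity == "redraw") {
        for (iter in 1:1000) {
          bad <- which(v <= 0)
          if (length(bad) == 0) break
          v[bad] <- stats::rnorm(length(bad), r$hg_mean, r$hg_sd)
        }
        if (any(v <= 0)) stop("failed to obtain positive draws for report ",
                              r$report_id, call. = FALSE)
      }
    }
    cov <- as.data.frame(r)[rep(1L, r$n_samples), , drop = FALSE]
    cov$pseudo_value <- v
    pieces[[i]] <- cov
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[c("report_id", "pseudo_value",
               setdiff(names(out), c("report_id", "pseudo_value")))]
  structure(out, class = c("hg_pseudo", "data.frame"),
            excluded = excluded, seed = as.integer(seed),
            positivity = positivity)
}

#' @export
print.hg_pseudo <- function(x, ...) {
  cat(sprintf(paste0("<hg_pseudo> %d pseudo-observations from %d reports ",
                     "(positivity=%s, seed=%d); %d report(s) excluded\n"),
              nrow(x), length(unique(x$report_id)), attr(x, "positivity"),
              attr(x, "seed"), nrow(attr(x, "excluded"))))
  invisible(x)
}
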