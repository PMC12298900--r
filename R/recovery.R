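#' Recover injected effects from a reconstructed synthetic database
#'
#' Audits the full chain generator -> report summaries -> pseudo-data ->
#' linear models: fits, per feeding habit, a wild-fish regression of log
#' pseudo-concentration on ecosystem type (reference `river`), water type
#' (reference `clear`) and genus-centered length, with cluster-robust
#' standard errors on `report_id`, and compares each coefficient with the
#' corresponding contrast of the generating configuration. The habit effect
#' is recovered as the difference of the two habit intercepts (reference
#' levels, genus-mean length). Market reports are excluded because their
#' water type is unrecorded.
#'
#' @param pseudo An `hg_pseudo` data frame from [reconstruct()].
#' @param config The `synthetic_config` that generated the database.
#' @param level Confidence level for the recovery intervals.
#' @return Data frame with one row per injected effect: `effect`, `truth`,
#'   `estimate`, `se`, `lwr`, `upr`, `covered` (whether the interval contains
#'   the truth).
#' @export
recover_effects <- function(pseudo, config, level = 0.95) {
  stopifnot(inherits(config, "synthetic_config"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  wild <- pseudo[pseudo$ecosystem_type != "market", , drop = FALSE]
  gmeans <- vapply(config$length_mean_by_genus, `[`, 0, 1)
  wild$length_c <- wild$length_mean_cm - gmeans[wild$genus]

  fit_one <- function(h) {
    d <- wild[wild$feeding_habit == h, , drop = FALSE]
    d$eco <- stats::relevel(base::factor(d$ecosystem_type), ref = "river")
    d$wat <- stats::relevel(base::factor(d$water_type), ref = "clear")
    fit <- stats::lm(log(pseudo_value) ~ eco + wat + length_c, data = d)
    V <- sandwich::vcovCL(fit, cluster = d$report_id, type = "HC1")
    list(coef = stats::coef(fit), se = sqrt(diag(V)))
  }
  fc <- fit_one("carnivore")
  fn <- fit_one("non_carnivore")

  eff <- function(name, truth, est, se) {
    data.frame(effect = name, truth = truth, estimate = unname(est),
               se = unname(se), lwr = unname(est - z * se),
               upr = unname(est + z * se),
               covered = unname(est - z * se <= truth &
                                  truth <= est + z * se),
               stringsAsFactors = FALSE)
  }
  ec <- config$ecosystem_effects; wc <- config$water_effects
  rows <- list(
    eff("habit_gap",
        config$habit_effect +
          (ec$carnivore[["river"]] - ec$non_carnivore[["river"]]) +
          (wc$carnivore[["clear"]] - wc$non_carnivore[["clear"]]),
        fc$coef[["(Intercept)"]] - fn$coef[["(Intercept)"]],
        sqrt(fc$se[["(Intercept)"]]^2 + fn$se[["(Intercept)"]]^2)))
  for (h in c("carnivore", "non_carnivore")) {
    f <- if (h == "carnivore") fc else fn
    for (lv in c("lake", "hydroelectric")) {
      nm <- paste0("eco", lv)
      rows[[length(rows) + 1]] <- eff(
        paste0(lv, "_", h),
        ec[[h]][[lv]] - ec[[h]][["river"]], f$coef[[nm]], f$se[[nm]])
    }
    for (lv in c("black", "white")) {
      nm <- paste0("wat", lv)
      rows[[length(rows) + 1]] <- eff(
        paste0(lv, "_", h),
        wc[[h]][[lv]] - wc[[h]][["clear"]], f$coef[[nm]], f$se[[nm]])
    }
    slope_truth <- if (h == "carnivore") config$size_slope_carnivore else
      config$size_slope_noncarnivore
    rows[[length(rows) + 1]] <- eff(paste0("slope_", h), slope_truth,
                                    f$coef[["length_c"]], f$se[["length_c"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
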