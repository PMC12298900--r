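#' @title Linear-model suite for reconstructed mercury data
#' @description
#' One-way ANOVA on ecosystem type and water type (feeding habits analyzed
#' separately), Tukey-Kramer all-pairs comparisons with a compact letter
#' display, log-scale size regressions per habit, and a four-term multiple
#' regression with type III sums of squares and partial R-squared, preceded
#' by Box-Cox maximum-likelihood transform selection. All fits operate on the
#' pseudo-observation data frame produced by [reconstruct()].
#' @name inference_models
NULL

# Box-Cox --------------------------------------------------------------------

#' Box-Cox power transform
#' @param x Positive values.
#' @param lambda Power; `lambda = 0` is the natural log.
#' @return Transformed values `(x^lambda - 1) / lambda` (or `log(x)`).
#' @export
bc_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Select a Box-Cox transform by profile maximum likelihood
#'
#' Profiles the Box-Cox log-likelihood on a fixed grid (default
#' `seq(-2, 2, 0.01)`) and returns the grid argmax; `lambda = 0` is handled
#' as the natural log. The reported lambda is the raw argmax, never rounded
#' to a "nice" value; pass `lambda = 0` downstream explicitly when a plain
#' log analysis is wanted.
#'
#' @param values Positive numeric vector, `n >= 3`, non-constant.
#' @param lambda Grid of candidate powers.
#' @return A `boxcox_fit` list: `lambda` (argmax), `profile` (data frame of
#'   lambda and profile log-likelihood), `transformed` values, `n`.
#' @export
boxcox_select <- function(values, lambda = seq(-2, 2, by = 0.01)) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be finite and > 0", call. = FALSE)
  }
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::var(values) == 0) {
    stop("degenerate input: values are constant (zero variance)", call. = FALSE)
  }
  prof <- MASS::boxcox(values ~ 1, lambda = lambda, plotit = FALSE,
                       interp = FALSE)
  best <- prof$x[which.max(prof$y)]
  structure(list(lambda = best,
                 profile = data.frame(lambda = prof$x, loglik = prof$y),
                 transformed = bc_transform(values, best),
                 n = length(values)),
            class = "boxcox_fit")
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf("<boxcox_fit> lambda = %.2f (grid argmax over [%g, %g], n = %d)\n",
              x$lambda, min(x$profile$lambda), max(x$profile$lambda), x$n))
  invisible(x)
}

# internal: apply the requested transform to concentrations
.transform_values <- function(v, transform) {
  switch(transform,
         log = log(v),
         boxcox = boxcox_select(v)$transformed,
         none = v,
         stop("unknown transform: ", transform))
}

# ANOVA ----------------------------------------------------------------------

#' One-way ANOVA on a site or water-type factor
#'
#' Classical one-way decomposition of the (transformed) Hg concentrations:
#' `SS_total = SS_between + SS_within`, `F = MS_between / MS_within`, with
#' the p-value from the F distribution. Feeding habits are analyzed
#' separately (pass `habit`); for `water_type` the `"unknown"` level (market
#' fish) is dropped. Levels with fewer than 2 observations are dropped with
#' a warning.
#'
#' @param data A data frame of pseudo-observations (e.g. from
#'   [reconstruct()]).
#' @param factor Grouping column: `"ecosystem_type"` or `"water_type"` (any
#'   factor column is accepted).
#' @param value Response column, concentrations in ug/g.
#' @param habit Optional `"carnivore"` / `"non_carnivore"` subset.
#' @param transform `"log"` (default, matching the published figures),
#'   `"boxcox"` (profile-ML lambda) or `"none"`.
#' @param alpha Type I error rate for downstream letter displays.
#' @return An `hg_anova` object: per-level summary table (n, mean, variance on
#'   the transformed scale), `F`, degrees of freedom, `p_value`, and the
#'   underlying `aov` fit.
#' @export
anova_oneway <- function(data, factor, value = "pseudo_value", habit = NULL,
                         transform = c("log", "boxcox", "none"),
                         alpha = 0.05) {
  transform <- match.arg(transform)
  stopifnot(factor %in% names(data), value %in% names(data))
  if (!is.null(habit)) data <- data[data$feeding_habit == habit, , drop = FALSE]
  if (identical(factor, "water_type")) {
    data <- data[data$water_type != "unknown", , drop = FALSE]
  }
  data <- data[is.finite(data[[value]]) & !is.na(data[[factor]]), , drop = FALSE]
  y <- .transform_values(data[[value]], transform)
  g <- as.character(data[[factor]])

  counts <- table(g)
  thin <- names(counts)[counts < 2]
  if (length(thin) > 0) {
    warning("dropping level(s) with < 2 observations: ",
            paste(thin, collapse = ", "))
    keep <- !g %in% thin
    y <- y[keep]; g <- g[keep]; data <- data[keep, , drop = FALSE]
  }
  if (length(unique(g)) < 2) {
    stop("need >= 2 factor levels with >= 2 observations each", call. = FALSE)
  }
  if (all(tapply(y, g, stats::var) == 0)) {
    stop("zero within-group variance in every group", call. = FALSE)
  }

  g <- base::factor(g)
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  tab <- data.frame(level = levels(g),
                    n = as.integer(table(g)),
                    mean = as.numeric(tapply(y, g, mean)),
                    variance = as.numeric(tapply(y, g, stats::var)))
  structure(list(factor = factor, habit = habit, transform = transform,
                 table = tab,
                 F = an$`F value`[1],
                 df_between = an$Df[1], df_within = an$Df[2],
                 p_value = an$`Pr(>F)`[1],
                 alpha = alpha, fit = fit,
                 data = data.frame(y = y, g = g,
                                   report_id = data$report_id)),
            class = "hg_anova")
}

#' @export
print.hg_anova <- function(x, ...) {
  cat(sprintf("<hg_anova> %s%s (%s scale): F(%d, %d) = %.3f, p = %.3g\n",
              x$factor, if (is.null(x$habit)) "" else paste0(" | ", x$habit),
              x$transform, x$df_between, x$df_within, x$F, x$p_value))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Tukey + compact letter display ---------------------------------------------

# Insert-and-absorb compact letter display. `levels_ordered` are the group
# names in display order (here: decreasing mean); `sig_pairs` is a 2-column
# character matrix of significantly different pairs. Guarantees the defining
# biconditional: two levels share a letter iff the pair is NOT significant.
.cld_insert_absorb <- function(levels_ordered, sig_pairs) {
  cols <- list(levels_ordered)
  if (length(sig_pairs)) {
    for (k in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[k, 1]; j <- sig_pairs[k, 2]
      nxt <- list()
      for (cl in cols) {
        if (i %in% cl && j %in% cl) {
          nxt <- c(nxt, list(setdiff(cl, i)), list(setdiff(cl, j)))
        } else {
          nxt <- c(nxt, list(cl))
        }
      }
      # absorb columns contained in (or duplicating) another
      keep <- rep(TRUE, length(nxt))
      for (a in seq_along(nxt)) {
        for (b in seq_along(nxt)) {
          if (a == b || !keep[a] || !keep[b]) next
          if (all(nxt[[a]] %in% nxt[[b]]) &&
              (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- nxt[keep]
    }
  }
  ord <- order(vapply(cols, function(cl) min(match(cl, levels_ordered)), 1))
  cols <- cols[ord]
  out <- stats::setNames(rep("", length(levels_ordered)), levels_ordered)
  for (ci in seq_along(cols)) {
    for (lv in cols[[ci]]) out[lv] <- paste0(out[lv], letters[ci])
  }
  out
}

#' Tukey-Kramer comparisons with a compact letter display
#'
#' All-pairs comparisons from the studentized-range distribution with
#' unequal-n (Tukey-Kramer) standard errors, via [stats::TukeyHSD()], plus a
#' compact letter display computed by the insert-and-absorb algorithm so that
#' two levels share at least one letter exactly when their adjusted p-value
#' is `>= alpha`.
#'
#' @param anova_result An `hg_anova` object from [anova_oneway()].
#' @param alpha Significance level (defaults to the one recorded in the
#'   ANOVA, 0.05).
#' @return A `tukey_letters` object: `pairs` (level_i, level_j, mean
#'   difference, adjusted p) and `letters` (named character vector, levels in
#'   decreasing mean order).
#' @export
tukey_letters <- function(anova_result, alpha = NULL) {
  stopifnot(inherits(anova_result, "hg_anova"))
  if (is.null(alpha)) alpha <- anova_result$alpha
  tk <- stats::TukeyHSD(anova_result$fit, conf.level = 1 - alpha)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(level_i = vapply(nm, `[`, "", 1),
                      level_j = vapply(nm, `[`, "", 2),
                      diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  tab <- anova_result$table
  lev_ord <- tab$level[order(-tab$mean)]
  sig <- as.matrix(pairs[pairs$p_adj < alpha, c("level_i", "level_j")])
  letters_map <- .cld_insert_absorb(lev_ord, sig)
  structure(list(pairs = pairs, letters = letters_map, alpha = alpha),
            class = "tukey_letters")
}

#' @export
print.tukey_letters <- function(x, ...) {
  cat(sprintf("<tukey_letters> alpha = %.2f\n", x$alpha))
  for (lv in names(x$letters)) cat(sprintf("  %-15s %s\n", lv, x$letters[lv]))
  invisible(x)
}

# Cluster-robust variance helper ---------------------------------------------

# Pseudo-observations within a report share that report's estimated mean, so
# they are not independent; the report is the effective unit of replication.
# CR ("HC1"-type) variances clustered on report_id correct the otherwise
# anti-conservative classical standard errors.
.vcov_for <- function(fit, se, cluster) {
  if (identical(se, "cluster") && !is.null(cluster)) {
    sandwich::vcovCL(fit, cluster = cluster, type = "HC1")
  } else {
    stats::vcov(fit)
  }
}

# Size regression ------------------------------------------------------------

#' Log-scale regression of mercury on fish total length
#'
#' Ordinary least squares of log concentration on total length (cm), fitted
#' per feeding habit. Standard errors are cluster-robust on `report_id` by
#' default because pseudo-observations within a report are correlated;
#' `se = "classical"` reproduces the naive individual-level analysis.
#'
#' @param data Pseudo-observation data frame.
#' @param habit Optional habit subset.
#' @param value,length_col Response and length columns.
#' @param se `"cluster"` or `"classical"`.
#' @return An `hg_sizereg` object: `intercept`, `slope` (per cm, log scale),
#'   `r_squared`, `slope_se`, `p_value`, `n`, `se_type`, and the `lm` fit.
#' @export
size_regression <- function(data, habit = NULL, value = "pseudo_value",
                            length_col = "length_mean_cm",
                            se = c("cluster", "classical")) {
  se <- match.arg(se)
  if (!is.null(habit)) data <- data[data$feeding_habit == habit, , drop = FALSE]
  data <- data[is.finite(data[[length_col]]) & is.finite(data[[value]]), ,
               drop = FALSE]
  if (nrow(data) < 3) stop("need >= 3 observations with finite length",
                           call. = FALSE)
  x <- data[[length_col]]
  if (stats::var(x) == 0) stop("degenerate design: all lengths equal",
                               call. = FALSE)
  y <- log(data[[value]])
  fit <- stats::lm(y ~ x)
  cl <- if ("report_id" %in% names(data)) data$report_id else NULL
  V <- .vcov_for(fit, se, cl)
  slope <- unname(stats::coef(fit)[2])
  slope_se <- sqrt(V[2, 2])
  df <- if (!is.null(cl) && se == "cluster") {
    length(unique(cl)) - 1
  } else {
    fit$df.residual
  }
  p <- 2 * stats::pt(abs(slope / slope_se), df, lower.tail = FALSE)
  structure(list(habit = habit,
                 intercept = unname(stats::coef(fit)[1]), slope = slope,
                 slope_se = slope_se,
                 r_squared = summary(fit)$r.squared,
                 p_value = p, n = nrow(data), se_type = se, fit = fit),
            class = "hg_sizereg")
}

#' @export
print.hg_sizereg <- function(x, ...) {
  cat(sprintf(
    "<hg_sizereg>%s log(Hg) = %.3f %+.4f * length; R2 = %.3f, p = %.3g (n = %d, %s SE)\n",
    if (is.null(x$habit)) "" else paste0(" [", x$habit, "]"),
    x$intercept, x$slope, x$r_squared, x$p_value, x$n, x$se_type))
  invisible(x)
}

# Multiple regression, type III ----------------------------------------------

#' Four-term multiple regression with type III partial R-squared
#'
#' Linear model of (log) Hg concentration on sampling location (ecosystem
#' type), feeding habit, fish size (total length) and water type, with
#' sum-to-zero contrasts for categorical terms. Type III SS per term is
#' `RSS(model without the term) - RSS(full model)`; the partial R-squared is
#' that SS divided by the total SS of the response, so in near-orthogonal
#' designs the partials add up to the multiple R-squared.
#'
#' Market reports are excluded by default: their water type is unrecorded
#' (`"unknown"`), which is perfectly confounded with the market level of the
#' location term and would make the model rank-deficient.
#'
#' @param data Pseudo-observation data frame.
#' @param value Response column (concentrations, ug/g).
#' @param transform `"log"`, `"boxcox"` or `"none"`.
#' @param include_market Keep market reports (their `"unknown"` water level
#'   then enters the water factor; aliasing, if any, is reported by term).
#' @return An `hg_type3` object: `terms` (term, df, type III SS, partial R2,
#'   F, p), `multiple_r2`, `residual_ss`, `total_ss`, `n` and the `lm` fit.
#' @export
multiple_regression_type3 <- function(data, value = "pseudo_value",
                                      transform = c("log", "boxcox", "none"),
                                      include_market = FALSE) {
  transform <- match.arg(transform)
  if (!include_market) {
    data <- data[data$ecosystem_type != "market", , drop = FALSE]
  }
  data <- data[is.finite(data[[value]]) & is.finite(data$length_mean_cm), ,
               drop = FALSE]
  df <- data.frame(
    y = .transform_values(data[[value]], transform),
    location = base::factor(data$ecosystem_type),
    habit = base::factor(data$feeding_habit),
    size = data$length_mean_cm,
    water = base::factor(data$water_type))
  for (term in c("location", "habit", "water")) {
    if (nlevels(df[[term]]) < 2) {
      stop("predictor '", term, "' has < 2 levels", call. = FALSE)
    }
  }
  if (stats::var(df$size) == 0) stop("predictor 'size' is constant",
                                     call. = FALSE)
  if (nrow(df) <= nlevels(df$location) + nlevels(df$water) + 2) {
    stop("n does not exceed the parameter count", call. = FALSE)
  }
  fit <- stats::lm(y ~ location + habit + size + water, data = df,
                   contrasts = list(location = "contr.sum",
                                    habit = "contr.sum",
                                    water = "contr.sum"))
  al <- stats::alias(fit)$Complete
  if (!is.null(al) && nrow(al) > 0) {
    stop("rank-deficient model: aliased term(s): ",
         paste(rownames(al), collapse = ", "), call. = FALSE)
  }
  a3 <- car::Anova(fit, type = "III")
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  total_ss <- sum((df$y - mean(df$y))^2)
  terms_tab <- data.frame(term = rownames(a3)[keep],
                          df = a3$Df[keep],
                          ss = a3$`Sum Sq`[keep],
                          partial_r2 = a3$`Sum Sq`[keep] / total_ss,
                          F = a3$`F value`[keep],
                          p_value = a3$`Pr(>F)`[keep],
                          stringsAsFactors = FALSE)
  rownames(terms_tab) <- NULL
  structure(list(terms = terms_tab,
                 multiple_r2 = summary(fit)$r.squared,
                 residual_ss = a3["Residuals", "Sum Sq"],
                 total_ss = total_ss, n = nrow(df), fit = fit,
                 transform = transform),
            class = "hg_type3")
}

#' @export
print.hg_type3 <- function(x, ...) {
  cat(sprintf("<hg_type3> n = %d, multiple R2 = %.3f (%s scale)\n",
              x$n, x$multiple_r2, x$transform))
  tt <- x$terms
  tt$partial_r2 <- sprintf("%.1f%%", 100 * tt$partial_r2)
  print(tt, row.names = FALSE)
  invisible(x)
}
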