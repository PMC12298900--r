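# ---- Box-Cox ---------------------------------------------------------------

test_that("profile maximum likelihood finds the normalizing power", {
  set.seed(101)
  x <- rlnorm(10000)                       # log-normal: lambda = 0 normalizes
  fit <- boxcox_select(x)
  expect_s3_class(fit, "boxcox_fit")
  expect_true(fit$lambda >= -0.1 && fit$lambda <= 0.1)
  expect_identical(fit$transformed, bc_transform(x, fit$lambda))

  y <- rnorm(10000, 10, 1)                 # already normal: lambda near 1
  fit2 <- boxcox_select(y)
  expect_true(fit2$lambda >= 0.5 && fit2$lambda <= 2)
  # profile is flat around 1: lambda = 1 lies inside the 95% profile interval
  ll1 <- fit2$profile$loglik[fit2$profile$lambda == 1]
  expect_lt(max(fit2$profile$loglik) - ll1, qchisq(0.95, 1) / 2)

  # lambda is the argmax of the returned grid profile
  expect_equal(fit$lambda,
               fit$profile$lambda[which.max(fit$profile$loglik)])
})

test_that("the profile agrees with the closed-form Box-Cox log-likelihood", {
  set.seed(7)
  x <- rlnorm(200, -1, 0.6)
  fit <- boxcox_select(x)
  # independent oracle: -n/2 log(RSS/n) + (lambda - 1) sum(log x), up to a
  # constant shared across lambdas
  oracle <- vapply(fit$profile$lambda, function(l) {
    y <- bc_transform(x, l)
    -length(x) / 2 * log(sum((y - mean(y))^2) / length(x)) +
      (l - 1) * sum(log(x))
  }, 0)
  shift <- fit$profile$loglik - oracle
  expect_lt(max(shift) - min(shift), 1e-6)
})

test_that("degenerate transform inputs are rejected", {
  expect_error(boxcox_select(rep(2, 10)), "constant")
  expect_error(boxcox_select(c(1, 2, -1)), "> 0")
  expect_error(boxcox_select(c(1, 2)), "at least 3")
})

# ---- one-way ANOVA ---------------------------------------------------------

test_that("two balanced groups give F equal to the squared pooled t", {
  d <- make_grouped_pseudo(c(0, 0.4), c(25, 25), sd = 0.5, seed = 3)
  a <- anova_oneway(d, "ecosystem_type", transform = "log")
  tt <- t.test(log(pseudo_value) ~ ecosystem_type, data = d,
               var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 48)
})

test_that("per-level summaries are on the transformed scale", {
  d <- make_grouped_pseudo(c(0, 1), c(10, 12), sd = 0.2, seed = 5)
  a <- anova_oneway(d, "ecosystem_type")
  for (lv in a$table$level) {
    expect_equal(a$table$mean[a$table$level == lv],
                 mean(log(d$pseudo_value[d$ecosystem_type == lv])))
  }
  expect_equal(sum(a$table$n), nrow(d))
})

test_that("an injected lake effect is detected with high power", {
  # lake vs river, effect log(2), residual SD 0.5, 200 per group
  hits <- vapply(1:20, function(s) {
    d <- make_grouped_pseudo(c(0, log(2)), c(200, 200), sd = 0.5, seed = s,
                             levels = c("river", "lake"))
    anova_oneway(d, "ecosystem_type")$p_value < 0.05
  }, NA)
  expect_true(all(hits))
})

test_that("degenerate ANOVA inputs error cleanly", {
  d <- make_grouped_pseudo(c(0), c(10), seed = 1)
  expect_error(anova_oneway(d, "ecosystem_type"), ">= 2 factor levels")
  d2 <- make_grouped_pseudo(c(0, 1), c(8, 8), sd = 0, seed = 1)
  d2$pseudo_value <- exp(rep(c(0, 1), each = 8))
  expect_error(anova_oneway(d2, "ecosystem_type"), "zero within-group")
})

test_that("the water-type analysis drops market (unknown) rows", {
  d <- make_grouped_pseudo(c(0, 0.5, 0.2), c(10, 10, 10), seed = 2,
                           factor_name = "water_type",
                           levels = c("black", "white", "unknown"))
  a <- anova_oneway(d, "water_type")
  expect_setequal(a$table$level, c("black", "white"))
})

# ---- Tukey letters ---------------------------------------------------------

test_that("with two groups the Tukey-adjusted p equals the unadjusted p", {
  d <- make_grouped_pseudo(c(0, 0.3), c(12, 17), sd = 0.4, seed = 9)
  a <- anova_oneway(d, "ecosystem_type")
  tk <- tukey_letters(a)
  tt <- t.test(log(pseudo_value) ~ ecosystem_type, data = d,
               var.equal = TRUE)
  expect_lt(abs(tk$pairs$p_adj - tt$p.value), 1e-8)
})

test_that("fully separated groups receive all-distinct letters", {
  d <- make_grouped_pseudo(c(0, 5, 10), c(15, 15, 15), sd = 0.2, seed = 4)
  lt <- tukey_letters(anova_oneway(d, "ecosystem_type"))
  expect_setequal(unname(lt$letters), c("a", "b", "c"))
})


test_that("two close groups share a letter, a distant one does not", {
  d <- make_grouped_pseudo(c(0, 0.02, 4), c(20, 20, 20), sd = 0.3, seed = 6)
  lt <- tukey_letters(anova_oneway(d, "ecosystem_type"))
  l <- lt$letters
  expect_gt(length(intersect(strsplit(l[["g1"]], "")[[1]],
                             strsplit(l[["g2"]], "")[[1]])), 0)
  expect_length(intersect(strsplit(l[["g1"]], "")[[1]],
                          strsplit(l[["g3"]], "")[[1]]), 0)
  expect_true(cld_oracle_check(lt))
})

test_that("the letter display always satisfies its defining biconditional", {
  # random group configurations, including overlapping chains a/ab/b
  for (s in 1:25) {
    set.seed(s)
    k <- sample(3:5, 1)
    d <- make_grouped_pseudo(cumsum(runif(k, 0, 0.6)),
                             sample(8:25, k, replace = TRUE),
                             sd = 0.4, seed = s + 100)
    lt <- tukey_letters(anova_oneway(d, "ecosystem_type"))
    expect_true(cld_oracle_check(lt))
    expect_true(all(nzchar(lt$letters)))     # letters cover all levels
  }
})

# ---- size regression -------------------------------------------------------

test_that("a noiseless line is fitted exactly", {
  d <- data.frame(report_id = sprintf("r%d", 1:20),
                  pseudo_value = exp(2 + 0.03 * (20:39)),
                  length_mean_cm = 20:39,
                  feeding_habit = "carnivore")
  r <- suppressWarnings(size_regression(d))  # perfect fit trips lm notices
  expect_equal(r$slope, 0.03, tolerance = 1e-10)
  expect_equal(r$intercept, 2, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
})

test_that("degenerate regression designs are rejected", {
  d <- data.frame(report_id = "r1", pseudo_value = exp(c(1, 2, 3)),
                  length_mean_cm = c(30, 30, 30), feeding_habit = "carnivore")
  expect_error(size_regression(d), "all lengths equal")
  expect_error(size_regression(d[1:2, ]), ">= 3 observations")
})

test_that("cluster-robust slope inference widens naive standard errors", {
  # strongly clustered rows: each report contributes many copies of one draw
  set.seed(12)
  n_rep <- 30
  x <- runif(n_rep, 20, 40)
  shared <- rnorm(n_rep, 0, 0.5)
  d <- data.frame(report_id = rep(sprintf("r%02d", 1:n_rep), each = 10),
                  length_mean_cm = rep(x, each = 10),
                  pseudo_value = exp(rep(0.02 * x + shared, each = 10) +
                                       rnorm(n_rep * 10, 0, 0.05)),
                  feeding_habit = "carnivore")
  r_cl <- size_regression(d, se = "cluster")
  r_cls <- size_regression(d, se = "classical")
  expect_gt(r_cl$slope_se, 2 * r_cls$slope_se)
  expect_equal(r_cl$slope, r_cls$slope)      # point estimate unchanged
})

# ---- type III multiple regression ------------------------------------------


test_that("on an orthogonal balanced design partial R2 sums to multiple R2", {
  d <- make_orthogonal_design()
  t3 <- multiple_regression_type3(d)
  expect_equal(sum(t3$terms$partial_r2), t3$multiple_r2, tolerance = 1e-8)
  # and type III SS matches sequential SS there
  fit <- lm(log(pseudo_value) ~ ecosystem_type + feeding_habit +
              length_mean_cm + water_type, data = d)
  seq_ss <- anova(fit)$`Sum Sq`[1:4]
  expect_equal(sort(t3$terms$ss), sort(seq_ss), tolerance = 1e-8)
})

test_that("type III SS equals the drop-one residual-SS increase", {
  # unbalanced data: type III != sequential; verify against manual refits
  set.seed(31)
  gen <- generate_reports(synthetic_config(n_reports = 120, seed = 31))
  ps <- reconstruct(gen$reports, seed = 32)
  t3 <- multiple_regression_type3(ps)
  d <- ps[ps$ecosystem_type != "market", ]
  d <- d[is.finite(d$length_mean_cm), ]
  df <- data.frame(y = log(d$pseudo_value),
                   location = factor(d$ecosystem_type),
                   habit = factor(d$feeding_habit),
                   size = d$length_mean_cm,
                   water = factor(d$water_type))
  ctr <- list(location = "contr.sum", habit = "contr.sum",
              water = "contr.sum")
  full <- lm(y ~ location + habit + size + water, data = df, contrasts = ctr)
  rss <- function(f) sum(residuals(f)^2)
  for (term in c("location", "habit", "size", "water")) {
    red <- suppressWarnings(update(full, as.formula(paste(". ~ . -", term))))
    expect_equal(t3$terms$ss[t3$terms$term == term], rss(red) - rss(full),
                 tolerance = 1e-8)
  }
})

test_that("a truly null term has vanishing partial R2", {
  d <- make_orthogonal_design(sd = 0.4, seed = 41, reps = 40)
  d$pseudo_value <- d$pseudo_value /
    exp(0.3 * (d$water_type == "black"))     # remove the water effect
  t3 <- multiple_regression_type3(d)
  expect_lt(t3$terms$partial_r2[t3$terms$term == "water"], 0.005)
  expect_gt(t3$terms$partial_r2[t3$terms$term == "habit"], 0.1)
})

test_that("invariants hold: nonnegative SS, bounded R2, permutation invariance", {
  gen <- generate_reports(synthetic_config(n_reports = 80, seed = 51))
  ps <- reconstruct(gen$reports, seed = 52)
  t3 <- multiple_regression_type3(ps)
  expect_true(all(t3$terms$ss >= 0))
  expect_true(all(t3$terms$partial_r2 >= 0 & t3$terms$partial_r2 <= 1))
  expect_true(t3$multiple_r2 >= max(t3$terms$partial_r2) &&
                t3$multiple_r2 <= 1)
  perm <- ps[sample(nrow(ps)), ]
  t3p <- multiple_regression_type3(perm)
  expect_equal(t3p$terms$ss, t3$terms$ss, tolerance = 1e-10)
  expect_equal(t3p$multiple_r2, t3$multiple_r2, tolerance = 1e-12)
})

test_that("aliased predictors are reported by name", {
  # keeping market fish makes water 'unknown' an exact copy of the market
  # location level
  gen <- generate_reports(synthetic_config(n_reports = 120, seed = 61))
  ps <- reconstruct(gen$reports, seed = 62)
  expect_error(multiple_regression_type3(ps, include_market = TRUE),
               "aliased|rank")
})
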