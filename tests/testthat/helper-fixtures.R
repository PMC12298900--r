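# Small in-code fixtures shared across test files.

# A minimal valid report data frame (internal column names).
make_report_df <- function(n = 3) {
  genera <- c("Cichla", "Leporinus", "Hoplias", "Schizodon",
              "Plagioscion", "Semaprochilodus")
  g <- genera[((seq_len(n) - 1) %% length(genera)) + 1]
  data.frame(
    report_id = sprintf("T%03d", seq_len(n)),
    study_id = sprintf("S%02d", ((seq_len(n) - 1) %% 2) + 1),
    first_author_year = "Someone 2010",
    genus = g,
    species = NA_character_,
    feeding_habit = unname(genus_habit_map()[g]),
    n_samples = 5L + seq_len(n),
    length_mean_cm = 30 + seq_len(n),
    length_sd_cm = 4,
    weight_mean_g = NA_real_,
    weight_sd_g = NA_real_,
    hg_mean = 0.4 + 0.05 * seq_len(n),
    hg_sd = 0.1,
    ecosystem_type = "river",
    water_type = "black",
    sub_basin = "Madeira",
    country = "Brazil",
    state = NA_character_,
    city = NA_character_,
    sampling_year = "2010",
    latitude = -3.1,
    longitude = -60.0,
    detection_method = "CVAAS",
    stringsAsFactors = FALSE)
}

make_db <- function(n = 3) as_fish_reports(make_report_df(n))

# Pseudo-observation frame built directly (bypassing reconstruction) for
# model unit tests: k groups of a factor with given group means on the log
# scale.
make_grouped_pseudo <- function(means, n_per_group, sd = 0.3, seed = 1,
                                factor_name = "ecosystem_type",
                                levels = NULL) {
  set.seed(seed)
  if (is.null(levels)) levels <- paste0("g", seq_along(means))
  rows <- lapply(seq_along(means), function(i) {
    y <- rnorm(n_per_group[i], means[i], sd)
    data.frame(report_id = sprintf("%s_%03d", levels[i], seq_len(n_per_group[i])),
               pseudo_value = exp(y),
               feeding_habit = "carnivore",
               lv = levels[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "lv"] <- factor_name
  out
}

# brute-force oracle: letters must realize exactly the non-significance
# graph; maximal cliques of that graph are the letter groups
cld_oracle_check <- function(lt) {
  lv <- names(lt$letters)
  share <- outer(lt$letters[lv], lt$letters[lv], Vectorize(function(a, b) {
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
  }))
  nonsig <- diag(length(lv)) == 1
  dimnames(nonsig) <- list(lv, lv)
  for (k in seq_len(nrow(lt$pairs))) {
    i <- lt$pairs$level_i[k]; j <- lt$pairs$level_j[k]
    ns <- lt$pairs$p_adj[k] >= lt$alpha
    nonsig[i, j] <- nonsig[j, i] <- ns
  }
  identical(unname(share), unname(nonsig))
}

make_orthogonal_design <- function(sd = 0.3, seed = 21, reps = 3) {
  # full factorial, balanced, with the numeric size variable symmetric
  # within every cell: all four terms mutually orthogonal
  g <- expand.grid(ecosystem_type = c("river", "lake"),
                   feeding_habit = c("carnivore", "non_carnivore"),
                   water_type = c("black", "clear"),
                   length_mean_cm = c(20, 40),
                   rep = seq_len(reps), stringsAsFactors = FALSE)
  set.seed(seed)
  eta <- 0.5 * (g$ecosystem_type == "lake") +
    1.0 * (g$feeding_habit == "carnivore") +
    0.02 * (g$length_mean_cm - 30) +
    0.3 * (g$water_type == "black")
  g$pseudo_value <- exp(eta + rnorm(nrow(g), 0, sd))
  g$report_id <- sprintf("r%03d", seq_len(nrow(g)))
  g
}
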