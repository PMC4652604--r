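# Classical twin genetic-variance analysis (within-pair and combined
# estimators) and intraclass correlation with a bootstrap null.

#' One-way ANOVA mean squares for twin pairs
#'
#' One-way ANOVA with pair as the grouping factor, two members per
#' pair, computed directly from the sums of squares (the closed form
#' keeps the bootstrap loop fast; it is identical to
#' `anova(lm(values ~ factor(pair)))`): with pair means `m_j` and
#' grand mean `m`, `MS_among = 2 * sum((m_j - m)^2) / (J - 1)` and
#' `MS_within = sum((x_1j - x_2j)^2 / 2) / J` for `J` pairs.
#'
#' @param values numeric vector of member values.
#' @param pair factor/vector of pair identifiers, one per value; every
#'   pair must appear exactly twice.
#' @return list with `ms_among`, `ms_within`, `df_among`, `df_within`,
#'   `n_pairs`.
#' @export
anova_mean_squares <- function(values, pair) {
  stopifnot(length(values) == length(pair), all(is.finite(values)))
  idx <- split(seq_along(values), pair)
  if (any(lengths(idx) != 2L))
    stop("every pair must have exactly two members")
  n_pairs <- length(idx)
  x1 <- values[vapply(idx, `[`, integer(1), 1L)]
  x2 <- values[vapply(idx, `[`, integer(1), 2L)]
  pm <- (x1 + x2) / 2
  grand <- mean(values)
  ms_among <- if (n_pairs > 1) 2 * sum((pm - grand)^2) / (n_pairs - 1)
              else 0
  ms_within <- sum((x1 - x2)^2 / 2) / n_pairs
  list(ms_among = ms_among, ms_within = ms_within,
       df_among = n_pairs - 1L, df_within = n_pairs,
       n_pairs = n_pairs)
}

# Satterthwaite degrees of freedom for a sum of two mean squares.
satterthwaite_df <- function(ms1, df1, ms2, df2) {
  (ms1 + ms2)^2 / (ms1^2 / df1 + ms2^2 / df2)
}

#' Genetic variance analysis of a twin dataset
#'
#' Prerequisites are evaluated first: Kolmogorov-Smirnov goodness of
#' fit to a normal distribution (moments estimated from the sample)
#' within each zygosity group, and a t-test of equal MZ/DZ means;
#' significantly unequal means (at `alpha_prereq`) abort the genetic
#' test, since the variance comparison would be biased. The F' test of
#' equal total variances -- the ratio of the larger to the smaller
#' per-group total mean square `(MS_among + MS_within)`, two-sided with
#' Satterthwaite degrees of freedom -- then selects the estimator at
#' `alpha_fprime`: the combined among-plus-within estimate (GCT) when
#' total variances differ, otherwise the within-pair estimate (GWT).
#' GWT = `MSW_DZ - MSW_MZ`, tested one-sided by
#' `F = MSW_DZ / MSW_MZ`; GCT = `((MSA_MZ + MSW_DZ) - (MSA_DZ +
#' MSW_MZ)) / 2`, tested one-sided by
#' `F = (MSA_MZ + MSW_DZ) / (MSA_DZ + MSW_MZ)` with Satterthwaite
#' degrees of freedom on both composites. Analysis uses per-subject
#' means over nights.
#'
#' @param data twin dataset as from [generate_twin_dataset()]: columns
#'   `pair_id`, `zygosity`, `member`, `night`, `value`.
#' @param alpha_fprime significance level of the F' selection test.
#' @param alpha_prereq significance level of the prerequisite tests.
#' @return object of class `gva_result`: list with `estimator`
#'   (`"GWT"`/`"GCT"`), `estimate`, `genetic_p`, `f_prime_p`,
#'   `ms` (per-zygosity mean squares), `prerequisites` (list with
#'   `ks_p` per zygosity, `means_t_p`, `passed`).
#' @export
gva <- function(data, alpha_fprime = 0.2, alpha_prereq = 0.05) {
  stopifnot(all(c("pair_id", "zygosity", "member", "value") %in%
                  names(data)))
  subj <- stats::aggregate(
    value ~ pair_id + zygosity + member, data = data, FUN = mean)
  groups <- split(subj, subj$zygosity)
  if (!all(c("MZ", "DZ") %in% names(groups)))
    stop("both MZ and DZ groups are required")
  if (any(vapply(groups, function(g) length(unique(g$pair_id)),
                 integer(1)) < 3))
    stop("fewer than 3 pairs in a zygosity group")

  ms <- lapply(groups, function(g) anova_mean_squares(g$value, g$pair_id))
  ks_p <- vapply(groups, function(g) {
    v <- g$value
    suppressWarnings(
      stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
  }, numeric(1))
  means_t_p <- stats::t.test(groups$MZ$value, groups$DZ$value)$p.value
  passed <- all(ks_p > alpha_prereq) && means_t_p > alpha_prereq

  # F' test of equal total variances (two-sided)
  tot_mz <- ms$MZ$ms_among + ms$MZ$ms_within
  tot_dz <- ms$DZ$ms_among + ms$DZ$ms_within
  df_mz <- satterthwaite_df(ms$MZ$ms_among, ms$MZ$df_among,
                            ms$MZ$ms_within, ms$MZ$df_within)
  df_dz <- satterthwaite_df(ms$DZ$ms_among, ms$DZ$df_among,
                            ms$DZ$ms_within, ms$DZ$df_within)
  if (tot_mz >= tot_dz) {
    f_prime_p <- 2 * stats::pf(tot_mz / tot_dz, df_mz, df_dz,
                               lower.tail = FALSE)
  } else {
    f_prime_p <- 2 * stats::pf(tot_dz / tot_mz, df_dz, df_mz,
                               lower.tail = FALSE)
  }
  f_prime_p <- min(1, f_prime_p)
  use_gct <- f_prime_p < alpha_fprime

  estimate <- genetic_p <- NA_real_
  if (passed) {
    if (use_gct) {
      num <- ms$MZ$ms_among + ms$DZ$ms_within
      den <- ms$DZ$ms_among + ms$MZ$ms_within
      estimate <- (num - den) / 2
      dfn <- satterthwaite_df(ms$MZ$ms_among, ms$MZ$df_among,
                              ms$DZ$ms_within, ms$DZ$df_within)
      dfd <- satterthwaite_df(ms$DZ$ms_among, ms$DZ$df_among,
                              ms$MZ$ms_within, ms$MZ$df_within)
      genetic_p <- stats::pf(num / den, dfn, dfd, lower.tail = FALSE)
    } else {
      estimate <- ms$DZ$ms_within - ms$MZ$ms_within
      genetic_p <- stats::pf(ms$DZ$ms_within / ms$MZ$ms_within,
                             ms$DZ$df_within, ms$MZ$df_within,
                             lower.tail = FALSE)
    }
  }
  structure(list(estimator = if (use_gct) "GCT" else "GWT",
                 estimate = estimate, genetic_p = genetic_p,
                 f_prime_p = f_prime_p,
                 ms = list(MZ = ms$MZ, DZ = ms$DZ),
                 prerequisites = list(ks_p = ks_p,
                                      means_t_p = means_t_p,
                                      passed = passed)),
            class = "gva_result")
}

#' @export
print.gva_result <- function(x, ...) {
  cat(sprintf(
    "<gva_result> estimator=%s estimate=%.4g genetic_p=%.4g f_prime_p=%.4g prerequisites %s\n",
    x$estimator, x$estimate, x$genetic_p, x$f_prime_p,
    if (x$prerequisites$passed) "passed" else "FAILED"))
  invisible(x)
}

#' Intraclass correlation for groups of two
#'
#' One-way random-effects ICC,
#' `(MS_among - MS_within) / (MS_among + MS_within)` for groups of
#' size 2: within-pair resemblance when the group is the twin pair,
#' night-to-night stability when the group is the subject.
#'
#' @param values numeric member values.
#' @param group group identifier per value (each appearing twice).
#' @return ICC in `[-1, 1]`.
#' @export
icc <- function(values, group) {
  ms <- anova_mean_squares(values, group)
  tot <- ms$ms_among + ms$ms_within
  if (tot <= 0) stop("degenerate sample: no variance for ICC")
  (ms$ms_among - ms$ms_within) / tot
}

#' Bootstrap null distribution for the ICC
#'
#' Recreates samples by drawing subject values randomly with
#' replacement up to the original sample size, breaking the pair
#' structure, forming consecutive pseudo-pairs and computing the ICC.
#' Only positive bootstrap ICCs are accepted; sampling continues until
#' `n_positive` of them are collected. Reports the top 1/100th
#' percentile (the P = 0.01 significance threshold) and the median
#' (the positive ICC expected by chance).
#'
#' @param values flattened numeric sample (an even count).
#' @param n_positive number of positive bootstrap ICCs to collect.
#' @param seed integer seed.
#' @param max_draws iteration cap on total bootstrap draws.
#' @return object of class `icc_boot`: list with `boot_p01`,
#'   `boot_median`, `n_positive`, `n_draws`.
#' @export
bootstrap_icc_null <- function(values, n_positive = 1000, seed = 1L,
                               max_draws = 1e6) {
  n <- length(values)
  stopifnot(n >= 4, n %% 2 == 0)
  if (stats::sd(values) == 0)
    stop("degenerate sample: constant values, ICC undefined")
  set.seed(as.integer(seed))
  kept <- numeric(n_positive)
  got <- 0L
  draws <- 0L
  grp <- rep(seq_len(n / 2), each = 2)
  while (got < n_positive) {
    draws <- draws + 1L
    if (draws > max_draws)
      stop("bootstrap iteration cap reached before ", n_positive,
           " positive ICCs")
    v <- sample(values, n, replace = TRUE)
    if (stats::sd(v) == 0) next
    r <- icc(v, grp)
    if (r > 0) {
      got <- got + 1L
      kept[got] <- r
    }
  }
  structure(list(boot_p01 = unname(stats::quantile(kept, 0.99)),
                 boot_median = stats::median(kept),
                 n_positive = n_positive, n_draws = draws),
            class = "icc_boot")
}

#' @export
print.icc_boot <- function(x, ...) {
  cat(sprintf(
    "<icc_boot> P=0.01 threshold %.3f, chance median %.3f (%d positive ICCs in %d draws)\n",
    x$boot_p01, x$boot_median, x$n_positive, x$n_draws))
  invisible(x)
}

#' Within-pair and night-to-night ICCs of a twin dataset
#'
#' Within-pair resemblance uses night-averaged subject values grouped
#' by pair; night-to-night stability uses the two nightly values
#' grouped by subject. Bootstrap thresholds accompany each ICC.
#'
#' @param data twin dataset (see [gva()]).
#' @param zygosity which group to analyse, `"MZ"` or `"DZ"`.
#' @param n_positive bootstrap positives to collect.
#' @param seed integer seed.
#' @return list with `within_pair` and `night_stability`, each a list
#'   of `icc`, `label`, `boot` (an `icc_boot`).
#' @export
twin_icc_analysis <- function(data, zygosity = c("MZ", "DZ"),
                              n_positive = 1000, seed = 1L) {
  zygosity <- match.arg(zygosity)
  d <- data[data$zygosity == zygosity, , drop = FALSE]
  if (!nrow(d)) stop("no rows for zygosity ", zygosity)
  subj <- stats::aggregate(value ~ pair_id + member, data = d,
                           FUN = mean)
  icc_wp <- icc(subj$value, subj$pair_id)
  boot_wp <- bootstrap_icc_null(subj$value, n_positive, seed)
  subj_id <- interaction(d$pair_id, d$member, drop = TRUE)
  icc_nn <- icc(d$value, subj_id)
  boot_nn <- bootstrap_icc_null(d$value, n_positive, seed + 1L)
  list(within_pair = list(icc = icc_wp,
                          label = landis_koch_label(icc_wp),
                          boot = boot_wp),
       night_stability = list(icc = icc_nn,
                              label = landis_koch_label(icc_nn),
                              boot = boot_nn))
}
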