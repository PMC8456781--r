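#' Integrin activity index from fibronectin-fragment binding
#'
#' \code{AI = (F - F_EDTA) / F_PB1}: fibronectin-fragment (FN7-10) binding,
#' background-corrected by the signal in EDTA-treated cells (EDTA chelates the
#' cations integrins need, abolishing ligand binding), normalized to total
#' \eqn{\alpha}5 integrin surface level (antibody PB1).
#'
#' @param F mean (or median) FN7-10 signal of the gated population.
#' @param F_EDTA FN7-10 signal in EDTA-treated cells.
#' @param F_PB1 total \eqn{\alpha}5 integrin signal (> 0).
#' @return the activity index, vectorized.
#' @export
#' @examples
#' activity_index_fn(300, 100, 400)  # 0.5
activity_index_fn <- function(F, F_EDTA, F_PB1) {
  if (any(F_PB1 <= 0)) stopf("'F_PB1' must be > 0")
  (F - F_EDTA) / F_PB1
}

#' Integrin activity index from conformation-specific antibodies
#'
#' \code{IA = (F_9EG7 - F_2ndAb) / (F_P5D2 - F_2ndAb)}: active \eqn{\beta}1
#' integrin (antibody 9EG7) over total \eqn{\beta}1 (antibody P5D2), both
#' corrected for secondary-antibody-only background.
#'
#' @param F_9EG7 active-\eqn{\beta}1 signal.
#' @param F_P5D2 total-\eqn{\beta}1 signal.
#' @param F_2ndAb secondary-only background signal.
#' @return the activity index, vectorized.
#' @export
#' @examples
#' activity_index_9eg7(900, 1700, 100)  # 0.5
activity_index_9eg7 <- function(F_9EG7, F_P5D2, F_2ndAb) {
  if (any(F_P5D2 - F_2ndAb <= 0)) {
    stopf("total staining (F_P5D2) must exceed the secondary-only background")
  }
  (F_9EG7 - F_2ndAb) / (F_P5D2 - F_2ndAb)
}

#' Per-condition stain summaries from a gated flow table
#'
#' @param flow data.frame with columns \code{stain}, \code{intensity} (e.g.
#'   from \code{\link{make_flow_population}} or \code{\link{read_flow}}).
#' @param statistic \code{"mean"} or \code{"median"} per stain.
#' @return named numeric vector of per-stain summaries.
#' @export
flow_summaries <- function(flow, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "mean") mean else median
  vapply(split(flow$intensity, flow$stain), fun, numeric(1))
}

#' Rectangular gate for synthetic flow populations
#'
#' Keeps cells whose intensity in every listed stain lies inside
#' \code{[min, max]}. Real gating happens upstream in acquisition software;
#' this utility only serves synthetic data.
#'
#' @param flow long data.frame (\code{cell_id}, \code{stain},
#'   \code{intensity}).
#' @param gates named list of \code{c(min, max)} per stain.
#' @return the gated subset of \code{flow}.
#' @export
rectangular_gate <- function(flow, gates) {
  keep_ids <- unique(flow$cell_id)
  for (st in names(gates)) {
    g <- gates[[st]]
    sub <- flow[flow$stain == st, ]
    ok <- sub$cell_id[sub$intensity >= g[1] & sub$intensity <= g[2]]
    keep_ids <- intersect(keep_ids, ok)
  }
  flow[flow$cell_id %in% keep_ids, ]
}

#' Relative expression by the 2^-ddCt method
#'
#' \deqn{2^{-((Ct_{gene,sample} - Ct_{ref,sample}) - (Ct_{gene,control} - Ct_{ref,control}))}}
#'
#' @param ct data.frame with columns \code{gene}, \code{sample}, \code{ct}.
#' @param gene gene of interest.
#' @param sample sample (condition) of interest.
#' @param control control condition.
#' @param reference_gene normalization gene (default \code{"GAPDH"}).
#' @return fold change relative to the control condition.
#' @export
#' @examples
#' ct <- data.frame(gene = rep(c("MYO10", "GAPDH"), 2),
#'                  sample = rep(c("si", "ctrl"), each = 2),
#'                  ct = c(24, 18, 26, 18))
#' relative_expression_ddct(ct, "MYO10", "si", "ctrl")  # 4
relative_expression_ddct <- function(ct, gene, sample, control,
                                     reference_gene = "GAPDH") {
  get_ct <- function(g, s) {
    v <- ct$ct[ct$gene == g & ct$sample == s]
    if (length(v) != 1 || is.na(v)) {
      stopf("missing or ambiguous Ct for gene '%s' in sample '%s'", g, s)
    }
    v
  }
  d_sample <- get_ct(gene, sample) - get_ct(reference_gene, sample)
  d_control <- get_ct(gene, control) - get_ct(reference_gene, control)
  2^-(d_sample - d_control)
}

group_stat <- function(statistic) {
  switch(statistic, mean = mean, median = median,
         stopf("unknown statistic '%s'", statistic))
}

#' Randomization (permutation) test for a two-group difference
#'
#' The observed statistic is \code{stat(a) - stat(b)}. Group labels are
#' permuted preserving group sizes; the two-sided Monte-Carlo p-value uses
#' the add-one correction \eqn{p = (1 + \#\{|s^*| \ge |s|\}) / (n + 1)}.
#' With \code{exact = TRUE} all \code{choose(n_a + n_b, n_a)} label
#' assignments are enumerated instead and the p-value is the exact fraction
#' \eqn{\#\{|s^*| \ge |s|\} / \binom{n}{n_a}}.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @param n_resamples number of label permutations (default 1000).
#' @param statistic \code{"mean"} (default) or \code{"median"}.
#' @param exact enumerate all assignments (feasible for small samples).
#' @param seed integer seed.
#' @return list with \code{p}, \code{observed}, \code{n_resamples},
#'   \code{statistic}, \code{exact}.
#' @export
#' @examples
#' randomization_test(c(1, 2, 3), c(101, 102, 103), exact = TRUE)$p  # 0.1
randomization_test <- function(group_a, group_b, n_resamples = 1000,
                               statistic = c("mean", "median"),
                               exact = FALSE, seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stopf("both groups need n >= 2")
  }
  if (!exact && n_resamples < 1) stopf("'n_resamples' must be >= 1")
  fun <- group_stat(statistic)
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  n <- length(pooled)
  s_obs <- fun(group_a) - fun(group_b)
  if (exact) {
    combos <- utils::combn(n, na)
    s_null <- apply(combos, 2, function(ix) fun(pooled[ix]) - fun(pooled[-ix]))
    p <- mean(abs(s_null) >= abs(s_obs) - 1e-12)
    return(list(p = p, observed = s_obs, n_resamples = ncol(combos),
                statistic = statistic, exact = TRUE))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_resamples), function(i) {
      ix <- sample.int(n, na)
      abs(fun(pooled[ix]) - fun(pooled[-ix])) >= abs(s_obs) - 1e-12
    }, logical(1)))
  })
  list(p = (1 + exceed) / (n_resamples + 1), observed = s_obs,
       n_resamples = n_resamples, statistic = statistic, exact = FALSE)
}

#' Bootstrap effect size for a two-group difference
#'
#' Difference of group means (or medians) with a percentile bootstrap
#' confidence interval from independent within-group resampling.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param statistic \code{"mean"} (default) or \code{"median"}.
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with \code{difference}, \code{ci} (length-2), \code{conf},
#'   \code{statistic}, \code{n_boot}.
#' @export
effect_size <- function(group_a, group_b, n_boot = 1000,
                        statistic = c("mean", "median"), conf = 0.95,
                        seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stopf("both groups need n >= 2")
  }
  if (n_boot < 1) stopf("'n_boot' must be >= 1")
  fun <- group_stat(statistic)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      fun(sample(group_a, replace = TRUE)) -
        fun(sample(group_b, replace = TRUE))
    }, numeric(1))
  })
  ci <- unname(quantile(diffs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        type = 7))
  list(difference = fun(group_a) - fun(group_b), ci = ci, conf = conf,
       statistic = statistic, n_boot = n_boot)
}

#' Tukey boxplot summary
#'
#' Median and quartiles by linear interpolation (quantile type 7, the rule
#' used by ggplot2 boxplots), whiskers at the most extreme data points within
#' 1.5 IQR of the quartiles, and points beyond the whiskers flagged as
#' outliers.
#'
#' @param values numeric vector, n >= 1.
#' @return list with \code{median}, \code{q1}, \code{q3}, \code{whisker_low},
#'   \code{whisker_high}, \code{outliers}.
#' @export
#' @examples
#' tukey_summary(1:7)
tukey_summary <- function(values) {
  if (!length(values)) stopf("'values' must be non-empty")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = values[!inside])
}
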