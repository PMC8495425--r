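# Group-level statistics for diffusion-coefficient comparisons: ECDFs,
# Kolmogorov-Smirnov and Mann-Whitney tests, Kruskal-Wallis with Dunn's
# post hoc, percent-of-vehicle normalization and summary tables.

#' Empirical cumulative distribution of diffusion coefficients
#'
#' Right-continuous ECDF as plotted value/fraction pairs (the cumulative
#' probability representation of a group's D values).
#'
#' @param values Numeric sample (n >= 1).
#' @return List: \code{values} (sorted), \code{fractions} (ending at 1).
#' @export
ecdf_curve <- function(values) {
  x <- as.numeric(values)
  if (length(x) == 0L) stop("ECDF of an empty sample", call. = FALSE)
  s <- sort(x)
  list(values = s, fractions = seq_along(s) / length(s))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Statistic \eqn{D = \sup_x |ECDF_a(x) - ECDF_b(x)|} with the asymptotic
#' two-sided p-value.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return List: \code{D_stat}, \code{p}.
#' @export
ks_compare <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D_stat = unname(ht$statistic), p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' U statistic with midrank ties; exact two-sided p when both samples are
#' small (min n <= 8) and tie-free, normal approximation otherwise.
#'
#' @param a,b Numeric samples (each n >= 1).
#' @return List: \code{U} (for sample a), \code{p}.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 8L && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across >= 3 groups, followed by Dunn's
#' pairwise z statistics on the pooled midranks,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(\frac{N(N+1)}{12} -
#'   \frac{\sum(t^3 - t)}{12(N-1)})(\frac1{n_i} + \frac1{n_j})}}
#' with multiplicity adjustment of the two-sided p-values (Holm by
#' default).
#'
#' @param groups Named list of numeric samples (>= 3 groups, each n >= 2).
#' @param alpha Significance level for the \code{significant} flag.
#' @param adjust \code{"holm"} (default), \code{"bonferroni"} or
#'   \code{"none"}.
#' @return List: \code{H}, \code{p} (omnibus), \code{pairwise} data.frame
#'   (\code{group1}, \code{group2}, \code{z}, \code{p_raw}, \code{p_adj},
#'   \code{significant}).
#' @export
kruskal_dunn <- function(groups, alpha = 0.05,
                         adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 3L)
    stop("kruskal_dunn needs at least 3 groups", call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  ht <- stats::kruskal.test(x, g)
  rk <- rank(x)
  N <- length(x)
  rbar <- tapply(rk, g, mean)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(s2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  list(H = unname(ht$statistic), p = ht$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = z, p_raw = p_raw, p_adj = p_adj,
                             significant = p_adj < alpha,
                             stringsAsFactors = FALSE))
}

#' Express a treated sample as percent of the vehicle mean
#'
#' Each treated value is divided by the vehicle group's mean and scaled to
#' percent; the summary is mean and SEM of the scaled values
#' (vehicle-mean uncertainty deliberately not propagated, matching the
#' usual percent-of-control plotting convention).
#'
#' @param treated Numeric sample.
#' @param vehicle Numeric control sample with positive mean.
#' @return List: \code{percent_mean}, \code{percent_sem}, \code{values}
#'   (scaled sample).
#' @export
percent_of_vehicle <- function(treated, vehicle) {
  vm <- mean(vehicle)
  if (!is.finite(vm) || vm <= 0)
    stop("vehicle mean must be positive", call. = FALSE)
  v <- treated / vm * 100
  n <- length(v)
  list(percent_mean = mean(v),
       percent_sem = if (n > 1L) stats::sd(v) / sqrt(n) else 0,
       values = v)
}

#' Summary statistics of one group of D values
#'
#' @param values Numeric sample (n >= 1).
#' @param label Group label.
#' @return One-row data.frame: \code{group}, \code{n}, \code{mean},
#'   \code{sem} (sd/sqrt(n); 0 with \code{single_value} flag at n = 1),
#'   \code{median}, \code{q25}, \code{q75} (linear-interpolation
#'   quartiles).
#' @export
group_summary <- function(values, label = "") {
  x <- as.numeric(values)
  n <- length(x)
  if (n == 0L) stop("empty group", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(group = label, n = n, mean = mean(x),
             sem = if (n > 1L) stats::sd(x) / sqrt(n) else 0,
             median = q[2], q25 = q[1], q75 = q[3],
             single_value = n == 1L,
             stringsAsFactors = FALSE)
}

#' Two-condition diffusion comparison report
#'
#' Runs the standard comparison between two groups of per-trajectory D
#' estimates: group summaries, ECDFs, the KS test, the Mann-Whitney test,
#' and the treated group as percent of vehicle.
#'
#' @param vehicle,treated Numeric vectors of QC-passed D values.
#' @param labels Character pair naming the groups.
#' @return List with \code{summary} (two-row data.frame), \code{ks},
#'   \code{mann_whitney}, \code{percent_of_vehicle}, \code{ecdf} (named
#'   list of two curves).
#' @export
compare_conditions <- function(vehicle, treated,
                               labels = c("vehicle", "treated")) {
  list(summary = rbind(group_summary(vehicle, labels[1]),
                       group_summary(treated, labels[2])),
       ks = ks_compare(vehicle, treated),
       mann_whitney = mann_whitney(vehicle, treated),
       percent_of_vehicle = percent_of_vehicle(treated, vehicle),
       ecdf = stats::setNames(list(ecdf_curve(vehicle), ecdf_curve(treated)),
                              labels))
}
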