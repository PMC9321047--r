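## Cross-focus, result-level statistics: volume-vs-movement regressions,
## aggregate-count summaries, two-group distribution comparisons, and
## prion induction frequencies. p-values are reported unadjusted by
## default (matching pairwise-test practice for this kind of dataset);
## an optional Holm adjustment helper is provided for users.

#' Regression of movement parameters on focus volume
#'
#' Ordinary least-squares regression of a movement-model parameter
#' (directional correlation gamma or movement variability sigma) on focus
#' volume or focus:cell volume ratio, with a two-sided test of the slope.
#' A positive gamma-vs-volume slope indicates larger foci move less
#' randomly; a negative sigma-vs-volume slope indicates larger foci move
#' less variably.
#'
#' @param x volumes or volume ratios (finite, nonconstant).
#' @param y movement parameter values, same length.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
volume_movement_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  if (stats::var(x) == 0) stop("zero variance in x: regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- stats::coef(sm)
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_value = unname(co["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Summarise aggregate counts per group
#'
#' For each group (strain), the percentage of cells carrying exactly one
#' aggregate, the mean count, and the full count distribution.
#'
#' @param counts a `count_table` (see [read_counts()] /
#'   [simulate_aggregate_counts()]).
#' @return data frame with one row per group: `group`, `n_cells`,
#'   `percent_single`, `percent_multiple`, `mean_count`; the per-group
#'   count distributions are attached as the `"distribution"` attribute
#'   (a named list of tables).
#' @export
aggregate_count_summary <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("group", "n_aggregates") %in% names(counts)))
  if (nrow(counts) == 0) stop("empty count table")
  groups <- split(counts$n_aggregates, counts$group)
  if (any(!vapply(groups, length, integer(1)))) stop("empty group")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    n <- groups[[g]]
    data.frame(group = g, n_cells = length(n),
               percent_single = 100 * mean(n == 1),
               percent_multiple = 100 * mean(n != 1),
               mean_count = mean(n))
  }))
  attr(out, "distribution") <- lapply(groups, table)
  out
}

#' Two-group distribution comparison
#'
#' Two-sided comparison of two samples by Welch's t-test (default; unequal
#' variances), a paired t-test, or the Kolmogorov-Smirnov test (sensitive
#' to spread as well as location). This delegates to the standard
#' implementations in \pkg{stats}.
#'
#' @param a,b numeric samples; `paired_t` requires equal lengths.
#' @param method `"welch_t"`, `"paired_t"` or `"ks"`.
#' @return list with `method`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
group_comparison <- function(a, b, method = c("welch_t", "paired_t", "ks")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  res <- switch(method,
    welch_t = stats::t.test(a, b, var.equal = FALSE),
    paired_t = {
      if (length(a) != length(b))
        stop("paired_t requires samples of equal length")
      if (stats::sd(a - b) <= 1e-12 * max(abs(a - b), 1))
        stop("degenerate paired samples: zero within-pair variance")
      stats::t.test(a, b, paired = TRUE)
    },
    ks = suppressWarnings(stats::ks.test(a, b)))
  list(method = method, statistic = unname(res$statistic),
       p_value = res$p.value, n_a = length(a), n_b = length(b))
}

#' Holm adjustment for a set of comparison p-values
#'
#' @param p_values numeric vector of unadjusted p-values.
#' @return adjusted p-values (Holm step-down).
#' @export
adjust_p_values <- function(p_values) stats::p.adjust(p_values, "holm")

#' Prion induction frequency from plate counts
#'
#' The induction frequency is the number of colonies on the selective
#' plate divided by the total number of cells plated there, i.e.
#' `colonies_selective / (cfu_total * density_factor)`, where `cfu_total`
#' counts colony-forming units on the permissive plate and the selective
#' plate received a `density_factor`-fold higher cell density.
#'
#' @param colonies_selective colony count on the selective plate (>= 0).
#' @param cfu_total CFU count on the permissive plate (> 0).
#' @param density_factor fold excess of cells plated selectively
#'   (default 100).
#' @param group label.
#' @return object of class `induction_count`: list with the counts and the
#'   derived `frequency`.
#' @export
induction_frequency <- function(colonies_selective, cfu_total,
                                density_factor = 100, group = NA_character_) {
  if (any(cfu_total <= 0)) stop("cfu_total must be positive")
  if (any(colonies_selective < 0)) stop("colony counts must be >= 0")
  structure(list(group = as.character(group),
                 colonies_selective = colonies_selective,
                 cfu_total = cfu_total, density_factor = density_factor,
                 frequency = colonies_selective /
                   (cfu_total * density_factor)),
            class = "induction_count")
}

#' @export
print.induction_count <- function(x, ...) {
  cat(sprintf(
    "<induction_count> %s: %d colonies / (%g CFU x %g) = frequency %.4g\n",
    x$group, x$colonies_selective, x$cfu_total, x$density_factor,
    x$frequency))
  invisible(x)
}

#' @export
as.data.frame.induction_count <- function(x, ...) {
  data.frame(group = x$group, colonies_selective = x$colonies_selective,
             cfu_total = x$cfu_total, density_factor = x$density_factor,
             frequency = x$frequency)
}

#' Fold change between two induction frequencies
#'
#' Ratio of frequencies (or of mean frequencies when several platings per
#' group are given), `a / b`.
#'
#' @param a,b `induction_count` objects, bare frequencies, or vectors of
#'   frequencies to be averaged.
#' @param average averaging convention across platings: `"mean"` (default)
#'   or `"median"` (robust to rare very high frequencies).
#' @return dimensionless fold change.
#' @export
induction_fold_change <- function(a, b, average = c("mean", "median")) {
  average <- match.arg(average)
  get_f <- function(z) {
    if (inherits(z, "induction_count")) z <- z$frequency
    do.call(average, list(as.numeric(z)))
  }
  fa <- get_f(a); fb <- get_f(b)
  if (fb == 0) stop("reference frequency is zero")
  fa / fb
}
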