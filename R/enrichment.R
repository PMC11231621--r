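#' 2x2 contingency table for a boolean property and a cluster
#'
#' Rows are in/out of the target cluster, columns YES/NO. Missing property
#' values are dropped before tallying, so the cells sum to the non-missing n.
#'
#' @param labels Tibble (`nurse_id`, `cluster`).
#' @param values Logical vector (or tibble with `nurse_id` and a logical
#'   column `value`) aligned with `labels`.
#' @param cluster Target cluster index.
#' @return A 2x2 integer matrix with dimnames in/out x YES/NO.
#' @export
contingency_table <- function(labels, values, cluster) {
  if (is.data.frame(values)) {
    values <- values$value[match(labels$nurse_id, values$nurse_id)]
  }
  stopifnot(length(values) == nrow(labels))
  keep <- !is.na(values)
  if (!any(keep)) stop("all property values are missing", call. = FALSE)
  v <- values[keep]
  inside <- labels$cluster[keep] == cluster
  if (!any(inside)) stop("cluster ", cluster, " is empty", call. = FALSE)
  matrix(c(sum(inside & v), sum(inside & !v),
           sum(!inside & v), sum(!inside & !v)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("in", "out"), c("YES", "NO")))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables whose point probability does not exceed the observed table's.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(abs(table - round(table)) > 1e-9)) {
    stop("contingency cells must be nonnegative integers", call. = FALSE)
  }
  stats::fisher.test(round(table))$p.value
}

#' Seeded permutation test for a numeric property
#'
#' Tests whether the in-cluster mean differs from the out-cluster mean:
#' statistic |mean_in - mean_out|, null generated by permuting the in/out
#' flags, p = (1 + #\{permuted >= observed\}) / (n_perm + 1). Exact-valid and
#' assumption-light; deterministic given `seed`.
#'
#' @param values Numeric vector (missing values dropped with their flags).
#' @param in_cluster Logical vector, same length as `values`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return p-value in (0, 1].
#' @export
permutation_test_numeric <- function(values, in_cluster, n_perm = 999L,
                                     seed = 1L) {
  stopifnot(length(values) == length(in_cluster))
  keep <- !is.na(values) & !is.na(in_cluster)
  values <- values[keep]; in_cluster <- in_cluster[keep]
  if (sum(in_cluster) < 2L || sum(!in_cluster) < 2L) {
    stop("need at least 2 non-missing values on each side", call. = FALSE)
  }
  obs <- abs(mean(values[in_cluster]) - mean(values[!in_cluster]))
  n_in <- sum(in_cluster)
  withr::with_seed(seed, {
    exceed <- sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(values), n_in)
      abs(mean(values[idx]) - mean(values[-idx])) >= obs - 1e-12
    }, logical(1)))
  })
  (1 + exceed) / (n_perm + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted q-values; the enrichment report is a screen across
#' many cluster-by-property tests, so FDR (not FWER) is controlled.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return q-values, elementwise >= p, clipped to 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Per-cluster enrichment/depletion report
#'
#' For every (cluster, static property) pair, quantifies whether the cluster
#' is enriched or depleted of the property relative to the rest of the
#' cohort. Boolean properties use the Fisher exact test on the YES
#' proportion; categorical properties are tested one-vs-rest per level (so
#' each level has its own enriched/depleted verdict); numeric properties use
#' the seeded permutation test on the mean. Effects are plain differences
#' (in-cluster minus out-cluster proportion or mean); direction is
#' "enriched" when the effect is positive, with a zero effect reported as
#' enriched by a fixed tie rule. BH adjustment runs across the full result
#' set.
#'
#' @param clustering An `rn_clustering` covering the cohort.
#' @param cohort An `rn_cohort`.
#' @param n_perm Permutations for numeric properties.
#' @param seed Base seed; each numeric test uses a distinct offset so
#'   permutations are independent across tests yet reproducible.
#' @return A tibble of class `rn_enrichment`, sorted by q: columns `cluster`,
#'   `family`, `element`, `level` (NA unless categorical), `effect`,
#'   `direction`, `p`, `q`, `n_in`, `n_out`.
#' @export
enrichment_report <- function(clustering, cohort, n_perm = 999L, seed = 1L) {
  labels <- clustering$labels
  missing_ids <- setdiff(cohort$ntype$nurse_id, labels$nurse_id)
  if (length(missing_ids)) {
    stop("clustering does not cover nurse id(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  tests <- list()
  test_i <- 0L
  for (fam in c("ntype", "npanel", "noutcome")) {
    tbl <- cohort[[fam]]
    tbl <- tbl[match(labels$nurse_id, tbl$nurse_id), ]
    schema <- cohort$schemas[[fam]]
    for (j in seq_len(schema_dim(schema))) {
      el <- schema$elements$element[j]
      type <- schema$elements$type[j]
      col <- tbl[[el]]
      for (cl in sort(unique(labels$cluster))) {
        inside <- labels$cluster == cl
        if (type %in% c("integer", "real")) {
          test_i <- test_i + 1L
          tests[[length(tests) + 1L]] <- numeric_test(
            col, inside, cl, fam, el, NA_character_, n_perm, seed + test_i)
        } else if (type == "boolean") {
          tests[[length(tests) + 1L]] <- boolean_test(col, inside, cl, fam, el,
                                                      NA_character_)
        } else {  # categorical: one-vs-rest per observed level
          for (lv in sort(unique(stats::na.omit(col)))) {
            tests[[length(tests) + 1L]] <- boolean_test(col == lv, inside, cl,
                                                        fam, el, lv)
          }
        }
      }
    }
  }
  res <- dplyr::bind_rows(tests)
  testable <- !is.na(res$p)
  res$q <- NA_real_
  res$q[testable] <- bh_adjust(res$p[testable])
  res <- dplyr::arrange(res, .data$q, .data$p)
  class(res) <- c("rn_enrichment", class(res))
  res
}

boolean_test <- function(flags, inside, cl, fam, el, level) {
  keep <- !is.na(flags)
  n_in <- sum(keep & inside); n_out <- sum(keep & !inside)
  if (n_in == 0L || n_out == 0L) {
    return(enrichment_row(cl, fam, el, level, NA_real_, NA_character_,
                          NA_real_, n_in, n_out))
  }
  p_in <- sum(flags[inside], na.rm = TRUE) / n_in
  p_out <- sum(flags[!inside], na.rm = TRUE) / n_out
  effect <- p_in - p_out
  tab <- matrix(c(sum(keep & inside & flags), sum(keep & inside & !flags),
                  sum(keep & !inside & flags), sum(keep & !inside & !flags)),
                nrow = 2, byrow = TRUE)
  enrichment_row(cl, fam, el, level, effect,
                 if (effect >= 0) "enriched" else "depleted",
                 fisher_exact_p(tab), n_in, n_out)
}

numeric_test <- function(values, inside, cl, fam, el, level, n_perm, seed) {
  keep <- !is.na(values)
  n_in <- sum(keep & inside); n_out <- sum(keep & !inside)
  if (n_in < 2L || n_out < 2L) {
    return(enrichment_row(cl, fam, el, level, NA_real_, NA_character_,
                          NA_real_, n_in, n_out))
  }
  effect <- mean(values[inside], na.rm = TRUE) - mean(values[!inside], na.rm = TRUE)
  p <- permutation_test_numeric(values, inside, n_perm, seed)
  enrichment_row(cl, fam, el, level, effect,
                 if (effect >= 0) "enriched" else "depleted", p, n_in, n_out)
}

enrichment_row <- function(cl, fam, el, level, effect, direction, p,
                           n_in, n_out) {
  tibble::tibble(cluster = as.integer(cl), family = fam, element = el,
                 level = level, effect = effect, direction = direction,
                 p = p, q = NA_real_, n_in = as.integer(n_in),
                 n_out = as.integer(n_out))
}

#' Cluster-conditional outcome rates (baseline predictor)
#'
#' The simplest predictive model the clustering supports: a new nurse's
#' expected outcome is the empirical rate of their assigned cluster. For
#' boolean outcomes the per-cluster YES rate gets a Wilson 95% interval; for
#' numeric outcomes the per-cluster mean gets a normal-approximation
#' interval.
#'
#' @param clustering An `rn_clustering`.
#' @param cohort An `rn_cohort`.
#' @param element Outcome element name (defaults to a boolean element of the
#'   NOutcome schema).
#' @param family Family the element lives in (default `"noutcome"`).
#' @param conf_level Interval coverage.
#' @return Tibble (`cluster`, `n`, `rate`, `ci_lo`, `ci_hi`); clusters with no
#'   non-missing value carry `NA` rates.
#' @export
cluster_conditional_rates <- function(clustering, cohort, element,
                                      family = "noutcome", conf_level = 0.95) {
  tbl <- cohort[[family]]
  schema <- cohort$schemas[[family]]
  stopifnot(element %in% schema$elements$element)
  type <- schema$elements$type[schema$elements$element == element]
  labels <- clustering$labels
  vals <- tbl[[element]][match(labels$nurse_id, tbl$nurse_id)]
  purrr::map_dfr(sort(unique(labels$cluster)), function(cl) {
    v <- vals[labels$cluster == cl]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) {
      return(tibble::tibble(cluster = cl, n = 0L, rate = NA_real_,
                            ci_lo = NA_real_, ci_hi = NA_real_))
    }
    if (type == "boolean") {
      ci <- wilson_interval(sum(v), n, conf_level)
      tibble::tibble(cluster = cl, n = n, rate = mean(v),
                     ci_lo = ci[1], ci_hi = ci[2])
    } else {
      m <- mean(v)
      se <- if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      tibble::tibble(cluster = cl, n = n, rate = m,
                     ci_lo = m - z * se, ci_hi = m + z * se)
    }
  })
}

wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  # at the boundaries centre - half is 0 (resp. 1) analytically; pin it so
  # floating-point cancellation cannot push the bound past the estimate
  lo <- if (x == 0) 0 else max(0, centre - half)
  hi <- if (x == n) 1 else min(1, centre + half)
  c(lo, hi)
}

#' Tidy / summarise an enrichment report
#'
#' @param x An `rn_enrichment`.
#' @param ... Unused.
#' @return `tidy()` returns the underlying tibble; `glance()` one row with
#'   the number of tests and the count significant at q < 0.05.
#' @export
tidy.rn_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.rn_enrichment
#' @export
glance.rn_enrichment <- function(x, ...) {
  tibble::tibble(n_tests = sum(!is.na(x$p)),
                 n_significant = sum(x$q < 0.05, na.rm = TRUE),
                 min_q = suppressWarnings(min(x$q, na.rm = TRUE)))
}
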