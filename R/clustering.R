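#' Hamming distance between two task-code sequences
#'
#' The number of aligned intervals in which the two trajectories carry
#' different task codes. Codes are categorical, and cohort grids are aligned,
#' so positionwise disagreement is the natural dissimilarity; it is symmetric
#' and zero iff the sequences are identical.
#'
#' @param a,b Integer code sequences of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("sequences differ in length: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  sum(a != b)
}

#' Pairwise trajectory distance matrix
#'
#' @param trajectories Long tibble (`nurse_id`, `interval`, `code`) on a
#'   shared grid, or an `rn_cohort`.
#' @param method Distance between aligned code sequences; `"hamming"` is the
#'   reference implementation, and the argument is the plug-in point for
#'   alternatives (e.g. an edit distance for unaligned use).
#' @return Symmetric numeric matrix with zero diagonal; nurse ids as dimnames,
#'   in increasing id order.
#' @export
trajectory_distances <- function(trajectories, method = c("hamming")) {
  method <- match.arg(method)
  if (inherits(trajectories, "rn_cohort")) trajectories <- trajectories$trajectories
  wide <- trajectories |>
    dplyr::arrange(.data$nurse_id, .data$interval) |>
    tidyr::pivot_wider(names_from = "interval", values_from = "code")
  ids <- wide$nurse_id
  m <- as.matrix(wide[-1])
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      di <- colSums(t(m[(i + 1L):n, , drop = FALSE]) != m[i, ])
      D[i, (i + 1L):n] <- di
      D[(i + 1L):n, i] <- di
    }
  }
  D
}

#' Cluster trajectories with k-medoids (PAM)
#'
#' Partitions trajectories into k archetypical activity patterns whose
#' centres are actual nurses (medoids), so each recovered pattern is an
#' exhibitable trajectory. The algorithm is deterministic: medoids are seeded
#' with the greedy BUILD phase (first medoid minimises total distance; each
#' subsequent medoid maximally reduces the objective, ties to the smallest
#' id), then best-improvement swaps run until no swap lowers the
#' total within-cluster distance to medoids or `max_iter` is reached. The
#' objective never increases across iterations. Because the swap phase is a
#' local search, the descent is repeated from `n_starts` deterministic
#' seedings (the points with the smallest total distances as first medoid)
#' and the best objective wins; on small instances this reliably reaches the
#' exhaustive optimum.
#'
#' @param distances Symmetric distance matrix from [trajectory_distances()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer recorded in the result (the fit itself is
#'   deterministic; the seed seeds any downstream stochastic consumers).
#' @param max_iter Maximum number of swap iterations.
#' @return An object of class `rn_clustering`: `labels` tibble
#'   (`nurse_id`, `cluster`), `medoids` tibble (`cluster`, `nurse_id`),
#'   `k`, `objective`, `silhouette` (mean; `NA` for k = 1), `iterations`,
#'   `seed`.
#' @export
cluster_trajectories <- function(distances, k, seed = 1L, max_iter = 100L,
                                 n_starts = 5L) {
  D <- as.matrix(distances)
  n <- nrow(D)
  ids <- as.integer(rownames(D) %||% seq_len(n))
  if (k < 1L || k > n) stop("k must be between 1 and n = ", n, call. = FALSE)
  # deterministic multi-start: run BUILD + swap from the n_starts points with
  # the smallest total distance as first medoid, keep the lowest objective
  firsts <- order(colSums(D))[seq_len(min(n_starts, n))]
  best <- NULL
  total_iter <- 0L
  for (f in firsts) {
    fit <- pam_descend(D, pam_seed(D, k, first = f), max_iter)
    total_iter <- total_iter + fit$iter
    if (is.null(best) || fit$obj < best$obj - 1e-12) best <- fit
  }
  med <- sort(best$med)
  assign <- apply(D[, med, drop = FALSE], 1, which.min)
  labels <- tibble::tibble(nurse_id = ids, cluster = as.integer(assign))
  sil <- if (k >= 2L) mean(silhouette_widths(D, assign)) else NA_real_
  structure(list(labels = labels,
                 medoids = tibble::tibble(cluster = seq_len(k),
                                          nurse_id = ids[med]),
                 k = as.integer(k), objective = pam_objective(D, med),
                 silhouette = sil, iterations = total_iter,
                 seed = as.integer(seed)),
            class = "rn_clustering")
}

pam_seed <- function(D, k, first = NULL) {
  # BUILD phase: start from the point minimising total distance (or a given
  # start), then add whichever point most reduces the objective (ties to the
  # smallest index)
  med <- first %||% unname(which.min(colSums(D)))
  while (length(med) < k) {
    dmin <- apply(D[, med, drop = FALSE], 1, min)
    gain <- vapply(seq_len(nrow(D)), function(h) {
      if (h %in% med) -Inf else sum(pmax(dmin - D[, h], 0))
    }, numeric(1))
    med <- c(med, which.max(gain))
  }
  med
}

pam_descend <- function(D, med, max_iter) {
  # best-improvement swap phase: objective is non-increasing by construction
  n <- nrow(D)
  obj <- pam_objective(D, med)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    best <- list(obj = obj, med = med)
    for (m_i in seq_along(med)) {
      for (h in setdiff(seq_len(n), med)) {
        cand <- med; cand[m_i] <- h
        o <- pam_objective(D, cand)
        if (o < best$obj - 1e-12) best <- list(obj = o, med = cand)
      }
    }
    if (best$obj >= obj - 1e-12) break
    med <- best$med
    obj <- best$obj
  }
  list(med = med, obj = obj, iter = iter)
}

pam_objective <- function(D, med) {
  if (length(med) == 1L) return(sum(D[, med]))
  sum(do.call(pmin, lapply(med, function(m) D[, m])))
}

#' @export
print.rn_clustering <- function(x, ...) {
  cat("<k-medoids clustering: k = ", x$k, ", objective = ", x$objective,
      ", mean silhouette = ",
      if (is.na(x$silhouette)) "NA" else sprintf("%.3f", x$silhouette),
      ">\n", sep = "")
  print(dplyr::count(x$labels, .data$cluster))
  invisible(x)
}

silhouette_widths <- function(D, assign) {
  n <- nrow(D)
  ks <- sort(unique(assign))
  vapply(seq_len(n), function(i) {
    own <- which(assign == assign[i])
    if (length(own) == 1L) return(0)  # singleton convention
    a <- sum(D[i, setdiff(own, i)]) / (length(own) - 1L)
    b <- min(vapply(setdiff(ks, assign[i]), function(kk) {
      mean(D[i, assign == kk])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

#' Mean silhouette of a labelling
#'
#' Computed by definition from the distance matrix: for each point,
#' a = mean distance to its own cluster (excluding itself), b = smallest mean
#' distance to another cluster, width = (b - a) / max(a, b); singletons get 0.
#'
#' @param distances Symmetric distance matrix.
#' @param labels Integer cluster labels (vector aligned with the matrix rows,
#'   or a tibble with `nurse_id`, `cluster`).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(distances, labels) {
  D <- as.matrix(distances)
  if (is.data.frame(labels)) {
    labels <- labels$cluster[match(as.integer(rownames(D)), labels$nurse_id)]
  }
  stopifnot(length(labels) == nrow(D))
  mean(silhouette_widths(D, labels))
}

#' Choose the number of clusters by mean silhouette
#'
#' Fits [cluster_trajectories()] for every k in `k_range` and returns the k
#' with the highest mean silhouette; ties go to the smallest k. When all
#' pairwise distances are zero the silhouette carries no signal: the smallest
#' k is returned with a warning.
#'
#' @param distances Symmetric distance matrix.
#' @param k_range Candidate k values, each in `[2, n - 1]`.
#' @param seed Passed through to [cluster_trajectories()].
#' @return The selected k (integer), with the per-k silhouettes attached as
#'   attribute `"scores"` (a tibble `k`, `silhouette`).
#' @export
select_k <- function(distances, k_range, seed = 1L) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (length(k_range) == 0L) stop("k_range is empty", call. = FALSE)
  if (any(k_range < 2L | k_range > n - 1L)) {
    stop("k_range must lie within [2, n - 1] = [2, ", n - 1L, "]", call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (all(D == 0)) {
    warning("all trajectories are identical (zero distances); ",
            "silhouette is degenerate, returning the smallest k", call. = FALSE)
    scores <- tibble::tibble(k = k_range, silhouette = NA_real_)
    return(structure(k_range[1], scores = scores))
  }
  scores <- tibble::tibble(
    k = k_range,
    silhouette = vapply(k_range, function(k) {
      cluster_trajectories(D, k, seed = seed)$silhouette
    }, numeric(1)))
  best <- scores$k[which.max(scores$silhouette)]  # which.max: first max = smallest k
  structure(as.integer(best), scores = scores)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two labelings of the same nurses,
#' corrected for chance: 1 for identical partitions (up to relabeling),
#' around 0 for independent ones.
#'
#' @param labels_a,labels_b Tibbles (`nurse_id`, `cluster`) or named vectors
#'   keyed by nurse id. The id sets must match.
#' @return The ARI (numeric).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  a <- as_label_vector(labels_a)
  b <- as_label_vector(labels_b)
  if (!setequal(names(a), names(b))) {
    stop("the two labelings cover different nurse ids", call. = FALSE)
  }
  b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

as_label_vector <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(as.character(x$cluster), as.character(x$nurse_id))
  } else {
    if (is.null(names(x))) names(x) <- seq_along(x)
    stats::setNames(as.character(x), names(x))
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clustering result
#'
#' @param x An `rn_clustering`.
#' @param ... Unused.
#' @return `tidy()`: one row per nurse (`nurse_id`, `cluster`, `is_medoid`);
#'   `glance()`: one row of fit summaries.
#' @export
tidy.rn_clustering <- function(x, ...) {
  x$labels |>
    dplyr::mutate(is_medoid = .data$nurse_id %in% x$medoids$nurse_id)
}

#' @rdname tidy.rn_clustering
#' @export
glance.rn_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, objective = x$objective, silhouette = x$silhouette,
                 iterations = x$iterations, seed = x$seed,
                 n = nrow(x$labels))
}
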