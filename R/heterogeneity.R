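# Across-trajectory heterogeneity tests, conservation clustering with
# Shannon diversity, and correlation helpers for event statistics.

#' Heterogeneity of an event statistic across trajectories
#'
#' Tests whether a per-event statistic differs across trajectory groups:
#' Kruskal-Wallis (rank-based; the standard choice for lifetimes, which
#' are heavily skewed) and one-way ANOVA (for shape statistics). Groups
#' with fewer than 2 events are dropped; if fewer than 2 groups remain the
#' tests are reported as `NA` rather than raised.
#'
#' @param data A data frame of events.
#' @param value Name of the statistic column (string).
#' @param group Name of the grouping column, typically the trajectory id.
#' @return A tibble with columns `test`, `statistic`, `p_value`,
#'   `n_groups`, `n_events`.
#' @export
heterogeneity_tests <- function(data, value, group = "id") {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  d <- data[is.finite(data[[value]]), c(value, group)]
  names(d) <- c("value", "group")
  keep <- names(which(table(d$group) >= 2L))
  d <- d[d$group %in% keep, , drop = FALSE]
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2L) {
    return(tibble::tibble(test = c("kruskal_wallis", "anova"),
                          statistic = NA_real_, p_value = NA_real_,
                          n_groups = nlevels(d$group), n_events = nrow(d)))
  }
  kw <- kruskal.test(value ~ group, data = d)
  av <- summary(aov(value ~ group, data = d))[[1L]]
  tibble::tibble(
    test = c("kruskal_wallis", "anova"),
    statistic = c(unname(kw$statistic), av[["F value"]][1L]),
    p_value = c(kw$p.value, av[["Pr(>F)"]][1L]),
    n_groups = nlevels(d$group),
    n_events = nrow(d)
  )
}

# k-means++ seeding: first centroid uniform, then each next centroid drawn
# with probability proportional to the squared distance to the nearest
# centroid chosen so far.
kmeanspp_centers <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      idx[j] <- sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    nd <- rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[idx, , drop = FALSE]
}

#' Shannon diversity of cluster occupancy per trajectory
#'
#' For one trajectory whose events received cluster labels, the Shannon
#' diversity is `H = -sum(p_j * log(p_j))` over the occupied clusters
#' (natural log, `0 * log(0) := 0`). `H = 0` means all the trajectory's
#' events fell in one cluster (perfect within-trajectory conservation);
#' uniform spread over k clusters gives `log(k)`.
#'
#' @param labels Cluster labels of one trajectory's events.
#' @return A single non-negative number.
#' @export
shannon_diversity <- function(labels) {
  p <- table(labels)
  p <- p[p > 0] / sum(p)
  -sum(p * log(p))
}

#' Within-trajectory conservation of event statistics by clustering
#'
#' Quantifies how conserved each event statistic is within trajectories:
#' events are clustered on the (standardized) statistic with k-means
#' seeded by k-means++ (squared Euclidean distance), and the Shannon
#' diversity of cluster occupancy is summed over trajectories. Clusterings
#' are repeated `n_restarts` times (the seeding is stochastic) and the
#' summed diversity averaged. Lower values mean a trajectory's events keep
#' falling in the same cluster, i.e. the statistic is conserved within
#' trajectories.
#'
#' Each statistic is standardized to zero mean and unit variance before
#' clustering so that different units are comparable under the squared
#' Euclidean metric.
#'
#' @param events Event data frame with a trajectory `id` column.
#' @param statistics Character vector of statistic columns to assess.
#' @param k_range Integer vector of cluster counts to scan.
#' @param n_restarts Clusterings averaged per statistic and k (default 50).
#' @param seed Optional integer seed.
#' @return A tibble: `statistic`, `n_clusters`, `summed_diversity`.
#' @export
conservation_clustering <- function(events,
                                    statistics = c("mean_radius",
                                                   "radial_skewness",
                                                   "mean_median_distance",
                                                   "radial_sd",
                                                   "lifetime"),
                                    k_range = 2:10, n_restarts = 50,
                                    seed = NULL) {
  stopifnot(is.data.frame(events), "id" %in% names(events))
  statistics <- intersect(statistics, names(events))
  if (length(statistics) == 0L) stop("no statistic columns found", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  purrr::map_dfr(statistics, function(stat) {
    ok <- is.finite(events[[stat]])
    v <- events[[stat]][ok]
    ids <- events$id[ok]
    s <- sd(v)
    z <- if (s > 0) (v - mean(v)) / s else v * 0
    xm <- matrix(z, ncol = 1L)
    purrr::map_dfr(k_range, function(k) {
      if (length(z) < k)
        stop("fewer events (", length(z), ") than clusters (", k, ")",
             call. = FALSE)
      hsum <- vapply(seq_len(n_restarts), function(r) {
        centers <- unique(kmeanspp_centers(xm, k))
        cl <- suppressWarnings(
          kmeans(xm, centers = centers, iter.max = 100L)$cluster
        )
        sum(vapply(split(cl, ids), shannon_diversity, numeric(1)))
      }, numeric(1))
      tibble::tibble(statistic = stat, n_clusters = k,
                     summed_diversity = mean(hsum))
    })
  })
}

#' Pearson correlation between paired event quantities
#'
#' @param x,y Paired numeric vectors (non-missing pairs used; at least 3).
#' @return A tibble: `estimate` (Pearson r), `p_value` (two-sided), `n`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input has no defined correlation", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x))
}
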