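# K-means clustering of longitudinal frailty trajectories with monotone
# dropout: missing-aware rescaled Euclidean distance, Lloyd iteration with
# restarts (plus a single-move refinement pass on small instances), a
# Calinski-Harabasz cluster-count criterion, Gaussian-kernel posterior
# membership probabilities, and rule-based robust/resilient/nonresilient
# labels.

#' Build the trajectory matrix
#'
#' Converts per-person monthly score series into a persons x 13 matrix
#' (anchors at days 0, 30, ..., 360). Persons with fewer than `min_observed`
#' observed anchors are dropped (their count is recorded in the
#' `n_dropped` attribute). Missingness must be a suffix of the series —
#' once a person is missing they stay missing (monotone dropout).
#'
#' @param series Tibble from [score_series()]: `person_id`, `anchor_index`
#'   (0..12), `score`. A ready-made persons x anchors matrix (NA = missing,
#'   rownames = person ids) is also accepted and gets the same checks.
#' @param min_observed Minimum observed anchors to retain a person
#'   (default 3, i.e. at least 3 months of follow-up).
#' @param n_anchors Series length (default 13).
#' @return Numeric matrix with persons as rownames and NA suffixes; attribute
#'   `n_dropped`.
#' @export
build_trajectories <- function(series, min_observed = 3L, n_anchors = 13L) {
  if (is.matrix(series)) {
    mat <- series
    ids <- rownames(mat)
  } else {
    wide <- series %>%
      select("person_id", "anchor_index", "score") %>%
      tidyr::pivot_wider(names_from = "anchor_index", values_from = "score")
    ids <- wide$person_id
    mat <- matrix(NA_real_, length(ids), n_anchors,
                  dimnames = list(ids, paste0("m", 0:(n_anchors - 1))))
    got <- intersect(as.character(0:(n_anchors - 1)), names(wide))
    for (j in got) mat[, as.integer(j) + 1L] <- wide[[j]]
  }
  obs <- !is.na(mat)
  # suffix rule: no observed anchor may follow a missing one
  bad <- apply(obs, 1, function(o) any(diff(o) > 0))
  if (any(bad)) {
    abort(paste0("non-suffix missingness (gaps) in trajectories for: ",
                 paste(head(ids[bad], 5), collapse = ", ")))
  }
  keep <- rowSums(obs) >= min_observed
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Missing-aware trajectory distance
#'
#' Squared distance between two trajectories observed on possibly different
#' anchor sets: `d^2 = (T / T_obs) * sum over shared anchors (a_t - b_t)^2`,
#' where `T` is the series length and `T_obs` the number of anchors observed
#' in both — the available-case rescaling used in longitudinal K-means.
#'
#' @param a,b Numeric vectors of equal length, NA = missing.
#' @return Nonnegative distance (not squared).
#' @export
traj_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  shared <- !is.na(a) & !is.na(b)
  if (!any(shared)) abort("trajectories share no observed anchor")
  sqrt(length(a) / sum(shared) * sum((a[shared] - b[shared])^2))
}

# squared distances from every row of X (NA-suffixed) to every complete
# center row in C; returns n x k matrix
traj_dist2_matrix <- function(X, C) {
  Tn <- ncol(X)
  M <- !is.na(X)
  X0 <- X
  X0[!M] <- 0
  # sum_obs (x - c)^2 = sum_obs x^2 - 2 sum_obs x*c + sum_obs c^2
  d2 <- (rowSums(X0^2) - 2 * X0 %*% t(C)) + M %*% t(C^2)
  d2 * (Tn / rowSums(M))
}

# W-minimizing centers: anchor-wise means weighted by each person's T/T_obs
traj_centers <- function(X, assign, k, fallback) {
  Tn <- ncol(X)
  M <- !is.na(X)
  wts <- Tn / rowSums(M)
  X0 <- X
  X0[!M] <- 0
  C <- matrix(NA_real_, k, Tn)
  for (c in seq_len(k)) {
    rows <- which(assign == c)
    if (length(rows) == 0) next
    wm <- M[rows, , drop = FALSE] * wts[rows]
    num <- colSums(X0[rows, , drop = FALSE] * wts[rows])
    den <- colSums(wm)
    C[c, ] <- ifelse(den > 0, num / den, fallback)
  }
  C
}

traj_within_sum <- function(X, C, assign) {
  d2 <- traj_dist2_matrix(X, C)
  sum(d2[cbind(seq_len(nrow(X)), assign)])
}

#' Longitudinal K-means
#'
#' Lloyd-style alternation between nearest-center assignment (under the
#' rescaled missing-aware distance of [traj_distance()]) and anchor-wise
#' weighted-mean center updates, iterated until the assignments stabilize;
#' best of `n_starts` restarts by within-cluster sum. The first start is
#' seeded farthest-first (deterministic Gonzalez traversal) and the rest
#' k-means++ (distance-squared sampling) — rare but well-separated trajectory
#' classes are then seeded reliably, which uniform seeding essentially never
#' does.
#' Empty clusters are repaired by reseeding with the trajectory farthest from
#' its center.
#' On small instances (n <= 100) a single-move refinement pass follows Lloyd
#' convergence. The within-cluster sum never increases across iterations.
#'
#' @param traj Trajectory matrix from [build_trajectories()] (or any numeric
#'   matrix with NA-suffix missingness and person rownames).
#' @param k Number of clusters (2..n-1).
#' @param n_starts Random restarts (default 20).
#' @param max_iter Lloyd iteration cap per start.
#' @param seed Integer seed.
#' @param track_wss Record the within-cluster sum after every iteration of
#'   the winning start (in `wss_trace`); off by default.
#' @return A `traj_clusters` object: `k`, `assignment` (named integer),
#'   `centers` (k x T), `within_ss`, `criterion` (Calinski-Harabasz),
#'   `iterations`, `best_start`, `posterior` (n x k matrix).
#' @export
kmeans_long <- function(traj, k, n_starts = 20L, max_iter = 200L, seed = 1L,
                        track_wss = FALSE) {
  X <- as.matrix(traj)
  n <- nrow(X)
  if (k > n) abort("k exceeds the number of trajectories")
  set.seed(seed)
  Tn <- ncol(X)
  M <- !is.na(X)
  anchor_mean <- colSums(ifelse(M, X, 0)) / pmax(colSums(M), 1)
  complete_row <- function(i) ifelse(M[i, ], X[i, ], anchor_mean)

  # seeding on mean-completed rows: farthest-first (deterministic, covers
  # well-separated classes) or k-means++ (distance-squared sampled)
  seed_start <- function(farthest_first) {
    seeds <- if (farthest_first) {
      which.max(traj_dist2_matrix(X, matrix(anchor_mean, 1)))
    } else {
      sample.int(n, 1)
    }
    C <- matrix(complete_row(seeds), 1)
    while (length(seeds) < k) {
      d2 <- do.call(pmin, as.data.frame(traj_dist2_matrix(X, C)))
      d2[seeds] <- 0
      nxt <- if (farthest_first) {
        which.max(d2)
      } else if (sum(d2) > 0) {
        sample.int(n, 1, prob = d2)
      } else {
        sample.int(n, 1)
      }
      seeds <- c(seeds, nxt)
      C <- rbind(C, complete_row(nxt))
    }
    C
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    C <- seed_start(farthest_first = (s == 1L))
    assign_old <- rep(0L, n)
    iter <- 0L
    wss_trace <- numeric(0)
    repeat {
      iter <- iter + 1L
      d2 <- traj_dist2_matrix(X, C)
      assign <- max.col(-d2, ties.method = "first")
      # repair empty clusters with the farthest trajectory
      for (c in which(tabulate(assign, k) == 0)) {
        far <- which.max(d2[cbind(seq_len(n), assign)])
        assign[far] <- c
      }
      C <- traj_centers(X, assign, k, anchor_mean)
      if (track_wss) wss_trace <- c(wss_trace, traj_within_sum(X, C, assign))
      if (identical(assign, assign_old) || iter >= max_iter) break
      assign_old <- assign
    }
    if (n <= 100L) {
      ref <- refine_single_moves(X, C, assign, k, anchor_mean)
      assign <- ref$assign; C <- ref$C
    }
    wss <- traj_within_sum(X, C, assign)
    if (is.null(best) || wss < best$wss - 1e-15) {
      best <- list(assign = assign, C = C, wss = wss, iter = iter, start = s,
                   trace = wss_trace)
    }
  }
  sol <- structure(list(
    k = k, assignment = set_names(best$assign, rownames(X)),
    centers = best$C, within_ss = best$wss, iterations = best$iter,
    best_start = best$start, wss_trace = best$trace), class = "traj_clusters")
  sol$criterion <- ch_criterion(X, sol)
  sol$posterior <- posterior_probs(X, sol)
  sol
}

# greedy single-point reassignment until no move lowers the within sum
refine_single_moves <- function(X, C, assign, k, fallback) {
  wss <- traj_within_sum(X, C, assign)
  n <- nrow(X)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (c in seq_len(k)) {
        if (c == assign[i] || sum(assign == assign[i]) == 1) next
        cand <- assign
        cand[i] <- c
        Cc <- traj_centers(X, cand, k, fallback)
        w <- traj_within_sum(X, Cc, cand)
        if (w < wss - 1e-12) {
          assign <- cand; C <- Cc; wss <- w; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(assign = assign, C = C, wss = wss)
}

#' Calinski-Harabasz criterion for a trajectory clustering
#'
#' `C = (B / (k - 1)) / (W / (n - k))` with between-cluster dispersion
#' `B = sum_c n_c * d^2(center_c, overall mean)` and within dispersion
#' `W = sum_i d^2(traj_i, center of its cluster)`, distances via the
#' missing-aware [traj_distance()]. Larger is better. Returns `Inf` (with a
#' `degenerate` attribute) when `W = 0`.
#'
#' @param traj Trajectory matrix.
#' @param solution A `traj_clusters` (or a list with `centers`, `assignment`).
#' @return Numeric criterion value.
#' @export
ch_criterion <- function(traj, solution) {
  X <- as.matrix(traj)
  n <- nrow(X)
  k <- nrow(solution$centers)
  stopifnot(k >= 2, n > k)
  assign <- as.integer(solution$assignment)
  M <- !is.na(X)
  wts <- ncol(X) / rowSums(M)
  X0 <- ifelse(M, X, 0)
  overall <- colSums(X0 * wts) / colSums(M * wts)
  nc <- tabulate(assign, k)
  B <- sum(nc * rowSums((solution$centers -
                           matrix(overall, k, ncol(X), byrow = TRUE))^2))
  W <- traj_within_sum(X, solution$centers, assign)
  if (W <= 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters
#'
#' Runs [kmeans_long()] for each `k` in `k_range` and returns the solution
#' maximizing the Calinski-Harabasz criterion, with the full per-k criterion
#' table attached as attribute `criterion_table`.
#'
#' @param traj Trajectory matrix.
#' @param k_range Candidate cluster counts (default 2..8).
#' @param n_starts,max_iter,seed Passed to [kmeans_long()] (each k gets a
#'   distinct deterministic sub-seed).
#' @return Best `traj_clusters`.
#' @export
select_k <- function(traj, k_range = 2:8, n_starts = 20L, max_iter = 200L,
                     seed = 1L) {
  sols <- lapply(k_range, function(k) {
    kmeans_long(traj, k, n_starts = n_starts, max_iter = max_iter,
                seed = seed + k)
  })
  crit <- vapply(sols, function(s) s$criterion, numeric(1))
  best <- sols[[which.max(crit)]]
  attr(best, "criterion_table") <- tibble(k = k_range, criterion = crit)
  best
}

#' Posterior cluster-membership probabilities
#'
#' Gaussian-kernel posteriors around the centers with pooled within-cluster
#' variance: `p_ic` proportional to `exp(-d^2(i, c) / (2 * sigma2))`,
#' `sigma2 = W / (n - k)`. Rows sum to 1. The per-cluster summary reported
#' alongside the fit is the mean posterior of the assigned cluster.
#'
#' @param traj Trajectory matrix.
#' @param solution A `traj_clusters`.
#' @return n x k matrix of probabilities.
#' @export
posterior_probs <- function(traj, solution) {
  X <- as.matrix(traj)
  d2 <- traj_dist2_matrix(X, solution$centers)
  n <- nrow(X)
  k <- nrow(solution$centers)
  sigma2 <- traj_within_sum(X, solution$centers,
                            as.integer(solution$assignment)) / max(n - k, 1)
  if (sigma2 <= 0) {
    # all points on their centers: hard assignment
    P <- matrix(0, n, k)
    P[cbind(seq_len(n), as.integer(solution$assignment))] <- 1
    return(P)
  }
  lp <- -d2 / (2 * sigma2)
  lp <- lp - apply(lp, 1, max)
  P <- exp(lp)
  P / rowSums(P)
}

#' Label cluster trajectory shapes
#'
#' Rule-based labels from each center: with baseline `b = center[1]`, peak
#' `p = max(center)` and end `e = center[13]` — *robust* if the rise above
#' baseline is below `delta_rise`; otherwise *resilient* if at least a
#' fraction `rho_recovery` of the rise is recovered by the end; otherwise
#' *nonresilient*. A `low`/`medium`/`high` level tag comes from baseline
#' thresholds.
#'
#' @param solution A `traj_clusters`.
#' @param delta_rise Minimum peak-minus-baseline to count as a rise
#'   (default 0.02).
#' @param rho_recovery Fraction of the rise that must be recovered
#'   (default 0.5).
#' @param level_cuts Baseline cutpoints for the level tag
#'   (default `c(0.1, 0.2)`).
#' @return Tibble: `cluster`, `n`, `share`, `baseline`, `peak`, `end`,
#'   `label`, `level`.
#' @export
label_clusters <- function(solution, delta_rise = 0.02, rho_recovery = 0.5,
                           level_cuts = c(0.1, 0.2)) {
  C <- solution$centers
  b <- C[, 1]
  p <- apply(C, 1, max)
  e <- C[, ncol(C)]
  label <- ifelse(p - b < delta_rise, "robust",
                  ifelse(p - e >= rho_recovery * (p - b), "resilient",
                         "nonresilient"))
  nc <- tabulate(as.integer(solution$assignment), nrow(C))
  tibble(cluster = seq_len(nrow(C)), n = nc, share = nc / sum(nc),
         baseline = b, peak = p, end = e, label = label,
         level = cut(b, c(-Inf, level_cuts, Inf),
                     labels = c("low", "medium", "high")))
}

#' @export
print.traj_clusters <- function(x, ...) {
  cat("<traj_clusters> k =", x$k, " n =", length(x$assignment),
      " within-SS =", signif(x$within_ss, 5),
      " CH =", signif(x$criterion, 5), "\n")
  print(as.data.frame(label_clusters(x)), digits = 3)
  invisible(x)
}

#' @export
tidy.traj_clusters <- function(x, ...) {
  as_tibble(x$centers, .name_repair = ~paste0("m", seq_along(.x) - 1)) %>%
    mutate(cluster = row_number()) %>%
    tidyr::pivot_longer(-"cluster", names_to = "month",
                        names_prefix = "m", values_to = "center") %>%
    mutate(month = as.integer(.data$month))
}

#' @export
glance.traj_clusters <- function(x, ...) {
  tibble(k = x$k, n = length(x$assignment), within_ss = x$within_ss,
         criterion = x$criterion, iterations = x$iterations,
         mean_assigned_posterior =
           mean(x$posterior[cbind(seq_along(x$assignment),
                                  as.integer(x$assignment))]))
}

#' Plot cluster center trajectories
#'
#' Center frailty trajectories by cluster with shape labels.
#' @param object A `traj_clusters`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.traj_clusters <- function(object, ...) {
  lab <- label_clusters(object)
  dat <- tidy(object) %>%
    left_join(lab %>% select("cluster", "label", "share"), by = "cluster") %>%
    mutate(cluster_lab = paste0("cluster ", .data$cluster, " (",
                                .data$label, ", ",
                                round(100 * .data$share), "%)"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$month, y = .data$center,
                                    colour = .data$cluster_lab)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Months since chemotherapy initiation",
                  y = "Cluster mean claims-based frailty", colour = NULL) +
    ggplot2::theme_minimal()
}
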