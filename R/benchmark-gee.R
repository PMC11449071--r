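# Weighted GEE benchmark contrasts of frailty change: builds the
# three-timepoint panel and fits a marginal model with gamma variance,
# identity link and AR(1) working correlation by Fisher scoring on the
# estimating equations, with a cluster-robust sandwich variance. Observation
# weights (SMR x IPAW) multiply the residual in the estimating function, the
# convention under which inverse-probability weights yield unbiased
# estimating equations.

#' Build the three-timepoint analysis panel
#'
#' One row per person per timepoint while under observation, carrying the
#' frailty score at that anchor and the combined SMR x IPAW weight. Anchors
#' default to index + 0/120/300 days (30-day months: 4 and 10 months).
#'
#' @param cohort Cohort tibble with `smr_weight` (see [smr_weights()]).
#' @param scores Score tibble (`person_id`, `anchor`, `score`) covering every
#'   observed person-timepoint (e.g. from [score_series()] or
#'   [frailty_score()] at the three anchors).
#' @param ipaw Tibble (`person_id`, `timepoint`, `ipaw_weight`) from
#'   [ipaw_weights()]; omit for all-1 attrition weights.
#' @param observed Tibble (`person_id`, `timepoint`) of observed
#'   person-timepoints; defaults to every person at every timepoint that has
#'   a score row.
#' @param timepoint_days Day offsets of T1/T2/T3.
#' @return Panel tibble: `person_id`, `arm`, `timepoint`, `anchor`, `score`,
#'   `weight`.
#' @export
build_panel <- function(cohort, scores, ipaw = NULL, observed = NULL,
                        timepoint_days = c(0L, 120L, 300L)) {
  grid <- tidyr::crossing(
    cohort %>% select("person_id", "arm", "match_group", "index_date",
                      "smr_weight"),
    timepoint = 1:3) %>%
    mutate(anchor = .data$index_date + timepoint_days[.data$timepoint])
  grid <- grid %>%
    left_join(scores %>% select("person_id", "anchor", "score"),
              by = c("person_id", "anchor"),
              relationship = "many-to-many") %>%
    distinct(.data$person_id, .data$match_group, .data$timepoint,
             .keep_all = TRUE)
  if (!is.null(observed)) {
    grid <- grid %>%
      semi_join(observed, by = c("person_id", "timepoint"))
    if (anyNA(grid$score)) {
      abort("missing frailty score for an observed person-timepoint")
    }
  } else {
    grid <- grid %>% filter(!is.na(.data$score))
  }
  if (is.null(ipaw)) {
    grid$ipaw_weight <- 1
  } else {
    keys <- intersect(c("person_id", "index_date", "timepoint"), names(ipaw))
    grid <- grid %>%
      left_join(ipaw, by = keys) %>%
      mutate(ipaw_weight = dplyr::coalesce(.data$ipaw_weight, 1))
  }
  grid %>%
    mutate(weight = .data$smr_weight * .data$ipaw_weight,
           cluster_id = paste(.data$person_id, .data$match_group,
                              sep = "::")) %>%
    select("person_id", "cluster_id", "arm", "timepoint", "anchor", "score",
           "weight") %>%
    arrange(.data$cluster_id, .data$timepoint)
}

# AR(1) correlation matrix on occasions 1..m (equally spaced convention)
ar1_matrix <- function(rho, m) rho^abs(outer(seq_len(m), seq_len(m), "-"))

#' Fit the weighted gamma/identity/AR(1) GEE
#'
#' Marginal mean model
#' `E[Y] = b0 + b1*arm + b2*T2 + b3*T3 + b4*arm*T2 + b5*arm*T3`
#' with gamma variance function (`V(mu) = phi * mu^2`), identity link, AR(1)
#' working correlation across the (nominally equally spaced) occasions, each
#' person a cluster, observation weights multiplying the residuals, and a
#' cluster-robust sandwich covariance for the 95% CIs.
#'
#' @param panel Panel tibble from [build_panel()] — or any tibble with columns
#'   `person_id` (cluster), `timepoint` (1..3), an outcome column, an
#'   arm indicator, and `weight`.
#' @param outcome,arm Column names of the outcome and the 0/1 (or
#'   `"chemo"`/`"comparator"`) arm variable.
#' @param corstr `"ar1"` (default) or `"independence"`.
#' @param max_iter,tol Fisher-scoring controls.
#' @return A `frailty_gee` object with `coefficients` tibble (Table-2 layout:
#'   intercept, arm, T2, T3, T2 x arm, T3 x arm), `rho`, `phi`, `vcov`,
#'   `n_clusters`, `n_obs`, `converged`.
#' @export
fit_gee <- function(panel, outcome = "score", arm = "arm", corstr = "ar1",
                    max_iter = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr, c("ar1", "independence"))
  stopifnot(nrow(panel) > 0, all(panel$weight >= 0))
  cl_col <- if ("cluster_id" %in% names(panel)) "cluster_id" else "person_id"
  a <- panel[[arm]]
  if (is.character(a)) a <- as.integer(a == "chemo")
  d <- tibble(cluster = panel[[cl_col]], t = as.integer(panel$timepoint),
              y = panel[[outcome]], arm = as.numeric(a), w = panel$weight) %>%
    arrange(.data$cluster, .data$t)
  X <- cbind(1, d$arm, d$t == 2, d$t == 3,
             d$arm * (d$t == 2), d$arm * (d$t == 3)) * 1
  colnames(X) <- c("(Intercept)", "arm", "T2", "T3", "T2:arm", "T3:arm")
  # drop columns with no variation (e.g. single-arm panels) from estimation;
  # with the arm term gone the interactions duplicate the time dummies, so
  # they go too
  active <- apply(X, 2, function(col) length(unique(col)) > 1)
  active[1] <- TRUE
  if (!active[2]) active[5:6] <- FALSE
  Xa <- X[, active, drop = FALSE]
  p <- ncol(Xa)

  # cluster layout: monotone follow-up means observation patterns are
  # prefixes; group clusters by their occasion set for vectorized algebra
  key <- tapply(d$t, d$cluster, function(tt) paste(sort(tt), collapse = ","))
  pattern_of <- key[match(d$cluster, names(key))]
  patterns <- sort(unique(pattern_of))

  beta <- qr.solve(crossprod(Xa * sqrt(d$w)),
                   crossprod(Xa * sqrt(d$w), d$y * sqrt(d$w)))
  rho <- 0; phi <- 1
  converged <- FALSE
  warned_negative <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- as.numeric(Xa %*% beta)
    if (any(mu <= 0)) {
      if (!warned_negative) {
        warn("identity link produced nonpositive fitted means; clamped")
        warned_negative <- TRUE
      }
      mu <- pmax(mu, 1e-8)
    }
    r <- (d$y - mu) / mu                      # Pearson residual (gamma)
    sw <- sum(d$w)
    phi <- max(sum(d$w * r^2) / max(sw - p, 1), 1e-12)
    if (corstr == "ar1") {
      # lag-1 moment estimator over adjacent within-cluster pairs
      lead_same <- c(d$cluster[-1] == d$cluster[-nrow(d)] &
                       d$t[-1] == d$t[-nrow(d)] + 1L, FALSE)
      i1 <- which(lead_same)
      if (length(i1) > 0) {
        wp <- sqrt(d$w[i1] * d$w[i1 + 1])
        rho_num <- sum(wp * r[i1] * r[i1 + 1])
        rho <- rho_num / (phi * max(sum(wp), 1e-12))
        rho <- min(max(rho, -0.99), 0.99)
        if (!is.finite(rho)) rho <- 0
      } else rho <- 0
    }
    # accumulate estimating equations per occasion-pattern group
    H <- matrix(0, p, p)
    U <- numeric(p)
    for (pat in patterns) {
      occ <- as.integer(strsplit(pat, ",")[[1]])
      m <- length(occ)
      Rinv <- solve(ar1_matrix(if (corstr == "ar1") rho else 0, 3)[occ, occ,
                                                                   drop = FALSE])
      rows <- which(pattern_of == pat)
      nc <- length(rows) / m
      ord <- rows[order(d$cluster[rows], d$t[rows])]
      # arrays: nc x m slices
      Gs <- lapply(seq_len(m), function(s) {
        idx <- ord[seq(s, length(ord), by = m)]
        list(G = Xa[idx, , drop = FALSE] / mu[idx],
             z = d$w[idx] * (d$y[idx] - mu[idx]) / mu[idx],
             Gw = Xa[idx, , drop = FALSE] * (d$w[idx] / mu[idx]))
      })
      for (s in seq_len(m)) for (tt in seq_len(m)) {
        if (Rinv[s, tt] == 0) next
        H <- H + Rinv[s, tt] * crossprod(Gs[[s]]$G, Gs[[tt]]$Gw)
        U <- U + Rinv[s, tt] * crossprod(Gs[[s]]$G, Gs[[tt]]$z)
      }
    }
    delta <- tryCatch(solve(H, U), error = function(e)
      abort(paste0("GEE scoring step failed (singular system): ",
                   conditionMessage(e))))
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 1) {
    abort(paste0("GEE did not converge in ", max_iter,
                 " iterations (last step ", signif(max(abs(delta)), 3), ")"))
  }
  mu <- pmax(as.numeric(Xa %*% beta), 1e-8)

  # sandwich: bread = H, meat = sum_i psi_i psi_i'
  M <- matrix(0, p, p)
  for (pat in patterns) {
    occ <- as.integer(strsplit(pat, ",")[[1]])
    m <- length(occ)
    Rinv <- solve(ar1_matrix(if (corstr == "ar1") rho else 0, 3)[occ, occ,
                                                                 drop = FALSE])
    rows <- which(pattern_of == pat)
    ord <- rows[order(d$cluster[rows], d$t[rows])]
    Gs <- lapply(seq_len(m), function(s) {
      idx <- ord[seq(s, length(ord), by = m)]
      list(G = Xa[idx, , drop = FALSE] / mu[idx],
           z = d$w[idx] * (d$y[idx] - mu[idx]) / mu[idx])
    })
    nc <- length(ord) / m
    Psi <- matrix(0, nc, p)
    for (s in seq_len(m)) for (tt in seq_len(m)) {
      if (Rinv[s, tt] == 0) next
      Psi <- Psi + Rinv[s, tt] * (Gs[[s]]$G * Gs[[tt]]$z)
    }
    M <- M + crossprod(Psi)
  }
  Hi <- solve(H)
  V <- Hi %*% M %*% t(Hi)

  est <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  se <- est
  est[active] <- as.numeric(beta)
  se[active] <- sqrt(pmax(diag(V), 0))
  coefs <- tibble(
    term = c("Intercept", "Chemo cohort", "T2: 4 months postindex",
             "T3: 10 months postindex", "T2 x chemo cohort",
             "T3 x chemo cohort"),
    estimate = as.numeric(est), std_error = as.numeric(se),
    conf_low = est - qnorm(0.975) * se,
    conf_high = est + qnorm(0.975) * se)
  Vfull <- matrix(NA_real_, ncol(X), ncol(X),
                  dimnames = list(colnames(X), colnames(X)))
  Vfull[active, active] <- V
  structure(list(coefficients = coefs, vcov = Vfull, rho = rho, phi = phi,
                 corstr = corstr, n_clusters = length(unique(d$cluster)),
                 n_obs = nrow(d), converged = converged,
                 variance = "cluster-robust sandwich"),
            class = "frailty_gee")
}

#' @export
print.frailty_gee <- function(x, ...) {
  cat("Weighted GEE (gamma variance, identity link,", x$corstr,
      "working correlation)\n")
  cat(x$n_clusters, "clusters,", x$n_obs, "observations; rho =",
      round(x$rho, 3), "; phi =", signif(x$phi, 3), "\n\n")
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @export
tidy.frailty_gee <- function(x, ...) x$coefficients

#' @export
glance.frailty_gee <- function(x, ...) {
  tibble(n_clusters = x$n_clusters, n_obs = x$n_obs, rho = x$rho,
         phi = x$phi, corstr = x$corstr, converged = x$converged)
}

#' Marginal arm-by-timepoint means from a GEE fit
#'
#' Cell means as linear combinations of the coefficients (e.g. chemo at T2 =
#' b0 + b1 + b2 + b4) with delta-method 95% CIs from the sandwich covariance.
#'
#' @param fit A `frailty_gee`.
#' @return Tibble: `arm`, `timepoint`, `mean`, `conf_low`, `conf_high`.
#' @export
marginal_means <- function(fit) {
  stopifnot(inherits(fit, "frailty_gee"))
  L <- rbind(
    c(1, 0, 0, 0, 0, 0), c(1, 0, 1, 0, 0, 0), c(1, 0, 0, 1, 0, 0),
    c(1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 1, 0), c(1, 1, 0, 1, 0, 1))
  b <- fit$coefficients$estimate
  b[is.na(b)] <- 0
  V <- fit$vcov
  V[is.na(V)] <- 0
  m <- as.numeric(L %*% b)
  se <- sqrt(pmax(diag(L %*% V %*% t(L)), 0))
  tibble(arm = rep(c("comparator", "chemo"), each = 3),
         timepoint = rep(1:3, 2), mean = m,
         conf_low = m - qnorm(0.975) * se,
         conf_high = m + qnorm(0.975) * se)
}

#' Plot marginal frailty means over follow-up
#'
#' Mean claims-based frailty by arm at the three timepoints with 95% CI
#' ribbons.
#' @param object A `frailty_gee` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frailty_gee <- function(object, ...) {
  mm <- marginal_means(object) %>%
    mutate(months = c(0, 4, 10)[.data$timepoint])
  ggplot2::ggplot(mm, ggplot2::aes(x = .data$months, y = .data$mean,
                                   colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Months since index", y = "Mean claims-based frailty",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
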