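## The study statistics over a cohort table: per-trainee normalized
## times, unadjusted and experience-adjusted group comparisons, the
## learning-curve trend, and graph-based clustering of planning
## profiles.

#' Per-trainee min-max normalization of planning times
#'
#' Each trainee's planning times are rescaled over their own session:
#' `(t - min) / (max - min)`, so 0 is that trainee's fastest plan and
#' 1 their slowest. A trainee with zero range gets 0.5 everywhere.
#'
#' @param cohort cohort data.frame.
#' @return The cohort with a `normalized_time` column.
#' @export
normalize_planning_times <- function(cohort) {
  n_per <- table(cohort$trainee_id)
  if (any(n_per < 2L))
    stopf("every trainee needs >= 2 plans to normalize (offending: %s)",
          paste(names(n_per)[n_per < 2L], collapse = ", "))
  norm <- stats::ave(cohort$planning_time_s, cohort$trainee_id,
                     FUN = function(t) {
                       rng <- max(t) - min(t)
                       if (rng == 0) rep(0.5, length(t))
                       else (t - min(t)) / rng
                     })
  cohort$normalized_time <- norm
  cohort
}

#' Two-group comparison of a continuous variable
#'
#' Per-group mean and standard error plus a Welch two-sample t-test.
#'
#' @param cohort cohort data.frame with a `group` column.
#' @param variable Column name of the outcome.
#' @return List of class `group_comparison`: per-group `mean`, `sem`,
#'   `difference` (A-nBx minus T-nBx), `p_value`.
#' @export
compare_group_means <- function(cohort, variable) {
  if (!variable %in% names(cohort)) stopf("no column '%s'", variable)
  x <- cohort[[variable]]
  g <- cohort$group
  for (gg in c("T-nBx", "A-nBx"))
    if (!any(g == gg)) stopf("group %s is empty", gg)
  xt <- x[g == "T-nBx"]; xa <- x[g == "A-nBx"]
  tt <- t.test(xa, xt)        # Welch by default
  structure(list(
    variable = variable,
    mean = c("T-nBx" = mean(xt), "A-nBx" = mean(xa)),
    sem = c("T-nBx" = sem(xt), "A-nBx" = sem(xa)),
    difference = mean(xa) - mean(xt),
    statistic = unname(tt$statistic), p_value = tt$p.value),
    class = "group_comparison")
}

#' Experience-adjusted group comparison
#'
#' Regression of the outcome on group + years of neurosurgical
#' experience: linear for continuous outcomes, logistic for binary
#' flags. The adjusted p-value is the group coefficient's. When
#' experience is constant (collinear), the unadjusted comparison is
#' returned with a flag.
#'
#' @inheritParams compare_group_means
#' @param binary Treat the outcome as a 0/1 flag (logistic model);
#'   auto-detected when the column has only two values.
#' @return `group_comparison` with `p_adjusted`, `adjusted_flagged`.
#' @export
adjusted_comparison <- function(cohort, variable, binary = NULL) {
  x <- cohort[[variable]]
  if (is.null(x)) stopf("no column '%s'", variable)
  if (is.null(binary)) binary <- all(x %in% c(0, 1, TRUE, FALSE))
  dat <- data.frame(y = as.numeric(x),
                    group = factor(cohort$group, c("T-nBx", "A-nBx")),
                    exp_y = cohort$experience_years)
  base <- if (binary) {
    tab <- table(factor(x != 0, c(FALSE, TRUE)), dat$group)
    ct <- compare_component_incidence(
      list(components = data.frame(component = variable,
                                   t_nbx = tab[2, "T-nBx"],
                                   a_nbx = tab[2, "A-nBx"]),
           group_stats = data.frame(group = colnames(tab),
                                    n = colSums(tab))),
      variable)
    structure(list(variable = variable,
                   mean = c("T-nBx" = mean(dat$y[dat$group == "T-nBx"]),
                            "A-nBx" = mean(dat$y[dat$group == "A-nBx"])),
                   sem = c("T-nBx" = NA_real_, "A-nBx" = NA_real_),
                   difference = diff(tapply(dat$y, dat$group, mean)),
                   statistic = ct$statistic, p_value = ct$p_value),
              class = "group_comparison")
  } else compare_group_means(cohort, variable)
  if (length(unique(dat$exp_y)) < 2L) {
    base$p_adjusted <- base$p_value
    base$adjusted_flagged <- TRUE
    return(base)
  }
  fit <- if (binary) glm(y ~ group + exp_y, binomial(), dat)
         else lm(y ~ group + exp_y, dat)
  co <- summary(fit)$coefficients
  base$p_adjusted <- co["groupA-nBx", 4]
  base$group_coef <- co["groupA-nBx", 1]
  base$adjusted_flagged <- FALSE
  base
}

#' Learning-curve trend within a subgroup
#'
#' Regression of log planning time on exercise order within one group:
#' a negative slope is a practice effect (faster planning later in the
#' session).
#'
#' @param cohort cohort data.frame.
#' @param subgroup `"T-nBx"`, `"A-nBx"` or `"all"`.
#' @return List with `slope` (log-time per exercise position), `se`,
#'   `p_value`, `n`.
#' @export
learning_curve_trend <- function(cohort, subgroup = c("all", "T-nBx", "A-nBx")) {
  subgroup <- match.arg(subgroup)
  d <- if (subgroup == "all") cohort else cohort[cohort$group == subgroup, ]
  if (length(unique(d$exercise_order)) < 2L)
    stopf("need >= 2 exercise positions for a trend")
  fit <- lm(log(planning_time_s) ~ exercise_order, data = d)
  co <- summary(fit)$coefficients
  list(subgroup = subgroup, slope = co["exercise_order", 1],
       se = co["exercise_order", 2], p_value = co["exercise_order", 4],
       n = nrow(d))
}

#' Graph-based clustering of planning profiles
#'
#' Standardizes the four planning features (trajectory changes, lobe
#' changes, tractography availability, normalized time), builds a
#' k-nearest-neighbour graph and partitions it by Leiden modularity
#' community detection; a 2D principal-component embedding of the
#' standardized features is attached for display. Records are sorted
#' into a canonical order internally, so the partition is invariant to
#' record order and deterministic given the seed.
#'
#' @param cohort cohort data.frame; `normalized_time` computed on the
#'   fly when absent.
#' @param seed Integer seed.
#' @param knn Neighbours per record in the graph.
#' @param resolution Leiden resolution parameter.
#' @return List of class `cluster_result`: `cluster` (integer per
#'   record), `embedding` (n x 2), `n_clusters`, `features`.
#' @export
cluster_planning_profiles <- function(cohort, seed = 1L, knn = 15L,
                                      resolution = 1.0) {
  if (is.null(cohort$normalized_time))
    cohort <- normalize_planning_times(cohort)
  feats <- cbind(trajectory_changes = as.numeric(cohort$n_trajectory_changes),
                 lobe_changes = as.numeric(cohort$n_lobe_changes),
                 tractography = as.numeric(cohort$group == "T-nBx"),
                 normalized_time = cohort$normalized_time)
  n <- nrow(feats)
  if (n <= knn) stopf("need more than knn = %d records, got %d", knn, n)
  z <- scale(feats)
  z[, apply(feats, 2L, function(c) sd(c) == 0)] <- 0
  ## canonical record order: the partition must not depend on row order
  ord <- do.call(order, as.data.frame(z))
  zs <- z[ord, , drop = FALSE]
  D <- as.matrix(stats::dist(zs))
  diag(D) <- Inf
  nb <- apply(D, 1L, function(r) order(r)[seq_len(knn)])
  edges <- cbind(rep(seq_len(n), each = knn), as.vector(nb))
  edges <- unique(t(apply(edges, 1L, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 5L)))
  cluster <- integer(n)
  cluster[ord] <- as.integer(memb)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  emb <- pc$x[, 1:2, drop = FALSE]
  ## fix the sign convention so the embedding is fully deterministic
  for (k in 1:2) if (sum(pc$rotation[, k]) < 0) emb[, k] <- -emb[, k]
  structure(list(cluster = cluster, embedding = emb,
                 n_clusters = length(unique(cluster)),
                 features = feats, knn = knn, resolution = resolution,
                 seed = seed),
            class = "cluster_result")
}
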