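# Fixture builders and independent oracles, kept deliberately naive:
# scalar loops and exhaustive enumeration, no shared code with the package.

make_view <- function(values, ids = sprintf("P%02d", seq_len(nrow(values))),
                      features = sprintf("f%03d", seq_len(ncol(values))),
                      name = "test") {
  dimnames(values) <- list(ids, features)
  expression_view(values, view_name = name)
}

random_cohort <- function(n = 12, n_views = 3, m = 15, seed = 1) {
  withr::with_seed(seed, {
    views <- lapply(seq_len(n_views), function(v) {
      make_view(matrix(rnorm(n * m), n, m), name = paste0("v", v))
    })
    cohort(views)
  })
}

# symmetric nonnegative affinity with two planted blocks
two_block_kernel <- function(n1, n2, within = c(0.7, 1), between = c(0, 0.2),
                             seed = 1) {
  n <- n1 + n2
  withr::with_seed(seed, {
    m <- matrix(runif(n * n, between[1], between[2]), n, n)
    m[seq_len(n1), seq_len(n1)] <- runif(n1 * n1, within[1], within[2])
    m[(n1 + 1):n, (n1 + 1):n] <- runif(n2 * n2, within[1], within[2])
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
    similarity_kernel(m, kind = "fused")
  })
}

manual_knn_sets <- function(sets, ids = sprintf("P%02d", seq_along(sets))) {
  structure(list(sets = sets, k = length(sets[[1]]) - 1L, patient_ids = ids),
            class = "knn_sets")
}

# normalized cut of a labelled partition: sum_g cut(g, complement) / vol(g)
ncut_value <- function(K, labels) {
  m <- as.matrix(K)
  sum(vapply(unique(labels), function(g) {
    inside <- labels == g
    cut <- sum(m[inside, !inside])
    vol <- sum(m[inside, ])
    cut / vol
  }, numeric(1)))
}

# exhaustive minimum normalized cut over all 2-way partitions (small n only)
min_ncut_bruteforce <- function(K) {
  n <- nrow(as.matrix(K))
  stopifnot(n <= 12)
  best <- Inf
  # fix patient 1 in group 1 to halve the enumeration
  for (code in 0:(2^(n - 1) - 1)) {
    labels <- c(1L, 1L + as.integer(intToBits(code)[seq_len(n - 1)]))
    if (length(unique(labels)) < 2L) next
    best <- min(best, ncut_value(K, labels))
  }
  best
}

# exhaustive minimum within-cluster sum of squares over 2-way partitions
min_wss_bruteforce <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 12)
  best <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    labels <- c(1L, 1L + as.integer(intToBits(code)[seq_len(n - 1)]))
    if (length(unique(labels)) < 2L) next
    wss <- sum(vapply(unique(labels), function(g) {
      pts <- X[labels == g, , drop = FALSE]
      ctr <- colMeans(pts)
      sum(sweep(pts, 2, ctr)^2)
    }, numeric(1)))
    best <- min(best, wss)
  }
  best
}

wss_of <- function(X, labels) {
  sum(vapply(unique(labels), function(g) {
    pts <- X[labels == g, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1)))
}

# hand-expanded multi-group log-rank statistic (Mantel-Haenszel form),
# written as explicit per-event-time sums; only handles 2 groups
logrank_2group_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  obs <- 0; exp1 <- 0; var1 <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_total <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    obs <- obs + d1
    exp1 <- exp1 + d * n1 / n_total
    if (n_total > 1) {
      var1 <- var1 + d * (n1 / n_total) * (1 - n1 / n_total) * (n_total - d) / (n_total - 1)
    }
  }
  (obs - exp1)^2 / var1
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# writes a small simulated cohort to disk and returns a ready-to-run config
write_fixture_config <- function(dir, seed = 17, C = NULL, C_range = NULL) {
  spec <- synthetic_spec(n_patients = 36, n_clusters = 3, n_features = c(25, 20, 15))
  sim <- simulate_cohort(spec, seed = seed)
  paths <- character(0)
  for (v in sim$cohort$views) {
    p <- file.path(dir, paste0(v$view_name, ".tsv"))
    write_expression_tsv(v, p)
    paths <- c(paths, p)
  }
  clin <- file.path(dir, "clinical.tsv")
  readr::write_tsv(tibble::as_tibble(sim$cohort$survival), clin)
  config <- list(
    views = lapply(paths, function(p) list(path = p)),
    clinical = list(path = clin, time_col = "time", event_col = "event"),
    params = list(alpha = 0.5),
    C = C,
    C_range = C_range,
    seed = 11,
    output_dir = file.path(dir, "out")
  )
  config[vapply(config, is.null, logical(1))] <- NULL
  list(config = config, sim = sim, spec = spec)
}

# full pipeline recovery for a synthetic spec: fuse, cluster at the true C,
# score against the planted labels
pipeline_ari <- function(spec, seed) {
  sim <- simulate_cohort(spec, seed = seed)
  fit <- skf(sim$cohort)
  asg <- spectral_cluster(fit$fused, C = spec$n_clusters, seed = seed)
  ari(asg$cluster, sim$labels$true_cluster)
}
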