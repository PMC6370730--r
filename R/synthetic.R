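#' Specification for a synthetic multi-view cohort
#'
#' Describes a planted-partition Gaussian cohort with cluster-linked
#' exponential survival — the minimal structure the fusion pipeline
#' assumes: patients fall into latent clusters, each view carries a
#' fraction of informative features whose cluster means are separated by a
#' fixed number of noise standard deviations, and each cluster has its own
#' hazard rate.
#'
#' @param n_patients Total cohort size (default 90).
#' @param n_clusters Number of planted clusters (default 3).
#' @param cluster_proportions Cluster mixing proportions (default equal);
#'   must sum to 1.
#' @param n_features Per-view feature counts; a named or unnamed numeric
#'   vector, one entry per view (default `c(gene = 120, mirna = 80,
#'   isoform = 100)`).
#' @param separation Between-cluster mean separation per informative
#'   feature, in units of `noise_sd` (default 6).
#' @param noise_sd Within-cluster standard deviation (default 1).
#' @param signal_fraction Fraction of informative features per view;
#'   recycled across views (default 0.3).
#' @param hazards Per-cluster exponential event rates (default
#'   `0.05 * 3^(0:(n_clusters - 1))`, i.e. adjacent clusters differ 3-fold
#'   in hazard).
#' @param censoring_rate Target fraction of censored patients in `[0, 1)`
#'   (default 0.2).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 90L,
                           n_clusters = 3L,
                           cluster_proportions = NULL,
                           n_features = c(gene = 120L, mirna = 80L, isoform = 100L),
                           separation = 6,
                           noise_sd = 1,
                           signal_fraction = 0.3,
                           hazards = NULL,
                           censoring_rate = 0.2) {
  check_scalar(n_patients, "n_patients", 3)
  check_scalar(n_clusters, "n_clusters", 1)
  if (n_clusters > n_patients) stopf("more clusters than patients")
  cluster_proportions <- cluster_proportions %||% rep(1 / n_clusters, n_clusters)
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-8 || any(cluster_proportions <= 0)) {
    stopf("`cluster_proportions` must be %d positive values summing to 1", n_clusters)
  }
  if (length(n_features) < 2L || any(n_features < 1)) {
    stopf("`n_features` needs at least 2 views with positive feature counts")
  }
  check_scalar(separation, "separation", 0)
  check_scalar(noise_sd, "noise_sd", .Machine$double.eps)
  signal_fraction <- rep_len(signal_fraction, length(n_features))
  if (any(signal_fraction < 0) || any(signal_fraction > 1)) {
    stopf("`signal_fraction` must lie in [0, 1]")
  }
  hazards <- hazards %||% (0.05 * 3^(seq_len(n_clusters) - 1))
  if (length(hazards) != n_clusters || any(hazards <= 0)) {
    stopf("`hazards` must be %d positive rates", n_clusters)
  }
  check_scalar(censoring_rate, "censoring_rate", 0, 1 - 1e-12)
  if (is.null(names(n_features))) names(n_features) <- paste0("view", seq_along(n_features))
  structure(list(
    n_patients = as.integer(n_patients), n_clusters = as.integer(n_clusters),
    cluster_proportions = cluster_proportions,
    n_features = setNames(as.integer(n_features), names(n_features)),
    separation = separation, noise_sd = noise_sd,
    signal_fraction = signal_fraction, hazards = hazards,
    censoring_rate = censoring_rate
  ), class = "synthetic_spec")
}

# largest-remainder apportionment of n patients to cluster proportions
planted_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(-(raw - counts))[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a multi-view cohort with planted clusters
#'
#' Each view draws its informative features from cluster-specific Gaussian
#' means (a random cluster ordering per feature, adjacent means
#' `separation * noise_sd` apart) and its remaining features from a shared
#' zero-mean Gaussian; all views share the planted labels but differ in
#' which features carry signal. Bit-identical output for a given seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list with `cohort` (a [cohort()] without survival) and
#'   `labels` (a tibble `patient_id`, `true_cluster`).
#' @export
generate_multiview <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(as.integer(seed), {
    counts <- planted_counts(spec$n_patients, spec$cluster_proportions)
    labels <- rep(seq_len(spec$n_clusters), times = counts)
    ids <- sprintf("P%04d", seq_len(spec$n_patients))
    views <- vector("list", length(spec$n_features))
    for (v in seq_along(spec$n_features)) {
      m <- spec$n_features[v]
      n_signal <- round(spec$signal_fraction[v] * m)
      vals <- matrix(rnorm(spec$n_patients * m, sd = spec$noise_sd),
                     spec$n_patients, m)
      if (n_signal > 0 && spec$n_clusters > 1) {
        centers <- seq_len(spec$n_clusters) - (spec$n_clusters + 1) / 2
        for (f in seq_len(n_signal)) {
          ordering <- sample(spec$n_clusters)
          mu <- spec$separation * spec$noise_sd * centers[ordering]
          vals[, f] <- vals[, f] + mu[labels]
        }
      }
      dimnames(vals) <- list(ids, sprintf("%s_f%04d", names(spec$n_features)[v], seq_len(m)))
      views[[v]] <- expression_view(vals, view_name = names(spec$n_features)[v])
    }
    list(
      cohort = cohort(views),
      labels = tibble::tibble(patient_id = ids, true_cluster = as.integer(labels))
    )
  })
}

#' Generate cluster-linked survival for planted labels
#'
#' Event times are exponential with each cluster's hazard; censoring times
#' are independent `Uniform(0, tau)` with `tau` solved numerically so the
#' expected censored fraction matches `spec$censoring_rate`.
#'
#' @param labels Integer cluster labels (or the `labels` tibble from
#'   [generate_multiview()]).
#' @param spec A [synthetic_spec()] supplying `hazards` and
#'   `censoring_rate`.
#' @param seed Integer seed.
#' @param patient_ids Identifiers; taken from the labels tibble when
#'   available.
#' @return A [survival_table()].
#' @export
generate_survival <- function(labels, spec, seed = 1L, patient_ids = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.data.frame(labels)) {
    patient_ids <- patient_ids %||% labels$patient_id
    labels <- labels$true_cluster
  }
  labels <- as.integer(labels)
  patient_ids <- patient_ids %||% sprintf("P%04d", seq_along(labels))
  rates <- spec$hazards[labels]
  withr::with_seed(as.integer(seed), {
    t_event <- rexp(length(labels), rate = rates)
    if (spec$censoring_rate <= 0) {
      return(survival_table(patient_ids, t_event, rep(1L, length(labels))))
    }
    # P(censored | rate, tau) for U ~ Uniform(0, tau): (1 - exp(-rate*tau)) / (rate*tau)
    cens_prob <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau))
    tau <- uniroot(function(x) cens_prob(x) - spec$censoring_rate,
                   lower = 1e-9, upper = 1e9, tol = 1e-10)$root
    u <- runif(length(labels), 0, tau)
    survival_table(patient_ids, pmin(t_event, u), as.integer(t_event <= u))
  })
}

#' Simulate a complete synthetic cohort (views + survival)
#'
#' Convenience wrapper over [generate_multiview()] and
#' [generate_survival()].
#'
#' @param spec A [synthetic_spec()] (defaults to the package defaults).
#' @param seed Integer seed; views and survival use derived sub-seeds so the
#'   whole cohort is reproducible from this one value.
#' @return A list with `cohort` (including survival) and `labels`.
#' @export
#' @examples
#' sim <- simulate_cohort(seed = 42)
#' sim$cohort
simulate_cohort <- function(spec = synthetic_spec(), seed = 1L) {
  seed <- as.integer(seed)
  mv <- generate_multiview(spec, seed = seed)
  surv <- generate_survival(mv$labels, spec, seed = seed + 1L)
  list(cohort = cohort(mv$cohort$views, surv), labels = mv$labels)
}
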