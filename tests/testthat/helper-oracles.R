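# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written as plain loops / direct formulas so they
# share no code path with the package implementation they check.

# Build a one-cluster daily observation table directly from per-egg events.
make_cluster_table <- function(cluster_id = "c1", temperature_c = 20,
                               rh_regime = "medium",
                               hatch_ages = integer(0),
                               death_ages = integer(0),
                               horizon = NULL) {
  n <- length(hatch_ages) + length(death_ages)
  max_age <- max(c(hatch_ages, death_ages, horizon, 0))
  ages <- 0:max_age
  tibble::tibble(
    cluster_id = cluster_id,
    temperature_c = temperature_c,
    rh_regime = rh_regime,
    age_days = ages,
    n_hatched_cum = vapply(ages, function(a) sum(hatch_ages <= a), numeric(1)),
    n_dead_cum = vapply(ages, function(a) sum(death_ages <= a), numeric(1)),
    n_alive = n - n_hatched_cum - n_dead_cum,
    n_yellow = n_alive,
    n_brown = 0L,
    n_blackhead = 0L
  )[, c("cluster_id", "temperature_c", "rh_regime", "age_days", "n_alive",
        "n_yellow", "n_brown", "n_blackhead", "n_hatched_cum", "n_dead_cum")]
}

# Minimal fate tibble from event vectors (one group).
make_fates <- function(ages, outcomes, group = "g1",
                       temperature_c = 20, rh_regime = "medium") {
  tibble::tibble(
    egg_id = sprintf("%s_e%03d", group, seq_along(ages)),
    cluster_id = group,
    temperature_c = temperature_c,
    rh_regime = rh_regime,
    outcome = outcomes,
    event_age_days = as.integer(ages),
    d_yellow = NA_integer_, d_brown = NA_integer_, d_blackhead = NA_integer_
  )
}

# Brute-force survivor fraction at each age (no censoring): the fraction of
# subjects whose death age exceeds x.
empirical_lx <- function(death_ages, at_ages) {
  vapply(at_ages, function(a) mean(death_ages > a), numeric(1))
}

# Brute-force two-group log-rank: explicit per-death-age hypergeometric
# mean and variance sums, scalar form.
brute_logrank2 <- function(time1, death1, time2, death2) {
  times <- sort(unique(c(time1[death1], time2[death2])))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    n1 <- sum(time1 >= t); n2 <- sum(time2 >= t)
    d1 <- sum(time1 == t & death1); d2 <- sum(time2 == t & death2)
    n <- n1 + n2; d <- d1 + d2
    if (n == 0 || d == 0) next
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n - d) * n1 * n2 / (n^2 * (n - 1))
  }
  if (V == 0) return(0)
  (O1 - E1)^2 / V
}

# Random small two-group cohort (deaths + right-censorings at integer ages).
random_two_group_fates <- function(n_per_group = 12, max_age = 8) {
  g <- rep(c("A", "B"), each = n_per_group)
  ages <- sample(seq_len(max_age), 2 * n_per_group, replace = TRUE)
  outcome <- ifelse(stats::runif(2 * n_per_group) < 0.7, "died", "hatched")
  if (!any(outcome == "died")) outcome[1] <- "died"
  tibble::tibble(
    egg_id = sprintf("e%03d", seq_along(g)),
    cluster_id = g,
    temperature_c = ifelse(g == "A", 8, 12),
    rh_regime = "medium",
    outcome = outcome,
    event_age_days = as.integer(ages),
    d_yellow = NA_integer_, d_brown = NA_integer_, d_blackhead = NA_integer_
  )
}

# Direct maximization of the Poisson log-likelihood for a model matrix;
# returns the residual deviance at the optimum.
poisson_deviance_oracle <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(exp(eta)) - sum(y * eta)
  }
  grad <- function(beta) {
    eta <- drop(X %*% beta)
    drop(t(X) %*% (exp(eta) - y))
  }
  start <- rep(0, ncol(X))
  start[1] <- log(mean(y))
  opt <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  sat <- sum(ifelse(y == 0, 0, y * log(y)) - y)
  2 * (sat + opt$value)
}
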