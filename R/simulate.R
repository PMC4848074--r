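#' Waiting times of a single-server FCFS queue (Lindley recurrence)
#'
#' Given per-customer interarrival times and service times, returns each
#' customer's delay in queue under first-come-first-served service with a
#' single server starting empty. Uses the Lindley recurrence
#' \eqn{W_{n+1} = \max(0, W_n + S_n - A_{n+1})} in its vectorized
#' reflected-random-walk form, which reproduces an event-driven simulation
#' of this system exactly.
#'
#' @param interarrival Interarrival times (hours); `interarrival[1]` is the
#'   first customer's arrival time after time zero.
#' @param service Service times (hours), same length.
#' @return Numeric vector of queueing delays, one per customer;
#'   `queue_waits(a, s)[1]` is always 0.
#' @examples
#' queue_waits(c(1, 1, 1), c(2, 2, 2))  # each arrival waits one hour longer
#' @export
queue_waits <- function(interarrival, service) {
  check_numeric(interarrival, "interarrival")
  check_numeric(service, "service")
  n <- length(interarrival)
  if (length(service) != n) {
    rlang::abort("`interarrival` and `service` must have equal length.",
                 class = "eslqueue_domain_error")
  }
  if (any(interarrival < 0) || any(service < 0)) {
    rlang::abort("times must be non-negative.", class = "eslqueue_domain_error")
  }
  if (n == 1L) return(0)
  # W_n = C_{n-1} - min_{0<=k<=n-1} C_k with C_k the partial sums of
  # X_i = S_i - A_{i+1}; the min over the prefix implements the max(0, .)
  # reflection of the recurrence.
  x <- service[-n] - interarrival[-1L]
  cfull <- c(0, cumsum(x))
  cfull - cummin(cfull)
}

draw_service <- function(dist, n) {
  switch(dist$family,
    exponential = stats::rexp(n, rate = 1 / dist$mean),
    deterministic = rep(dist$mean, n),
    lognormal = {
      sigma2 <- log(1 + dist$scv)
      stats::rlnorm(n, meanlog = log(dist$mean) - sigma2 / 2,
                    sdlog = sqrt(sigma2))
    },
    gamma = stats::rgamma(n, shape = 1 / dist$scv,
                          scale = dist$mean * dist$scv))
}

# Deterministic per-replication substream seed so results do not depend on
# the order replications are executed in.
replication_seed <- function(seed, rep) {
  (as.double(seed) %% 2147483647 + 1000003 * rep) %% 2147483647 + 1
}

#' Simulate an M/G/1 FCFS queue
#'
#' Discrete-event simulation of the single-server queue with Poisson
#' arrivals: an independent check on the closed-form mean-wait analysis and
#' the engine for settings the analytics do not cover. Waits are averaged
#' over customers after a warm-up truncation; independent replications (one
#' seeded substream each) give a confidence interval on the mean.
#'
#' @param sys An [mg1_system()] object with utilization below 1.
#' @param n_customers Customers per replication.
#' @param warmup Customers discarded from the start of each replication
#'   before averaging; defaults to 10% of `n_customers`.
#' @param replications Number of independent replications (at least 2, so a
#'   confidence interval exists).
#' @param seed Master seed; each replication derives its own substream from
#'   it, so results are reproducible and independent of execution order.
#' @param event_log If `TRUE`, attach a per-customer event log (first
#'   replication only) with arrival, service start and departure times.
#' @return An object of class `mg1_sim`: a list with `mean_wait`,
#'   `mean_sojourn`, `ci99_halfwidth` (99% t-interval half-width across
#'   replication means, hours), `n_effective` (customers averaged per
#'   replication), a `replications` tibble of per-replication means, and
#'   optionally `events`.
#' @examples
#' sys <- mg1_system(0.25, service_dist("exponential", mean = 2))
#' simulate_mg1(sys, n_customers = 5000, replications = 3, seed = 42)
#' @export
simulate_mg1 <- function(sys, n_customers = 1e5,
                         warmup = ceiling(0.1 * n_customers),
                         replications = 5, seed = 1, event_log = FALSE) {
  mg1_utilization(sys, require_stable = TRUE)
  stopifnot(is.numeric(n_customers), length(n_customers) == 1L,
            n_customers >= 1, is.numeric(warmup), warmup >= 0)
  if (warmup >= n_customers) {
    rlang::abort("`warmup` must be smaller than `n_customers`.",
                 class = "eslqueue_domain_error")
  }
  if (replications < 2) {
    rlang::abort("at least 2 replications are needed for a confidence interval.",
                 class = "eslqueue_domain_error")
  }
  n <- as.integer(n_customers)
  keep <- seq.int(as.integer(warmup) + 1L, n)

  events <- NULL
  one_rep <- function(r) {
    set.seed(replication_seed(seed, r))
    ia <- stats::rexp(n, rate = sys$arrival_rate)
    s <- draw_service(sys$service, n)
    w <- queue_waits(ia, s)
    if (event_log && r == 1L) {
      arr <- cumsum(ia)
      events <<- tibble::tibble(
        customer_id = seq_len(n), arrival_h = arr,
        service_start_h = arr + w, departure_h = arr + w + s)
    }
    c(mean(w[keep]), mean((w + s)[keep]))
  }
  reps <- vapply(seq_len(replications), one_rep, numeric(2))
  rep_tbl <- tibble::tibble(replication = seq_len(replications),
                            mean_wait = reps[1L, ], mean_sojourn = reps[2L, ])
  m <- mean(rep_tbl$mean_wait)
  hw <- stats::qt(0.995, df = replications - 1) *
    stats::sd(rep_tbl$mean_wait) / sqrt(replications)
  structure(list(
    mean_wait = m,
    mean_sojourn = mean(rep_tbl$mean_sojourn),
    ci99_halfwidth = hw,
    n_effective = length(keep),
    replications = rep_tbl,
    events = events,
    seed = seed
  ), class = "mg1_sim")
}

#' @export
print.mg1_sim <- function(x, ...) {
  cat(sprintf(
    "M/G/1 simulation: mean wait %.4f h (99%% CI +/- %.4f), mean sojourn %.4f h\n",
    x$mean_wait, x$ci99_halfwidth, x$mean_sojourn))
  cat(sprintf("  %d replications x %d effective customers, seed %s\n",
              nrow(x$replications), x$n_effective, format(x$seed)))
  invisible(x)
}
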