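test_that("partial likelihood matches closed forms and the double-loop oracle", {
  # single event, risk set of one: -[0 - log(e^0)] = 0
  expect_equal(neg_log_partial_likelihood(0, 1, 1), 0)
  # two events, zero risks: first risk set has 2, second has 1
  expect_equal(neg_log_partial_likelihood(c(0, 0), c(1, 2), c(1, 1)), log(2))
  # random data, including ties, against the naive oracle
  for (s in 1:20) {
    d <- random_surv(10, s)
    d$event[1] <- 1L
    expect_equal(neg_log_partial_likelihood(d$risk, d$time, d$event),
                 oracle_nlpl(d$risk, d$time, d$event),
                 tolerance = 1e-10)
  }
  expect_error(neg_log_partial_likelihood(c(0, 0), c(1, 2), c(0, 0)), "no events")
  # averaged variant divides by the event count
  d <- random_surv(12, 99); d$event[1] <- 1L
  expect_equal(neg_log_partial_likelihood(d$risk, d$time, d$event, average = TRUE),
               neg_log_partial_likelihood(d$risk, d$time, d$event) / sum(d$event))
})

test_that("partial likelihood is invariant to constant risk shifts", {
  for (s in 1:5) {
    d <- random_surv(15, s); d$event[2] <- 1L
    base <- neg_log_partial_likelihood(d$risk, d$time, d$event)
    expect_equal(neg_log_partial_likelihood(d$risk + 37.5, d$time, d$event),
                 base, tolerance = 1e-8)
    expect_equal(neg_log_partial_likelihood(d$risk - 500, d$time, d$event),
                 base, tolerance = 1e-8)
  }
})

test_that("partial-likelihood gradient matches finite differences", {
  d <- random_surv(12, 4); d$event[1] <- 1L
  g <- pathsurv:::nlpl_gradient(d$risk, d$time, d$event)
  eps <- 1e-6
  for (i in seq_along(d$risk)) {
    rp <- d$risk; rp[i] <- rp[i] + eps
    rm <- d$risk; rm[i] <- rm[i] - eps
    fd <- (neg_log_partial_likelihood(rp, d$time, d$event) -
           neg_log_partial_likelihood(rm, d$time, d$event)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("concordance matches perfect orderings and exhaustive enumeration", {
  t <- c(3, 1, 4, 2, 5)
  expect_equal(concordance_index(-t, t, rep(1, 5)), 1.0)
  expect_equal(concordance_index(t, t, rep(1, 5)), 0.0)
  for (s in 1:20) {
    d <- random_surv(20, s + 100); d$event[1] <- 1L
    expect_identical(concordance_index(d$risk, d$time, d$event),
                     oracle_cindex(d$risk, d$time, d$event))
    expect_identical(concordance_index(d$risk, d$time, d$event, ties = "strict"),
                     oracle_cindex(d$risk, d$time, d$event, ties = "strict"))
  }
  expect_error(concordance_index(c(1, 2), c(1, 2), c(0, 0)), "no comparable pairs")
  expect_equal(concordance_index(-t, t, rep(1, 5), percent = TRUE), 100)
})

test_that("concordance agrees with the survival package on tie-free data", {
  set.seed(8)
  time <- rexp(40); risk <- rnorm(40); event <- rbinom(40, 1, 0.6)
  event[1] <- 1L
  ref <- survival::concordance(survival::Surv(time, event) ~ risk, reverse = TRUE)
  expect_equal(concordance_index(risk, time, event), unname(ref$concordance),
               tolerance = 1e-12)
})

test_that("complementary risks give complementary concordance without ties", {
  for (s in 1:5) {
    set.seed(s)
    time <- sort(rexp(15)); risk <- rnorm(15); event <- rbinom(15, 1, 0.8)
    event[1] <- 1L
    expect_equal(concordance_index(risk, time, event) +
                 concordance_index(-risk, time, event), 1)
  }
})

test_that("Kaplan-Meier reproduces closed forms and the hand product-limit", {
  all_cens <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(all_cens), 0L)

  km3 <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km3$survival, c(2 / 3, 1 / 3, 0))
  # all events, distinct times: equals the empirical survival function
  expect_equal(km3$survival, 1 - (1:3) / 3)

  time <- c(1, 2, 2, 3, 4, 5, 6, 7)
  event <- c(1, 1, 0, 1, 0, 1, 0, 0)
  km <- kaplan_meier(time, event)
  expect_equal(km$time, c(1, 2, 3, 5))
  expect_equal(km$survival, c(0.875, 0.75, 0.6, 0.4))
  expect_equal(km$survival, oracle_km(time, event)$survival)
  # non-increasing step function bounded by 1
  expect_true(all(diff(km$survival) <= 0) && km$survival[1] <= 1)
})

test_that("log-rank test matches symmetry, the O-E oracle, and rejects bad input", {
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  ta <- 1:10; tb <- 11:20
  lr <- logrank_test(ta, rep(1, 10), tb, rep(1, 10))
  expect_equal(lr$statistic, oracle_logrank(ta, rep(1, 10), tb, rep(1, 10)),
               tolerance = 1e-8)
  expect_lt(lr$p_value, 0.05)

  expect_error(logrank_test(1:3, rep(0, 3), 4:6, rep(0, 3)), "no events")
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("median split sends ties at the median to the low group", {
  expect_equal(which(median_split(c(1, 2, 3, 4))), c(3L, 4L))
  expect_equal(which(median_split(c(1, 1, 2, 2))), c(3L, 4L))
  expect_error(median_split(c(5, 5, 5)), "no split possible")
})

test_that("KS comparison handles identical, separated and single-point samples", {
  same <- ks_compare(1:10, 1:10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(2)
  far <- ks_compare(rnorm(100), rnorm(100, 3))
  expect_lt(far$p_value, 0.001)

  expect_equal(ks_compare(0, 1)$statistic, 1)
  expect_error(ks_compare(numeric(0), 1), "non-empty")
})
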