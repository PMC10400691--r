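test_that("experiment config validates feasibility", {
  expect_error(experiment_config(beds = 0))
  expect_error(experiment_config(initial_demand = 50, policies = 2),
               "initial_demand")
  expect_error(experiment_config(queue_length = 3, policies = 0),
               "replace_count")
  # pure ex-post policies tolerate short queues
  expect_s3_class(experiment_config(queue_length = 3, policies = c(1, 3)),
                  "experiment_config")
})

test_that("degenerate death probabilities pin mortality to 0 or 1", {
  for (p_fix in c(0, 1)) {
    tri <- triangular(p_fix, p_fix, p_fix)
    mix <- population_mix(share_comorbid = 0, baseline = tri)
    cfg <- experiment_config(replications = 1, mix = mix, policies = 0,
                             master_seed = 1)
    res <- run_replication(policy_spec(0), cfg)
    expect_equal(res$m_total, rep(p_fix, 4))
    expect_equal(res$m_healthy, rep(p_fix, 4))
    expect_true(all(is.na(res$m_comorbid)))
    expect_equal(res$treated_healthy, rep(60, 4))
  }
})

test_that("a replication reproduces a hand-traced toy instance", {
  # B = 3 beds, demand of 4, queue of 2, one reallocation, policy 3.
  # Demand: ids 1-4, p = (.1, .5, .3, .2), y = (0, 1, 0, 0),
  #   comorbid = (0, 1, 1, 0).
  # Ex-ante initial allocation keeps the 3 lowest p: ids 1, 4, 3.
  #   t=0: deaths 0 -> m_0 = 0; healthy treated {1,4}, comorbid {3}.
  # Queue: ids 5 (p=.05, y=1, comorbid), 6 (p=.9, y=0, healthy).
  # Ex-post pool {1,4,3,5,6}: keep ids 5, 1, 4; discharge 3; deny 6.
  #   t=1: y of {5,1,4} = (1,0,0) -> m_1 = 1/3; healthy {1,4} m = 0;
  #   comorbid {5} m = 1; admitted comorbid 1, discharged comorbid 1.
  src <- function(count, id_offset) {
    if (id_offset == 0) fixed_patients(1:4, c(0, 1, 1, 0),
                                       c(0.1, 0.5, 0.3, 0.2),
                                       c(0, 1, 0, 0))
    else fixed_patients(5:6, c(1, 0), c(0.05, 0.9), c(1, 0))
  }
  cfg <- experiment_config(replications = 1, horizon = 1, beds = 3,
                           initial_demand = 4, queue_length = 2,
                           policies = 3, master_seed = 1)
  res <- run_replication(policy_spec(3), cfg, patient_source = src)
  expect_equal(res$time, c(0, 1))
  expect_equal(res$m_total, c(0, 1 / 3))
  expect_equal(res$m_healthy, c(0, 0))
  expect_equal(res$m_comorbid, c(0, 1))
  expect_equal(res$treated_healthy, c(2, 2))
  expect_equal(res$treated_comorbid, c(1, 1))
  expect_equal(res$admitted_comorbid, c(1, 1))
  expect_equal(res$admitted_healthy, c(2, 0))
  expect_equal(res$discharged_comorbid, c(0, 1))
  expect_equal(res$discharged_healthy, c(0, 0))
})

test_that("treated counts always sum to capacity and mortality decomposes", {
  cfg <- small_config()
  for (pid in c(0, 3, 5)) {
    res <- do.call(rbind, lapply(1:10, function(r)
      run_replication(policy_spec(pid), cfg, r)))
    expect_true(all(res$treated_healthy + res$treated_comorbid == 60))
    # B * m_t = nh * m^n + nv * m^v, with absent-group terms zero
    lhs <- 60 * res$m_total
    rhs <- ifelse(res$treated_healthy > 0,
                  res$treated_healthy * res$m_healthy, 0) +
           ifelse(res$treated_comorbid > 0,
                  res$treated_comorbid * res$m_comorbid, 0)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("policies sharing an initial mode have identical t = 0 cohorts", {
  cfg <- small_config()
  for (pair in list(c(0, 1), c(2, 3), c(4, 5))) {
    for (r in 1:5) {
      a <- run_replication(policy_spec(pair[1]), cfg, r)
      b <- run_replication(policy_spec(pair[2]), cfg, r)
      expect_identical(a[a$time == 0, ], b[b$time == 0, ])
    }
  }
})

test_that("experiments are bitwise reproducible from the master seed", {
  cfg <- experiment_config(replications = 10, policies = c(0, 5),
                           master_seed = 31)
  ex1 <- run_experiment(cfg)
  ex2 <- run_experiment(cfg)
  expect_identical(ex1$replications, ex2$replications)
  expect_identical(ex1$summary, ex2$summary)
})

test_that("single-replication summaries equal the replication itself", {
  cfg <- experiment_config(replications = 1, policies = 3, master_seed = 9)
  ex <- run_experiment(cfg)
  one <- run_replication(policy_spec(3), cfg, 1)
  expect_equal(ex$summary$mean_m_total, one$m_total)
  expect_equal(ex$summary$sd_m_total, rep(NA_real_, 4))
  expect_equal(ex$summary$n_reps, rep(1L, 4))
})

test_that("ex-post policies dominate in mean t = 1 mortality (3 <= 1 <= 0)", {
  cfg <- experiment_config(replications = 300, policies = c(0, 1, 3),
                           master_seed = 5)
  ex <- run_experiment(cfg)
  s <- ex$summary[ex$summary$time == 1, ]
  m <- s$mean_m_total; names(m) <- s$policy
  se <- s$sd_m_total / sqrt(s$n_reps); names(se) <- s$policy
  expect_lt(m["3"], m["1"] + 2 * sqrt(se["3"]^2 + se["1"]^2))
  expect_lt(m["1"], m["0"] + 2 * sqrt(se["1"]^2 + se["0"]^2))
})

test_that("healthy-group mortality under random allocation is unbiased", {
  cfg <- experiment_config(replications = 400, policies = 0, master_seed = 13)
  ex <- run_experiment(cfg)
  s <- ex$summary
  # random allocation never selects on prognosis, so the healthy group's
  # mortality stays at the baseline triangle mean at every time point
  for (t in 0:3) {
    mh <- s$mean_m_healthy[s$time == t]
    se <- s$sd_m_healthy[s$time == t] / sqrt(400)
    expect_lt(abs(mh - 0.165), 3 * se)
  }
})

test_that("sensitivity grid honours scale invariance in e and skips infeasible cells", {
  cfg <- experiment_config(replications = 20, policies = c(0, 5),
                           master_seed = 3)
  grid <- sensitivity_grid(cfg, demands = 70, queues = 10,
                           misestimations = c(0.9, 1, 1.1))
  expect_length(grid, 3)
  expect_identical(grid[[1]]$experiment$replications,
                   grid[[2]]$experiment$replications)
  expect_identical(grid[[2]]$experiment$replications,
                   grid[[3]]$experiment$replications)
  # the e = 1 cell equals a plain run of the base configuration
  expect_identical(grid[[2]]$experiment$summary, run_experiment(cfg)$summary)

  expect_warning(
    short <- sensitivity_grid(cfg, demands = 70, queues = 3,
                              misestimations = 1),
    "infeasible")
  expect_length(short, 0)
})

test_that("larger queues strengthen the mortality reduction of ex-post triage", {
  cfg <- experiment_config(replications = 150, policies = 5, master_seed = 19)
  grid <- sensitivity_grid(cfg, demands = 70, queues = c(10, 60),
                           misestimations = 1)
  m1 <- vapply(grid, function(cell) {
    s <- cell$experiment$summary
    s$mean_m_total[s$time == 1]
  }, numeric(1))
  w <- vapply(grid, `[[`, numeric(1), "w")
  expect_lte(m1[w == 60], m1[w == 10])
})
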