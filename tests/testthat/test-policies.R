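test_that("policy ids map to the fixed initial/consecutive combinations", {
  modes <- t(vapply(0:5, function(i) {
    s <- policy_spec(i)
    c(s$initial_mode, s$consecutive_mode)
  }, character(2)))
  expect_equal(modes[, 1],
               c("random", "random", "exante", "exante", "mixed", "mixed"))
  expect_equal(modes[, 2],
               rep(c("random_replacement", "expost"), 3))
  expect_error(policy_spec(6))
})

test_that("ex-ante initial allocation picks the lowest death probabilities", {
  set.seed(10)
  demand <- fixed_patients(1:70, rbinom(70, 1, 0.5), runif(70),
                           rbinom(70, 1, 0.3))
  alloc <- initial_allocation(policy_spec(2), demand, beds = 60)
  # brute-force sort oracle
  expect_setequal(alloc$treated, demand$id[order(demand$p)][1:60])
  expect_lt(max(demand$p[demand$id %in% alloc$treated]),
            min(demand$p[demand$id %in% alloc$denied]))
  expect_length(alloc$treated, 60)
  expect_setequal(c(alloc$treated, alloc$denied), demand$id)
})

test_that("demand equal to capacity admits everyone in every mode", {
  set.seed(11)
  demand <- fixed_patients(1:60, rbinom(60, 1, 0.5), runif(60), 0)
  for (pid in c(0, 2)) {
    alloc <- initial_allocation(policy_spec(pid), demand, beds = 60)
    expect_setequal(alloc$treated, demand$id)
    expect_length(alloc$denied, 0)
  }
  expect_error(initial_allocation(policy_spec(2), demand, beds = 61),
               "infeasible demand")
})

test_that("mixed initial allocation fills 54 random and 6 triage slots", {
  set.seed(12)
  demand <- fixed_patients(1:70, rbinom(70, 1, 0.5), runif(70), 0)
  alloc <- initial_allocation(policy_spec(4), demand, beds = 60)
  expect_length(alloc$treated, 60)
  # the 6 triage slots are the lowest-p patients among the 16 not taken
  # by the 54 random slots
  rand54 <- alloc$treated[1:54]
  tri6 <- alloc$treated[55:60]
  rest <- demand[!demand$id %in% rand54, ]
  expect_setequal(tri6, rest$id[order(rest$p)][1:6])
})

test_that("random replacement swaps exactly replace_count patients", {
  set.seed(13)
  treated <- fixed_patients(1:60, 0, runif(60), 0)
  queue <- fixed_patients(61:70, 0, runif(10), 0)
  alloc <- step_random_replacement(treated, queue, 6)
  expect_length(alloc$discharged, 6)
  expect_length(alloc$admitted, 6)
  expect_length(alloc$denied, 4)
  expect_length(alloc$treated, 60)
  expect_true(all(alloc$discharged %in% treated$id))
  expect_true(all(alloc$admitted %in% queue$id))
  expect_setequal(alloc$treated,
                  c(setdiff(treated$id, alloc$discharged), alloc$admitted))

  # degenerate counts
  none <- step_random_replacement(treated, queue, 0)
  expect_setequal(none$treated, treated$id)
  expect_setequal(none$denied, queue$id)
  all10 <- step_random_replacement(treated, queue, 10)
  expect_setequal(all10$admitted, queue$id)
  expect_error(step_random_replacement(treated, queue, 11), "exceeds")
})

test_that("ex-post triage keeps the lowest-probability pool members", {
  set.seed(14)
  treated <- fixed_patients(1:60, 0, runif(60), 0)
  queue <- fixed_patients(61:70, 0, runif(10), 0)
  alloc <- step_expost_triage(treated, queue, beds = 60)
  pool_p <- c(treated$p, queue$p)
  names(pool_p) <- c(treated$id, queue$id)
  keep_oracle <- as.integer(names(sort(pool_p)[1:60]))
  expect_setequal(alloc$treated, keep_oracle)
  expect_lt(max(pool_p[as.character(alloc$treated)]),
            min(pool_p[as.character(c(alloc$discharged, alloc$denied))]))

  # empty queue leaves the cohort unchanged
  empty <- fixed_patients(integer(0), integer(0), numeric(0), integer(0))
  keep <- step_expost_triage(treated, empty, beds = 60)
  expect_setequal(keep$treated, treated$id)

  # a uniformly better queue displaces the worst bed-holders
  good_queue <- fixed_patients(61:70, 0, treated$p[order(treated$p)][1:10] / 100, 0)
  sw <- step_expost_triage(treated, good_queue, beds = 60)
  expect_setequal(sw$admitted, good_queue$id)
  expect_setequal(sw$discharged, treated$id[order(treated$p,
                                                  decreasing = TRUE)][1:10])
})

test_that("bed count is conserved by every operation", {
  set.seed(15)
  for (i in 1:10) {
    demand <- fixed_patients(1:70, rbinom(70, 1, 0.7), runif(70), 0)
    queue <- fixed_patients(71:80, rbinom(10, 1, 0.7), runif(10), 0)
    for (pid in 0:5) {
      spec <- policy_spec(pid)
      alloc <- initial_allocation(spec, demand, beds = 60)
      expect_length(alloc$treated, 60)
      treated <- demand[match(alloc$treated, demand$id), ]
      step <- if (spec$consecutive_mode == "expost")
        step_expost_triage(treated, queue, beds = 60)
      else step_random_replacement(treated, queue, 6)
      expect_length(step$treated, 60)
      expect_length(intersect(step$admitted, step$discharged), 0)
      expect_setequal(step$treated,
                      c(setdiff(treated$id, step$discharged), step$admitted))
    }
  }
})

test_that("allocations are exactly invariant to the misestimation scale", {
  set.seed(16)
  demand <- fixed_patients(1:70, rbinom(70, 1, 0.7), runif(70), 0)
  queue <- fixed_patients(71:80, rbinom(10, 1, 0.7), runif(10), 0)
  for (pid in c(2, 3, 4, 5)) {
    spec <- policy_spec(pid)
    allocs <- lapply(c(0.9, 1, 1.1), function(e) {
      set.seed(77)
      a <- initial_allocation(spec, demand, beds = 60, e = e)
      treated <- demand[match(a$treated, demand$id), ]
      s <- if (spec$consecutive_mode == "expost")
        step_expost_triage(treated, queue, beds = 60, e = e)
      else step_random_replacement(treated, queue, 6)
      list(a, s)
    })
    expect_identical(allocs[[1]], allocs[[2]])
    expect_identical(allocs[[2]], allocs[[3]])
  }
})

test_that("ex-post never leaves more death probability than random replacement", {
  set.seed(17)
  for (i in 1:20) {
    treated <- fixed_patients(1:60, rbinom(60, 1, 0.7), runif(60), 0)
    queue <- fixed_patients(61:70, rbinom(10, 1, 0.7), runif(10), 0)
    p_of <- function(ids) {
      all_p <- c(treated$p, queue$p); names(all_p) <- c(treated$id, queue$id)
      sum(all_p[as.character(ids)])
    }
    ex <- step_expost_triage(treated, queue, beds = 60)
    rnd <- step_random_replacement(treated, queue, 6)
    expect_lte(p_of(ex$treated), p_of(rnd$treated))
  }
})

test_that("ties in perceived probability are resolved without bias or crash", {
  set.seed(18)
  demand <- fixed_patients(1:70, 0, rep(0.5, 70), 0)
  alloc <- initial_allocation(policy_spec(2), demand, beds = 60)
  expect_length(alloc$treated, 60)
  # all-tied pool: every patient can win a bed across seeds
  picks <- unlist(lapply(1:50, function(s) {
    set.seed(s)
    initial_allocation(policy_spec(2), demand, beds = 60)$denied
  }))
  expect_gt(length(unique(picks)), 30)
})
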