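test_that("lattice initialisation is a seeded uniform permutation", {
  expect_equal(init_lattice(1, 5), 1L)
  expect_equal(init_lattice(5, 42), init_lattice(5, 42))
  expect_false(identical(init_lattice(50, 1), init_lattice(50, 2)))
  expect_equal(sort(init_lattice(1000, 3)), 1:1000)
  expect_error(init_lattice(0, 1), ">= 1")
})

test_that("default rule range grows with the lattice and stays in bounds", {
  expect_equal(compute_R(4), 3L)
  expect_equal(compute_R(600), 98L)
  expect_equal(compute_R(5000), 283L)
  Rs <- vapply(4:400, compute_R, integer(1))
  expect_true(all(diff(Rs) >= 0))
  expect_true(all(Rs >= 3L & Rs <= (4:400) - 1L))
  expect_error(compute_R(3), "at least 4")
})

test_that("the swap rule compares neighbour against range-r cell, with wraparound", {
  n <- 8
  # distances from read 1: read 2 is far, read 5 is close -> phi_5 at c_1 swaps
  D <- matrix(1, n, n); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 5
  D[1, 5] <- D[5, 1] <- 0.5
  res <- apply_rule(1:n, i = 1, r = 5, D)
  expect_true(res$swapped)
  expect_equal(res$order, c(1L, 5L, 3L, 4L, 2L, 6L, 7L, 8L))

  # same rule at c_{N-3} reaches x_1 through the periodic boundary
  D2 <- matrix(1, n, n); diag(D2) <- 0
  D2[5, 6] <- D2[6, 5] <- 5
  D2[5, 1] <- D2[1, 5] <- 0.5
  res2 <- apply_rule(1:n, i = n - 3, r = 5, D2)
  expect_true(res2$swapped)
  expect_equal(res2$order, c(6L, 2L, 3L, 4L, 5L, 1L, 7L, 8L))

  # equal distances never swap
  Deq <- matrix(2, n, n); diag(Deq) <- 0
  for (i in 1:n) for (r in 3:(n - 1))
    expect_false(apply_rule(1:n, i, r, Deq)$swapped)

  expect_error(apply_rule(1:n, 1, 2, D), "r must")
  expect_error(apply_rule(1:n, 1, n, D), "r must")
})

test_that("compiled sweep matches a plain loop of apply_rule calls", {
  set.seed(13)
  for (t in 1:5) {
    n <- 12
    X <- matrix(runif(n * 8), n)
    D <- as.matrix(dist(X))
    ord <- init_lattice(n, t)
    R <- 5L
    ref <- reference_sweep(ord, D, R)
    got <- run_iteration(ord, D, R = R)
    expect_equal(got$order, ref$order)
    expect_equal(got$swaps, ref$swaps)
    expect_equal(sort(got$order), 1:n)
  }
})

test_that("a lattice at a fixpoint stays put and reports zero swaps", {
  n <- 10
  Deq <- matrix(3, n, n); diag(Deq) <- 0
  got <- run_iteration(1:n, Deq, R = 4L)
  expect_equal(got$swaps, 0L)
  expect_equal(got$order, 1:n)
})

test_that("identical reads converge immediately; converged states are true fixpoints", {
  n <- 20
  D0 <- matrix(0, n, n)
  cv <- run_to_convergence(init_lattice(n, 9), D0, R = 6L)
  expect_true(cv$converged)
  expect_equal(cv$iterations, 1L)
  expect_equal(cv$swaps_per_iteration, 0L)

  set.seed(31)
  inst <- random_cluster_instance(80, g = 3)
  cv <- run_to_convergence(init_lattice(80, 4), inst$D, R = 10L)
  expect_true(cv$converged)
  expect_equal(brute_force_triggers(cv$order, inst$D, cv$R), 0L)
  expect_equal(sort(cv$order), 1:80)
})

test_that("convergence runs are deterministic in the seed", {
  set.seed(17)
  inst <- random_cluster_instance(60, g = 2)
  a <- run_to_convergence(init_lattice(60, 123), inst$D, R = 10L)
  b <- run_to_convergence(init_lattice(60, 123), inst$D, R = 10L)
  expect_identical(a$order, b$order)
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$swaps_per_iteration, b$swaps_per_iteration)
})

test_that("two well-separated groups end up contiguous on the circle", {
  set.seed(5)
  centers <- rbind(rep(c(1, 0), each = 8), rep(c(0, 1), each = 8)) / 8
  X <- centers[rep(1:2, each = 50), ] + matrix(rnorm(100 * 16, 0, 0.004), 100)
  D <- as.matrix(dist(X))
  lab <- rep(1:2, each = 50)
  cv <- run_to_convergence(init_lattice(100, 77), D)
  expect_true(cv$converged)
  r <- rle(lab[cv$order])$lengths
  circular_runs <- length(r) -
    (length(r) > 1 && lab[cv$order][1] == lab[cv$order][100])
  expect_lte(circular_runs, 2)
})

test_that("non-convergent dynamics stop, warn, and return a valid permutation", {
  set.seed(2)
  n <- 40
  X <- matrix(runif(n * 16), n); X <- X / rowSums(X)
  D <- as.matrix(dist(X))   # unstructured: frustrated, no fixpoint expected
  expect_warning(cv <- run_to_convergence(init_lattice(n, 8), D, R = 12L,
                                          max_iterations = 300),
                 "did not reach")
  expect_false(cv$converged)
  expect_true(cv$stopped %in% c("cycle", "max_iterations"))
  expect_equal(sort(cv$order), 1:n)
})

test_that("the optional state trace records one snapshot per iteration", {
  set.seed(19)
  inst <- random_cluster_instance(50, g = 2)
  cv <- run_to_convergence(init_lattice(50, 3), inst$D, R = 10L,
                           trace = TRUE)
  expect_true(cv$converged)
  expect_equal(dim(cv$trace), c(50L, cv$iterations))
  expect_equal(cv$trace[, cv$iterations], cv$order)
  for (j in seq_len(ncol(cv$trace)))
    expect_equal(sort(cv$trace[, j]), 1:50)
})
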