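test_that("egalitarian initialisation divides the grooming budget equally", {
  net10 <- init_egalitarian(10)
  expect_equal(unique(net10[row(net10) != col(net10)]), 100 / 9)
  expect_equal(rowSums(net10), rep(100, 10))

  net2 <- init_egalitarian(2)
  expect_equal(net2[1, 2], 100)
  expect_equal(net2[2, 1], 100)

  net20 <- init_egalitarian(20)
  expect_equal(unique(net20[row(net20) != col(net20)]), 100 / 19)
  expect_equal(rowSums(net20), rep(100, 20))

  expect_error(init_egalitarian(1), ">= 2")
})

test_that("social_network validates budget, sign and shape", {
  w <- matrix(c(0, 60, 40, 50, 0, 50, 10, 90, 0), 3, 3, byrow = TRUE)
  expect_s3_class(social_network(w), "social_network")
  expect_error(social_network(w[, 1:2]), "square")
  w_bad <- w; w_bad[1, 2] <- 70
  expect_error(social_network(w_bad), "sum to 100")
  w_neg <- w; w_neg[1, 2] <- -10; w_neg[1, 3] <- 110
  expect_error(social_network(w_neg), "non-negative")
  w_diag <- w; diag(w_diag) <- c(1, 0, 0); w_diag[1, 2] <- 59
  expect_error(social_network(w_diag), "zero")
})

test_that("transfer moves exactly the cross-subgroup share onto companions", {
  # individual 1 grooms {2: 40, 3: 30, 4: 30}; shares an area with 2 only;
  # at T=50 it loses 15+15 across the split and gives all 30 to individual 2
  w <- matrix(c(0, 40, 30, 30,
                40, 0, 30, 30,
                30, 30, 0, 40,
                30, 30, 40, 0), 4, 4, byrow = TRUE)
  net <- social_network(w)
  a <- day_assignment(c(1, 1, 2, 2))
  out <- transfer_update(net, a, 50)
  expect_equal(out[1, ], c(0, 70, 15, 15))
  expect_equal(rowSums(out), rep(100, 4))

  expect_equal(unclass(transfer_update(net, a, 0)), unclass(net))

  out100 <- transfer_update(net, a, 100)
  expect_equal(out100[1, ], c(0, 100, 0, 0))
  expect_equal(out100[3, ], c(0, 0, 0, 100))
})

test_that("an individual alone in its area keeps its outgoing links frozen", {
  net <- init_egalitarian(5)
  a <- day_assignment(c(2, 1, 1, 1, 1))
  out <- transfer_update(net, a, 80)
  expect_equal(out[1, ], unclass(net)[1, ])        # row of the loner: frozen
  expect_equal(out[2, 1], 25 * 0.2)                # others drop their link to it
  expect_equal(rowSums(out), rep(100, 5))
})

test_that("a day without a split leaves the network untouched", {
  net <- random_network(6)
  a <- day_assignment(rep(1L, 6))
  expect_equal(unclass(transfer_update(net, a, 90)), unclass(net))
})

test_that("grooming budgets are conserved and non-negative under any update sequence", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    net <- random_network(n)
    for (step in 1:30) {
      a <- day_assignment(sample(1:2, n, replace = TRUE))
      net <- transfer_update(net, a, stats::runif(1, 0, 100))
      expect_true(all(abs(rowSums(net) - 100) < 1e-9))
      expect_true(all(net >= 0))
    }
  }
})

test_that("repeated transfer with a fixed split clusters monotonically toward 100", {
  set.seed(7)
  net <- random_network(8)
  a <- day_assignment(c(1, 1, 1, 1, 2, 2, 2, 2))
  prev <- within_subgroup_sums(net, a)
  for (k in 1:60) {
    net <- transfer_update(net, a, 30)
    cur <- within_subgroup_sums(net, a)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
  expect_equal(prev, rep(100, 8), tolerance = 1e-6)
})

test_that("transfer agrees with a link-by-link brute force on all small partitions", {
  set.seed(11)
  for (n in 3:6) {
    net <- random_network(n)
    asg <- all_assignments(n)
    for (Tpct in c(0, 25, 100)) {
      for (j in seq_len(nrow(asg))) {
        a <- asg[j, ]
        got <- transfer_update(net, day_assignment(a), Tpct)
        want <- bf_transfer_update(unclass(net), a, Tpct)
        expect_equal(unclass(got), want, tolerance = 1e-12)
      }
    }
  }
})

test_that("the irreversible-fission criterion needs both subgroup size and social-time concentration", {
  net <- init_egalitarian(10)
  half <- day_assignment(rep(c(1, 2), each = 5))
  # homogeneous network: within sums are 4 * 100/9 ~ 44.4 < 95
  expect_false(check_irreversible(net, half))

  # a subgroup of 2 is a dispersion, never a fission, whatever the weights
  skewed <- day_assignment(c(rep(1, 8), 2, 2))
  net_skew <- transfer_update(net, skewed, 100)
  expect_false(check_irreversible(net_skew, skewed))

  # full transfer along a 5/5 split saturates the criterion the next day
  net_split <- transfer_update(net, half, 100)
  expect_true(check_irreversible(net_split, half))
  expect_equal(within_subgroup_sums(net_split, half), rep(100, 10))

  # a single-area day is never a fission
  expect_false(check_irreversible(net_split, day_assignment(rep(1L, 10))))

  # threshold boundary is inclusive
  near <- make_fixture("near_fission", 10, within = 95)
  expect_true(check_irreversible(near, half, threshold = 95))
})
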