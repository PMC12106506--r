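test_that("paired_t matches the hand calculation and the dz identity", {
  # differences 1, 2, 3: mean 2, sd 1 -> d = 2, t = 2 sqrt(3)
  r <- paired_t(c(3, 5, 7), c(2, 3, 4))
  expect_equal(r$d, 2)
  expect_equal(r$t, 2 * sqrt(3))
  expect_equal(r$df, 2L)

  # identical samples
  r0 <- paired_t(1:5, 1:5)
  expect_equal(r0$t, 0)
  expect_equal(r0$d, 0)

  # t = d sqrt(n) on random data, and agreement with stats::t.test
  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- rnorm(n, 1); y <- rnorm(n)
    r <- paired_t(x, y)
    expect_equal(r$t, r$d * sqrt(r$n), tolerance = 1e-12)
    tt <- t.test(x, y, paired = TRUE)
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  }

  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_error(paired_t(1, 1), "at least 2")

  # pairwise-complete dropping
  rp <- paired_t(c(3, 5, 7, NA), c(2, 3, 4, 9))
  expect_equal(rp$n, 3)
  expect_equal(rp$n_dropped, 1)
})

test_that("cohens_d_from_t applies the paired standardizer", {
  expect_equal(cohens_d_from_t(0, 17), 0)
  expect_equal(cohens_d_from_t(2 * sqrt(3), 3), 2, tolerance = 1e-12)
  expect_error(cohens_d_from_t(1, 1), ">= 2")
})

test_that("rm_anova_2x2 matches the aov Error-strata oracle", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(5:15, 1)
    d <- expand.grid(subject = factor(seq_len(n)),
                     a = factor(c("act", "pas")), b = factor(c("av", "va")))
    d$value <- rnorm(nrow(d), 100) + 15 * (d$a == "pas") +
      rnorm(nrow(d), 0, 5)
    mine <- rm_anova_2x2(d)
    oa <- summary(aov(value ~ a * b + Error(subject / (a * b)), data = d))
    f_or <- c(oa[["Error: subject:a"]][[1]]["a", "F value"],
              oa[["Error: subject:b"]][[1]]["b", "F value"],
              oa[["Error: subject:a:b"]][[1]]["a:b", "F value"])
    p_or <- c(oa[["Error: subject:a"]][[1]]["a", "Pr(>F)"],
              oa[["Error: subject:b"]][[1]]["b", "Pr(>F)"],
              oa[["Error: subject:a:b"]][[1]]["a:b", "Pr(>F)"])
    expect_equal(mine$F, f_or, tolerance = 1e-10)
    expect_equal(mine$p, p_or, tolerance = 1e-10)
    # definitional identity, df1 = 1
    expect_equal(mine$partial_eta_sq, mine$F / (mine$F + n - 1),
                 tolerance = 1e-12)
  }
})

test_that("2x2 ANOVA condition effect is the squared paired t on margins", {
  set.seed(44)
  n <- 11
  base <- rnorm(n, 300, 60)
  side <- rnorm(n, 40, 10)
  k <- rnorm(n, 35, 8)  # active = passive - k_i per subject, no interaction
  d <- rbind(
    data.frame(subject = 1:n, a = "active", b = "av", value = base + side - k),
    data.frame(subject = 1:n, a = "active", b = "va", value = base - side - k),
    data.frame(subject = 1:n, a = "passive", b = "av", value = base + side),
    data.frame(subject = 1:n, a = "passive", b = "va", value = base - side)
  )
  res <- rm_anova_2x2(d)
  marg <- aggregate(value ~ subject + a, d, mean)
  t_cond <- paired_t(marg$value[marg$a == "active"],
                     marg$value[marg$a == "passive"])
  expect_equal(res$F[res$effect == "a"], t_cond$t^2, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "a:b"], 0)

  # all cells identical within subject -> no effects at all
  flat <- d
  flat$value <- rep(base, 4)
  expect_true(all(rm_anova_2x2(flat)$F == 0))

  # incomplete subject dropped with a warning
  expect_warning(res2 <- rm_anova_2x2(d[-1, ]), "dropped")
  expect_equal(attr(res2, "n"), n - 1)
})

test_that("partial_eta_sq is F df1 / (F df1 + df2)", {
  expect_equal(partial_eta_sq(0, 1, 16), 0)
  expect_equal(partial_eta_sq(16, 1, 16), 0.5)
  expect_equal(partial_eta_sq(3, 2, 12), 6 / 18)
  expect_error(partial_eta_sq(-1, 1, 16), ">= 0")
})

test_that("noncentral-t power matches stats::power.t.test and is monotone", {
  grid <- expand.grid(d = c(0.3, 0.6, 0.95, 1.4), n = c(5, 14, 30))
  for (i in seq_len(nrow(grid))) {
    for (tails in c("one", "two")) {
      mine <- power_paired_t(grid$d[i], grid$n[i], 0.05, tails)
      # strict = TRUE includes the opposite-tail rejection region, i.e. the
      # exact two-sided power rather than the one-sided approximation
      oracle <- power.t.test(n = grid$n[i], delta = grid$d[i], sd = 1,
                             sig.level = 0.05, type = "paired", strict = TRUE,
                             alternative = if (tails == "one") "one.sided"
                                           else "two.sided")$power
      expect_equal(mine, oracle, tolerance = 1e-9)
    }
  }
  # null effect, one tail: power equals alpha
  expect_equal(power_paired_t(0, 20, 0.05, "one"), 0.05, tolerance = 1e-10)
  # strictly increasing in n and d; tends to 1
  p_n <- power_paired_t(0.5, 3:60, 0.05, "two")
  expect_true(all(diff(p_n) > 0))
  d_seq <- seq(0.1, 2, by = 0.1)
  p_d <- vapply(d_seq, power_paired_t, 1, n = 15, alpha = 0.05, tails = "two")
  expect_true(all(diff(p_d) > 0))
  expect_gt(power_paired_t(0.5, 500, 0.05, "two"), 0.99999)
})

test_that("required_n is the minimal n reaching the target power", {
  set.seed(55)
  for (i in 1:12) {
    d <- runif(1, 0.25, 1.8)
    target <- runif(1, 0.5, 0.99)
    tails <- sample(c("one", "two"), 1)
    n <- required_n(d, 0.05, target, tails)
    # brute-force scan oracle
    scan <- 2:max(n + 5, 10)
    ok <- power_paired_t(d, scan, 0.05, tails) >= target
    expect_equal(n, scan[which(ok)[1]])
    expect_gte(power_paired_t(d, n, 0.05, tails), target)
    if (n > 2) expect_lt(power_paired_t(d, n - 1, 0.05, tails), target)
  }
  expect_equal(required_n(50, 0.05, 0.95, "one"), 2L)  # floor of the search
  expect_error(required_n(0, 0.05, 0.95), "positive")
})
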