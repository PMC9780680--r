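# XP-CLR site model, omega estimation, window scan.

test_that("the sweep model nests the neutral model at c = 1", {
  set.seed(2)
  for (i in 1:30) {
    p1 <- runif(1, 0.05, 0.95)
    n <- sample(c(10, 20, 40), 1)
    k <- sample(0:n, 1)
    omega <- runif(1, 0.01, 0.3)
    ll_sweep_c1 <- xpclrSiteLoglik(p1, k, n, omega, c = 1)
    ll_neutral <- xpclrSiteLoglik(p1, k, n, omega, c = 1)
    expect_equal(ll_sweep_c1, ll_neutral, tolerance = 1e-10)
  }
})

test_that("site likelihood is symmetric under allele relabeling", {
  set.seed(4)
  for (i in 1:20) {
    p1 <- runif(1, 0.05, 0.95)
    n <- 20; k <- sample(0:n, 1)
    omega <- runif(1, 0.02, 0.2)
    cc <- runif(1, 0.05, 1)
    expect_equal(xpclrSiteLoglik(p1, k, n, omega, cc),
                 xpclrSiteLoglik(1 - p1, n - k, n, omega, cc),
                 tolerance = 1e-9)
  }
})

test_that("degenerate drift (omega -> 0) approaches Binomial(n, p1)", {
  p1 <- 0.3; n <- 20; k <- 7
  ll <- xpclrSiteLoglik(p1, k, n, omega = 1e-4, c = 1)
  expect_equal(ll, dbinom(k, n, p1, log = TRUE), tolerance = 2e-3)
})

test_that("a strongly differentiated site favours the sweep model", {
  # p1 = 0.5 but object population fixed derived: sweep (c = 0.1) beats
  # neutral
  ll_sweep <- xpclrSiteLoglik(0.5, 20, 20, omega = 0.05, c = 0.1)
  ll_neut <- xpclrSiteLoglik(0.5, 20, 20, omega = 0.05, c = 1)
  expect_gt(ll_sweep, ll_neut)
})

test_that("site likelihood agrees with a dense brute-force quadrature", {
  # independent oracle: Riemann integral on a 20001-point grid written from
  # the model definition
  brute <- function(p1, k, n, omega, cc) {
    x <- seq(1e-6, 1 - 1e-6, length.out = 20001)
    s <- sqrt(omega * p1 * (1 - p1))
    f <- dnorm(x, p1, s)
    g <- x * dbinom(k, n, cc * x + 1 - cc) + (1 - x) * dbinom(k, n, cc * x)
    log(sum(f * g) * (x[2] - x[1]) +
          pnorm(0, p1, s) * (k == 0) + pnorm(1, p1, s, lower.tail = FALSE) * (k == n))
  }
  set.seed(9)
  for (i in 1:10) {
    p1 <- runif(1, 0.1, 0.9); n <- 20; k <- sample(0:n, 1)
    omega <- runif(1, 0.05, 0.3); cc <- runif(1, 0.1, 1)
    expect_equal(xpclrSiteLoglik(p1, k, n, omega, cc),
                 brute(p1, k, n, omega, cc), tolerance = 1e-3)
  }
})

test_that("omega estimation floors at zero divergence and needs 50 sites", {
  set.seed(21)
  freqs <- runif(200, 0.1, 0.9)
  m <- t(replicate(400, rbinom(200, 1, freqs)))
  storage.mode(m) <- "integer"
  p <- makeTestPanel(m, positions = sort(sample.int(1e6, 200)),
                     pops = rep(c("A", "B"), each = 100))
  pa <- popPanel(p, "A"); pb <- popPanel(p, "B")
  # same underlying frequencies, large n -> omega near the floor
  expect_lt(estimateOmega(pa, pb), 0.01)
  small <- makeTestPanel(m[1:40, 1:30], positions = sort(sample.int(1e6, 30)),
                         pops = rep(c("A", "B"), each = 10))
  expect_error(estimateOmega(popPanel(small, "A"),
                             popPanel(small, "B")),
               "at least 50")
})

test_that("identical panels give window scores near zero", {
  set.seed(31)
  freqs <- runif(400, 0.1, 0.9)
  m <- t(replicate(40, rbinom(400, 1, freqs)))
  storage.mode(m) <- "integer"
  pos <- sort(sample.int(2e5, 400))
  p <- makeTestPanel(m, positions = pos, pops = rep(c("A", "B"), each = 10))
  pa <- popPanel(p, "A")
  xp <- xpclrScan(pa, pa, windows = makeWindows(2e5), omega = 0.05)
  expect_true(all(xp$score[!is.na(xp$score)] <= 0.5))
  expect_true(all(xp$score[!is.na(xp$score)] >= 0))
})

test_that("window score rises with differentiation at the centre SNP", {
  # differentiated background, centre SNP swept progressively further;
  # at the window centre the escape probability is ~0, so the sweep model
  # is rewarded as the centre count approaches fixation
  mk <- function(kv, pos) {
    m <- sapply(kv, function(ki) sample(c(rep(1L, ki), rep(0L, 20 - ki))))
    storage.mode(m) <- "integer"
    makeTestPanel(m, positions = pos, pops = rep("A", 10))
  }
  set.seed(41)
  n_bg <- 30
  pos <- sort(c(sample(setdiff(1:99000, 50000), n_bg), 50000L))
  ctr <- which(pos == 50000L)
  k_bg <- rbinom(n_bg, 20, 0.75)
  scores <- sapply(c(8, 12, 16, 20), function(k_center) {
    k <- numeric(n_bg + 1); k[-ctr] <- k_bg; k[ctr] <- k_center
    xpclrScan(mk(rep(10, n_bg + 1), pos), mk(k, pos),
              windows = makeWindows(1e5), omega = 0.01,
              ldTrim = FALSE)$score[1]
  })
  expect_true(all(diff(scores) > -1e-6))
  expect_gt(scores[4], scores[1])
})

test_that("omega estimation recovers the drift scale of a split pair", {
  omegas <- vapply(1:20, function(s) {
    cfg <- simConfig(region_length = 1e4, N_anc = 500, N_hi = 500,
                     N_lo = 500, t_out_split = NULL, t_hilo_split = 50,
                     mu = 1e-5, rho = 1e-5, sweep = NULL, n_sample = 10,
                     seed = 4000 + s)
    res <- simulateSweep(cfg)
    both <- res$panel
    estimateOmega(popPanel(both, "lo"),
                  popPanel(both, "hi"))
  }, numeric(1))
  # both branches drift t = 50 generations at N = 500
  expected <- 2 * (1 - exp(-50 / 500))
  expect_lt(abs(mean(omegas) - expected) / expected, 0.3)
})
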