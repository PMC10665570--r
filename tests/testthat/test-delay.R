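test_that("zero delays are the identity and single spikes shift by their delay", {
  r <- spike_raster(matrix(0, 20, 2))
  r[6, 1] <- 1  # spike at step index 5 (0-based), unit 0
  d0 <- delay_vector(2, theta_d = 10)
  expect_equal(rv(apply_delay(r, d0)), rv(r))

  d <- delay_vector(2, theta_d = 10, shadow = c(3, 0))
  out <- apply_delay(r, d)
  expect_equal(sum(out), 1)
  expect_equal(which(unclass(out)[, 1] > 0), 9L)  # 0-based step 5 + 3
})

test_that("spikes shifted past the horizon are dropped, never created", {
  r <- spike_raster(matrix(0, 20, 1))
  r[20, 1] <- 1  # 0-based step 19
  d <- delay_vector(1, theta_d = 10, shadow = 2)
  out <- apply_delay(r, d)
  expect_equal(sum(out), 0)
})

test_that("spike count is conserved in-horizon and non-increasing otherwise", {
  set.seed(3)
  for (trial in 1:10) {
    r <- random_raster(30, 6, p = 0.2)
    d <- delay_vector(6, theta_d = 40,
                      shadow = sample(0:12, 6, replace = TRUE))
    out <- apply_delay(r, d)
    expect_lte(sum(out), sum(r))
    # conservation when every shifted time stays in range
    last_spike <- apply(unclass(r), 2, function(col)
      if (any(col > 0)) max(which(col > 0)) else 0L)
    if (all(last_spike + d$effective <= 30)) expect_equal(sum(out), sum(r))
  }
})

test_that("delay composition equals the summed delay when nothing truncates", {
  set.seed(9)
  r <- random_raster(40, 4, p = 0.1)
  r[30:40, ] <- 0  # head-room so no truncation occurs
  d1 <- delay_vector(4, theta_d = 20, shadow = c(1, 2, 0, 3))
  d2 <- delay_vector(4, theta_d = 20, shadow = c(2, 1, 4, 0))
  d12 <- delay_vector(4, theta_d = 20, shadow = d1$shadow + d2$shadow)
  expect_equal(rv(apply_delay(apply_delay(r, d1), d2)),
               rv(apply_delay(r, d12)))
})

test_that("projection clips to [0, theta_d] and rounds down by default", {
  d <- delay_vector(4, theta_d = 128, shadow = c(135.7, -0.3, 3.8, 128.0))
  expect_identical(d$effective, c(128L, 0L, 3L, 128L))
  dn <- delay_vector(2, theta_d = 10, shadow = c(3.8, 3.2),
                     rounding = "nearest")
  expect_identical(dn$effective, c(4L, 3L))
  # shadow is untouched by projection
  expect_equal(d$shadow, c(135.7, -0.3, 3.8, 128.0))
})

test_that("projection after optimizer-style perturbations always yields integers in range", {
  set.seed(21)
  d <- delay_vector(8, theta_d = 16)
  for (step in 1:50) {
    d$shadow <- d$shadow + rnorm(8, sd = 3)
    d <- project_delays(d)
    expect_true(all(d$effective == floor(d$effective)))
    expect_true(all(d$effective >= 0L & d$effective <= 16L))
  }
})

test_that("delay gradient follows the backward finite difference of the train", {
  # single spike at step m, upstream +1 at that step only: the estimator
  # reads -(s_d[m] - s_d[m-1]) * upstream[m] = -1 for that unit
  s <- matrix(0, 10, 1); s[4, 1] <- 1
  up <- matrix(0, 10, 1); up[4, 1] <- 1
  expect_equal(delay_gradient(up, s), -1)
  # upstream on the following step pulls the other way
  up2 <- matrix(0, 10, 1); up2[5, 1] <- 1
  expect_equal(delay_gradient(up2, s), 1)
  # zero upstream, zero gradient
  expect_equal(delay_gradient(matrix(0, 10, 1), s), 0)
})

test_that("constant upstream telescopes to the boundary term", {
  set.seed(7)
  for (trial in 1:10) {
    s <- unclass(random_raster(25, 3, p = 0.2))
    up <- matrix(2.5, 25, 3)
    g <- delay_gradient(up, s)
    # sum of backward differences telescopes to s[last]; gradient is its
    # negative times the constant
    expect_equal(g, -2.5 * s[25, ], tolerance = 1e-12)
  }
})

test_that("delay gradient sign matches numerical shifts of a smoothed alignment loss", {
  # independent oracle: central difference of a quadratic loss on the
  # epsilon-smoothed train w.r.t. a +/-1-step shift of each unit's delay
  cfg <- default_cfg(tau_s = 4, tau_r = 4, alpha_r = 0)
  eps_k <- response_kernel(cfg)
  smooth <- function(s) {
    Tn <- nrow(s); y <- matrix(0, Tn, ncol(s))
    for (k in seq_along(eps_k)) {
      if (k > Tn) break
      y[k:Tn, ] <- y[k:Tn, ] + eps_k[k] * s[seq_len(Tn - k + 1), , drop = FALSE]
    }
    y
  }
  shift1 <- function(s, d) {
    Tn <- nrow(s); out <- matrix(0, Tn, ncol(s))
    for (i in seq_len(ncol(s))) {
      di <- d[i]
      if (di == 0) out[, i] <- s[, i]
      else if (di < Tn) out[(di + 1):Tn, i] <- s[seq_len(Tn - di), i]
    }
    out
  }
  set.seed(1)
  agree <- 0L; total <- 0L
  for (trial in 1:20) {
    s <- unclass(random_raster(60, 6, p = 0.08))
    d_true <- sample(1:8, 6, replace = TRUE)
    target <- smooth(shift1(s, d_true))
    d0 <- pmax(0L, d_true + sample(c(-3L, -2L, 2L, 3L), 6, replace = TRUE))
    loss_at <- function(d) sum(0.5 * (smooth(shift1(s, d)) - target)^2)
    sd0 <- shift1(s, d0)
    resid <- smooth(sd0) - target
    # dL/ds_d by the adjoint of the smoothing
    up <- matrix(0, 60, 6)
    for (k in seq_along(eps_k)) {
      if (k > 60) break
      up[seq_len(60 - k + 1), ] <- up[seq_len(60 - k + 1), ] +
        eps_k[k] * resid[k:60, , drop = FALSE]
    }
    g <- delay_gradient(up, sd0)
    for (i in 1:6) {
      dp <- d0; dp[i] <- dp[i] + 1L
      dm <- d0; dm[i] <- max(0L, dm[i] - 1L)
      numg <- (loss_at(dp) - loss_at(dm)) / 2
      if (abs(numg) > 1e-12) {
        total <- total + 1L
        if (sign(numg) == sign(g[i])) agree <- agree + 1L
      }
    }
  }
  expect_gte(agree / total, 0.9)
})
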