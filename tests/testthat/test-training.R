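# miniature rate-coded task: class c = elevated rate on channel c
channel_task <- function(n, n_channels = 3, n_steps = 60, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lab <- (i - 1L) %% n_channels
    x <- matrix(as.numeric(runif(n_steps * n_channels) < 0.01),
                n_steps, n_channels)
    x[runif(n_steps) < 0.3, lab + 1L] <- 1
    list(raster = spike_raster(x), label = lab)
  })
}

test_that("surrogate derivative matches its closed form around the threshold", {
  cfg <- surrogate_config(tau_scale = 1, tau_theta = 1)
  expect_equal(surrogate_grad(10, cfg, 10), 1)          # peak at threshold
  expect_equal(surrogate_grad(11, cfg, 10), exp(-1))    # one width off
  expect_equal(surrogate_grad(9, cfg, 10), surrogate_grad(11, cfg, 10))
  u <- seq(0, 20, by = 0.5)
  expect_equal(surrogate_grad(10 + u, cfg, 10), surrogate_grad(10 - u, cfg, 10))
  cfg2 <- surrogate_config(tau_scale = 0.6, tau_theta = 3)
  expect_equal(surrogate_grad(13, cfg2, 10), 0.6 * exp(-1))
  expect_error(surrogate_config(tau_scale = 0), "positive")
})

test_that("analytic gradients match numerical differences in the smooth regime", {
  # soft threshold + full refractory backward: the surrogate is the exact
  # derivative, so BPTT must reproduce central differences everywhere
  set.seed(42)
  cfg <- srm_config(tau_s = 3, tau_r = 3, alpha_r = 2, theta_u = 10)
  spec <- network_spec(list(layer_spec(3, 4), layer_spec(4, 3)), 3, cfg)
  model <- build_network(spec, seed = 7)
  sg <- surrogate_config(tau_theta = 2)
  x <- matrix(as.numeric(runif(40 * 3) < 0.15), 40, 3)
  lc <- loss_config(target_true = 10, target_false = 2)
  soft_loss <- function(m) {
    fwd <- network_forward(m, x, soft = TRUE, surrogate = sg)
    counts <- colSums(fwd$spikes)
    sum(0.5 * (c(10, 2, 2) - counts)^2)
  }
  loss0 <- soft_loss(model)
  gr <- axodelay:::sample_grads(model, x, 0L, lc, sg, soft = TRUE,
                                refr_grad = "full")
  n_ok <- 0L; n_tot <- 0L
  for (li in 1:2) for (nm in c("W", "b")) {
    g <- if (nm == "W") gr$grads[[li]]$dW else gr$grads[[li]]$db
    for (i in seq_along(model$layers[[li]][[nm]])) {
      h <- 1e-5
      m1 <- model; m1$layers[[li]][[nm]][i] <- m1$layers[[li]][[nm]][i] + h
      m2 <- model; m2$layers[[li]][[nm]][i] <- m2$layers[[li]][[nm]][i] - h
      num <- (soft_loss(m1) - soft_loss(m2)) / (2 * h)
      rel <- abs(g[i] - num) / max(1e-6, abs(g[i]) + abs(num))
      n_tot <- n_tot + 1L
      # absolute floor: the central difference carries cancellation noise of
      # order eps_machine * loss / h, which dominates near-zero gradients
      if (rel <= 1e-4 || abs(g[i] - num) <= 1e-8 * abs(loss0)) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("a zero learning rate leaves every parameter untouched", {
  data <- channel_task(12)
  cfg <- srm_config(tau_s = 3, tau_r = 3)
  spec <- network_spec(
    list(layer_spec(3, 4, vad = TRUE, theta_d = 8), layer_spec(4, 3)), 3, cfg)
  model <- build_network(spec, seed = 5)
  fit <- train_network(model, data,
                       train_config(lr = 0, batch_size = 4, epochs = 2,
                                    pretrain_epochs = 0, seed = 5),
                       loss_config(target_true = 8, target_false = 1))
  expect_identical(fit$model$layers, model$layers)
})

test_that("training is reproducible: same seed, same history and parameters", {
  data <- channel_task(12)
  cfg <- srm_config(tau_s = 3, tau_r = 3)
  spec <- network_spec(list(layer_spec(3, 5), layer_spec(5, 3)), 3, cfg)
  fits <- lapply(1:2, function(rep) {
    train_network(build_network(spec, seed = 3), data,
                  train_config(lr = 0.1, batch_size = 4, epochs = 3,
                               pretrain_epochs = 0, seed = 11),
                  loss_config(target_true = 8, target_false = 1),
                  surrogate_config(tau_theta = 2))
  })
  expect_identical(fits[[1]]$history, fits[[2]]$history)
  expect_identical(fits[[1]]$model$layers, fits[[2]]$model$layers)
})

test_that("the rate loss is driven down on a separable miniature task", {
  data <- channel_task(30)
  cfg <- srm_config(tau_s = 3, tau_r = 3, alpha_r = 2)
  spec <- network_spec(list(layer_spec(3, 6), layer_spec(6, 3)), 3, cfg)
  fit <- train_network(build_network(spec, seed = 2), data,
                       train_config(lr = 0.1, batch_size = 6, epochs = 40,
                                    pretrain_epochs = 40, seed = 2),
                       loss_config(target_true = 8, target_false = 1),
                       surrogate_config(tau_theta = 2))
  expect_lt(tail(fit$history$rate_loss, 1), fit$history$rate_loss[1] / 2)
  expect_gte(tail(fit$history$train_acc, 1), 0.9)
})

test_that("evaluation returns the fraction of argmax-correct samples", {
  # a hand-built model whose readout mirrors the active channel: weights
  # strong on the diagonal make the true neuron's line fire most
  cfg <- srm_config(tau_s = 3, tau_r = 3)
  spec <- network_spec(list(layer_spec(3, 3)), 3, cfg)
  model <- build_network(spec, seed = 1)
  model$layers[[1]]$W <- diag(3) * 14
  model$layers[[1]]$b <- rep(0, 3)
  data <- channel_task(15)
  expect_equal(evaluate_network(model, data), 1.0)
  # inverted labels: everything wrong
  flipped <- lapply(data, function(s) {
    s$label <- (s$label + 1L) %% 3L
    s
  })
  expect_equal(evaluate_network(model, flipped), 0)
  expect_error(evaluate_network(model, list()), "empty")
})

test_that("a fixed predictor against permuted labels scores at chance", {
  cfg <- srm_config(tau_s = 2, tau_r = 2)
  spec <- network_spec(list(layer_spec(4, 4)), 4, cfg)
  model <- build_network(spec, seed = 8)
  set.seed(31)
  n <- 1000L
  data <- lapply(seq_len(n), function(i) {
    list(raster = random_raster(10, 4, p = 0.3),
         label = sample.int(4L, 1L) - 1L)
  })
  acc <- evaluate_network(model, data)
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(acc - 0.25), 3 * sigma)
})

test_that("divergent training aborts with a diagnostic", {
  data <- channel_task(6)
  cfg <- srm_config(tau_s = 3, tau_r = 3)
  spec <- network_spec(list(layer_spec(3, 3)), 3, cfg)
  model <- build_network(spec, seed = 1)
  model$layers[[1]]$W[1, 1] <- Inf
  expect_error(
    train_network(model, data,
                  train_config(lr = 0.1, batch_size = 3, epochs = 1,
                               pretrain_epochs = 0)),
    "NaN|Inf|diverged|finite")
})

test_that("enabling the suppressed loss reduces false-class firing after pretraining", {
  data <- channel_task(30)
  cfg <- srm_config(tau_s = 3, tau_r = 3)
  spec <- network_spec(list(layer_spec(3, 6), layer_spec(6, 3)), 3, cfg)
  lc <- loss_config(target_true = 8, target_false = 0, use_dloss = TRUE)
  sgc <- surrogate_config(tau_theta = 2)
  false_spikes <- function(model) sum(vapply(data, function(s) {
    cnt <- colSums(network_forward(model, s$raster)$spikes)
    sum(cnt[-(s$label + 1L)])
  }, numeric(1)))
  # phase 1: rate loss only (pretrain_epochs = epochs keeps L_Mem off)
  f1 <- train_network(build_network(spec, seed = 2), data,
                      train_config(lr = 0.1, batch_size = 6, epochs = 25,
                                   pretrain_epochs = 25, seed = 3), lc, sgc)
  expect_true(all(f1$history$dloss == 0))
  # phase 2: the membrane penalty switches on
  f2 <- train_network(f1$model, data,
                      train_config(lr = 0.1, batch_size = 6, epochs = 15,
                                   pretrain_epochs = 0, seed = 4), lc, sgc)
  expect_gt(f2$history$dloss[1], 0)
  expect_lt(false_spikes(f2$model), false_spikes(f1$model))
  # the winner-takes-all pressure does not destroy the classification
  expect_gte(tail(f2$history$train_acc, 1), 0.9)
})
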