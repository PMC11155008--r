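# independent elementwise weighted-mean oracle, deliberately loop-based
fedavg_oracle <- function(updates) {
  total <- sum(vapply(updates, function(u) u$n_samples, 1))
  out <- lapply(updates[[1]]$parameters, function(a) a * 0)
  for (u in updates) {
    for (nm in names(out)) {
      a <- out[[nm]]
      for (i in seq_along(a)) {
        a[i] <- a[i] + (u$n_samples / total) * u$parameters[[nm]][i]
      }
      out[[nm]] <- a
    }
  }
  out
}

make_updates <- function(cfg, ns, seed0 = 100) {
  lapply(seq_along(ns), function(k) {
    list(client_id = paste0("c", k),
         parameters = random_params_like(cfg, seed0 + k),
         n_samples = ns[k])
  })
}

test_that("weighted averaging matches the brute-force oracle", {
  cfg <- micro_cfg()
  ups <- make_updates(cfg, c(3, 7, 5))
  got <- aggregate_fedavg(ups)
  want <- fedavg_oracle(ups)
  for (nm in names(got)) {
    expect_lt(max(abs(got[[nm]] - want[[nm]])), 1e-12)
  }
})

test_that("scalar weighted mean and shared-parameter fixed point", {
  u <- list(list(parameters = list(w = 0), n_samples = 1),
            list(parameters = list(w = 1), n_samples = 3))
  expect_equal(aggregate_fedavg(u)$w, 0.75)

  cfg <- micro_cfg()
  theta <- random_params_like(cfg, 1)
  same <- lapply(c(2, 9, 4), function(n) {
    list(parameters = theta, n_samples = n)
  })
  agg <- aggregate_fedavg(same)
  for (nm in names(theta)) {
    expect_equal(agg[[nm]], theta[[nm]], tolerance = 1e-14)
  }
})

test_that("aggregation is permutation-invariant and convex-bounded", {
  cfg <- micro_cfg()
  ups <- make_updates(cfg, c(4, 1, 9), seed0 = 300)
  a1 <- aggregate_fedavg(ups)
  a2 <- aggregate_fedavg(rev(ups))
  for (nm in names(a1)) {
    expect_lt(max(abs(a1[[nm]] - a2[[nm]])), 1e-12)
    lo <- pmin(ups[[1]]$parameters[[nm]],
               pmin(ups[[2]]$parameters[[nm]], ups[[3]]$parameters[[nm]]))
    hi <- pmax(ups[[1]]$parameters[[nm]],
               pmax(ups[[2]]$parameters[[nm]], ups[[3]]$parameters[[nm]]))
    expect_true(all(a1[[nm]] >= lo - 1e-12 & a1[[nm]] <= hi + 1e-12))
  }
  # equal sizes reduce to the unweighted mean
  eq <- make_updates(cfg, c(5, 5), seed0 = 400)
  am <- aggregate_fedavg(eq)
  for (nm in names(am)) {
    expect_equal(am[[nm]],
                 (eq[[1]]$parameters[[nm]] + eq[[2]]$parameters[[nm]]) / 2,
                 tolerance = 1e-14)
  }
  expect_error(aggregate_fedavg(list()), "no client")
  bad <- make_updates(cfg, c(2, 2))
  bad[[2]]$parameters$fc2_b <- 1
  expect_error(aggregate_fedavg(bad), "fc2_b")
})

test_that("a single-client federation reproduces centralized training", {
  d <- micro_data(12, seed = 21, separable = TRUE)
  mcfg <- micro_cfg(init_seed = 8)
  fed_cfg <- federated_config(
    n_rounds = 2, local_epochs = 2,
    client_train_cfg = train_config(batch_size = 4, optimizer = "sgd",
                                    learning_rate = 0.05),
    seed = 77
  )
  fed <- run_federated(list(list(client_id = "only", train_data = d)),
                       mcfg, fed_cfg)
  central <- build_model(mcfg)
  cfg_c <- train_config(batch_size = 4, optimizer = "sgd",
                        learning_rate = 0.05, epochs = 4,
                        seed = fedcrt:::derive_seed(77, 1L))
  fit <- train_local(central, d, NULL, cfg_c)
  expect_identical(fed$params, fit$params)
})

test_that("identical clients stay identical and zero local epochs is a no-op", {
  d <- micro_data(8, seed = 31, separable = TRUE)
  mcfg <- micro_cfg(init_seed = 12)
  ccfg <- train_config(batch_size = 4, optimizer = "sgd",
                       learning_rate = 0.05)
  # identical data, identical seeds => identical updates every round,
  # so the global model equals either client, i.e. a one-client run
  two <- run_federated(
    list(list(client_id = "a", train_data = d, seed = 99L),
         list(client_id = "b", train_data = d, seed = 99L)),
    mcfg,
    federated_config(n_rounds = 2, local_epochs = 1,
                     client_train_cfg = ccfg, seed = 5)
  )
  one <- run_federated(
    list(list(client_id = "a", train_data = d, seed = 99L)),
    mcfg,
    federated_config(n_rounds = 2, local_epochs = 1,
                     client_train_cfg = ccfg, seed = 5)
  )
  expect_equal(two$params, one$params, tolerance = 1e-14)

  frozen <- federated_config(n_rounds = 3, local_epochs = 0,
                             client_train_cfg = ccfg, seed = 5)
  fed0 <- run_federated(list(list(client_id = "a", train_data = d)),
                        mcfg, frozen)
  expect_identical(fed0$params, get_parameters(build_model(mcfg)))
})

test_that("the round log records every client every round", {
  d1 <- micro_data(8, seed = 51, separable = TRUE)
  d2 <- micro_data(6, seed = 52, separable = TRUE)
  v <- micro_data(4, seed = 53)
  fed <- run_federated(
    list(list(client_id = "a", train_data = d1, val_data = v),
         list(client_id = "b", train_data = d2)),
    micro_cfg(init_seed = 3),
    federated_config(n_rounds = 3, local_epochs = 1,
                     client_train_cfg = train_config(batch_size = 4,
                                                     optimizer = "sgd",
                                                     learning_rate = 0.05),
                     seed = 2)
  )
  expect_equal(nrow(fed$round_log), 6L)
  expect_setequal(unique(fed$round_log$client_id), c("a", "b"))
  expect_equal(fed$round_log$n_samples[fed$round_log$client_id == "a"],
               rep(8, 3))
  expect_equal(nrow(fed$global_log), 3L)
})
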