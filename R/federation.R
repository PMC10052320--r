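# Client/server federated-learning simulation: FedAvg aggregation, client
# sampling, and the two-stage orchestration (federated VAE + distribution
# sharing, then federated training of the task model on augmented shards).
# The simulation is single-process with in-memory message passing.

#' Configuration of a federated simulation
#'
#' @param m number of clients (>= 1; >= 2 for a real federation).
#' @param rounds number of communication rounds. One round is one
#'   aggregation after `local_epochs` epochs of local training on each
#'   participating client.
#' @param r active-user ratio in (0, 1]; `ceiling(r * m)` clients are drawn
#'   uniformly without replacement each round.
#' @param local_epochs local epochs per round (default 2 — parameters are
#'   uploaded once every two epochs).
#' @param weight_source `"augmented_counts"` weights the aggregation by the
#'   clients' current (post-augmentation) shard sizes; `"original_counts"`
#'   restores weighting by the original shard sizes.
#' @param seed base seed; per-round participation and per-client training
#'   seeds are derived from it deterministically.
#' @export
federation_config <- function(m, rounds, r = 1, local_epochs = 2L,
                              weight_source = c("augmented_counts",
                                                "original_counts"),
                              seed = NULL) {
  m <- assert_positive_int(m, "m")
  if (rounds < 0) stopf("rounds must be non-negative")
  if (r <= 0 || r > 1) stopf("active-user ratio r must be in (0, 1]")
  weight_source <- match.arg(weight_source)
  structure(list(m = m, rounds = as.integer(rounds), r = r,
                 local_epochs = as.integer(local_epochs),
                 weight_source = weight_source, seed = seed),
            class = "federation_config")
}

#' Federated averaging of model parameters
#'
#' Every tensor of the result is the weight-normalized average
#' `sum(n_i * w_i) / sum(n_i)` of the clients' tensors. Parameter lists are
#' combinable only if their names and shapes match. Weights are normalized
#' before use, so a single update is returned bit-identically.
#'
#' @param updates list of named parameter lists (all with identical names
#'   and shapes).
#' @param weights positive per-update weights, typically local sample counts.
#' @return aggregated parameter list.
#' @export
fedavg_aggregate <- function(updates, weights) {
  if (length(updates) == 0) stopf("no updates to aggregate")
  if (length(weights) != length(updates)) {
    stopf("need one weight per update")
  }
  if (any(weights <= 0) || !all(is.finite(weights))) {
    stopf("aggregation weights must be positive and finite")
  }
  ref <- updates[[1]]
  for (u in updates[-1]) {
    if (!identical(names(u), names(ref))) {
      stopf("parameter names differ between updates")
    }
    for (nm in names(ref)) {
      if (!identical(dim(u[[nm]]) %||% length(u[[nm]]),
                     dim(ref[[nm]]) %||% length(ref[[nm]]))) {
        stopf("shape mismatch in parameter '%s'", nm)
      }
    }
  }
  ws <- weights / sum(weights)
  out <- lapply(ref, function(p) p * ws[1])
  if (length(updates) > 1) {
    for (i in 2:length(updates)) {
      for (nm in names(ref)) {
        out[[nm]] <- out[[nm]] + updates[[i]][[nm]] * ws[i]
      }
    }
  }
  out
}

sample_participants <- function(m, r, seed) {
  k <- as.integer(ceiling(r * m))
  with_seed(seed, sort(sample.int(m, k)))
}

# Shared FedAvg loop. `evaluate` is NULL or function(params) -> scalar.
fedavg_rounds <- function(model, clients, config, train_cfg, params,
                          weights, evaluate = NULL, seed_salt = 0L,
                          checkpoint_rounds = integer(0)) {
  records <- vector("list", config$rounds)
  checkpoints <- list()
  for (round in seq_len(config$rounds)) {
    part <- sample_participants(
      config$m, config$r,
      if (is.null(config$seed)) NULL
      else derive_seed(config$seed, seed_salt, round, 0L))
    updates <- vector("list", length(part))
    losses <- numeric(length(part))
    for (j in seq_along(part)) {
      k <- part[j]
      fit <- train_local(
        model, clients[[k]], train_cfg, epochs = config$local_epochs,
        seed = if (is.null(config$seed)) NULL
        else derive_seed(config$seed, seed_salt, round, k),
        params = params)
      updates[[j]] <- fit$params
      losses[j] <- mean(fit$loss_trace)
    }
    params <- fedavg_aggregate(updates, weights[part])
    records[[round]] <- list(
      round = round, participants = part,
      mean_local_loss = mean(losses),
      accuracy = if (is.null(evaluate)) NA_real_ else evaluate(params))
    if (round %in% checkpoint_rounds) {
      checkpoints[[as.character(round)]] <- params
    }
  }
  list(params = params, records = records, checkpoints = checkpoints)
}

round_records_df <- function(records) {
  data.frame(
    round = vapply(records, `[[`, integer(1), "round"),
    n_participants = vapply(records, function(r) length(r$participants),
                            integer(1)),
    mean_local_loss = vapply(records, `[[`, numeric(1), "mean_local_loss"),
    accuracy = vapply(records, `[[`, numeric(1), "accuracy"))
}

#' Stage one: federated VAE training and distribution sharing
#'
#' Trains the VAE by FedAvg for `config$rounds` communication rounds
#' (aggregation weighted by shard size), then has every client encode its
#' shard with the *global* encoder, expand the encodings into sigma points,
#' estimate per-class latent parameters, and emit its distribution
#' information; the server broadcast is simulated by returning all payloads.
#'
#' @param clients list of non-empty [client_dataset()] shards.
#' @param vae_template a `vae_model` providing architecture and initial
#'   parameters.
#' @param config a [federation_config()].
#' @param train_cfg a [training_config()].
#' @param family latent distribution family to share.
#' @param alpha sigma-point placement constant.
#' @param probe optional image batch on which the global reconstruction
#'   error is recorded each round.
#' @param checkpoint_rounds rounds whose global VAE parameters should be
#'   kept (returned as `checkpoints`), e.g. for tracking how the
#'   generated-vs-original loss gap evolves over training.
#' @return list with the trained global `vae` (model with final params),
#'   `dis` (list of [distribution_info()], one per client), `records`, and
#'   `recon_trace` (per-round probe reconstruction error, if `probe` given).
#' @export
run_stage1 <- function(clients, vae_template, config,
                       train_cfg = training_config(),
                       family = "uniform", alpha = 2, probe = NULL,
                       checkpoint_rounds = integer(0)) {
  if (any(vapply(clients, dataset_size, integer(1)) == 0)) {
    stopf("stage 1 requires non-empty client shards")
  }
  if (length(clients) != config$m) {
    stopf("config$m = %d but %d clients supplied", config$m, length(clients))
  }
  sizes <- vapply(clients, dataset_size, integer(1))
  evaluate <- if (is.null(probe)) NULL else {
    function(params) reconstruction_error(vae_template, probe, params)
  }
  fit <- fedavg_rounds(vae_template, clients, config, train_cfg,
                       vae_template$params, sizes, evaluate, seed_salt = 1L,
                       checkpoint_rounds = checkpoint_rounds)
  global_vae <- vae_template
  global_vae$params <- fit$params
  dis <- lapply(clients, estimate_client_di, model = global_vae,
                family = family, alpha = alpha)
  list(vae = global_vae, dis = dis, records = fit$records,
       checkpoints = fit$checkpoints,
       recon_trace = vapply(fit$records, `[[`, numeric(1), "accuracy"))
}

#' Stage two: federated training of the task model
#'
#' Plain FedAvg on the (typically augmented) client shards: each round,
#' `ceiling(r * m)` clients are sampled uniformly without replacement, train
#' locally for `local_epochs` epochs, and the server aggregates weighted by
#' `config$weight_source`. With `rounds = 0` the factory's initial
#' parameters are returned unchanged.
#'
#' @param clients list of [client_dataset()] (augmented or not).
#' @param model_factory function(seed) returning an initialized task model
#'   (e.g. wrapping [build_cnn_classifier()]).
#' @param config a [federation_config()].
#' @param train_cfg a [training_config()].
#' @param test_set optional [image_dataset()]; when given, global test
#'   accuracy is recorded every round.
#' @param original_sizes original (pre-augmentation) shard sizes, used when
#'   `config$weight_source = "original_counts"`.
#' @return list with final `model`, `params`, and `records` (a data frame of
#'   per-round participation, mean local loss and test accuracy).
#' @export
run_stage2 <- function(clients, model_factory, config,
                       train_cfg = training_config(), test_set = NULL,
                       original_sizes = NULL) {
  if (length(clients) != config$m) {
    stopf("config$m = %d but %d clients supplied", config$m, length(clients))
  }
  model <- model_factory(if (is.null(config$seed)) NULL
                         else derive_seed(config$seed, 2L, 0L))
  weights <- switch(config$weight_source,
    augmented_counts = vapply(clients, dataset_size, integer(1)),
    original_counts = original_sizes %||%
      vapply(clients, function(cl) sum(!cl$synthetic), integer(1)))
  evaluate <- if (is.null(test_set)) NULL else {
    function(params) evaluate_accuracy(model, test_set, params)
  }
  fit <- fedavg_rounds(model, clients, config, train_cfg, model$params,
                       weights, evaluate, seed_salt = 2L)
  model$params <- fit$params
  list(model = model, params = fit$params,
       records = round_records_df(fit$records))
}

#' Run the full two-stage pipeline (FedDIS)
#'
#' Stage one trains the VAE federally and exchanges per-class latent
#' distribution information; every client then augments its shard from the
#' others' payloads; stage two trains the task model by FedAvg on the
#' augmented shards.
#'
#' @inheritParams run_stage1
#' @inheritParams run_stage2
#' @param vae_config,task_config [federation_config()] for the two stages.
#' @param vae_train_cfg optional separate [training_config()] for the VAE
#'   stage (small fixtures typically want a larger learning rate and smaller
#'   batches than the task model); defaults to `train_cfg`.
#' @param seed experiment seed; overrides the seeds inside the two configs
#'   so a single integer reproduces the whole run.
#' @return list with `stage1` (see [run_stage1()]), `clients_augmented`,
#'   `stage2` (see [run_stage2()]), and `emd_before`/`emd_after` pairwise
#'   heterogeneity matrices.
#' @export
run_feddis <- function(clients, vae_template, model_factory,
                       vae_config, task_config,
                       train_cfg = training_config(),
                       vae_train_cfg = train_cfg,
                       family = "uniform", alpha = 2,
                       test_set = NULL, seed = NULL) {
  if (!is.null(seed)) {
    vae_config$seed <- derive_seed(seed, 101L)
    task_config$seed <- derive_seed(seed, 102L)
  }
  s1 <- run_stage1(clients, vae_template, vae_config, vae_train_cfg,
                   family = family, alpha = alpha)
  aug <- augment_clients(clients, s1$dis, s1$vae,
                         seed = if (is.null(seed)) NULL
                         else derive_seed(seed, 103L))
  s2 <- run_stage2(aug, model_factory, task_config, train_cfg, test_set,
                   original_sizes = vapply(clients, dataset_size,
                                           integer(1)))
  list(stage1 = s1, clients_augmented = aug, stage2 = s2,
       emd_before = pairwise_emd(clients), emd_after = pairwise_emd(aug))
}

#' Run the FedAvg baseline on the raw shards
#'
#' The comparison arm: stage-two federated training only, on the original
#' (non-augmented) shards.
#' @inheritParams run_feddis
#' @export
run_fedavg_baseline <- function(clients, model_factory, task_config,
                                train_cfg = training_config(),
                                test_set = NULL, seed = NULL) {
  if (!is.null(seed)) task_config$seed <- derive_seed(seed, 102L)
  run_stage2(clients, model_factory, task_config, train_cfg, test_set)
}
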