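#' Training configuration
#'
#' Defaults are the deployed training recipe: mini-batch 4, learning rate
#' 2e-4, Adam with betas (0.9, 0.99), 125000 iterations, 3 x 128 x 128
#' inputs (three adjacent slices) and a two-step schedule (`T = 2`). The
#' norm of the three loss terms is mean-squared error by default (`"L1"`
#' selectable).
#'
#' @param batch_size Mini-batch size.
#' @param lr Learning rate.
#' @param adam_betas Length-2 vector `(b1, b2)`.
#' @param iterations Total optimizer steps.
#' @param input_size Side of the square training crop, pixels.
#' @param T Diffusion steps.
#' @param seed RNG seed for sampling and shuffling.
#' @param loss_norm `"L2"` (mean-squared) or `"L1"` (mean-absolute).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 4, lr = 2e-4, adam_betas = c(0.9, 0.99),
                         iterations = 125000, input_size = 128, T = 2,
                         seed = 1, loss_norm = c("L2", "L1")) {
  loss_norm <- match.arg(loss_norm)
  assert_that(batch_size >= 1 && iterations >= 1, "sizes must be positive")
  assert_that(T >= 2, "T must be >= 2")
  assert_that(length(adam_betas) == 2, "adam_betas must have length 2")
  structure(as.list(environment()), class = "train_config")
}

loss_norm_fn <- function(kind) {
  if (kind == "L2") {
    list(value = function(d) mean(d^2), grad = function(d) 2 * d / length(d))
  } else {
    list(value = function(d) mean(abs(d)), grad = function(d) sign(d) / length(d))
  }
}

#' Two-stage diffusion losses
#'
#' Computes the full objective for one slice pair at step `t`:
#' stage I restores the clean slice from the degraded intermediate
#' (`F_stage_I = ||x0_hat - x0||`), the estimate is re-degraded to step
#' `t - 1` and compared against the true intermediate
#' (`F_error = ||x_hat_{t-1} - x_{t-1}||`), and stage II restores again from
#' the re-degraded estimate under the error-modulated time embedding
#' (`F_stage_II = ||x0_hat_hat - x0||`). The final loss is the sum of the
#' three. `t` must be at least 2 so that stage II sees a valid step.
#'
#' The re-degraded slice entering stage II is treated as a constant with
#' respect to stage-I weights (detached); the error term still propagates
#' through the degradation operator into stage I.
#'
#' @param x0 Clean slice (matrix).
#' @param xT Degraded endpoint slice.
#' @param context List with `prev` and `nxt`: the adjacent degraded slices.
#' @param net An [hd_network()], or a function `(triplet, t, modulation)`
#'   standing in for it (losses only, no gradients).
#' @param op A [build_gabor_operator()] result matching the slice shape.
#' @param sched An [alpha_schedule()].
#' @param t Step in `2..T`.
#' @param loss_norm `"L2"` or `"L1"`.
#' @param with_grads If `TRUE` (and `net` is a network) the parameter
#'   gradient tree is returned alongside.
#' @return A list of class `loss_bundle`: `F_stage_I`, `F_stage_II`,
#'   `F_error`, `L_final`, the two estimates, and optionally `grads`.
#' @export
compute_losses <- function(x0, xT, context, net, op, sched, t,
                           loss_norm = "L2", with_grads = FALSE) {
  assert_that(t >= 2, "stage II is undefined at t = 1; t must be >= 2")
  assert_that(t <= sched$T, "t exceeds the schedule")
  nf <- loss_norm_fn(loss_norm)
  x_t <- forward_degrade(x0, xT, t, op, sched)
  trip1 <- array(c(context$prev, x_t, context$nxt), c(dim(x0), 3))

  is_fun <- is.function(net)
  if (is_fun) {
    x0h <- net(trip1, t, NULL)
  } else {
    f1 <- net_forward(net$params, net$config, trip1, t)
    x0h <- f1$out
  }
  F_I <- nf$value(x0h - x0)

  x_tm1 <- forward_degrade(x0, xT, t - 1, op, sched)
  x_tm1_hat <- forward_degrade(x0h, xT, t - 1, op, sched)
  F_err <- nf$value(x_tm1_hat - x_tm1)

  trip2 <- array(c(context$prev, x_tm1_hat, context$nxt), c(dim(x0), 3))
  if (is_fun) {
    x0hh <- net(trip2, t - 1, NULL)
    phc <- NULL
  } else {
    phc <- phi_fwd(net$params$phi, x0h, xT)
    mod <- list(beta = phc$beta, gamma = phc$gamma)
    f2 <- net_forward(net$params, net$config, trip2, t - 1, mod = mod)
    x0hh <- f2$out
  }
  F_II <- nf$value(x0hh - x0)

  out <- structure(list(F_stage_I = F_I, F_stage_II = F_II, F_error = F_err,
                        L_final = F_I + F_II + F_err,
                        x0_hat = x0h, x0_hat2 = x0hh),
                   class = "loss_bundle")
  if (!with_grads || is_fun) return(out)

  # gradient on the stage-I output: data term plus the error term routed
  # back through the (self-adjoint) degradation operator
  g1 <- nf$grad(x0h - x0)
  a_tm1 <- schedule_alpha(sched, t - 1)
  if (a_tm1 != 0) {
    g1 <- g1 + a_tm1 * apply_operator(op, nf$grad(x_tm1_hat - x_tm1))
  }
  b1 <- net_backward(net$params, net$config, f1$cache, g1)
  b2 <- net_backward(net$params, net$config, f2$cache, nf$grad(x0hh - x0))
  grads <- tree_add(b1$grads, b2$grads)
  grads$phi <- tree_add(grads$phi,
                        phi_bwd(phc, net$params$phi, b2$dbeta, b2$dgamma))
  out$grads <- grads
  out
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# ---- training loop ---------------------------------------------------------

# Extract the pair list from a paired_dataset or accept a bare list of
# list(full =, degraded =) volume pairs.
dataset_pairs <- function(dataset) {
  pairs <- if (inherits(dataset, "paired_dataset")) dataset$pairs else dataset
  assert_that(is.list(pairs) && length(pairs) >= 1, "dataset is empty")
  pairs
}

# Sample one training example: a random volume, slice and square crop.
# Context slices use edge replication at volume boundaries.
sample_example <- function(pairs, crop) {
  p <- pairs[[sample.int(length(pairs), 1)]]
  full <- p$full$voxels
  degr <- p$degraded$voxels
  d <- dim(full)
  z <- sample.int(d[3], 1)
  zp <- max(1L, z - 1L)
  zn <- min(d[3], z + 1L)
  i0 <- if (d[1] > crop) sample.int(d[1] - crop + 1L, 1) else 1L
  j0 <- if (d[2] > crop) sample.int(d[2] - crop + 1L, 1) else 1L
  ri <- i0:(i0 + crop - 1L)
  rj <- j0:(j0 + crop - 1L)
  list(x0 = full[ri, rj, z], xT = degr[ri, rj, z],
       context = list(prev = degr[ri, rj, zp], nxt = degr[ri, rj, zn]))
}

#' Train the restoration network
#'
#' Runs the two-stage objective with Adam over random slice crops from a
#' paired dataset. Each iteration samples `batch_size` examples and a step
#' `t` uniformly from `2..T` per example (with the deployed `T = 2` every
#' step exercises both stages). Fully deterministic for a fixed seed on one
#' device.
#'
#' @param net An [hd_network()].
#' @param dataset A [make_paired_dataset()] result (or a bare list of
#'   `list(full, degraded)` volume pairs).
#' @param cfg A [train_config()].
#' @param op Optional degradation operator; built for the crop shape with
#'   default Gabor parameters when omitted.
#' @param resume Optional `state` element of a previous [hd_train()] result
#'   (or of a loaded checkpoint): training continues from that optimizer
#'   and RNG state up to `cfg$iterations` total.
#' @param checkpoint_path,checkpoint_every Optional periodic checkpointing.
#' @param quiet Suppress progress messages.
#' @return List with the trained `net`, a `log` data frame (iteration,
#'   F_stage_I, F_stage_II, F_error, L_final) and the final `state`.
#' @export
hd_train <- function(net, dataset, cfg = train_config(), op = NULL,
                     resume = NULL, checkpoint_path = NULL,
                     checkpoint_every = NULL, quiet = TRUE) {
  assert_that(inherits(net, "hd_network"), "net must be an hd_network")
  assert_that(inherits(cfg, "train_config"), "cfg must be a train_config")
  pairs <- dataset_pairs(dataset)
  d <- dim(pairs[[1]]$full$voxels)
  div <- 2^(net$config$n_scales - 1) * net$config$kv_reduction
  crop <- min(cfg$input_size, d[1], d[2])
  crop <- max(div, (crop %/% div) * div)
  assert_that(d[1] >= crop && d[2] >= crop, "volumes smaller than one block")
  if (is.null(op)) op <- build_gabor_operator(gabor_params(), c(crop, crop))
  assert_that(all(op$shape == crop), "operator shape must match the crop")
  sched <- alpha_schedule(cfg$T)

  params <- net$params
  if (is.null(resume)) {
    astate <- adam_init(params)
    start <- 1L
    set.seed(cfg$seed)
    log_rows <- matrix(NA_real_, cfg$iterations, 5)
  } else {
    astate <- resume$adam
    start <- resume$iteration + 1L
    assign(".Random.seed", resume$rng, envir = globalenv())
    log_rows <- matrix(NA_real_, cfg$iterations, 5)
    if (!is.null(resume$log_rows)) {
      log_rows[seq_len(nrow(resume$log_rows)), ] <- resume$log_rows
    }
  }
  if (start > cfg$iterations) {
    warning("resume state already at or past cfg$iterations", call. = FALSE)
  }

  for (it in seq.int(start, length.out = max(0L, cfg$iterations - start + 1L))) {
    gacc <- NULL
    fI <- fII <- ferr <- 0
    for (b in seq_len(cfg$batch_size)) {
      ex <- sample_example(pairs, crop)
      t <- if (cfg$T == 2) 2L else sample(2:cfg$T, 1)
      lb <- compute_losses(ex$x0, ex$xT, ex$context,
                           structure(list(params = params,
                                          config = net$config),
                                     class = "hd_network"),
                           op, sched, t, loss_norm = cfg$loss_norm,
                           with_grads = TRUE)
      gacc <- if (is.null(gacc)) lb$grads else tree_add(gacc, lb$grads)
      fI <- fI + lb$F_stage_I; fII <- fII + lb$F_stage_II
      ferr <- ferr + lb$F_error
    }
    gacc <- tree_map(gacc, function(g) g / cfg$batch_size)
    up <- adam_update(params, gacc, astate, cfg$lr,
                      cfg$adam_betas[1], cfg$adam_betas[2])
    params <- up$params
    astate <- up$state
    bs <- cfg$batch_size
    log_rows[it, ] <- c(it, fI / bs, fII / bs, ferr / bs,
                        (fI + fII + ferr) / bs)
    if (!quiet && it %% 100 == 0) {
      message(sprintf("[hdpact] iter %d L=%.5f", it, log_rows[it, 5]))
    }
    if (!is.null(checkpoint_path) && !is.null(checkpoint_every) &&
        it %% checkpoint_every == 0) {
      st <- list(adam = astate, iteration = it,
                 rng = get(".Random.seed", envir = globalenv()),
                 log_rows = log_rows[seq_len(it), , drop = FALSE])
      save_checkpoint(structure(list(params = params, config = net$config),
                                class = "hd_network"),
                      checkpoint_path, state = st)
    }
  }
  net$params <- params
  log <- as.data.frame(log_rows[seq_len(cfg$iterations), , drop = FALSE])
  names(log) <- c("iteration", "F_stage_I", "F_stage_II", "F_error",
                  "L_final")
  state <- list(adam = astate, iteration = cfg$iterations,
                rng = get(".Random.seed", envir = globalenv()),
                log_rows = log_rows)
  list(net = net, log = log, state = state)
}

#' Transfer fine-tuning on cluster-sampled data
#'
#' Initialises every weight from a model pretrained on sparse-sampled pairs
#' and continues training on cluster-scheme pairs with identical
#' hyperparameters except the iteration budget (default 9792). The
#' architectures must match exactly.
#'
#' @param pretrained An [hd_network()] or a checkpoint path.
#' @param dataset Cluster-scheme paired dataset.
#' @param cfg A [train_config()]; `iterations` defaults to 9792 if the
#'   config still carries the from-scratch default.
#' @param config Optional [network_config()] the checkpoint is expected to
#'   match; a structural mismatch (channels, scales, reduction, state size,
#'   embedding) is an error.
#' @param ... Passed to [hd_train()].
#' @return As [hd_train()].
#' @export
transfer_finetune <- function(pretrained, dataset, cfg = NULL, config = NULL,
                              ...) {
  if (is.character(pretrained)) pretrained <- load_checkpoint(pretrained)$net
  assert_that(inherits(pretrained, "hd_network"),
              "pretrained must be an hd_network or checkpoint path")
  if (!is.null(config)) {
    structural <- c("base_channels", "n_scales", "eca_kernel", "kv_reduction",
                    "ssm_state_size", "time_embed_dim")
    same <- vapply(structural, function(f)
      identical(pretrained$config[[f]], config[[f]]), TRUE)
    assert_that(all(same),
                sprintf("checkpoint architecture mismatch in: %s",
                        paste(structural[!same], collapse = ", ")))
  }
  if (is.null(cfg)) cfg <- train_config(iterations = 9792)
  hd_train(pretrained, dataset, cfg, ...)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a network checkpoint
#'
#' A checkpoint is a single RDS archive holding the weights, the network
#' configuration and (optionally) the optimizer/RNG state, accompanied by a
#' JSON sidecar (`<path>.json`) carrying the configuration and a
#' configuration hash for quick, library-agnostic inspection.
#'
#' @param net An [hd_network()].
#' @param path Output file path.
#' @param state Optional training state (from [hd_train()]).
#' @rdname checkpoint
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: a list
#'   with `net`, `state`.
#' @export
save_checkpoint <- function(net, path, state = NULL) {
  assert_that(inherits(net, "hd_network"), "net must be an hd_network")
  cfg_plain <- unclass(net$config)
  saveRDS(list(params = net$params, config = cfg_plain, state = state,
               format = 1L), path)
  sidecar <- list(format = 1L, config = cfg_plain,
                  config_hash = config_hash(cfg_plain))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @param path Checkpoint file path.
#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  assert_that(file.exists(path), sprintf("checkpoint not found: %s", path))
  ck <- readRDS(path)
  cfg <- do.call(network_config, ck$config[setdiff(names(ck$config), NULL)])
  net <- structure(list(params = ck$params, config = cfg),
                   class = "hd_network")
  list(net = net, state = ck$state)
}
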