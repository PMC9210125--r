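# Alternating adversarial training: one discriminator update (on real HR vs
# generated SR, detached from the generator) followed by one generator
# update (content + adversarial loss), with Adam and a learning rate halved
# after every `halving_interval` epochs.

#' Training configuration
#'
#' Defaults follow the reference schedule: Adam with moments (0.9, 0.999),
#' initial learning rate 1e-4 halved after every 50 epochs, 200 epochs.
#' Desk-scale runs shrink `total_epochs`/`batch_size` and typically raise
#' the learning rate; see the vignette.
#'
#' @param initial_lr Initial learning rate (> 0), shared by both networks.
#' @param halving_interval Epochs between learning-rate halvings.
#' @param total_epochs Number of epochs (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param hr_patch HR patch side for training crops; divisible by 8 and by
#'   the scale factor.
#' @param seed Seed governing shuffling and any patch subsampling.
#' @param mode `"gan"` (adversarial + content) or `"mse_only"` (content
#'   loss only; the discriminator is untouched).
#' @param betas Adam moment parameters.
#' @param grad_clip Optional element-wise gradient clip (GAN training can
#'   be unstable); `NULL` disables.
#' @return A `training_config` list.
#' @export
training_config <- function(initial_lr = 1e-4, halving_interval = 50L,
                            total_epochs = 200L, batch_size = 16L,
                            hr_patch = 96L, seed = 0L,
                            mode = c("gan", "mse_only"),
                            betas = c(0.9, 0.999), grad_clip = NULL) {
  mode <- match.arg(mode)
  betas <- as.numeric(unlist(betas))
  if (length(betas) != 2L || any(betas <= 0) || any(betas >= 1))
    stop("betas must be two Adam moment parameters in (0, 1)")
  if (initial_lr <= 0) stop("initial_lr must be > 0")
  if (halving_interval < 1L) stop("halving_interval must be >= 1")
  if (total_epochs < 1L) stop("total_epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (hr_patch %% 8L != 0L) stop("hr_patch must be divisible by 8")
  if (seed < 0) stop("seed must be >= 0")
  structure(list(initial_lr = initial_lr,
                 halving_interval = as.integer(halving_interval),
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 hr_patch = as.integer(hr_patch), seed = as.integer(seed),
                 mode = mode, betas = betas, grad_clip = grad_clip),
            class = "training_config")
}

#' Learning rate at an epoch
#'
#' `initial_lr / 2^floor(epoch / halving_interval)` — halved after every
#' `halving_interval` epochs.
#'
#' @param config A [training_config].
#' @param epoch 0-based epoch index in `[0, total_epochs)`.
#' @return The per-step learning rate.
#' @examples
#' lr_at_epoch(training_config(), 150)  # 1e-4 / 8
#' @export
lr_at_epoch <- function(config, epoch) {
  if (epoch < 0 || epoch >= config$total_epochs)
    stop(sprintf("epoch %d outside [0, %d)", epoch, config$total_epochs))
  config$initial_lr / 2^(floor(epoch / config$halving_interval))
}

ensure_optimizer <- function(handle) {
  if (is.null(handle$opt)) handle$opt <- adam_init(handle$mod)
  handle$opt
}

#' One alternating training step
#'
#' In `"gan"` mode: first one discriminator update minimising
#' [discriminator_loss()] on real HR vs generated SR (the SR batch is
#' detached from the generator), then one generator update minimising the
#' weighted total loss.  In `"mse_only"` mode the discriminator is left
#' untouched and only the content term is optimised.  Handles are updated
#' in place; with a zero learning rate parameters are bit-identical before
#' and after.
#'
#' @param gen A `medsr_generator` handle.
#' @param disc A `medsr_discriminator` handle (may be `NULL` in
#'   `"mse_only"` mode).
#' @param batch Non-empty list of [paired_sample]s of identical geometry.
#' @param weights A [loss_weights].
#' @param rate Learning rate for this step.
#' @param mode `"gan"` or `"mse_only"`.
#' @param betas Adam moment parameters.
#' @param grad_clip Optional element-wise gradient clip.
#' @return A `loss_breakdown` with an extra `discriminator` element
#'   (`NA` in `"mse_only"` mode), invisibly.
#' @export
train_step <- function(gen, disc, batch, weights = loss_weights(),
                       rate = 1e-4, mode = c("gan", "mse_only"),
                       betas = c(0.9, 0.999), grad_clip = NULL) {
  mode <- match.arg(mode)
  if (length(batch) == 0L) stop("batch must be non-empty")
  lr_list <- lapply(batch, `[[`, "lr")
  hr_arr <- batch_from_images(lapply(batch, `[[`, "hr"))
  sr <- generator_forward_node(gen, lr_list)
  if (!all(is.finite(sr$value))) stop("non-finite generator output")

  d_loss <- NA_real_
  if (mode == "gan") {
    fake_detached <- nd_const(sr$value)
    s_real <- disc$forward_node(nd_const(hr_arr), train = TRUE)
    s_fake <- disc$forward_node(fake_detached, train = TRUE)
    dl <- nd_add(nd_mean_neglog(s_real), nd_mean_neglog1m(s_fake))
    if (!is.finite(dl$value)) stop("non-finite discriminator loss")
    nd_backward(dl)
    adam_step(disc$mod, ensure_optimizer(disc), rate, betas[1], betas[2],
              grad_clip = grad_clip)
    d_loss <- dl$value
  }

  content <- nd_mse(sr, hr_arr)
  if (mode == "gan" && weights$a2 > 0) {
    s_gen <- disc$forward_node(sr, train = TRUE)
    adv <- nd_mean_neglog(s_gen)
    gl <- nd_wsum(list(content, adv), c(weights$a1, weights$a2))
    adv_value <- adv$value
  } else {
    gl <- nd_wsum(list(content), weights$a1)
    adv_value <- 0
  }
  if (!is.finite(gl$value)) stop("non-finite generator loss")
  nd_backward(gl)
  adam_step(gen$mod, ensure_optimizer(gen), rate, betas[1], betas[2],
            grad_clip = grad_clip)

  out <- total_loss(content$value, adv_value, weights)
  out$discriminator <- d_loss
  invisible(out)
}

validation_metrics <- function(gen, pairs) {
  res <- vapply(pairs, function(p) {
    sr <- generator_forward(gen, p$lr)
    c(psnr(sr, p$hr),
      if (nrow(p$hr) >= 11L && ncol(p$hr) >= 11L) ssim(sr, p$hr) else NA_real_)
  }, numeric(2))
  ps <- res[1L, ]
  c(psnr = mean(ps[is.finite(ps)]), ssim = mean(res[2L, ], na.rm = TRUE))
}

#' Train a super-resolution model
#'
#' Runs `total_epochs` over seeded, shuffled minibatches of the dataset,
#' logging per-epoch losses, learning rate and validation PSNR/SSIM.  One
#' pair in ten (seeded) is held out for validation when the dataset has at
#' least ten pairs; otherwise validation is computed on the training pairs.
#' The best-validation-PSNR and the last state are checkpointed when
#' `out_dir` is given.
#'
#' @param config A [training_config].
#' @param gen_spec A [generator_spec].
#' @param disc_spec A [discriminator_spec] (ignored in `"mse_only"` mode).
#' @param dataset Non-empty list of [paired_sample]s with identical LR/HR
#'   geometry (use [extract_patches()] for heterogeneous images).
#' @param scale Integer scale factor of the dataset.
#' @param weights A [loss_weights].
#' @param out_dir Optional directory for checkpoints and the log file.
#' @param verbose Emit a log line per epoch.
#' @param validate_every Compute validation metrics every this many epochs
#'   (always at the last epoch); other epochs log `NA`.
#' @return List with `generator`, `discriminator` (or `NULL`), `log` (a
#'   data frame with one row per epoch), and `best_epoch`.
#' @export
train_sr <- function(config, gen_spec, disc_spec = discriminator_spec(),
                     dataset, scale, weights = loss_weights(),
                     out_dir = NULL, verbose = FALSE, validate_every = 1L) {
  if (length(dataset) == 0L) stop("dataset must be non-empty")
  r <- scale_factor(scale)
  gen <- build_generator(gen_spec, r, seed = config$seed)
  disc <- NULL
  if (config$mode == "gan") {
    side <- nrow(dataset[[1L]]$hr)
    disc <- build_discriminator(disc_spec, side,
                                seed = derive_seed(config$seed, 1))
  }
  n <- length(dataset)
  val_idx <- integer(0)
  if (n >= 10L)
    val_idx <- with_seed(derive_seed(config$seed, 2),
                         sort(sample.int(n, n %/% 10L)))
  train_idx <- setdiff(seq_len(n), val_idx)
  val_pairs <- if (length(val_idx)) dataset[val_idx] else dataset
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log <- vector("list", config$total_epochs)
  best_psnr <- -Inf
  best_epoch <- NA_integer_
  for (epoch in seq_len(config$total_epochs) - 1L) {
    rate <- lr_at_epoch(config, epoch)
    ord <- with_seed(derive_seed(config$seed, 100 + epoch),
                     sample(train_idx))
    sums <- c(content = 0, adversarial = 0, total = 0, disc = 0)
    nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      lb <- train_step(gen, disc, dataset[idx], weights, rate,
                       mode = config$mode, betas = config$betas,
                       grad_clip = config$grad_clip)
      sums <- sums + c(lb$content, lb$adversarial, lb$total,
                       ifelse(is.na(lb$discriminator), 0, lb$discriminator))
      nb <- nb + 1L
    }
    vm <- c(psnr = NA_real_, ssim = NA_real_)
    if (epoch %% validate_every == 0L || epoch == config$total_epochs - 1L)
      vm <- validation_metrics(gen, val_pairs)
    log[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = rate,
      content = sums[["content"]] / nb,
      adversarial = sums[["adversarial"]] / nb,
      total = sums[["total"]] / nb,
      disc_loss = if (config$mode == "gan") sums[["disc"]] / nb else NA_real_,
      val_psnr = vm[["psnr"]], val_ssim = vm[["ssim"]])
    if (verbose)
      log_line(epoch = epoch, lr = rate,
               content = signif(sums[["content"]] / nb, 6),
               val_psnr = signif(vm[["psnr"]], 6),
               file = if (!is.null(out_dir)) file.path(out_dir, "train.log"))
    if (is.finite(vm[["psnr"]]) && vm[["psnr"]] > best_psnr) {
      best_psnr <- vm[["psnr"]]
      best_epoch <- epoch
      if (!is.null(out_dir))
        save_checkpoint(gen, file.path(out_dir, "best.rds"))
    }
  }
  if (!is.null(out_dir)) {
    save_checkpoint(gen, file.path(out_dir, "last.rds"))
    utils::write.csv(do.call(rbind, log), file.path(out_dir, "log.csv"),
                     row.names = FALSE)
  }
  list(generator = gen, discriminator = disc, log = do.call(rbind, log),
       best_epoch = best_epoch)
}

# ---- checkpoints -----------------------------------------------------------

#' Save a generator checkpoint
#'
#' Stores the architecture spec, scale, seed and all parameter values, so
#' the model can be rebuilt exactly with [load_checkpoint()].
#'
#' @param gen A `medsr_generator` handle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(gen, path) {
  saveRDS(list(kind = "generator", spec = gen$spec, scale = gen$scale,
               seed = gen$seed,
               params = lapply(gen$mod$params, function(p) p$value)),
          path)
  invisible(path)
}

#' Load a generator checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `medsr_generator` handle with restored parameters.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$kind, "generator")) stop("not a generator checkpoint")
  gen <- build_generator(ck$spec, ck$scale, seed = ck$seed)
  if (!identical(sort(names(ck$params)), sort(names(gen$mod$params))))
    stop("checkpoint parameters do not match the architecture")
  for (nm in names(ck$params)) gen$mod$params[[nm]]$value <- ck$params[[nm]]
  gen
}

# ---- ablation harness ------------------------------------------------------

#' Compare feature-aggregation variants
#'
#' Trains each requested variant under an identical seed and configuration
#' on the same dataset, and reports per-variant PSNR/SSIM on the training
#' set together with total and aggregation-head parameter counts.  Across
#' the `hr_only` / `bilinear` / `deconv` variants the aggregation head is
#' the only differing component.
#'
#' @param variants Character vector drawn from `"srgan_baseline_agg"`
#'   (plain residual trunk + adversarial loss), `"hr_only_agg"`,
#'   `"bilinear_multires_agg"`, `"deconv_agg"` (multi-resolution trunk with
#'   the named head, content loss only) and `"deconv_agg_plus_gan"` (the
#'   full model).
#' @param config A [training_config].
#' @param gen_spec Base [generator_spec]; its `aggregation`/`trunk` fields
#'   are overridden per variant.
#' @param disc_spec A [discriminator_spec] for the adversarial variants.
#' @param dataset List of [paired_sample]s.
#' @param scale Integer scale factor.
#' @param weights A [loss_weights] for the adversarial variants.
#' @return Data frame with one row per variant: `variant`, `psnr`, `ssim`,
#'   `n_params`, `head_params`.
#' @export
run_ablation <- function(variants, config, gen_spec, disc_spec = discriminator_spec(),
                         dataset, scale, weights = loss_weights()) {
  all_variants <- c("srgan_baseline_agg", "hr_only_agg",
                    "bilinear_multires_agg", "deconv_agg",
                    "deconv_agg_plus_gan")
  if (length(variants) == 0L) stop("variants must be non-empty")
  variants <- match.arg(variants, all_variants, several.ok = TRUE)
  rows <- lapply(variants, function(v) {
    sp <- gen_spec
    cf <- config
    sp$trunk <- if (v == "srgan_baseline_agg") "plain" else "multires"
    sp$aggregation <- switch(v,
                             hr_only_agg = "hr_only",
                             bilinear_multires_agg = "bilinear",
                             "deconv")
    cf$mode <- if (v %in% c("srgan_baseline_agg", "deconv_agg_plus_gan"))
      "gan" else "mse_only"
    fit <- train_sr(cf, sp, disc_spec, dataset, scale, weights)
    vm <- validation_metrics(fit$generator, dataset)
    data.frame(variant = v, psnr = vm[["psnr"]], ssim = vm[["ssim"]],
               n_params = n_params(fit$generator),
               head_params = n_params(fit$generator, "agg."))
  })
  do.call(rbind, rows)
}
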