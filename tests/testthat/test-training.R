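make_tiny_pairs <- function(n = 2, side = 32, scale = 4, seed = 20) {
  hrs <- generate_dataset(n, phantom_spec(size = side), seed = seed)
  make_pairs(hrs, scale)
}

test_that("the learning-rate schedule halves after every interval", {
  cfg <- training_config()
  expect_equal(lr_at_epoch(cfg, 0), 1e-4)
  expect_equal(lr_at_epoch(cfg, 49), 1e-4)
  expect_equal(lr_at_epoch(cfg, 50), 5e-5)
  expect_equal(lr_at_epoch(cfg, 150), 1.25e-5)
  expect_error(lr_at_epoch(cfg, 200), "outside")
  expect_error(lr_at_epoch(cfg, -1), "outside")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(training_config(initial_lr = 0), "initial_lr")
  expect_error(training_config(total_epochs = 0), "total_epochs")
  expect_error(training_config(hr_patch = 20), "divisible by 8")
  expect_error(training_config(betas = c(0.9, 1.2)), "betas")
})

test_that("a zero learning rate leaves parameters bit-identical", {
  gen <- build_generator(tiny_gen_spec(), 4, seed = 1)
  before <- lapply(gen$mod$params, function(p) p$value)
  train_step(gen, NULL, make_tiny_pairs(1), loss_weights(1, 0), rate = 0,
             mode = "mse_only")
  after <- lapply(gen$mod$params, function(p) p$value)
  expect_identical(before, after)
})

test_that("training steps are deterministic for a fixed seed and batch", {
  batch <- make_tiny_pairs(2)
  run <- function() {
    gen <- build_generator(tiny_gen_spec(), 4, seed = 5)
    disc <- build_discriminator(tiny_disc_spec(), 32, seed = 6)
    for (i in 1:2)
      train_step(gen, disc, batch, loss_weights(), 1e-4, mode = "gan")
    list(g = lapply(gen$mod$params, function(p) p$value),
         d = lapply(disc$mod$params, function(p) p$value))
  }
  expect_identical(run(), run())
})

test_that("content-only optimisation reduces the loss on a repeated batch", {
  gen <- build_generator(tiny_gen_spec(), 4, seed = 2)
  batch <- make_tiny_pairs(1)
  losses <- vapply(1:50, function(i)
    train_step(gen, NULL, batch, loss_weights(1, 0), 1e-3,
               mode = "mse_only")$content, 0)
  expect_lt(mean(losses[41:50]), mean(losses[1:10]))
  # noise-tolerant monotonicity: most consecutive pairs decrease
  expect_gte(mean(diff(losses) < 0), 0.7)
})

test_that("a smoke run completes, checkpoints and logs one row per epoch", {
  d <- withr::local_tempdir()
  cfg <- training_config(initial_lr = 1e-3, total_epochs = 1, batch_size = 1,
                         hr_patch = 32, mode = "mse_only", seed = 3)
  fit <- train_sr(cfg, tiny_gen_spec(), dataset = make_tiny_pairs(1),
                  scale = 4, out_dir = d)
  expect_identical(nrow(fit$log), 1L)
  expect_true(file.exists(file.path(d, "last.rds")))
  expect_true(file.exists(file.path(d, "best.rds")))
  expect_true(file.exists(file.path(d, "log.csv")))
  reloaded <- load_checkpoint(file.path(d, "last.rds"))
  lr_img <- make_tiny_pairs(1)[[1]]$lr
  expect_identical(generator_forward(reloaded, lr_img),
                   generator_forward(fit$generator, lr_img))
})

test_that("identical config and seed reproduce the training log bit-for-bit", {
  cfg <- training_config(initial_lr = 1e-3, halving_interval = 1,
                         total_epochs = 2, batch_size = 2, hr_patch = 32,
                         mode = "gan", seed = 11)
  ds <- make_tiny_pairs(3)
  run <- function() train_sr(cfg, tiny_gen_spec(), tiny_disc_spec(), ds, 4)$log
  l1 <- run()
  l2 <- run()
  expect_identical(l1, l2)
  expect_identical(nrow(l1), 2L)
  # schedule invariant: logged rates equal the closed form
  expect_equal(l1$lr, vapply(0:1, function(e) lr_at_epoch(cfg, e), 0))
  expect_true(all(is.finite(l1$disc_loss)))
})

test_that("adversarial training keeps scores and losses finite on a tiny run", {
  cfg <- training_config(initial_lr = 1e-3, total_epochs = 3, batch_size = 2,
                         hr_patch = 32, mode = "gan", seed = 13)
  fit <- train_sr(cfg, tiny_gen_spec(), tiny_disc_spec(), make_tiny_pairs(2),
                  scale = 4)
  expect_true(all(is.finite(fit$log$total)))
  expect_true(all(is.finite(fit$log$disc_loss)))
  s <- discriminator_forward(fit$discriminator, make_tiny_pairs(1)[[1]]$hr)
  expect_true(s > 0 && s < 1)
})

test_that("the ablation harness isolates the aggregation head", {
  ds <- make_tiny_pairs(2)
  cfg <- training_config(initial_lr = 1e-3, total_epochs = 2, batch_size = 2,
                         hr_patch = 32, mode = "mse_only", seed = 7)
  tab <- run_ablation(c("hr_only_agg", "bilinear_multires_agg", "deconv_agg"),
                      cfg, tiny_gen_spec(), tiny_disc_spec(), ds, 4)
  expect_identical(nrow(tab), 3L)
  hp <- setNames(tab$head_params, tab$variant)
  expect_gt(hp[["deconv_agg"]], hp[["bilinear_multires_agg"]])
  expect_gt(hp[["bilinear_multires_agg"]], hp[["hr_only_agg"]] - 1)
  # identical trunks: total params differ only by the head
  np <- setNames(tab$n_params, tab$variant)
  expect_equal(np[["deconv_agg"]] - hp[["deconv_agg"]],
               np[["bilinear_multires_agg"]] - hp[["bilinear_multires_agg"]])
  # repeated variant under the same seed reproduces its row
  tab2 <- run_ablation("deconv_agg", cfg, tiny_gen_spec(), tiny_disc_spec(),
                       ds, 4)
  expect_equal(tab2$psnr, tab$psnr[tab$variant == "deconv_agg"])
})
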