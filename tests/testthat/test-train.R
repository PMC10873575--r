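# Training loop, freezing schedule, prediction, ablation, cross-domain.

small_data <- function(n = 300L, delta = 3, seed = 21L, ...) {
  simulate_dataset(sim_config(n_instances = n, proportion = 0.5, delta = delta,
                              noise_sigma = 1, seed = seed, ...))
}

test_that("each phase leaves the frozen module bit-identical", {
  ms <- small_data()
  ns <- asNamespace("nanocon")
  # epoch 1 is the contrastive phase: classifier must equal its initialization
  fit1 <- nanocon(ms, epochs = 1L, seed = 3L, batch_size = 50L)
  vocab <- build_vocab()
  init <- ns$init_params(fit1$config, attr(vocab, "vocab_size"), seed = 3L)
  cls <- ns$classifier_param_names(init)
  expect_identical(fit1$params[cls], init[cls])
  expect_false(identical(fit1$params$emb, init$emb))
  # epoch 2 is the classification phase: encoder frozen at its epoch-1 state
  fit2 <- nanocon(ms, epochs = 2L, seed = 3L, batch_size = 50L)
  enc <- ns$encoder_param_names(init)
  expect_identical(fit2$params[enc], fit1$params[enc])
  expect_false(identical(fit2$params[cls], fit1$params[cls]))
  # absolute change of frozen parameters is exactly zero
  drift <- sum(vapply(cls, function(nm)
    sum(abs(fit1$params[[nm]] - init[[nm]])), numeric(1)))
  expect_identical(drift, 0)
})

test_that("training the combined loss reduces it on separable data", {
  ms <- small_data(n = 400L)
  fit <- nanocon(ms, epochs = 5L, seed = 2L, batch_size = 64L)
  h <- fit$history
  con_loss <- h$loss[h$phase == "contrastive"]
  expect_lt(con_loss[length(con_loss)], con_loss[1])
  cls_loss <- h$loss[h$phase == "classification"]
  expect_lt(cls_loss[length(cls_loss)], cls_loss[1] + 1e-9)
})

test_that("degenerate training inputs are rejected", {
  ms <- small_data(n = 100L)
  onecls <- ms[ms$info$label == 0L]
  expect_error(nanocon(onecls, epochs = 1L), "both classes")
  unl <- ms
  unl$info$label[1] <- NA_integer_
  expect_error(nanocon(unl, epochs = 1L), "unlabeled")
  expect_error(nanocon(ms, epochs = 0L), "epochs")
})

test_that("prediction is deterministic, complete and class-separating", {
  sf <- shared_fit()
  fit <- sf$fit
  test <- sf$splits$test
  p <- predict(fit, test)
  expect_length(p, nrow(test$info))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict(fit, test), p)
  # the same instance twice gets the same probability
  dup <- test[c(1L, 1L, 2L)]
  pd <- predict(fit, dup)
  expect_equal(pd[1], pd[2])
  # large effect size: positives score above negatives on average
  expect_gt(mean(p[test$info$label == 1L]), mean(p[test$info$label == 0L]))
  cls <- predict(fit, test, type = "class")
  expect_true(all(cls %in% 0:1))
})

test_that("representations export at repr_dim for visualization", {
  sf <- shared_fit()
  repr <- predict(sf$fit, sf$splits$test[1:7], type = "repr")
  expect_equal(dim(repr), c(7L, sf$fit$config$repr_dim))
  expect_true(all(is.finite(repr)))
})

test_that("the full pipeline is reproducible bit-for-bit under a fixed seed", {
  ms <- small_data(n = 200L)
  sp <- split_dataset(ms, seed = 4L)
  f1 <- nanocon(sp$train, sp$validation, epochs = 2L, seed = 9L)
  f2 <- nanocon(sp$train, sp$validation, epochs = 2L, seed = 9L)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, sp$test), predict(f2, sp$test))
  expect_identical(f1$history, f2$history)
})

test_that("model selection returns the best validation AUPRC epoch", {
  sf <- shared_fit()
  h <- sf$fit$history
  top <- max(h$val_auprc, na.rm = TRUE)
  # ties go to the later epoch, whose classifier head is the most trained
  expect_equal(sf$fit$best_epoch, max(h$epoch[h$val_auprc == top]))
})

test_that("checkpoints round-trip and reject a mismatched vocabulary", {
  sf <- shared_fit()
  f <- withr::local_tempfile(fileext = ".json.gz")
  save_checkpoint(sf$fit, f)
  back <- load_checkpoint(f)
  test <- sf$splits$test[1:10]
  expect_equal(predict(back, test), predict(sf$fit, test), tolerance = 1e-12)
  tampered <- back
  tampered$vocab_hash <- "0"
  expect_error(predict(tampered, test), "vocabulary")
})

test_that("run_ablation flips exactly the requested branch", {
  expect_error(run_ablation(list(), "mask_everything"), "unknown ablation")
  ms <- small_data(n = 200L)
  sp <- split_dataset(ms, seed = 1L)
  rep <- run_ablation(sp, "no_contrast", epochs = 2L, seed = 1L)
  fit <- attr(rep, "model")
  expect_true("no_contrast" %in% fit$config$ablation)
  expect_equal(fit$alpha, 0)  # contrastive term disabled
  expect_s3_class(rep, "metric_report")
})

test_that("cross-domain evaluation transfers between matched simulators", {
  sf <- shared_fit()
  # same generative parameters, new seed: transfer should stay strong
  domain_b <- simulate_dataset(sim_config(n_instances = 300L, proportion = 0.25,
                                          delta = 3, noise_sigma = 1,
                                          seed = 77L))
  in_dom <- evaluate(sf$fit, sf$splits$test)
  cross <- cross_domain_eval(sf$fit, domain_b)
  expect_gt(cross$AUROC, 0.9)
  expect_lt(abs(cross$AUROC - in_dom$AUROC), 0.1)
  # a domain whose class signal lives in a different track transfers poorly
  domain_c <- simulate_dataset(sim_config(n_instances = 300L, proportion = 0.25,
                                          delta = 3, noise_sigma = 1,
                                          effect_tracks = "stds", seed = 78L))
  far <- cross_domain_eval(sf$fit, domain_c)
  expect_lt(far$AUPRC, in_dom$AUPRC)
  expect_error(cross_domain_eval(sf$fit, data.frame()), "methyl_set")
})

test_that("training on the evaluation set reproduces in-domain metrics", {
  sf <- shared_fit()
  direct <- evaluate(sf$fit, sf$splits$test)
  via_cross <- cross_domain_eval(sf$fit, sf$splits$test)
  expect_identical(unclass(direct), unclass(via_cross))
})
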