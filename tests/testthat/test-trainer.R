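# small two-monomer dataset (4 atom types) used for fast trainer checks
trainer_manifest <- function() {
  fixture("trainer_manifest", function() {
    cfg <- fx_config()
    me <- fx_monomer("methane"); mo <- fx_monomer("methanol")
    # 16 dimers over 4 atom types: enough equations to pin all 10
    # pairwise products of each bilinear family
    dimers <- c(generate_dimer_configs(me, me, 5, cfg),
                generate_dimer_configs(mo, mo, 5, cfg),
                generate_dimer_configs(me, mo, 6, cfg))
    saptfit:::as_manifest(generate_reference_energies(dimers, cfg))
  })
}

test_that("loss obeys its closed-form special cases", {
  man <- trainer_manifest()
  truth <- fx_config()$ground_truth
  # model-consistent references: zero residuals, zero loss at any gamma
  expect_lt(sapt_loss(truth, man, gamma = 0.4), 1e-18)
  expect_lt(sapt_loss(truth, man, gamma = 0), 1e-18)

  # hand-built example: one dimer with every component residual 0.25, so
  # (by the component-sum invariant) total residual 1:
  # gamma 0.4 -> 0.6 * 1^2 + 0.4 * (4 * 0.25^2) = 0.7
  d <- man$dimer[[1]]
  shifted <- d$reference
  d$reference <- saptfit:::as_components(
    shifted[c("elst", "exch", "indu", "disp")] - 0.25)
  man1 <- saptfit:::as_manifest(list(d))
  expect_equal(sapt_loss(truth, man1, gamma = 0.4), 0.7, tolerance = 1e-8)
  # gamma 0 keeps only the total-energy MSE
  expect_equal(sapt_loss(truth, man1, gamma = 0), 1.0, tolerance = 1e-8)
  # gamma 1 keeps only the component MSEs: 4 * 0.0625
  expect_equal(sapt_loss(truth, man1, gamma = 1), 0.25, tolerance = 1e-8)

  # permutation invariance
  perm <- man[sample(nrow(man)), ]
  expect_equal(sapt_loss(truth, perm, 0.4), sapt_loss(truth, man, 0.4),
               tolerance = 1e-15)

  # a missing reference is an error naming the dimer
  man$dimer[[2]]$reference <- NULL
  expect_error(sapt_loss(truth, man), regexp = man$name[2],
               class = "saptfit_reference_error")
})

test_that("starting at the ground truth terminates immediately", {
  man <- trainer_manifest()
  fit <- fit_global_parameters(man, params_init = fx_config()$ground_truth,
                               strategy = "joint")
  expect_lt(fit$loss, 1e-16)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2)
})

test_that("fit recovers ground-truth parameters on noiseless data", {
  man <- trainer_manifest()
  fit <- fit_global_parameters(man, max_iter = 3000)
  truth <- fx_config()$ground_truth
  present <- c("HC", "C4", "O2", "HO")
  for (cl in c("kelst", "kexch", "kindu", "kdisp")) {
    i <- match(present, truth$type)
    expect_lt(max(abs(fit$parameters[[cl]][i] / truth[[cl]][i] - 1)), 0.01)
  }
  expect_true(all(diff(fit$trace$loss) <= 0))   # best-so-far trace
})

test_that("gamma = 1 decouples the component fits", {
  man <- trainer_manifest()
  joint <- fit_global_parameters(man, gamma = 1, max_iter = 3000)
  present <- c("HC", "C4", "O2", "HO")
  i <- match(present, joint$parameters$type)
  for (cmp in c("exch", "indu")) {
    alone <- fit_global_parameters(man, gamma = 1, components = cmp,
                                   max_iter = 3000)
    cl <- paste0("k", cmp)
    expect_lt(max(abs(alone$parameters[[cl]][i] /
                        joint$parameters[[cl]][i] - 1)), 1e-3)
  }
  # dispersion carries near-zero couplings whose fitted values sit in a
  # numerically flat direction; there the decoupling shows up in the
  # predicted energies rather than in the raw parameters
  alone <- fit_global_parameters(man, gamma = 1, components = "disp",
                                 max_iter = 3000)
  e_joint <- purrr::map_dbl(man$dimer, function(d)
    dispersion_energy(d, joint$parameters))
  e_alone <- purrr::map_dbl(man$dimer, function(d)
    dispersion_energy(d, alone$parameters))
  expect_lt(max(abs(e_joint - e_alone)), 1e-4)
})

test_that("fit rejects degenerate inputs", {
  man <- trainer_manifest()
  bad <- uniform_parameters()
  bad$kexch <- 1e300                        # overflows the bilinear form
  expect_error(fit_global_parameters(man, params_init = bad,
                                     strategy = "joint"),
               class = "saptfit_fit_error")
  expect_error(fit_global_parameters(man[0, ]))
})

test_that("augmentation adds the smallest failing dimer until the pool is
           controlled", {
  cfg <- fx_config()
  # training set without any nitrogen chemistry; pool holds formamide
  # homodimers whose N3/HN parameters the initial fit cannot know
  lib_names <- c("methane", "methanol", "formaldehyde")
  train_dimers <- unlist(lapply(lib_names, function(nm) {
    generate_dimer_configs(fx_monomer(nm), fx_monomer(nm), 2, cfg)
  }), recursive = FALSE)
  pool_dimers <- generate_dimer_configs(fx_monomer("formamide"),
                                        fx_monomer("formamide"), 3, cfg)
  train <- saptfit:::as_manifest(generate_reference_energies(train_dimers, cfg))
  pool <- saptfit:::as_manifest(generate_reference_energies(pool_dimers, cfg))

  out <- augment_training_set(train, pool, threshold = 1.0, max_iter = 2500)
  pred <- predict_sapt(out$train, out$fit$parameters)
  refs <- reference_components(out$train)
  expect_true(any(grepl("formamide", out$train$name)))
  # the pool dimers remaining outside the train set are all controlled
  remaining <- setdiff(pool$name, out$train$name)
  if (length(remaining) > 0) {
    rem <- pool[pool$name %in% remaining, ]
    pr <- predict_sapt(rem, out$fit$parameters)
    rr <- reference_components(rem)
    expect_true(all(abs(pr$total - rr$total) <= 1.0))
  }

  # an infinite threshold reduces to a single plain fit
  plain <- augment_training_set(train, pool, threshold = Inf, max_iter = 50)
  expect_equal(nrow(plain$train), nrow(train))
  expect_equal(nrow(plain$history), 1)
})

test_that("tidy, glance and autoplot work on fit objects", {
  man <- trainer_manifest()
  fit <- fit_global_parameters(man, params_init = fx_config()$ground_truth)
  td <- tidy(fit)
  expect_equal(nrow(td), 36)
  expect_setequal(unique(td$component), c("elst", "exch", "indu", "disp"))
  gl <- glance(fit)
  expect_equal(gl$n_dimers, nrow(man))
  expect_s3_class(autoplot(fit), "ggplot")
})
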