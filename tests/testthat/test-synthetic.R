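test_that("monomer library spans all classes and all nine atom types", {
  lib <- builtin_monomer_library()
  expect_gte(length(lib), 8)
  types <- sort(unique(unlist(lapply(lib, function(m) m$atoms$type))))
  expect_equal(types, sort(atom_type_labels()))
  classes <- unique(vapply(lib, function(m) m$group_class, ""))
  expect_setequal(classes, c("alkane", "alkene", "alkyne", "alcohol",
                             "aldehyde", "ketone", "carboxylic_acid",
                             "amide"))
  # every monomer types cleanly from scratch
  for (m in lib) {
    fresh <- sapt_monomer(m$atoms[, c("element", "x", "y", "z")],
                          name = m$name)
    expect_no_error(assign_atom_types(fresh))
  }
})

test_that("generated properties are valid, neutral and seed-deterministic", {
  cfg <- synth_config(seed = 77)
  for (m in builtin_monomer_library()[c(1, 8, 9)]) {
    g <- generate_properties(m, cfg)
    expect_no_error(validate_properties(g$properties))
    # electronic monopoles sum to minus the electron count
    expect_equal(sum(g$properties$mono_e), -sum(g$properties$Z),
                 tolerance = 1e-10)
    g2 <- generate_properties(m, cfg)
    expect_identical(g$properties, g2$properties)
    g3 <- generate_properties(m, synth_config(seed = 78))
    expect_false(isTRUE(all.equal(g$properties, g3$properties)))
  }
  # zero jitter pins the base values exactly across calls
  cfg0 <- synth_config(seed = 5, property_jitter = 0)
  a <- generate_properties(builtin_monomer_library()[[2]], cfg0)
  b <- generate_properties(builtin_monomer_library()[[2]], cfg0)
  expect_identical(a$properties$sigma, b$properties$sigma)
})

test_that("dimer configurations respect the contact floor and the seed", {
  cfg <- fx_config()
  a <- fx_monomer("acetone"); b <- fx_monomer("formic_acid")
  expect_length(generate_dimer_configs(a, b, 0, cfg), 0)
  ds <- generate_dimer_configs(a, b, 6, cfg)
  for (d in ds) {
    dmin <- min(saptfit:::cross_distances(
      saptfit:::monomer_positions(d$a), saptfit:::monomer_positions(d$b)))
    expect_gte(dmin / saptfit:::BOHR_ANGSTROM, 2.0)
  }
  ds2 <- generate_dimer_configs(a, b, 6, cfg)
  expect_equal(ds, ds2)
})

test_that("reference energies are model-consistent and noise is seeded", {
  cfg <- fx_config()                         # zero noise
  ds <- generate_dimer_configs(fx_monomer("methanol"), fx_monomer("ethene"),
                               2, cfg)
  with_ref <- generate_reference_energies(ds, cfg)
  for (d in with_ref) {
    direct <- sapt_energy(d, cfg$ground_truth)
    expect_components_equal(d$reference, direct, 1e-9)
    expect_equal(d$reference$total,
                 sum(d$reference[c("elst", "exch", "indu", "disp")]),
                 tolerance = 1e-12)
  }
  noisy_cfg <- synth_config(seed = 101, noise_sigma = 0.25)
  n1 <- generate_reference_energies(ds, noisy_cfg)
  n2 <- generate_reference_energies(ds, noisy_cfg)
  expect_equal(n1[[1]]$reference, n2[[1]]$reference)
  n3 <- generate_reference_energies(
    ds, synth_config(seed = 102, noise_sigma = 0.25))
  expect_false(isTRUE(all.equal(n1[[1]]$reference, n3[[1]]$reference)))
  # the noiseless core is unchanged: remove the noise by differencing
  expect_false(isTRUE(all.equal(n1[[1]]$reference$elst,
                                with_ref[[1]]$reference$elst)))
})

test_that("benchmark suite has homodimer train / heterodimer test structure", {
  suite <- fx_suite()
  cfg <- fx_config()
  expect_equal(nrow(suite$train), 9 * cfg$n_train_replicates)
  expect_equal(nrow(suite$test), choose(9, 2) * cfg$n_test_per_pair)
  for (d in suite$train$dimer) expect_equal(d$a$name, d$b$name)
  for (d in suite$test$dimer) expect_false(d$a$name == d$b$name)
  expect_false(anyDuplicated(suite$train$name) > 0)
  # deterministic under the fixed seed
  again <- make_benchmark_suite(fx_config())
  expect_equal(again$train$dimer[[1]]$reference,
               suite$train$dimer[[1]]$reference)
})

test_that("manifests round-trip through the on-disk layout", {
  suite <- fx_suite()
  sub <- suite$test[1:3, ]
  dir <- withr::local_tempdir()
  write_manifest(sub, dir, name = "roundtrip")
  back <- read_manifest(dir)
  expect_equal(back$name, sub$name)
  expect_equal(back$subgroup, sub$subgroup)
  expect_equal(back$hbond, sub$hbond)
  for (i in 1:3) {
    expect_equal(back$dimer[[i]]$reference, sub$dimer[[i]]$reference,
                 tolerance = 1e-12)
    expect_equal(as.data.frame(back$dimer[[i]]$a$properties),
                 as.data.frame(sub$dimer[[i]]$a$properties),
                 tolerance = 1e-12)
    e_back <- sapt_energy(back$dimer[[i]], default_parameters("base"))
    e_orig <- sapt_energy(sub$dimer[[i]], default_parameters("base"))
    expect_components_equal(e_back, e_orig, 1e-6)
  }
  # a missing referenced file is detected
  unlink(file.path(dir, "xyz", paste0(sub$name[2], ".xyz")))
  expect_error(read_manifest(dir), class = "saptfit_manifest_error")
})
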