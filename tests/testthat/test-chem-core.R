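test_that("bond perception applies the covalent-radius rule", {
  me <- builtin_monomer_library()[[1]]        # methane, bonds perceived
  expect_equal(nrow(me$bonds), 4)
  expect_true(all(me$bonds[, 1] == 1))        # all bonds involve the carbon

  lone <- sapt_monomer(tibble::tibble(element = "H", x = 0, y = 0, z = 0))
  expect_equal(nrow(perceive_bonds(lone)$bonds), 0)

  # formaldehyde: distance table against covalent-radius cutoffs gives
  # exactly {C-O, C-H, C-H}; H..O distances (~2.0 A) exceed 1.2*(0.31+0.66)
  fd <- builtin_monomer_library()[[6]]
  expect_equal(nrow(fd$bonds), 3)
  expect_setequal(
    apply(fd$bonds, 1, function(b) paste(sort(fd$atoms$element[b]),
                                         collapse = "-")),
    c("C-O", "C-H", "C-H"))

  clash <- sapt_monomer(tibble::tibble(element = c("C", "C"),
                                       x = c(0, 0.1), y = 0, z = 0))
  expect_error(perceive_bonds(clash), class = "saptfit_geometry_error")

  lonely <- sapt_monomer(tibble::tibble(element = c("C", "C"),
                                        x = c(0, 9), y = 0, z = 0))
  expect_warning(perceive_bonds(lonely), "without bonds")
})

test_that("bond perception is invariant under rigid motion", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      m <- builtin_monomer_library()[[sample(9, 1)]]
      rot <- random_rotation_matrix()
      m2 <- saptfit:::transform_monomer(m, rot, rnorm(3, 0, 5))
      m2$bonds <- NULL
      m2 <- perceive_bonds(m2)
      expect_identical(m2$bonds, m$bonds)
    }
  })
})

test_that("atom typing follows element and coordination", {
  lib <- builtin_monomer_library()
  types <- lapply(lib, function(m) sort(m$atoms$type))
  names(types) <- vapply(lib, function(m) m$name, "")
  expect_equal(types$methane, sort(c("C4", rep("HC", 4))))
  expect_equal(types$formamide, sort(c("C3", "O1", "N3", "HN", "HN", "HC")))
  expect_equal(types$methanol, sort(c("C4", "O2", "HO", rep("HC", 3))))

  # O with three neighbors is outside the enumeration
  bad <- sapt_monomer(
    tibble::tibble(element = c("O", "H", "H", "H"),
                   x = c(0, 0.96, -0.48, -0.48),
                   y = c(0, 0, 0.83, -0.83), z = 0))
  expect_error(assign_atom_types(bad), class = "saptfit_typing_error")

  # carbon with a single neighbor likewise
  co <- sapt_monomer(tibble::tibble(element = c("C", "O"),
                                    x = c(0, 1.13), y = 0, z = 0))
  expect_error(assign_atom_types(co), class = "saptfit_typing_error")
})

test_that("XYZ I/O round-trips and rejects malformed input", {
  d <- fx_dimer()
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(d, path)
  back <- read_dimer_xyz(path)
  expect_equal(nrow(back$a$atoms), nrow(d$a$atoms))
  expect_equal(as.matrix(back$b$atoms[, c("x", "y", "z")]),
               as.matrix(d$b$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)

  # multi-frame order is preserved
  m1 <- builtin_monomer_library()[[1]]
  m2 <- builtin_monomer_library()[[4]]
  write_xyz(list(list(comment = "first", atoms = m1$atoms),
                 list(comment = "second", atoms = m2$atoms)), path)
  frames <- read_xyz(path)
  expect_length(frames, 2)
  expect_equal(frames[[1]]$comment, "first")
  expect_equal(nrow(frames[[2]]$atoms), 4)

  writeLines(c("3", "truncated", "C 0 0 0", "H 1 0 0"), path)
  expect_error(read_xyz(path), class = "saptfit_parse_error")
  writeLines(c("1", "bad element", "Xx 0 0 0"), path)
  expect_error(read_xyz(path), class = "saptfit_parse_error")
  writeLines(c("2", "no split marker", "C 0 0 0", "C 4 0 0"), path)
  expect_error(read_dimer_xyz(path), class = "saptfit_parse_error")
})

test_that("property sidecars validate and round-trip", {
  m <- fx_monomer("methane")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_properties(m$properties, path, name = m$name)
  back <- read_properties(path, n_atoms = 5)
  expect_equal(as.data.frame(back), as.data.frame(m$properties),
               tolerance = 1e-12)

  bad <- m$properties
  bad$qxx[1] <- bad$qxx[1] + 0.1            # breaks tracelessness
  expect_error(validate_properties(bad), class = "saptfit_properties_error")
  bad <- m$properties
  bad$sigma[2] <- -1
  expect_error(validate_properties(bad), class = "saptfit_properties_error")
  expect_error(read_properties(path, n_atoms = 4),
               class = "saptfit_properties_error")
})

test_that("parameter tables carry the published values and round-trip exactly", {
  base <- default_parameters("base")
  expect_equal(base$kelst[base$type == "HC"], 3.644)
  aug <- default_parameters("augmented")
  expect_equal(aug$kelst[aug$type == "O2"], 5.115)

  withr::with_seed(3, {
    p <- uniform_parameters()
    p$kelst <- exp(rnorm(9)); p$kexch <- exp(rnorm(9))
    p$kindu <- exp(rnorm(9)); p$kdisp <- exp(rnorm(9))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_parameters(p, path)
    expect_identical(read_parameters(path), validate_parameters(p))
  })

  expect_error(validate_parameters(base[base$type != "N3", ]),
               class = "saptfit_parameters_error")
  neg <- base; neg$kexch[3] <- -0.1
  expect_error(validate_parameters(neg), class = "saptfit_parameters_error")
})
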