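fake_components <- function(mat) {
  tibble::tibble(name = paste0("d", seq_len(nrow(mat))),
                 elst = mat[, 1], exch = mat[, 2], indu = mat[, 3],
                 disp = mat[, 4], total = rowSums(mat[, 1:4, drop = FALSE]))
}

test_that("error report reproduces hand-computed MAE and RMSE", {
  ref <- fake_components(matrix(0, 3, 4))
  pred <- ref
  pred$total <- c(1, -1, 2)                 # residuals {1, -1, 2}
  rep <- error_report(pred, ref)
  expect_equal(rep$mae[rep$component == "total"], 4 / 3)
  expect_equal(rep$rmse[rep$component == "total"], sqrt(2))
  expect_equal(rep$n, rep(3, 5))

  # zero residuals and the single-residual identity
  expect_true(all(error_report(ref, ref)[, c("mae", "rmse")] == 0))
  one <- error_report(fake_components(matrix(-0.7, 1, 4)),
                      fake_components(matrix(0, 1, 4)))
  expect_equal(one$mae[one$component == "elst"], 0.7)
  expect_equal(one$rmse[one$component == "elst"], 0.7)

  expect_error(error_report(pred, ref[1:2, ]),
               class = "saptfit_evaluation_error")
})

test_that("RMSE dominates MAE on random residuals", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      pred <- fake_components(matrix(rnorm(40), 10, 4))
      refs <- fake_components(matrix(rnorm(40), 10, 4))
      er <- error_report(pred, refs)
      expect_true(all(er$rmse >= er$mae - 1e-12))
    }
  })
})

test_that("correlation table is long, complete and correctly flagged", {
  pred <- fake_components(matrix(rnorm(12), 3, 4))
  tab <- correlation_table(pred, pred, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(tab), 15)               # 3 dimers x 5 energy fields
  expect_true(all(tab$reference == tab$predicted))
  expect_equal(sum(tab$hbond), 5)

  # flag rule: alkane-alkane is never hydrogen-bonded, acid-bearing is
  d_alk <- generate_dimer_configs(fx_monomer("methane"),
                                  fx_monomer("ethane"), 1, fx_config())[[1]]
  expect_false(is_hbonded(d_alk))
  d_acid <- generate_dimer_configs(fx_monomer("formic_acid"),
                                   fx_monomer("methane"), 1, fx_config())[[1]]
  expect_true(is_hbonded(d_acid))
})

test_that("center-of-mass scan preserves the input geometry at factor 1
           and decays at long range", {
  d <- fx_dimer()
  params <- default_parameters("base")
  sc <- com_scan(d, params, grid = c(0.9, 1.0, 1.3, 4, 8))
  expect_equal(sc$total[2], sapt_energy(d, params)$total, tolerance = 1e-10)
  expect_lt(abs(sc$total[5]), 0.05)
  expect_true(all(diff(sc$separation) > 0))
  expect_true(all(is.finite(sc$total)))
})

test_that("scan equilibrium is stable under monomer relabeling", {
  d <- fx_dimer()
  params <- default_parameters("base")
  grid <- seq(0.7, 2.4, by = 0.05)
  sc1 <- suppressWarnings(com_scan(d, params, grid = grid))
  dsw <- d; dsw$a <- d$b; dsw$b <- d$a
  sc2 <- suppressWarnings(com_scan(dsw, params, grid = grid))
  expect_equal(sc1$total, sc2$total, tolerance = 1e-8)
  expect_equal(attr(sc1, "equilibrium"), attr(sc2, "equilibrium"),
               tolerance = 1e-6)
})

test_that("close-approach scan points are flagged but still evaluated", {
  # two single-atom monomers 0.3 bohr apart: factor 1 is inside the 0.5 bohr
  # contact floor, the stretched points are not
  d <- two_site_dimer(1, -1, c(0, 0, 0), matrix(0, 3, 3), c(0, 0, 0),
                      1, -1, c(0.1, 0, 0), matrix(0, 3, 3),
                      c(0.3, 0, 0), alpha = 2)
  sc <- suppressWarnings(
    com_scan(d, default_parameters("base"), grid = c(1, 3, 10)))
  expect_equal(sc$flagged, c(TRUE, FALSE, FALSE))
  expect_true(all(is.finite(sc$total)))
})
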