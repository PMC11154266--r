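#' Greedy training-set augmentation
#'
#' Alternates fitting and screening: fit on the current training set, predict
#' every pool dimer's total energy, and while any pool error exceeds
#' `threshold` move the smallest offending dimer (fewest atoms, ties broken
#' by name) from the pool into the training set and refit. Refits are
#' warm-started from the previous parameters by default. Terminates when all
#' pool errors are within the threshold or the pool is exhausted.
#'
#' @param train,pool Dataset tibbles with `dimer` list-columns; all dimers
#'   need reference components.
#' @param threshold Total-energy error tolerance, kcal/mol (default 1,
#'   the chemical-accuracy target).
#' @param params_init Initial parameter table for the first fit.
#' @param gamma Loss partition parameter.
#' @param warm_start Start each refit from the previous fit's parameters.
#' @param config An [induction_config()].
#' @param ... Passed on to [fit_global_parameters()].
#' @return List with elements `train` (augmented manifest), `fit` (final
#'   [fit_global_parameters()] result), and `history` (tibble: one row per
#'   outer iteration with the added dimer and the worst pool error).
#' @export
augment_training_set <- function(train, pool, threshold = 1.0,
                                 params_init = uniform_parameters(),
                                 gamma = 0.4, warm_start = TRUE,
                                 config = induction_config(), ...) {
  stopifnot(threshold > 0)
  history <- list()
  params <- params_init
  repeat {
    fit <- fit_global_parameters(train, params_init = params, gamma = gamma,
                                 config = config, ...)
    if (warm_start) params <- fit$parameters
    if (nrow(pool) == 0) {
      history[[length(history) + 1]] <- tibble::tibble(
        added = NA_character_, max_pool_error = NA_real_,
        n_train = nrow(train))
      break
    }
    pred <- predict_sapt(pool, fit$parameters, config)
    refs <- reference_components(pool)
    err <- abs(pred$total - refs$total)
    history[[length(history) + 1]] <- tibble::tibble(
      added = NA_character_, max_pool_error = max(err),
      n_train = nrow(train))
    failing <- which(err > threshold)
    if (length(failing) == 0) break
    natoms <- vapply(pool$dimer[failing], function(d)
      nrow(d$a$atoms) + nrow(d$b$atoms), 1L)
    pick <- failing[order(natoms, pool$name[failing])][1]
    history[[length(history)]]$added <- pool$name[pick]
    train <- dplyr::bind_rows(train, pool[pick, ])
    pool <- pool[-pick, ]
  }
  list(train = train, fit = fit, history = dplyr::bind_rows(history))
}
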