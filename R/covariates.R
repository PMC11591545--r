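#' Stepwise covariate search
#'
#' Forward inclusion followed by backward elimination of power-model
#' covariate effects on the free structural parameters. Candidate effects
#' enter as `theta * (cov / median(cov))^beta` (linear in `beta` on the log
#' scale). A candidate is added when it reduces the importance-sampling OFV
#' by more than `forward` (3.84, chi-squared 1 df at p < 0.05) and survives
#' elimination only if its removal worsens the OFV by more than `backward`
#' (6.63, p < 0.01). The full decision trace is returned.
#'
#' All OFVs are computed with the same Monte Carlo seed so that model
#' comparisons share their random draws.
#'
#' @param data the analysis dataset
#' @param spec base [model_spec()] (its `covariates` should be empty)
#' @param candidates covariate column names to test
#' @param on structural parameters eligible for effects (default: all free)
#' @param forward,backward OFV improvement thresholds
#' @param control a [saem_control()]
#' @param seed integer seed
#' @param n_mc Monte Carlo size of the OFV used for the comparisons
#' @param init initial values, as in [fit_popmodel()]
#' @return list of class `covariate_search`: `final_fit`, `selected`
#'   (tibble of retained param/covariate pairs with coefficients), `trace`
#'   (every tested step with OFVs and decisions)
#' @export
covariate_search <- function(data, spec = model_spec(),
                             candidates = c("WT", "BSA", "AGE", "CRCL", "ALB"),
                             on = NULL, forward = 3.84, backward = 6.63,
                             control = saem_control(), seed = 1L,
                             n_mc = 2000L, init = default_init(spec)) {
  data <- validate_pkdata(data)
  on <- on %||% spec$free
  for (cv in candidates) {
    if (!cv %in% names(data)) abort(sprintf("Covariate %s not in the dataset.", cv))
    per_sub <- data[[cv]][match(unique(data$ID), data$ID)]
    if (anyNA(per_sub)) {
      abort(sprintf("Covariate %s missing for subjects: %s", cv,
                    paste(unique(data$ID)[is.na(per_sub)], collapse = ", ")))
    }
  }

  fit_with <- function(cov_list) {
    sp <- spec
    sp$covariates <- cov_list
    ft <- suppressWarnings(fit_popmodel(data, sp, init = init,
                                        control = control, seed = seed))
    # common-seed OFV for comparability across models
    ft$ofv_cmp <- log_likelihood(ft, n_mc = n_mc, seed = derive_seed(seed, "cmp"))$ofv
    ft
  }

  current <- list()
  base_fit <- fit_with(current)
  best_ofv <- base_fit$ofv_cmp
  trace <- list()
  step <- 0L

  pairs_all <- tidyr::expand_grid(param = on, cov = candidates)
  in_model <- function(pm, cv) {
    !is.null(current[[pm]]) && cv %in% current[[pm]]
  }

  repeat { # forward
    step <- step + 1L
    cand_rows <- dplyr::filter(pairs_all,
                               !purrr::map2_lgl(.data$param, .data$cov, in_model))
    if (nrow(cand_rows) == 0L) break
    ofvs <- numeric(nrow(cand_rows))
    for (r in seq_len(nrow(cand_rows))) {
      trial <- current
      pm <- cand_rows$param[r]; cv <- cand_rows$cov[r]
      trial[[pm]] <- c(trial[[pm]], cv)
      ofvs[r] <- fit_with(trial)$ofv_cmp
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = step, phase = "forward", param = pm, covariate = cv,
        ofv = ofvs[r], delta = best_ofv - ofvs[r],
        action = "tested")
    }
    gain <- best_ofv - ofvs
    if (max(gain) > forward) {
      r <- which.max(gain)
      pm <- cand_rows$param[r]; cv <- cand_rows$cov[r]
      current[[pm]] <- c(current[[pm]], cv)
      best_ofv <- ofvs[r]
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = step, phase = "forward", param = pm, covariate = cv,
        ofv = ofvs[r], delta = gain[r], action = "added")
    } else break
  }

  repeat { # backward
    included <- purrr::imap_dfr(current, function(cvs, pm) {
      tibble::tibble(param = pm, cov = cvs)
    })
    if (nrow(included) == 0L) break
    step <- step + 1L
    worsens <- numeric(nrow(included))
    for (r in seq_len(nrow(included))) {
      trial <- current
      pm <- included$param[r]; cv <- included$cov[r]
      trial[[pm]] <- setdiff(trial[[pm]], cv)
      if (length(trial[[pm]]) == 0L) trial[[pm]] <- NULL
      ofv_r <- fit_with(trial)$ofv_cmp
      worsens[r] <- ofv_r - best_ofv
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = step, phase = "backward", param = pm, covariate = cv,
        ofv = ofv_r, delta = worsens[r], action = "tested")
    }
    if (min(worsens) < backward) {
      r <- which.min(worsens)
      pm <- included$param[r]; cv <- included$cov[r]
      current[[pm]] <- setdiff(current[[pm]], cv)
      if (length(current[[pm]]) == 0L) current[[pm]] <- NULL
      best_ofv <- best_ofv + worsens[r]
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = step, phase = "backward", param = pm, covariate = cv,
        ofv = best_ofv, delta = worsens[r], action = "removed")
    } else break
  }

  final_fit <- if (length(current)) fit_with(current) else base_fit
  selected <- if (length(final_fit$beta)) {
    dplyr::bind_rows(purrr::imap(final_fit$beta, function(b, pm) {
      tibble::tibble(param = pm, covariate = names(b), beta = as.numeric(b))
    }))
  } else {
    tibble::tibble(param = character(), covariate = character(),
                   beta = numeric())
  }
  structure(list(final_fit = final_fit, selected = selected,
                 trace = dplyr::bind_rows(trace), base_ofv = base_fit$ofv_cmp),
            class = "covariate_search")
}

#' @export
print.covariate_search <- function(x, ...) {
  cat("<covariate_search> forward/backward stepwise power-model selection\n")
  if (nrow(x$selected) == 0L) {
    cat("  no covariate retained\n")
  } else {
    print(x$selected, n = Inf)
  }
  invisible(x)
}
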