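# MEDRAS-like stochastic rejoining of DSB free ends over a fixed repair
# window. Every DSB contributes two co-located free ends. Ends fire with a
# class-dependent kinetic rate (fast for simple breaks, slow for complex);
# a firing end picks a partner among the currently free ends with weight
# exp(-d^2 / (2 sigma^2)) in end separation d, the original partner
# included (at d = 0, weight 1). Joining the original partner restitutes
# the break; any other joint is a misrepair. Ends still free at the end of
# the window are residual, as are breaks drawn as outright unrepairable.
# Implemented as an exact Gillespie event loop.

#' Repair-kinetics parameters
#'
#' Interaction rates of free DSB ends and the repair window follow the
#' repair model underlying the analysis (fast rate 2.07 per hour, slow rate
#' 0.259 per hour, 24 h). The wrong-end pairing scale and the probability
#' that a complex break is outright unrepairable are surrogate calibration
#' parameters (see the methods vignette).
#'
#' @param lambda_fast Rejoining rate of simple-break ends (per hour).
#' @param lambda_slow Rejoining rate of complex-break ends (per hour).
#' @param repair_time Repair window (hours).
#' @param misjoin_sigma Gaussian distance scale of wrong-end pairing (um).
#' @param complex_unrepaired_prob Probability a complex break never
#'   restitutes (stays residual).
#' @param repetitions Repair repetitions per damage pattern used by
#'   [mean_post_repair()].
#' @return List of class `repair_params`.
#' @export
repair_params <- function(lambda_fast = 2.07, lambda_slow = 0.259,
                          repair_time = 24, misjoin_sigma = 0.25,
                          complex_unrepaired_prob = 0.60,
                          repetitions = 10L) {
  stopifnot(lambda_fast > 0, lambda_slow > 0, repair_time > 0,
            misjoin_sigma >= 0, complex_unrepaired_prob >= 0,
            complex_unrepaired_prob <= 1, repetitions >= 1)
  structure(list(lambda_fast = lambda_fast, lambda_slow = lambda_slow,
                 repair_time = repair_time, misjoin_sigma = misjoin_sigma,
                 complex_unrepaired_prob = complex_unrepaired_prob,
                 repetitions = as.integer(repetitions)),
            class = "repair_params")
}

#' Simulate repair of one damage pattern
#'
#' Gillespie event loop over the free DSB ends of a damage record. Each end
#' of an eligible break fires at half its class rate, so an isolated break
#' restitutes at the full class rate (survival exp(-lambda t)). A break is
#' counted misrepaired when both its ends are joined and at least one joint
#' is to a wrong partner; breaks with a free end at the end of the window,
#' and unrepairable complex breaks, are residual. Post-repair damage is
#' misrepaired plus residual.
#'
#' @param damage A `damage_record`.
#' @param params A `repair_params` list.
#' @param rng_seed Optional integer seed.
#' @return List of class `repair_outcome` with counts `n_initial`,
#'   `n_correct`, `n_misrepaired`, `n_residual`, `n_post`.
#' @export
repair_run <- function(damage, params = repair_params(), rng_seed = NULL) {
  stopifnot(inherits(damage, "damage_record"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(damage$dsbs)
  if (n == 0L) {
    return(new_repair_outcome(0L, 0L, 0L, 0L))
  }
  pos <- as.matrix(damage$dsbs[, c("x", "y", "z")])
  complex <- damage$dsbs$complexity == "complex"
  unrepairable <- complex & stats::runif(n) < params$complex_unrepaired_prob

  # two co-located ends per break; ends 2i-1, 2i belong to break i
  end_break <- rep(seq_len(n), each = 2)
  end_rate <- ifelse(complex[end_break], params$lambda_slow,
                     params$lambda_fast) / 2
  free <- !unrepairable[end_break]   # ends of unrepairable breaks never join
  joined_to <- rep(NA_integer_, 2L * n)

  sigma2 <- 2 * params$misjoin_sigma^2
  t <- 0
  repeat {
    free_idx <- which(free)
    if (length(free_idx) < 2L) break
    total_rate <- sum(end_rate[free_idx])
    t <- t + stats::rexp(1, total_rate)
    if (t > params$repair_time) break
    i <- free_idx[sample.int(length(free_idx), 1L,
                             prob = end_rate[free_idx])]
    others <- free_idx[free_idx != i]
    d2 <- rowSums((pos[end_break[others], , drop = FALSE] -
                     matrix(pos[end_break[i], ], length(others), 3,
                            byrow = TRUE))^2)
    w <- if (sigma2 > 0) exp(-d2 / sigma2) else as.numeric(d2 == 0)
    # the original partner is co-located (d = 0, weight 1)
    if (all(w <= 0)) next   # no reachable partner; time still advances
    j <- others[sample.int(length(others), 1L, prob = w)]
    joined_to[i] <- j
    joined_to[j] <- i
    free[c(i, j)] <- FALSE
  }

  ends_of <- function(b) c(2L * b - 1L, 2L * b)
  correct <- mis <- resid <- 0L
  for (b in seq_len(n)) {
    e <- ends_of(b)
    if (unrepairable[b] || any(free[e])) {
      resid <- resid + 1L
    } else if (identical(joined_to[e[1]], e[2])) {
      correct <- correct + 1L
    } else {
      mis <- mis + 1L
    }
  }
  new_repair_outcome(n, correct, mis, resid)
}

new_repair_outcome <- function(n_initial, n_correct, n_mis, n_resid) {
  stopifnot(n_correct + n_mis + n_resid == n_initial)
  structure(list(n_initial = n_initial, n_correct = n_correct,
                 n_misrepaired = n_mis, n_residual = n_resid,
                 n_post = n_mis + n_resid),
            class = "repair_outcome")
}

#' @export
print.repair_outcome <- function(x, ...) {
  cat("Repair outcome: ", x$n_initial, " initial -> ", x$n_correct,
      " correct, ", x$n_misrepaired, " misrepaired, ", x$n_residual,
      " residual (post-repair ", x$n_post, ")\n", sep = "")
  invisible(x)
}

#' Mean post-repair damage over repeated repair simulations
#'
#' Repeats [repair_run()] on the same damage pattern with derived seeds and
#' returns the mean and sample SD of the post-repair DSB count; this pair
#' is one dose-effect data point with its error bar.
#'
#' @param damage A `damage_record`.
#' @param params A `repair_params` list (`repetitions` controls the number
#'   of repeats).
#' @param rng_seed Integer seed from which per-repetition seeds are
#'   derived.
#' @return List with `mean`, `sd`, and the vector of `n_post` values.
#' @export
mean_post_repair <- function(damage, params = repair_params(), rng_seed = 1L) {
  reps <- params$repetitions
  n_post <- vapply(seq_len(reps), function(r) {
    repair_run(damage, params, rng_seed = derive_seed(rng_seed, "repair", r))$n_post
  }, numeric(1))
  list(mean = mean(n_post), sd = if (reps >= 2) stats::sd(n_post) else 0,
       n_post = n_post)
}
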