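## Synthetic GFP flow-cytometry assays.
##
## Two experimental designs are emulated: (i) a bulk time course in which a
## preselected population (all cells carrying one expressing mini-chromosome)
## is cultured for weeks and the GFP-negative / single / double fractions are
## read at sampled days; (ii) a limiting-dilution clone assay in which many
## single founding cells are each expanded for a fixed number of days and the
## per-clone GFP-negative fraction is recorded. Populations are tracked as
## class counts, not per-cell agents, so 2^21-cell clones stay cheap.

#' Simulate a bulk GFP time course
#'
#' Propagates a population of carrying cells through `divisions_per_day`
#' generations per day under the segregation model, recording the flow
#' fractions at the sampled days. Between daily passages the population is
#' subsampled without replacement (multivariate hypergeometric) to at most
#' `max_cells`, mirroring daily dilution of the culture.
#'
#' @param params A [segregation_params()].
#' @param days Total culture length in days.
#' @param sample_days Days at which flow fractions are recorded (day 0 is the
#'   preselected starting population).
#' @param initial_cells Founding population size (all cells `(1, 1)`).
#' @param max_cells Passage cap on the tracked population.
#' @param seed Optional RNG seed.
#' @return A data frame (class `flow_timecourse`) with columns `day`,
#'   `fraction_gfp_negative`, `fraction_gfp_single`,
#'   `fraction_gfp_double_or_more`, `n_cells`.
#' @examples
#' tc <- simulate_flow_timecourse(segregation_params(p_lag_loss = 0.004),
#'                                days = 10, sample_days = c(0, 5, 10),
#'                                initial_cells = 1e4, seed = 1)
#' @export
simulate_flow_timecourse <- function(params, days = 25,
                                     sample_days = seq(0, days, by = 5),
                                     initial_cells = 1e5, max_cells = 1e6,
                                     seed = NULL) {
  stopifnot(inherits(params, "segregation_params"), days >= 0,
            all(sample_days >= 0 & sample_days <= days), initial_cells >= 1)
  kernels <- build_division_kernels(params)
  with_seed(seed, {
    state <- population_state(initial_cells, 1, 1, k_max = params$k_max)
    rows <- list()
    record <- function(day, state) {
      fr <- classify_gfp(state)
      fr$day <- day
      fr$n_cells <- state_total(state)
      rows[[length(rows) + 1]] <<- fr
    }
    if (0 %in% sample_days) record(0, state)
    for (day in seq_len(days)) {
      for (g in seq_len(params$divisions_per_day)) {
        state <- propagate_generation_stochastic(state, params, kernels)
      }
      if (state_total(state) > max_cells) {
        kept <- rmvhyper(as.numeric(state), max_cells)
        state <- structure(matrix(kept, nrow(state), ncol(state),
                                  dimnames = dimnames(state)),
                           class = c("population_state", "matrix"))
      }
      if (day %in% sample_days) record(day, state)
    }
    out <- do.call(rbind, rows)
    out <- out[, c("day", "fraction_gfp_negative", "fraction_gfp_single",
                   "fraction_gfp_double_or_more", "n_cells")]
    class(out) <- c("flow_timecourse", "data.frame")
    out
  })
}

#' Simulate a limiting-dilution clone assay
#'
#' Expands `n_clones` clones, each from a single cell carrying one expressing
#' mini-chromosome, for `divisions_per_day * duration_days` generations, and
#' reports the per-clone GFP-negative (and double-GFP) fractions.
#'
#' @param params A [segregation_params()].
#' @param n_clones Number of clones (>= 1).
#' @param duration_days Days of expansion before flow analysis (default 7).
#' @param seed Optional RNG seed.
#' @return A data frame (class `clone_assay`) with columns `clone_id`,
#'   `gfp_negative_fraction`, `gfp_double_fraction`; attributes
#'   `duration_days` and `divisions_per_day`.
#' @examples
#' ca <- simulate_clone_assay(segregation_params(p_lag_loss = 0.00286),
#'                            n_clones = 50, seed = 1)
#' stats::median(ca$gfp_negative_fraction)
#' @export
simulate_clone_assay <- function(params, n_clones, duration_days = 7,
                                 seed = NULL) {
  stopifnot(inherits(params, "segregation_params"), is_count(n_clones),
            n_clones >= 1, duration_days >= 0)
  n_gen <- num_divisions(duration_days, params$divisions_per_day)
  kernels <- build_division_kernels(params)
  with_seed(seed, {
    neg <- numeric(n_clones); dbl <- numeric(n_clones)
    for (i in seq_len(n_clones)) {
      state <- population_state(1, 1, 1, k_max = params$k_max)
      for (g in seq_len(n_gen)) {
        state <- propagate_generation_stochastic(state, params, kernels)
      }
      fr <- classify_gfp(state)
      neg[i] <- fr$fraction_gfp_negative
      dbl[i] <- fr$fraction_gfp_double_or_more
    }
    out <- data.frame(clone_id = sprintf("clone_%04d", seq_len(n_clones)),
                      gfp_negative_fraction = neg,
                      gfp_double_fraction = dbl)
    attr(out, "duration_days") <- duration_days
    attr(out, "divisions_per_day") <- params$divisions_per_day
    class(out) <- c("clone_assay", "data.frame")
    out
  })
}
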