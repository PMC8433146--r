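## Branching-process model of mini-chromosome inheritance.
##
## Each cell division replicates every mini-chromosome copy into two sister
## chromatids which then segregate independently of other copies:
##
##   faithful       (prob 1 - p_ns - p_ll): one chromatid to each daughter
##   nondisjunction (prob p_ns):            both chromatids to one daughter
##                                          (chosen uniformly), producing a
##                                          double-copy and a null daughter
##   anaphase lag   (prob p_ll):            one chromatid lost; one daughter
##                                          (chosen uniformly) inherits one
##
## GFP expression status is carried by the chromatids; after segregation each
## expressing copy is silenced permanently with probability p_silence. For a
## one-copy mother the probability that a given daughter fails to inherit the
## chromosome is (p_ns + p_ll)/2 — the per-division loss rate r of the
## retention model f_n = f_0 (1 - r)^n.

#' Segregation model parameters
#'
#' @param p_nondisjunction Per-copy per-division probability that both sister
#'   chromatids segregate to the same daughter (source of double-GFP cells).
#' @param p_lag_loss Per-copy per-division probability that one chromatid is
#'   lost (anaphase lag): one daughter inherits a single copy, the other none.
#' @param p_silence Per-expressing-copy per-division probability of permanent
#'   GFP silencing (the chromosome is retained but scores GFP-negative).
#' @param divisions_per_day Cell divisions per day; DT40 cells divide three
#'   times per day.
#' @param k_max Largest per-cell copy number tracked; higher states are
#'   truncated (with a warning) to keep the state space finite.
#' @return An object of class `segregation_params`.
#' @examples
#' segregation_params(p_lag_loss = 0.004)          # r_eff = 0.002
#' effective_loss_rate(segregation_params(0.002, 0.002))
#' @export
segregation_params <- function(p_nondisjunction = 0, p_lag_loss = 0,
                               p_silence = 0, divisions_per_day = 3L,
                               k_max = 4L) {
  stopifnot(is_prob(p_nondisjunction), is_prob(p_lag_loss), is_prob(p_silence))
  if (p_nondisjunction + p_lag_loss > 1)
    stop("p_nondisjunction + p_lag_loss must be <= 1")
  if (!is_count(divisions_per_day) || divisions_per_day < 1)
    stop("divisions_per_day must be a positive integer")
  if (!is_count(k_max) || k_max < 1) stop("k_max must be a positive integer")
  structure(list(p_nondisjunction = p_nondisjunction, p_lag_loss = p_lag_loss,
                 p_silence = p_silence,
                 divisions_per_day = as.integer(divisions_per_day),
                 k_max = as.integer(k_max)),
            class = "segregation_params")
}

#' Effective per-division loss rate implied by the mechanistic parameters
#'
#' The per-daughter probability of not inheriting the chromosome from a
#' one-copy mother: `(p_nondisjunction + p_lag_loss) / 2`. This is the
#' quantity the retention model estimates as `r`.
#'
#' @param params A `segregation_params`.
#' @return Numeric scalar in \[0, 1\].
#' @export
effective_loss_rate <- function(params) {
  (params$p_nondisjunction + params$p_lag_loss) / 2
}

#' Expected retained fraction after n divisions
#'
#' Evaluates the retention model `f_n = f_0 (1 - r)^n`, where `r` is the
#' per-division loss rate and `f_0` the initial retaining fraction (1 when
#' the culture starts from a single carrying cell).
#'
#' @param r_eff Per-division loss rate in \[0, 1\].
#' @param n Number of divisions (>= 0).
#' @param f0 Initial retaining fraction in (0, 1\].
#' @return Expected fraction of cells retaining the chromosome.
#' @examples
#' expected_retention(0.00143, 21)   # ~0.9704, i.e. ~2.96% negative
#' @export
expected_retention <- function(r_eff, n, f0 = 1) {
  stopifnot(all(r_eff >= 0 & r_eff <= 1), all(n >= 0), f0 > 0, f0 <= 1)
  f0 * (1 - r_eff)^n
}

## ---- population state ------------------------------------------------------

#' Construct a population state
#'
#' Cell counts indexed by (copies, expressing copies), `0 <= expressing <=
#' copies <= k_max`. The default is a pure population of single-copy,
#' expressing cells — the state after puromycin preselection or at the root
#' of a limiting-dilution clone.
#'
#' @param n_cells Number of cells placed in class `(copies, expressing)`.
#' @param copies,expressing Class of the founding cells.
#' @param k_max Copy-number cap of the state space.
#' @return An object of class `population_state`: a `(k_max+1) x (k_max+1)`
#'   count matrix, rows = copies 0..k_max, cols = expressing 0..k_max.
#' @export
population_state <- function(n_cells = 1, copies = 1, expressing = copies,
                             k_max = 4L) {
  stopifnot(is_count(n_cells), n_cells >= 1, is_count(copies), is_count(expressing),
            expressing <= copies, copies <= k_max)
  counts <- matrix(0, nrow = k_max + 1, ncol = k_max + 1,
                   dimnames = list(copies = 0:k_max, expressing = 0:k_max))
  counts[copies + 1, expressing + 1] <- n_cells
  structure(counts, class = c("population_state", "matrix"))
}

validate_state <- function(state) {
  if (!inherits(state, "population_state")) stop("not a population_state")
  if (any(state < 0)) stop("negative cell counts")
  if (sum(state) <= 0) stop("empty population")
  k <- nrow(state) - 1
  bad <- which(state > 0, arr.ind = TRUE)
  if (any(bad[, 2] > bad[, 1])) stop("expressing copies exceed total copies")
  invisible(state)
}

state_total <- function(state) sum(state)

#' GFP class fractions of a population
#'
#' Maps the copy/expression state onto the three flow-cytometry gates:
#' GFP-negative (no expressing copy — includes silenced carriers),
#' single-GFP (one expressing copy) and double-or-more.
#'
#' @param state A `population_state`.
#' @return A one-row data frame with `fraction_gfp_negative`,
#'   `fraction_gfp_single`, `fraction_gfp_double_or_more`.
#' @export
classify_gfp <- function(state) {
  validate_state(state)
  tot <- sum(state)
  by_expr <- colSums(state)
  data.frame(
    fraction_gfp_negative = unname(by_expr[1] / tot),
    fraction_gfp_single = unname(by_expr[2] / tot),
    fraction_gfp_double_or_more = unname(sum(by_expr[-(1:2)]) / tot),
    row.names = NULL
  )
}

## ---- division kernel -------------------------------------------------------

## Exact daughter-pair distribution for a mother of class (copies, expressing).
## Enumerates the 5 segregation outcomes per copy (faithful, nondisjunction to
## daughter 1 or 2, lag with survivor in daughter 1 or 2), then convolves the
## independent per-daughter silencing thinning. Returns a data frame with
## daughter classes (c1, e1, c2, e2) and probabilities summing to 1.
## States above k_max are truncated (copies capped, expressing capped at the
## capped copy number).
division_kernel_class <- function(copies, expressing, params) {
  p_ns <- params$p_nondisjunction
  p_ll <- params$p_lag_loss
  p_f <- 1 - p_ns - p_ll
  if (copies == 0) {
    return(data.frame(c1 = 0, e1 = 0, c2 = 0, e2 = 0, prob = 1))
  }
  ## per-copy outcomes: (to daughter1, to daughter2, prob)
  out_d1 <- c(1, 2, 0, 1, 0)
  out_d2 <- c(1, 0, 2, 0, 1)
  out_p <- c(p_f, p_ns / 2, p_ns / 2, p_ll / 2, p_ll / 2)
  keep <- out_p > 0
  out_d1 <- out_d1[keep]; out_d2 <- out_d2[keep]; out_p <- out_p[keep]
  grid <- expand.grid(rep(list(seq_along(out_p)), copies))
  expr_flags <- c(rep(TRUE, expressing), rep(FALSE, copies - expressing))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    idx <- as.integer(grid[i, ])
    p <- prod(out_p[idx])
    d1 <- out_d1[idx]; d2 <- out_d2[idx]
    c(c1 = sum(d1), e1 = sum(d1[expr_flags]),
      c2 = sum(d2), e2 = sum(d2[expr_flags]), prob = p)
  })
  kern <- as.data.frame(do.call(rbind, rows))
  ## silencing: each expressing chromatid in each daughter silenced w.p. p_s
  p_s <- params$p_silence
  if (p_s > 0) {
    expanded <- lapply(seq_len(nrow(kern)), function(i) {
      r <- kern[i, ]
      e1s <- 0:r$e1; e2s <- 0:r$e2
      g <- expand.grid(e1 = e1s, e2 = e2s)
      g$c1 <- r$c1; g$c2 <- r$c2
      g$prob <- r$prob *
        stats::dbinom(g$e1, r$e1, 1 - p_s) *
        stats::dbinom(g$e2, r$e2, 1 - p_s)
      g[, c("c1", "e1", "c2", "e2", "prob")]
    })
    kern <- do.call(rbind, expanded)
  }
  ## truncate above k_max
  k <- params$k_max
  over <- kern$c1 > k | kern$c2 > k
  if (any(over)) {
    kern$e1 <- pmin(kern$e1, pmin(kern$c1, k))
    kern$e2 <- pmin(kern$e2, pmin(kern$c2, k))
    kern$c1 <- pmin(kern$c1, k)
    kern$c2 <- pmin(kern$c2, k)
    attr(kern, "truncated") <- TRUE
  }
  ## aggregate identical daughter pairs
  key <- paste(kern$c1, kern$e1, kern$c2, kern$e2)
  agg <- rowsum(kern$prob, key)
  parts <- do.call(rbind, strsplit(rownames(agg), " "))
  out <- data.frame(c1 = as.integer(parts[, 1]), e1 = as.integer(parts[, 2]),
                    c2 = as.integer(parts[, 3]), e2 = as.integer(parts[, 4]),
                    prob = as.numeric(agg))
  attr(out, "truncated") <- isTRUE(attr(kern, "truncated"))
  out
}

#' Precompute division kernels for every reachable class
#'
#' Exact daughter-pair distributions for all classes `(copies, expressing)`
#' with `copies <= k_max`, reusable across generations and clones.
#'
#' @param params A `segregation_params`.
#' @return Named list of kernel data frames (`c1`, `e1`, `c2`, `e2`, `prob`),
#'   keyed by `"copies expressing"`.
#' @export
build_division_kernels <- function(params) {
  k <- params$k_max
  kernels <- list()
  truncated <- FALSE
  for (cc in 0:k) for (ee in 0:cc) {
    kn <- division_kernel_class(cc, ee, params)
    truncated <- truncated || isTRUE(attr(kn, "truncated"))
    kernels[[paste(cc, ee)]] <- kn
  }
  if (truncated)
    message("note: copy numbers above k_max = ", k,
            " are truncated at the state-space cap")
  kernels
}

#' Simulate one cell division
#'
#' Draws the two daughter states of a single mother cell under the
#' segregation model.
#'
#' @param copies,expressing Mother state (`expressing <= copies`).
#' @param params A `segregation_params`.
#' @param kernels Optional precomputed [build_division_kernels()] output.
#' @return A 2x2 matrix: rows = daughters, columns = `copies`, `expressing`.
#' @export
sample_division <- function(copies, expressing, params, kernels = NULL) {
  stopifnot(is_count(copies), is_count(expressing), expressing <= copies)
  if (copies > params$k_max) stop("copies exceeds k_max")
  kern <- if (!is.null(kernels)) kernels[[paste(copies, expressing)]]
          else division_kernel_class(copies, expressing, params)
  i <- sample.int(nrow(kern), 1, prob = kern$prob)
  matrix(c(kern$c1[i], kern$e1[i], kern$c2[i], kern$e2[i]),
         nrow = 2, byrow = TRUE, dimnames = list(NULL, c("copies", "expressing")))
}

#' Propagate a population through one generation (stochastic)
#'
#' Every cell divides once; within each occupied class the mothers are
#' allocated to daughter-pair outcomes by a multinomial draw over the exact
#' division kernel. The total cell count doubles exactly (no cell death).
#'
#' @param state A `population_state`.
#' @param params A `segregation_params`.
#' @param kernels Optional precomputed [build_division_kernels()] output
#'   (reused across generations for speed).
#' @return The next-generation `population_state`.
#' @export
propagate_generation_stochastic <- function(state, params, kernels = NULL) {
  validate_state(state)
  if (is.null(kernels)) kernels <- build_division_kernels(params)
  k <- params$k_max
  if (nrow(state) != k + 1) stop("state k_max does not match params$k_max")
  nxt <- matrix(0, k + 1, k + 1, dimnames = dimnames(state))
  occ <- which(state > 0, arr.ind = TRUE)
  for (j in seq_len(nrow(occ))) {
    cc <- occ[j, 1] - 1; ee <- occ[j, 2] - 1
    n <- state[occ[j, 1], occ[j, 2]]
    kern <- kernels[[paste(cc, ee)]]
    if (n > 2^31 - 1)
      stop("class count exceeds the multinomial sampler's range; ",
           "cap the population (see simulate_flow_timecourse's max_cells)")
    if (nrow(kern) == 1) {
      draws <- n
    } else {
      draws <- as.numeric(stats::rmultinom(1, n, kern$prob))
    }
    for (i in which(draws > 0)) {
      nxt[kern$c1[i] + 1, kern$e1[i] + 1] <- nxt[kern$c1[i] + 1, kern$e1[i] + 1] + draws[i]
      nxt[kern$c2[i] + 1, kern$e2[i] + 1] <- nxt[kern$c2[i] + 1, kern$e2[i] + 1] + draws[i]
    }
  }
  structure(nxt, class = c("population_state", "matrix"))
}

#' Propagate class proportions through one generation (deterministic)
#'
#' Applies the exact one-generation transition in expectation: each mother
#' class contributes the marginal distribution of its two daughters. The
#' deterministic twin of [propagate_generation_stochastic()], used as its
#' convergence oracle.
#'
#' @param proportions A `(k_max+1) x (k_max+1)` matrix of class proportions
#'   summing to 1 (same indexing as `population_state`).
#' @param params A `segregation_params`.
#' @param kernels Optional precomputed kernels.
#' @return Matrix of next-generation expected proportions (sums to 1).
#' @export
propagate_generation_expected <- function(proportions, params, kernels = NULL) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0))
  if (is.null(kernels)) kernels <- build_division_kernels(params)
  k <- params$k_max
  nxt <- matrix(0, k + 1, k + 1, dimnames = dimnames(proportions))
  occ <- which(proportions > 0, arr.ind = TRUE)
  for (j in seq_len(nrow(occ))) {
    cc <- occ[j, 1] - 1; ee <- occ[j, 2] - 1
    p <- proportions[occ[j, 1], occ[j, 2]]
    kern <- kernels[[paste(cc, ee)]]
    for (i in seq_len(nrow(kern))) {
      w <- p * kern$prob[i] / 2  # each daughter is half the next generation
      nxt[kern$c1[i] + 1, kern$e1[i] + 1] <- nxt[kern$c1[i] + 1, kern$e1[i] + 1] + w
      nxt[kern$c2[i] + 1, kern$e2[i] + 1] <- nxt[kern$c2[i] + 1, kern$e2[i] + 1] + w
    }
  }
  nxt
}
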