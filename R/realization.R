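#' Sample quenched firing thresholds
#'
#' Thresholds are drawn i.i.d. from Normal(mean, width) and
#' rejection-resampled so that every value lies strictly above the reset
#' potential `V_r`: a threshold below reset would make the neuron fire
#' deterministically at every step and break the diffusion description.
#' At the widths used here (width <= 2.5 mV against a 10 mV reset-to-mean
#' gap) the rejected mass is below 3e-7, so the sampled distribution is
#' the stated Gaussian for every practical purpose.
#'
#' @param count Number of thresholds (>= 1).
#' @param mean Distribution centre (mV); must exceed `V_r`.
#' @param width Standard deviation (mV), non-negative.
#' @param V_r Reset potential (mV) used as the lower rejection bound.
#' @param seed Optional integer seed; if supplied, `set.seed` is called
#'   first so the draw is reproducible.
#' @return Numeric vector of `count` thresholds (mV).
#' @export
#' @examples
#' sample_thresholds(5, 20, 0)      # degenerate width: all exactly 20
#' sample_thresholds(8, 20, 2, seed = 1)
sample_thresholds <- function(count, mean, width, V_r = 10, seed = NULL) {
  stopifnot(count >= 1, width >= 0)
  if (mean <= V_r)
    stop("threshold distribution centre must lie above the reset potential")
  if (!is.null(seed)) set.seed(seed)
  th <- stats::rnorm(count, mean, width)
  bad <- which(th <= V_r)
  while (length(bad)) {
    th[bad] <- stats::rnorm(length(bad), mean, width)
    bad <- bad[th[bad] <= V_r]
  }
  th
}

#' Build a concrete network realization
#'
#' Samples one quenched instance of a [network_spec()]: per-neuron
#' thresholds (Gaussian per population, widths `w_E`, `w_I`) and a sparse
#' directed connectivity in which every ordered pair of distinct neurons
#' is connected independently with probability `eps`. Edge weights are
#' determined by the postsynaptic/presynaptic population labels. The
#' first `round(gamma*N)` indices are excitatory. Self-connections are
#' excluded.
#'
#' Thresholds and connectivity use separate RNG streams derived from
#' `seed`, so the same quenched network can later be re-simulated with
#' fresh noise.
#'
#' @param spec A `network_spec`.
#' @param seed Integer master seed for the realization.
#' @return A list of class `network_realization` with fields
#'   `thresholds` (numeric, mV), `population` (character, "E"/"I"),
#'   `connectivity` (a `dgCMatrix`, postsynaptic rows x presynaptic
#'   columns, entries in mV), `spec`, and `seed_record`.
#' @export
#' @examples
#' r <- build_realization(network_spec(structure = population_structure(N = 50)), seed = 1)
#' Matrix::nnzero(r$connectivity)
build_realization <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$structure$N
  n_e <- spec$structure$N_E
  pop <- rep(c("E", "I"), c(n_e, n - n_e))

  th <- numeric(n)
  set.seed(derive_seed(seed, 1L))
  th[seq_len(n_e)] <- sample_thresholds(n_e, spec$constants$theta_mean,
                                        spec$heterogeneity$w_E,
                                        V_r = spec$constants$V_r)
  if (n > n_e)
    th[(n_e + 1):n] <- sample_thresholds(n - n_e, spec$constants$theta_mean,
                                         spec$heterogeneity$w_I,
                                         V_r = spec$constants$V_r)

  set.seed(derive_seed(seed, 2L))
  eps <- spec$structure$eps
  post <- integer(0); pre <- integer(0)
  if (eps > 0) {
    # column by column (presynaptic j) keeps memory at O(N) per draw
    lst <- vector("list", n)
    for (j in seq_len(n)) {
      tgt <- which(stats::runif(n) < eps)
      tgt <- tgt[tgt != j]
      lst[[j]] <- tgt
    }
    post <- unlist(lst, use.names = FALSE)
    pre <- rep.int(seq_len(n), lengths(lst))
  }
  w <- weight_lookup(spec$weights, pop[post], pop[pre])
  conn <- Matrix::sparseMatrix(i = post, j = pre, x = w, dims = c(n, n))

  structure(list(thresholds = th, population = pop, connectivity = conn,
                 spec = spec, seed_record = as.integer(seed)),
            class = "network_realization")
}

weight_lookup <- function(weights, post_pop, pre_pop) {
  out <- numeric(length(post_pop))
  out[post_pop == "E" & pre_pop == "E"] <- weights$J_EE
  out[post_pop == "I" & pre_pop == "E"] <- weights$J_IE
  out[post_pop == "E" & pre_pop == "I"] <- weights$J_EI
  out[post_pop == "I" & pre_pop == "I"] <- weights$J_II
  out
}

#' @export
print.network_realization <- function(x, ...) {
  cat("<network_realization>\n")
  cat(sprintf("  N = %d (E %d / I %d), %d edges, seed %d\n",
              length(x$thresholds), sum(x$population == "E"),
              sum(x$population == "I"), Matrix::nnzero(x$connectivity),
              x$seed_record))
  cat(sprintf("  thresholds: mean %.3f mV, sd %.3f mV\n",
              mean(x$thresholds), stats::sd(x$thresholds)))
  invisible(x)
}

#' Per-neuron in-degrees of a realization
#'
#' @param realization A `network_realization`.
#' @return Integer vector of in-degrees (number of presynaptic partners).
#' @export
in_degrees <- function(realization) {
  m <- realization$connectivity
  as.integer(Matrix::rowSums(m != 0))
}
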