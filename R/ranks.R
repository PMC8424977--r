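# Rank statistics underlying the MaRR procedure.

#' Assign reproducibility ranks to abundance values
#'
#' Converts a vector of metabolite abundances (or any per-feature score)
#' into ranks, with rank 1 given to the *largest* value: highly abundant
#' signals are "highly ranked". Ties are broken by uniformly random
#' assignment among the tied positions, driven by a dedicated seed so the
#' result is deterministic given `(values, tie_seed)`; the ambient RNG
#' state of the session is left untouched.
#'
#' @param values Numeric vector of length M; must be finite with no
#'   missing values (the MaRR procedure assumes a complete matrix --
#'   impute first, see [impute_knn()]).
#' @param tie_seed Integer seed used only for random tie-breaking.
#' @return Integer vector that is a permutation of `1:M`; rank 1
#'   corresponds to the largest value.
#' @seealso [max_rank()], [marr_pair()]
#' @export
#' @examples
#' assign_ranks(c(3.0, 1.0, 2.0))
assign_ranks <- function(values, tie_seed = 1L) {
  if (!is.numeric(values) || length(values) < 1L) {
    stop_("'values' must be a non-empty numeric vector")
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    stop_("missing or non-finite abundance value at index ",
          paste(utils::head(bad, 5L), collapse = ", "),
          if (length(bad) > 5L) " (and others)" else "",
          "; MaRR assumes a complete matrix")
  }
  with_seed(tie_seed, as.integer(rank(-values, ties.method = "random")))
}

#' Maximum rank statistic of a replicate pair
#'
#' For each metabolite, the larger of its two within-replicate ranks,
#' `Max_m = max(R_m1, R_m2)`. Metabolites that are consistently highly
#' ranked in both replicates have a small maximum rank; a threshold on
#' the maximum rank separates reproducible from irreproducible signals.
#'
#' @param ranks_a,ranks_b Integer rank vectors of equal length M, each a
#'   permutation of `1:M` (see [assign_ranks()]).
#' @return Integer vector of per-metabolite maximum ranks.
#' @export
#' @examples
#' max_rank(c(1L, 2L, 3L), c(2L, 1L, 3L))
max_rank <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b)) {
    stop_("rank vectors differ in length (", length(ranks_a), " vs ",
          length(ranks_b), ")")
  }
  check_permutation(ranks_a, "ranks_a")
  check_permutation(ranks_b, "ranks_b")
  as.integer(pmax(ranks_a, ranks_b))
}

check_permutation <- function(r, label) {
  m <- length(r)
  if (!all(sort(as.integer(r)) == seq_len(m))) {
    stop_("'", label, "' is not a permutation of 1..", m)
  }
  invisible(TRUE)
}

#' Empirical survival function of scaled maximum ranks
#'
#' The fraction of metabolites whose scaled maximum rank `Max_m / M` is
#' at least `x`. This is the observed counterpart of the limiting
#' survival function used to estimate the proportion of reproducible
#' signals.
#'
#' @param max_ranks Integer vector of maximum rank statistics (values in
#'   `1:M`, see [max_rank()]).
#' @param x Numeric vector of evaluation points in (0, 1] (values above
#'   1 give 0).
#' @return Numeric vector of survival probabilities in `[0, 1]`,
#'   nonincreasing in `x`.
#' @export
empirical_survival <- function(max_ranks, x) {
  m <- length(max_ranks)
  check_max_ranks(max_ranks)
  scaled <- max_ranks / m
  vapply(x, function(xi) mean(scaled >= xi), numeric(1))
}

check_max_ranks <- function(max_ranks) {
  m <- length(max_ranks)
  if (m < 1L || anyNA(max_ranks)) stop_("invalid maximum rank vector")
  mr <- as.integer(max_ranks)
  if (any(mr < 1L) || any(mr > m)) {
    stop_("maximum ranks must lie in 1..M (M = ", m, ")")
  }
  invisible(TRUE)
}

#' Limiting survival function under the ideal setting
#'
#' Under a perfect split -- every reproducible metabolite's scaled
#' maximum rank falls below `pi1` and irreproducible ranks are
#' independent -- the scaled maximum rank of an irreproducible
#' metabolite converges in distribution to the survival function
#' \deqn{S_{\pi_1}(x) = 1 \; (x < \pi_1); \quad
#'       1 - (x-\pi_1)^2/(1-\pi_1)^2 \; (\pi_1 \le x \le 1); \quad
#'       0 \; (x > 1).}
#'
#' @param pi1 Proportion of reproducible signals, strictly in (0, 1).
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of survival probabilities.
#' @export
#' @examples
#' ideal_survival(0.35, c(0.2, 0.675, 1))
ideal_survival <- function(pi1, x) {
  if (!is.numeric(pi1) || length(pi1) != 1L || !is.finite(pi1) ||
      pi1 <= 0 || pi1 >= 1) {
    stop_("'pi1' must be a single number strictly between 0 and 1")
  }
  out <- 1 - (x - pi1)^2 / (1 - pi1)^2
  out[x < pi1] <- 1
  out[x > 1] <- 0
  out
}
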