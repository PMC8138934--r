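#' Permutation test comparing two group compositions
#'
#' Asks how often, given the samples that make up the two compared
#' groups, a composition difference at least as large as the observed one
#' would arise by chance under random re-assignment of sample labels. The
#' test statistic is the L1 distance between the groups' mean Boolean
#' subset-fraction vectors, `T = sum_s |mean_A(s) - mean_B(s)|`; any
#' statistic of the same signature can be plugged in.
#'
#' When the number of distinct label splits is at most `n_perm` the null
#' distribution is enumerated exhaustively and the p-value is the exact
#' fraction of splits (observed split included) with `T >= T_obs`.
#' Otherwise `n_perm` random re-assignments are drawn and the add-one
#' estimator `p = (1 + #[T_perm >= T_obs]) / (1 + n_perm)` is used, so p
#' can never be 0.
#'
#' @param groupA,groupB lists of [composition_profile()]s (at least 2
#'   each), or numeric matrices of per-sample composition vectors (rows =
#'   samples).
#' @param n_perm permutation budget.
#' @param seed RNG seed for the sampled mode.
#' @param statistic function(meanA, meanB) -> scalar; default L1.
#' @param exhaustive force exhaustive (`TRUE`) or sampled (`FALSE`) mode;
#'   default auto.
#' @return A `permutation_test` object: `observed_statistic`, `p_value`,
#'   `n_permutations`, `exhaustive`, `seed` and the null statistics.
#' @export
#' @examples
#' a <- matrix(rep(c(.5, .3, .2), each = 3), 3)
#' b <- matrix(rep(c(.2, .3, .5), each = 3), 3)
#' composition_permutation_test(a, b)$p_value
composition_permutation_test <- function(groupA, groupB, n_perm = 10000,
                                         seed = 1L, statistic = NULL,
                                         exhaustive = NULL) {
  A <- as_composition_matrix(groupA)
  B <- as_composition_matrix(groupB)
  if (nrow(A) < 2 || nrow(B) < 2)
    abort2("each group needs at least 2 samples", class = "stats_error")
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse p-value")
  stat <- statistic %||% function(ma, mb) sum(abs(ma - mb))
  X <- rbind(A, B)
  nA <- nrow(A); n <- nrow(X)
  t_obs <- stat(colMeans(A), colMeans(B))

  n_splits <- choose(n, nA)
  do_exhaustive <- exhaustive %||% (n_splits <= n_perm)
  if (do_exhaustive) {
    splits <- utils::combn(n, nA)
    t_null <- apply(splits, 2, function(ia)
      stat(colMeans(X[ia, , drop = FALSE]),
           colMeans(X[-ia, , drop = FALSE])))
    p <- sum(t_null >= t_obs - 1e-12) / ncol(splits)
    n_used <- ncol(splits)
  } else {
    t_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      ia <- sample(n, nA)
      stat(colMeans(X[ia, , drop = FALSE]),
           colMeans(X[-ia, , drop = FALSE]))
    }, 0))
    p <- (1 + sum(t_null >= t_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(observed_statistic = t_obs, p_value = p,
                 n_permutations = n_used,
                 exhaustive = isTRUE(do_exhaustive), seed = seed,
                 null_statistics = t_null),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "<permutation_test> T = %.4f, p = %.4g (%s, %d permutations)\n",
    x$observed_statistic, x$p_value,
    if (x$exhaustive) "exhaustive" else "sampled", x$n_permutations))
  invisible(x)
}

as_composition_matrix <- function(g) {
  if (is.matrix(g)) return(g)
  if (is.list(g) && all(vapply(g, inherits, TRUE, "composition_profile")))
    return(profile_matrix(usable_profiles(g)))
  abort2("groups must be matrices or lists of composition profiles",
         class = "stats_error")
}
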