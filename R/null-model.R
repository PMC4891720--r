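# Exact and approximate null distributions of the longest homo-repeat under
# i.i.d. residue sampling, and expected protein counts over a length
# distribution.
#
# The exact computation tracks the joint state (M, K) along the chain, where
# M is the longest run of the focal amino acid seen so far and K the length
# of the run touching the C-terminal end (K = 0 when the chain ends in a
# different residue). Appending the focal residue turns (M, K) into
# (M, K + 1), or promotes (M, M) to (M + 1, M + 1); appending any other
# residue resets K to 0. The chain of length 1 starts at
# P(M = 0, K = 0) = 1 - p and P(M = 1, K = 1) = p. Marginalizing over K
# gives P(longest run = M) for every chain length visited, so one sweep to
# the largest length serves a whole length distribution.

# Core sweep. Returns list(M, marg, cap, truncated): `marg` has one column
# per requested length (in input order) holding P(M) for M = 0..cap. When
# cap < max(lengths) the top row is an absorbing tail bin, i.e. row `cap`
# holds P(longest run >= cap); total mass is conserved exactly.
longest_run_marginals <- function(p, lengths, m_max = max(lengths)) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a single probability in [0, 1]")
  }
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L || any(is.na(lengths)) || any(lengths < 1L)) {
    abort("`lengths` must be positive integers")
  }
  Lmax <- max(lengths)
  cap <- min(Lmax, max(1L, as.integer(m_max)))
  n <- cap + 1L
  J <- matrix(0, n, n)
  J[1L, 1L] <- 1 - p
  J[2L, 2L] <- J[2L, 2L] + p
  marg <- matrix(0, n, length(lengths))
  idx <- split(seq_along(lengths), lengths)
  if (!is.null(idx[["1"]])) marg[, idx[["1"]]] <- rowSums(J)
  if (Lmax >= 2L) {
    di <- cbind(2:n, 2:n)
    for (L in 2:Lmax) {
      Nw <- matrix(0, n, n)
      Nw[, 1L] <- rowSums(J) * (1 - p)          # append a non-focal residue
      off <- J
      off[di] <- 0
      off[1L, 1L] <- 0
      Nw[, 2:n] <- Nw[, 2:n] + off[, 1:(n - 1L), drop = FALSE] * p # K -> K+1
      d <- J[cbind(1:n, 1:n)] * p               # promotions M -> M+1
      Nw[di] <- Nw[di] + d[1:(n - 1L)]
      Nw[n, n] <- Nw[n, n] + d[n]               # absorbing tail bin
      J <- Nw
      key <- as.character(L)
      if (!is.null(idx[[key]])) marg[, idx[[key]]] <- rowSums(J)
    }
  }
  list(M = 0:cap, marg = marg, cap = cap, truncated = cap < Lmax)
}

new_run_length_distribution <- function(M, prob, p, L, truncated) {
  out <- tibble::tibble(M = M, prob = prob)
  attr(out, "p") <- p
  attr(out, "L") <- L
  attr(out, "truncated") <- truncated
  class(out) <- c("run_length_distribution", class(out))
  out
}

#' Exact distribution of the longest run in an i.i.d. chain
#'
#' Probability that the longest run of a focal amino acid (per-residue
#' probability `p`) in a chain of length `L` equals M, for M = 0..L,
#' computed by the exact joint recursion over (longest run so far,
#' C-terminal run length).
#'
#' @param p Per-residue probability of the focal amino acid.
#' @param L Chain length (>= 1).
#' @param m_max Optional truncation: when `m_max < L` the returned
#'   distribution runs over `M = 0..m_max` and its last entry holds the
#'   whole tail `P(longest >= m_max)` (mass is conserved exactly). Use the
#'   default for the full distribution.
#' @return A tibble (class `run_length_distribution`) with columns `M` and
#'   `prob`, attributes `p`, `L`, `truncated`.
#' @examples
#' exact_longest_run_distribution(0.5, 2)
#' @export
exact_longest_run_distribution <- function(p, L, m_max = L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1) {
    abort("`L` must be a single integer >= 1")
  }
  res <- longest_run_marginals(p, as.integer(L), m_max = m_max)
  new_run_length_distribution(res$M, res$marg[, 1L], p, as.integer(L),
                              res$truncated)
}

#' @export
print.run_length_distribution <- function(x, ...) {
  cat(sprintf("<run_length_distribution> p = %g, L = %d%s\n",
              attr(x, "p"), attr(x, "L"),
              if (isTRUE(attr(x, "truncated"))) " (tail-truncated)" else ""))
  NextMethod()
}

#' @describeIn exact_longest_run_distribution Summary statistics of the
#'   distribution (mean, mode, tail mass beyond the conventional repeat
#'   threshold of 5).
#' @param x A `run_length_distribution`.
#' @param ... Unused.
#' @export
glance.run_length_distribution <- function(x, ...) {
  tibble::tibble(
    p = attr(x, "p"), L = attr(x, "L"),
    mean_M = sum(x$M * x$prob),
    mode_M = x$M[which.max(x$prob)],
    p_ge_5 = sum(x$prob[x$M >= 5])
  )
}

#' @describeIn exact_longest_run_distribution Column plot of P(M) on a log
#'   probability scale.
#' @param object A `run_length_distribution`.
#' @export
autoplot.run_length_distribution <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$prob > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$M, y = .data$prob)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "longest run length M", y = "P(M)",
                  title = sprintf("Longest-run distribution (p = %g, L = %d)",
                                  attr(object, "p"), attr(object, "L")))
}

#' Brute-force longest-run distribution by full enumeration
#'
#' Independent reference for [exact_longest_run_distribution()]: enumerates
#' all 2^L two-letter strings (focal residue vs. anything else), weighs each
#' by `p^k (1-p)^(L-k)` and bins by its longest focal run. Only feasible for
#' small L; refuses L > 16.
#'
#' @inheritParams exact_longest_run_distribution
#' @return A `run_length_distribution` tibble over `M = 0..L`.
#' @export
brute_force_longest_run_distribution <- function(p, L) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    abort("`p` must be a single probability in [0, 1]")
  }
  L <- as.integer(L)
  if (is.na(L) || L < 1L) abort("`L` must be >= 1")
  if (L > 16L) abort("enumeration guard: L must be <= 16")
  probs <- numeric(L + 1L)
  shifts <- 0:(L - 1L)
  for (i in 0:(2^L - 1)) {
    bits <- bitwAnd(bitwShiftR(i, shifts), 1L)
    r <- rle(bits)
    m <- if (any(r$values == 1L)) max(r$lengths[r$values == 1L]) else 0L
    k <- sum(bits)
    probs[m + 1L] <- probs[m + 1L] + p^k * (1 - p)^(L - k)
  }
  new_run_length_distribution(0:L, probs, p, L, truncated = FALSE)
}

#' Closed-form approximation of the single-repeat probability
#'
#' When a run of length M is rare (`L * p^M < 0.01`, p <= 0.05, M >= 4),
#' the probability that a chain of length L contains a homo-repeat of
#' length M is well approximated by counting placements: two terminal
#' positions flanked by one different residue, and `L - M - 1` interior
#' positions flanked by two:
#' `2 p^M (1-p) + (L-M-1) p^M (1-p)^2`.
#' A warning is raised when `L * p^M >= 0.01`, outside the stated validity
#' domain.
#'
#' @inheritParams exact_longest_run_distribution
#' @param M Repeat length (>= 1, < L).
#' @return The approximate probability (single number).
#' @examples
#' approx_repeat_probability(0.05, 5, 395)
#' @export
approx_repeat_probability <- function(p, M, L) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    abort("`p` must be a single probability in [0, 1]")
  }
  M <- as.integer(M); L <- as.integer(L)
  if (is.na(M) || M < 1L) abort("`M` must be >= 1")
  if (is.na(L) || L <= M) abort("`L` must exceed `M`")
  if (L * p^M >= 0.01) {
    warn(sprintf(
      "approximation outside its validity domain: L * p^M = %.3g >= 0.01",
      L * p^M))
  }
  2 * p^M * (1 - p) + (L - M - 1) * p^M * (1 - p)^2
}

#' Expected number of proteins per longest-run length
#'
#' Sums the null longest-run distribution over a proteome's length
#' distribution: `N(M) = sum_L n_L P(p, M, L)`, the expected number of
#' proteins whose longest run of the focal amino acid equals M under
#' i.i.d. residue sampling. `method = "exact"` uses the recursion (one
#' sweep over all lengths, including M = 0); `method = "approx"` uses the
#' closed-form placement approximation (M >= 1 only, valid for rare
#' repeats).
#'
#' @param profile A `proteome_profile` (see [profile_proteome()]).
#' @param amino_acid One or more canonical amino-acid letters. Amino acids
#'   sharing the same frequency share a single recursion sweep, so a
#'   uniform-composition profile costs one sweep for all 20.
#' @param method `"exact"` or `"approx"`.
#' @param m_max Largest exactly-resolved M (default `min(40, max length)`).
#'   With the exact method, rows are flagged `tail = TRUE` where the entry
#'   holds the lumped tail `P(longest >= m_max)` rather than an exact-M
#'   value; total expected counts still sum to `n_proteins`.
#' @param p Optional override of the amino-acid frequency (used e.g. to
#'   evaluate a uniform 1/20 composition); a single value recycled over
#'   `amino_acid`, or one value per amino acid. Default: profile
#'   frequencies.
#' @return Tibble `amino_acid`, `M`, `expected`, `method`, `tail`.
#' @examples
#' prof <- profile_proteome(tibble::tibble(id = "a", sequence = "Q"))
#' expected_counts(prof, "Q")
#' @export
expected_counts <- function(profile, amino_acid,
                            method = c("exact", "approx"),
                            m_max = NULL, p = NULL) {
  stopifnot(inherits(profile, "proteome_profile"))
  method <- match.arg(method)
  if (!all(amino_acid %in% AA20)) {
    abort(paste0("unknown amino acid: ",
                 setdiff(amino_acid, AA20)[1L]))
  }
  if (is.null(p)) {
    p <- profile$aa_frequencies$frequency[
      match(amino_acid, profile$aa_frequencies$amino_acid)]
    if (anyNA(p) || any(p == 0)) {
      abort(paste0("amino acid absent from profile: ",
                   amino_acid[is.na(p) | p == 0][1L]))
    }
  } else {
    p <- rep_len(p, length(amino_acid))
  }
  lens <- profile$length_counts$length
  cnts <- profile$length_counts$count
  Lmax <- max(lens)
  if (is.null(m_max)) m_max <- min(40L, Lmax)
  if (method == "exact") {
    by_p <- split(seq_along(amino_acid), p)
    purrr::map(by_p, function(ii) {
      res <- longest_run_marginals(p[ii[1L]], lens, m_max = m_max)
      expected <- as.numeric(res$marg %*% cnts)
      purrr::map(amino_acid[ii], function(aa) {
        tibble::tibble(amino_acid = aa, M = res$M, expected = expected,
                       method = "exact",
                       tail = res$truncated & res$M == res$cap)
      }) |> dplyr::bind_rows()
    }) |>
      dplyr::bind_rows() |>
      dplyr::arrange(match(.data$amino_acid, amino_acid), .data$M)
  } else {
    Ms <- seq_len(min(m_max, Lmax - 1L))
    purrr::map2(amino_acid, p, function(aa, pa) {
      expected <- vapply(Ms, function(m) {
        ok <- lens > m
        sum(cnts[ok] * (2 * pa^m * (1 - pa) +
                          (lens[ok] - m - 1) * pa^m * (1 - pa)^2))
      }, numeric(1))
      tibble::tibble(amino_acid = aa, M = as.integer(Ms),
                     expected = expected, method = "approx", tail = FALSE)
    }) |> dplyr::bind_rows()
  }
}
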