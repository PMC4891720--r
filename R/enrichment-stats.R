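# Observed-vs-expected fold comparison (10-fold rule), disease-association
# Z-score, resampling enrichment for target sets, and interaction-partner
# summaries.

#' Compare observed and expected repeat counts per length
#'
#' Joins observed protein counts (from [observed_counts()], exact mode) with
#' expected counts (from [expected_counts()]) over the union of repeat
#' lengths M >= 1, missing entries treated as 0, and computes the fold ratio
#' observed / expected. Conventions: 0 observed with 0 expected gives ratio
#' 0; positive observed with 0 expected gives an infinite ratio, flagged in
#' the `infinite` column (TSV output carries the flag, never a numeric
#' sentinel). Tail-lumped expected rows (see [expected_counts()]) are
#' dropped before joining so every compared M is exact.
#'
#' @param observed Tibble `M`, `count` for one amino acid.
#' @param expected Tibble from [expected_counts()] for the same amino acid.
#' @return Tibble (class `fold_table`) `amino_acid`, `M`, `observed`,
#'   `expected`, `fold_ratio`, `infinite`, dense over the union M range.
#' @export
fold_comparison <- function(observed, expected) {
  stopifnot(is.data.frame(observed), all(c("M", "count") %in% names(observed)),
            is.data.frame(expected),
            all(c("amino_acid", "M", "expected") %in% names(expected)))
  if (any(observed$count < 0) || any(expected$expected < 0)) {
    abort("negative counts are not allowed")
  }
  if ("tail" %in% names(expected)) {
    expected <- dplyr::filter(expected, !.data$tail)
  }
  aa <- unique(expected$amino_acid)
  if (length(aa) != 1L) abort("`expected` must cover a single amino acid")
  mmax <- max(c(observed$M, expected$M, 1L))
  grid <- tibble::tibble(M = seq_len(mmax))
  out <- grid |>
    dplyr::left_join(dplyr::select(observed, "M", observed = "count"),
                     by = "M") |>
    dplyr::left_join(dplyr::select(expected, "M", "expected"), by = "M") |>
    tidyr::replace_na(list(observed = 0L, expected = 0)) |>
    dplyr::mutate(
      amino_acid = aa,
      fold_ratio = dplyr::case_when(
        .data$expected > 0 ~ .data$observed / .data$expected,
        .data$observed > 0 ~ Inf,
        TRUE ~ 0
      ),
      infinite = is.infinite(.data$fold_ratio)
    ) |>
    dplyr::relocate("amino_acid")
  class(out) <- c("fold_table", class(out))
  out
}

#' @describeIn fold_comparison Observed vs expected counts per M on a log
#'   count scale.
#' @param object A `fold_table`.
#' @param ... Unused.
#' @export
autoplot.fold_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "source", values_to = "count") |>
    dplyr::filter(.data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$M, y = .data$count,
                                   colour = .data$source)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~amino_acid) +
    ggplot2::labs(x = "longest run length M", y = "proteins",
                  title = "Observed vs expected homo-repeat counts")
}

#' Minimal repeat length with a significant observed excess
#'
#' The 10-fold rule: the smallest repeat length M at which the observed
#' protein count is at least `min_observed` and exceeds the null expectation
#' by at least `fold_threshold` (infinite ratios qualify). Returns
#' `NA_integer_` when no length qualifies (printed as a dash in report
#' tables).
#'
#' @param table A `fold_table` from [fold_comparison()].
#' @param fold_threshold Minimum observed/expected ratio (default 10).
#' @param min_observed Minimum observed protein count (default 1).
#' @return A single integer M, or `NA_integer_`.
#' @export
minimal_significant_length <- function(table, fold_threshold = 10,
                                       min_observed = 1L) {
  stopifnot(is.data.frame(table),
            all(c("M", "observed", "fold_ratio") %in% names(table)))
  hit <- table$observed >= min_observed & table$fold_ratio >= fold_threshold
  if (!any(hit)) NA_integer_ else as.integer(min(table$M[hit]))
}

#' Disease-association Z-score from contingency counts
#'
#' Given a proteome of N proteins of which N_a carry an annotation (e.g.
#' OMIM disease linkage) and N_b carry a qualifying homo-repeat, with N_ab
#' carrying both, tests departure from independence:
#' mean = N_a N_b / N, sd = sqrt(mean (1 - N_a/N) (1 - N_b/N)),
#' z = (N_ab - mean) / sd. Scores are banded `strong` (z > 5), `moderate`
#' (3 < z <= 5) or `none`, matching the conventional colour coding of
#' association heatmaps.
#'
#' @param counts Data frame with columns `N`, `N_a`, `N_b`, `N_ab` (one row
#'   per test; an `amino_acid` column, if present, is carried through).
#' @param sd_method `"binomial"` (default, as above) or `"poisson"`
#'   (`sd = sqrt(mean)`).
#' @return Tibble (class `association_table`) with the input columns plus
#'   `mean`, `sd`, `z`, `band`.
#' @examples
#' association_z(tibble::tibble(N = 59053, N_a = 2501, N_b = 1503, N_ab = 125))
#' @export
association_z <- function(counts, sd_method = c("binomial", "poisson")) {
  sd_method <- match.arg(sd_method)
  stopifnot(is.data.frame(counts),
            all(c("N", "N_a", "N_b", "N_ab") %in% names(counts)))
  with(counts, {
    if (any(N_ab > pmin(N_a, N_b)) || any(N_a > N) || any(N_b > N) ||
        any(c(N, N_a, N_b, N_ab) < 0)) {
      abort("invalid contingency counts: need N_ab <= min(N_a, N_b) <= N, all >= 0")
    }
  })
  m <- counts$N_a * counts$N_b / counts$N
  s <- if (sd_method == "binomial") {
    sqrt(m * (1 - counts$N_a / counts$N) * (1 - counts$N_b / counts$N))
  } else {
    sqrt(m)
  }
  if (any(s == 0)) {
    abort("undefined Z: zero rms deviation (N_a or N_b is 0 or N)")
  }
  z <- (counts$N_ab - m) / s
  out <- tibble::as_tibble(counts) |>
    dplyr::mutate(mean = m, sd = s, z = z,
                  band = dplyr::case_when(z > 5 ~ "strong",
                                          z > 3 ~ "moderate",
                                          TRUE ~ "none"))
  class(out) <- c("association_table", class(out))
  out
}

#' @describeIn association_z Bar plot of Z-scores coloured by band.
#' @param object An `association_table`.
#' @param ... Unused.
#' @export
autoplot.association_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"amino_acid" %in% names(df)) df$amino_acid <- as.character(seq_len(nrow(df)))
  df$amino_acid <- stats::reorder(df$amino_acid, -df$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amino_acid, y = .data$z,
                                   fill = .data$band)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(3, 5), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(strong = "forestgreen",
                                          moderate = "gold",
                                          none = "grey80")) +
    ggplot2::labs(x = "homo-repeat amino acid", y = "association Z-score",
                  title = "Disease association of repeat-bearing proteins")
}

#' Resampling enrichment of homo-repeats in a protein target set
#'
#' For every amino acid and every repeat length in `lengths`, counts the
#' target proteins whose longest run reaches that length (cumulative
#' counting, `longest >= m`; set `counting = "exact"` for `longest == m`),
#' then draws `n_samples` random protein sets of the same size from the
#' whole universe (uniformly, without replacement within each draw) and
#' standardizes: `z = (C - mean(R)) / sd(R)`. Cells with `sd(R) = 0` get
#' z = 0 when C equals every resample and an infinite flagged z otherwise.
#' Cells with z > 5 are marked significant. Fully deterministic for a fixed
#' `seed`.
#'
#' @param target_ids Character vector of protein ids (subset of the
#'   universe).
#' @param universe A longest-run table from [longest_run_table()] covering
#'   the whole proteome the targets are drawn against.
#' @param lengths Integer repeat lengths to test (default 4:9).
#' @param n_samples Number of random extractions (default 20).
#' @param seed Integer seed (required; recorded in the output attribute).
#' @param counting `"at_least"` (default) or `"exact"`.
#' @return Tibble (class `enrichment_table`) `amino_acid`, `motif_length`,
#'   `target_count`, `resample_mean`, `resample_sd`, `z`, `degenerate`,
#'   `significant`.
#' @export
resample_enrichment <- function(target_ids, universe, lengths = 4:9,
                                n_samples = 20L, seed,
                                counting = c("at_least", "exact")) {
  counting <- match.arg(counting)
  stopifnot(is.data.frame(universe),
            all(c("protein_id", "amino_acid", "longest") %in% names(universe)))
  if (missing(seed)) abort("`seed` is required for reproducible resampling")
  ids <- unique(universe$protein_id)
  target_ids <- unique(as.character(target_ids))
  if (length(target_ids) < 1L) abort("`target_ids` must be non-empty")
  if (!all(target_ids %in% ids)) {
    abort("`target_ids` must be a subset of the universe protein ids")
  }
  if (length(target_ids) > length(ids)) {
    abort("more targets than universe proteins")
  }
  # wide matrix of longest run per protein x amino acid
  W <- matrix(0L, nrow = length(ids), ncol = length(AA20),
              dimnames = list(ids, AA20))
  W[cbind(match(universe$protein_id, ids),
          match(universe$amino_acid, AA20))] <- universe$longest
  count_set <- function(rows) {
    sub <- W[rows, , drop = FALSE]
    vapply(lengths, function(m) {
      if (counting == "at_least") colSums(sub >= m) else colSums(sub == m)
    }, numeric(ncol(W)))  # aa x length
  }
  C <- count_set(match(target_ids, ids))
  draws <- withr::with_seed(as.integer(seed), {
    replicate(n_samples,
              count_set(sample.int(length(ids), length(target_ids))))
  })  # aa x length x sample
  Rm <- apply(draws, c(1, 2), mean)
  Rs <- apply(draws, c(1, 2), sd)
  z <- ifelse(Rs > 0, (C - Rm) / Rs, ifelse(C == Rm, 0, Inf * sign(C - Rm)))
  out <- tibble::tibble(
    amino_acid = rep(AA20, times = length(lengths)),
    motif_length = rep(as.integer(lengths), each = length(AA20)),
    target_count = as.integer(C),
    resample_mean = as.numeric(Rm),
    resample_sd = as.numeric(Rs),
    z = as.numeric(z),
    degenerate = as.vector(Rs == 0 & C != Rm),
    significant = z > 5
  )
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_samples") <- as.integer(n_samples)
  class(out) <- c("enrichment_table", class(out))
  out
}

#' @describeIn resample_enrichment Tile plot of enrichment Z-scores by
#'   amino acid and motif length.
#' @param object An `enrichment_table`.
#' @param ... Unused.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$zcap <- pmin(pmax(df$z, -8), 8)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif_length,
                                   y = .data$amino_acid, fill = .data$zcap)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = dplyr::filter(df, .data$significant),
                       ggplot2::aes(label = "*"), size = 5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  name = "Z") +
    ggplot2::labs(x = "motif length", y = "amino acid",
                  title = "Target-set homo-repeat enrichment")
}

#' Interaction-partner summary per repeat class
#'
#' Computes each protein's interaction degree from an undirected edge list
#' (self-loops dropped, duplicate edges collapsed regardless of direction)
#' and summarizes mean degree and its standard error per protein group
#' (typically, proteins harbouring a given homo-repeat), plus a
#' whole-universe `"proteome"` row.
#'
#' @param edges Data frame whose first two columns are protein ids.
#' @param groups Named list of protein-id vectors.
#' @param universe Optional id vector defining the background; defaults to
#'   the union of all edge endpoints and group members. Ids without edges
#'   count with degree 0.
#' @return Tibble (class `partner_table`) `group`, `mean_partners`, `sem`,
#'   `n_proteins`, with the `"proteome"` row last.
#' @export
partner_summary <- function(edges, groups, universe = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named list of protein-id vectors")
  }
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  uniq <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[uniq]; hi <- hi[uniq]
  if (is.null(universe)) {
    universe <- unique(c(lo, hi, unlist(groups, use.names = FALSE)))
  }
  universe <- unique(as.character(universe))
  deg <- table(factor(c(lo, hi), levels = universe))
  degree_of <- function(ids) as.numeric(deg[match(ids, universe)])
  summarize_ids <- function(ids, label) {
    d <- degree_of(ids)
    tibble::tibble(group = label, mean_partners = mean(d),
                   sem = if (length(d) > 1) sd(d) / sqrt(length(d)) else 0,
                   n_proteins = length(d))
  }
  rows <- purrr::imap(groups, function(ids, label) {
    ids <- unique(as.character(ids))
    ids <- ids[ids %in% universe]
    if (length(ids) == 0L) {
      warn(paste0("group with no members in universe skipped: ", label))
      return(NULL)
    }
    summarize_ids(ids, label)
  })
  rows <- unname(purrr::compact(rows))
  out <- dplyr::bind_rows(c(rows, list(summarize_ids(universe, "proteome"))))
  class(out) <- c("partner_table", class(out))
  out
}

#' @describeIn partner_summary Mean degree with SEM error bars per group;
#'   dashed line marks the proteome average.
#' @param object A `partner_table`.
#' @param ... Unused.
#' @export
autoplot.partner_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  base <- df$mean_partners[df$group == "proteome"]
  df <- dplyr::filter(df, .data$group != "proteome")
  df$group <- stats::reorder(df$group, -df$mean_partners)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_partners)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_partners - .data$sem,
                                        ymax = .data$mean_partners + .data$sem),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = base, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "repeat class", y = "mean interaction partners",
                  title = "Interaction partners per homo-repeat class")
}
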