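# Synthetic proteomes, spiked repeats, disease labels and interaction edges
# with recorded ground truth. All generators are pure functions of their
# arguments plus a required integer seed.

#' Sample a null proteome of i.i.d. sequences
#'
#' Generates protein records whose residues are drawn independently from a
#' fixed amino-acid frequency vector, with chain lengths from a chosen
#' length model. The default model emulates a eukaryotic proteome:
#' lognormal lengths with mean 395 and standard deviation 530 residues
#' (the human proteome's moments), rounded and clamped to
#' `[min_length, max_length]`; proteome length distributions are heavily
#' right-skewed, which the lognormal captures with just those two moments.
#'
#' @param n_proteins Number of sequences (>= 1).
#' @param length_model `"lognormal"` (default), `"fixed"` or `"empirical"`.
#' @param mean_length,sd_length Target moments of the lognormal model
#'   (defaults 395 and 530).
#' @param fixed_length Chain length for the `"fixed"` model.
#' @param length_counts Tibble `length`, `count` for the `"empirical"`
#'   model (lengths sampled proportional to counts).
#' @param aa_freq Named numeric vector of residue frequencies over the 20
#'   canonical amino acids (need not cover all 20; must sum to 1). Default:
#'   uniform 1/20.
#' @param seed Integer seed (required).
#' @param min_length,max_length Clamp bounds for the lognormal model.
#' @return Tibble `id`, `description`, `sequence`; byte-identical for
#'   identical arguments.
#' @examples
#' sample_null_proteome(3, length_model = "fixed", fixed_length = 10, seed = 1)
#' @export
sample_null_proteome <- function(n_proteins,
                                 length_model = c("lognormal", "fixed",
                                                  "empirical"),
                                 mean_length = 395, sd_length = 530,
                                 fixed_length = NULL, length_counts = NULL,
                                 aa_freq = NULL, seed,
                                 min_length = 30L, max_length = 10000L) {
  length_model <- match.arg(length_model)
  if (missing(seed)) abort("`seed` is required")
  n_proteins <- as.integer(n_proteins)
  if (is.na(n_proteins) || n_proteins < 1L) abort("`n_proteins` must be >= 1")
  aa_freq <- check_aa_freq(aa_freq)
  withr::with_seed(as.integer(seed), {
    lens <- switch(length_model,
      lognormal = {
        sdlog2 <- log(1 + (sd_length / mean_length)^2)
        meanlog <- log(mean_length) - sdlog2 / 2
        pmin(pmax(as.integer(round(rlnorm(n_proteins, meanlog,
                                          sqrt(sdlog2)))),
                  as.integer(min_length)), as.integer(max_length))
      },
      fixed = {
        if (is.null(fixed_length) || fixed_length < 1) {
          abort("`fixed_length` must be >= 1 for the fixed length model")
        }
        rep(as.integer(fixed_length), n_proteins)
      },
      empirical = {
        if (is.null(length_counts) ||
            !all(c("length", "count") %in% names(length_counts))) {
          abort("`length_counts` (length, count) required for empirical model")
        }
        sample(as.integer(length_counts$length), n_proteins, replace = TRUE,
               prob = length_counts$count)
      })
    res <- sample(names(aa_freq), sum(lens), replace = TRUE, prob = aa_freq)
    seqs <- vapply(split(res, rep.int(seq_len(n_proteins), lens)),
                   paste, character(1), collapse = "")
    seqs <- unname(seqs[as.character(seq_len(n_proteins))])
    tibble::tibble(
      id = sprintf("SYN%06d", seq_len(n_proteins)),
      description = sprintf("synthetic null protein len=%d seed=%d",
                            lens, as.integer(seed)),
      sequence = seqs
    )
  })
}

check_aa_freq <- function(aa_freq) {
  if (is.null(aa_freq)) {
    return(setNames(rep(1 / 20, 20), AA20))
  }
  if (is.null(names(aa_freq)) || !all(names(aa_freq) %in% AA20) ||
      any(aa_freq < 0) || abs(sum(aa_freq) - 1) > 1e-9) {
    abort("`aa_freq` must be named over canonical amino acids, >= 0, sum 1")
  }
  aa_freq[aa_freq > 0]
}

#' Spike homo-repeats into a fraction of proteins
#'
#' Inserts (never overwrites) a run of `run_length` copies of `amino_acid`
#' at a uniformly chosen position in `ceiling(fraction * n)` randomly chosen
#' proteins, and records the ground truth. Because insertion can land next
#' to existing copies of the same residue, the resulting longest run is
#' at least `run_length`.
#'
#' @param records Tibble of protein records.
#' @param amino_acid Canonical amino-acid letter to insert.
#' @param run_length Length of the inserted run (>= 1).
#' @param fraction Fraction of proteins to spike (0 < fraction <= 1).
#' @param seed Integer seed (required).
#' @return List with `records` (modified tibble, same order) and `truth`
#'   (tibble `protein_id`, `amino_acid`, `length`, `offset`; `offset` is the
#'   1-based start of the inserted run in the new sequence).
#' @export
spike_repeats <- function(records, amino_acid, run_length, fraction, seed) {
  check_records(records)
  if (missing(seed)) abort("`seed` is required")
  if (!amino_acid %in% AA20) abort(paste0("unknown amino acid: ", amino_acid))
  run_length <- as.integer(run_length)
  if (is.na(run_length) || run_length < 1L) abort("`run_length` must be >= 1")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1]")
  }
  n <- nrow(records)
  n_spike <- as.integer(ceiling(fraction * n))
  run <- strrep(amino_acid, run_length)
  withr::with_seed(as.integer(seed), {
    pick <- sort(sample.int(n, n_spike))
    lens <- nchar(records$sequence[pick])
    # insertion point: after position pos (0 = prepend, len = append)
    pos <- as.integer(floor(runif(n_spike) * (lens + 1)))
    records$sequence[pick] <- paste0(
      substr(records$sequence[pick], 1L, pos), run,
      substr(records$sequence[pick], pos + 1L, lens))
    list(
      records = records,
      truth = tibble::tibble(protein_id = records$id[pick],
                             amino_acid = amino_acid,
                             length = run_length,
                             offset = pos + 1L)
    )
  })
}

#' Simulate binary disease labels with a target relative risk
#'
#' Labels each protein 1 with probability `base_rate`, except members of
#' `target_ids`, which are labelled with probability
#' `base_rate * relative_risk`. A relative risk of 1 gives a null
#' association; larger values give recoverable enrichment.
#'
#' @param ids All protein ids.
#' @param target_ids Subset of `ids` with elevated risk.
#' @param base_rate Baseline label probability.
#' @param relative_risk Risk multiplier for targets
#'   (`base_rate * relative_risk <= 1`).
#' @param seed Integer seed (required).
#' @return Tibble `id`, `label` (0/1).
#' @export
simulate_disease_labels <- function(ids, target_ids, base_rate, relative_risk,
                                    seed) {
  if (missing(seed)) abort("`seed` is required")
  ids <- as.character(ids)
  target_ids <- as.character(target_ids)
  if (!all(target_ids %in% ids)) abort("`target_ids` must be a subset of `ids`")
  p_t <- base_rate * relative_risk
  if (base_rate < 0 || base_rate > 1 || p_t > 1 || relative_risk < 0) {
    abort("label probabilities must lie in [0, 1]")
  }
  pr <- ifelse(ids %in% target_ids, p_t, base_rate)
  withr::with_seed(as.integer(seed), {
    tibble::tibble(id = ids, label = as.integer(runif(length(ids)) < pr))
  })
}

#' Simulate an interaction edge list with group-specific mean degrees
#'
#' Draws each protein's target degree from a Poisson distribution with its
#' group's mean (or `background_mean` for ungrouped proteins), then pairs
#' degree stubs uniformly at random (configuration-model style), dropping
#' self-loops and collapsing duplicate edges. Realized group mean degrees
#' therefore track the requested means up to the small loss from dropped
#' pairs.
#'
#' @param ids All protein ids.
#' @param groups Named list of protein-id vectors (may be empty).
#' @param group_means Named numeric vector of mean degrees, names matching
#'   `groups`.
#' @param background_mean Mean degree for proteins in no group (default 16,
#'   a typical proteome-wide interaction average).
#' @param seed Integer seed (required).
#' @return Tibble `from`, `to` (undirected, deduplicated edges).
#' @export
simulate_interaction_edges <- function(ids, groups = list(),
                                       group_means = numeric(),
                                       background_mean = 16, seed) {
  if (missing(seed)) abort("`seed` is required")
  ids <- as.character(ids)
  if (length(groups) > 0) {
    if (!setequal(names(groups), names(group_means))) {
      abort("`groups` and `group_means` must have matching names")
    }
    all_members <- unlist(groups, use.names = FALSE)
    if (!all(all_members %in% ids)) {
      abort(paste0("unknown group member: ",
                   setdiff(all_members, ids)[1L]))
    }
  }
  if (background_mean < 0 || any(group_means < 0)) {
    abort("mean degrees must be >= 0")
  }
  lambda <- rep(background_mean, length(ids))
  for (g in names(groups)) {
    lambda[ids %in% groups[[g]]] <- group_means[[g]]
  }
  withr::with_seed(as.integer(seed), {
    d <- rpois(length(ids), lambda)
    stubs <- rep.int(seq_along(ids), d)
    if (length(stubs) < 2L) {
      return(tibble::tibble(from = character(), to = character()))
    }
    if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
    stubs <- sample(stubs)
    a <- stubs[seq(1L, length(stubs), by = 2L)]
    b <- stubs[seq(2L, length(stubs), by = 2L)]
    keep <- a != b
    lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
    uniq <- !duplicated(as.numeric(lo) * (length(ids) + 1) + hi)
    tibble::tibble(from = ids[lo[uniq]], to = ids[hi[uniq]])
  })
}
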