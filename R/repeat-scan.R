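# Maximal-run (homo-repeat) detection and per-protein longest-run tables.

# Decompose every sequence into maximal runs in one pass: all sequences are
# concatenated, run-length encoded once, and runs are assigned back to their
# protein via the cumulative start positions. Ambiguity codes break runs and
# are themselves never reported. Returns a data.table with columns
# protein_id, amino_acid, start (1-based), length.
proteome_runs <- function(ids, seqs) {
  lens <- nchar(seqs)
  # the '!' separator keeps runs from merging across protein boundaries
  chars <- strsplit(paste(seqs, collapse = "!"), "", fixed = TRUE)[[1]]
  r <- rle(chars)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  # concatenated start of protein i: its residues plus i - 1 separators
  prot_start <- cumsum(lens) - lens + seq_along(lens)
  pidx <- findInterval(run_start, prot_start)
  dt <- data.table::data.table(
    protein_id = ids[pidx],
    amino_acid = r$values,
    start = run_start - prot_start[pidx] + 1L,
    length = r$lengths
  )
  dt[dt$amino_acid %in% AA20, ]
}

#' Find maximal single-amino-acid runs in one sequence
#'
#' A maximal run is an uninterrupted stretch of one canonical amino acid
#' that cannot be extended in either direction. Ambiguity codes (X/B/Z/U/O)
#' break runs, and runs of ambiguity codes are never reported. Coordinates
#' are 1-based with closed `start`/`end` (`end = start + length - 1`).
#'
#' @param sequence A single sanitized amino-acid string.
#' @param min_length Minimum run length to report (default 5, the
#'   conventional homo-repeat threshold; any value down to 1 is allowed).
#' @return Tibble with columns `amino_acid`, `start`, `end`, `length`, in
#'   left-to-right order. Empty sequence gives an empty tibble.
#' @examples
#' find_maximal_runs("QQQAQQ", min_length = 2)
#' @export
find_maximal_runs <- function(sequence, min_length = 5L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (min_length < 1L) abort("`min_length` must be >= 1")
  if (is.na(sequence) || !nzchar(sequence)) {
    return(tibble::tibble(amino_acid = character(), start = integer(),
                          end = integer(), length = integer()))
  }
  dt <- proteome_runs("x", toupper(sequence))
  dt <- dt[dt$length >= min_length, ]
  tibble::tibble(amino_acid = dt$amino_acid, start = dt$start,
                 end = dt$start + dt$length - 1L, length = dt$length)
}

#' Catalogue homo-repeats across a protein set
#'
#' Applies [find_maximal_runs()] to every record and returns the combined
#' catalogue, the per-protein repeat inventory used throughout the pipeline.
#'
#' @param records Tibble of protein records (`id`, `sequence`).
#' @inheritParams find_maximal_runs
#' @return Tibble `protein_id`, `amino_acid`, `start`, `end`, `length`,
#'   ordered by record then position.
#' @export
scan_repeats <- function(records, min_length = 5L) {
  check_records(records)
  if (min_length < 1L) abort("`min_length` must be >= 1")
  dt <- proteome_runs(records$id, records$sequence)
  dt <- dt[dt$length >= min_length, ]
  tibble::tibble(protein_id = dt$protein_id, amino_acid = dt$amino_acid,
                 start = dt$start, end = dt$start + dt$length - 1L,
                 length = dt$length)
}

#' Longest homo-repeat per protein and amino acid
#'
#' For every protein and every one of the 20 canonical amino acids, the
#' length of the longest maximal run (0 when the amino acid is absent).
#' This is the longest-run statistic M on which all observed counts and
#' enrichment tests are built.
#'
#' @param records Tibble of protein records (`id`, `sequence`).
#' @return Tibble `protein_id`, `amino_acid`, `longest` with exactly
#'   `20 * nrow(records)` rows.
#' @examples
#' recs <- tibble::tibble(id = "p", sequence = "QQQAQQ")
#' dplyr::filter(longest_run_table(recs), longest > 0)
#' @export
longest_run_table <- function(records) {
  check_records(records)
  dt <- proteome_runs(records$id, records$sequence)
  agg <- dt[, list(longest = max(length)), by = list(protein_id, amino_acid)]
  full <- CJ(protein_id = records$id, amino_acid = AA20, sorted = FALSE)
  out <- agg[full, on = c("protein_id", "amino_acid")]
  out$longest[is.na(out$longest)] <- 0L
  tibble::as_tibble(out[order(match(out$protein_id, records$id),
                              match(out$amino_acid, AA20)), ])
}

#' Count proteins by longest-run length
#'
#' Tabulates, for one amino acid, how many proteins have a given longest-run
#' length M. `mode = "exact"` counts proteins whose longest run equals M;
#' `mode = "at_least"` counts proteins whose longest run is at least M
#' (the cumulative tail, non-increasing in M).
#'
#' @param table A longest-run table from [longest_run_table()].
#' @param amino_acid One canonical amino-acid letter.
#' @param mode `"exact"` or `"at_least"`.
#' @return Tibble `M`, `count`, dense over `M = 0 .. max(longest)` observed
#'   for that amino acid.
#' @export
observed_counts <- function(table, amino_acid, mode = c("exact", "at_least")) {
  mode <- match.arg(mode)
  if (!amino_acid %in% AA20) {
    abort(paste0("unknown amino acid: ", amino_acid))
  }
  stopifnot(is.data.frame(table),
            all(c("protein_id", "amino_acid", "longest") %in% names(table)))
  vals <- table$longest[table$amino_acid == amino_acid]
  if (length(vals) == 0L) {
    return(tibble::tibble(M = integer(), count = integer()))
  }
  mmax <- max(vals)
  m <- 0:mmax
  exact <- vapply(m, function(k) sum(vals == k), integer(1))
  if (mode == "exact") {
    tibble::tibble(M = m, count = exact)
  } else {
    tibble::tibble(M = m, count = rev(cumsum(rev(exact))))
  }
}

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c("protein_id", "amino_acid", "longest"))
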