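# End-to-end orchestration: profile -> scan -> expected counts -> fold
# comparison -> minimal significant lengths, with optional disease,
# target-set and interaction stages. All outputs are TSV with a '#' manifest
# header; logs go to stderr, never into data files.

#' Run the full homo-repeat analysis on a FASTA file
#'
#' Executes the complete pipeline and writes one TSV per stage into
#' `out_dir`: `profile.tsv` (length counts and amino-acid frequencies),
#' `catalogue.tsv` (all maximal runs of at least `min_length`),
#' `expected_observed.tsv` (per amino acid and repeat length, observed and
#' expected protein counts with fold ratios), `minimal_lengths.tsv` (the
#' 10-fold-rule minimal significant length per amino acid, dash when none).
#' When `labels` is given, `disease.tsv` adds the contingency Z-score per
#' amino acid; when `target_ids` is given, `enrichment.tsv` adds the
#' resampling enrichment table; when `edges` is given, `partners.tsv` adds
#' the interaction-degree summary per repeat class. Every output carries a
#' '#'-prefixed manifest (parameters, input paths, package version). On any
#' stage error, already-written outputs are removed.
#'
#' @param fasta Path to the input proteome FASTA.
#' @param out_dir Output directory (created if missing).
#' @param labels Optional disease labels: a TSV path or data frame with
#'   columns `id`, `label` (0/1).
#' @param target_ids Optional target set: a character vector of protein
#'   ids, or a path to a one-id-per-line text file ('#' comments allowed).
#' @param edges Optional interaction edges: a TSV path (two id columns,
#'   '#' comments) or data frame.
#' @param min_length Minimum run length for the catalogue (default 5).
#' @param fold_threshold Fold-ratio threshold of the 10-fold rule.
#' @param min_observed Minimum observed count for the 10-fold rule.
#' @param qualifying_length Repeat length from which a protein counts as
#'   repeat-bearing in the disease test (default 5).
#' @param lengths Motif lengths for the resampling stage (default 4:9).
#' @param n_samples Random extractions for the resampling stage.
#' @param seed Integer seed, required when `target_ids` is given.
#' @param counting `"exact"` or `"at_least"` observed counting for the
#'   fold comparison (default exact: proteins counted once, at their
#'   longest run).
#' @return Invisibly, a named list of the stage tibbles plus `paths`.
#' @export
run_analysis <- function(fasta, out_dir, labels = NULL, target_ids = NULL,
                         edges = NULL, min_length = 5L, fold_threshold = 10,
                         min_observed = 1L, qualifying_length = 5L,
                         lengths = 4:9, n_samples = 20L, seed = NULL,
                         counting = c("exact", "at_least")) {
  counting <- match.arg(counting)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  manifest <- c(
    sprintf("# polyrun %s", as.character(utils::packageVersion("polyrun"))),
    sprintf("# input=%s", fasta),
    sprintf("# min_length=%d fold_threshold=%g min_observed=%d", min_length,
            fold_threshold, min_observed),
    sprintf("# qualifying_length=%d n_samples=%d seed=%s counting=%s",
            qualifying_length, n_samples,
            if (is.null(seed)) "NA" else as.character(seed), counting)
  )
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) replace(col, is.infinite(col), NA) else col
    })
    writeLines(manifest, path)
    suppressWarnings(readr::write_tsv(df, path, append = TRUE,
                                      col_names = TRUE))
    written <<- c(written, path)
    path
  }
  stage <- function(label, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("stage '", label, "' failed: ", conditionMessage(e)))
    })
    message(sprintf("[polyrun] %s done in %.2fs", label,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  records <- stage("read", read_fasta(fasta))
  profile <- stage("profile", profile_proteome(records))
  stage("write-profile", write_profile_tsv(profile, file.path(out_dir, "profile.tsv")))
  written <- c(written, file.path(out_dir, "profile.tsv"))
  catalogue <- stage("scan", scan_repeats(records, min_length = min_length))
  emit(catalogue, "catalogue.tsv")
  lrt <- stage("longest-runs", longest_run_table(records))

  comp <- stage("compare", {
    present <- profile$aa_frequencies$amino_acid[
      profile$aa_frequencies$frequency > 0]
    obs_list <- purrr::map(present, ~ observed_counts(lrt, .x, mode = counting))
    names(obs_list) <- present
    mx <- max(c(purrr::map_int(obs_list, ~ max(c(.x$M, 0L))),
                qualifying_length)) + 2L
    exp_all <- expected_counts(profile, present, method = "exact", m_max = mx)
    purrr::map(present, function(aa) {
      fold_comparison(obs_list[[aa]],
                      dplyr::filter(exp_all, .data$amino_acid == aa))
    }) |> dplyr::bind_rows()
  })
  emit(comp, "expected_observed.tsv")

  minimal <- stage("minimal-lengths", {
    comp |>
      dplyr::group_by(.data$amino_acid) |>
      dplyr::group_modify(~ tibble::tibble(
        minimal_length = minimal_significant_length(
          .x, fold_threshold = fold_threshold,
          min_observed = min_observed))) |>
      dplyr::ungroup()
  })
  emit(dplyr::mutate(minimal,
                     minimal_length = ifelse(is.na(.data$minimal_length), "-",
                                             as.character(.data$minimal_length))),
       "minimal_lengths.tsv")

  out <- list(records = records, profile = profile, catalogue = catalogue,
              longest_runs = lrt, expected_observed = comp, minimal = minimal)

  if (!is.null(labels)) {
    disease <- stage("disease", {
      lab <- if (is.data.frame(labels)) labels else read_labels_tsv(labels)
      if (!all(c("id", "label") %in% names(lab))) {
        abort("labels need columns `id`, `label`")
      }
      flagged <- lab$id[lab$label == 1]
      N <- nrow(records)
      N_a <- length(intersect(flagged, records$id))
      cont <- lrt |>
        dplyr::filter(.data$longest >= qualifying_length) |>
        dplyr::group_by(.data$amino_acid) |>
        dplyr::summarise(
          N_b = dplyr::n_distinct(.data$protein_id),
          N_ab = dplyr::n_distinct(intersect(.data$protein_id, flagged)),
          .groups = "drop") |>
        dplyr::mutate(N = N, N_a = N_a)
      association_z(cont)
    })
    emit(disease, "disease.tsv")
    out$disease <- disease
  }

  if (!is.null(target_ids)) {
    enrich <- stage("resample", {
      if (is.null(seed)) abort("`seed` is required for the resampling stage")
      tids <- if (length(target_ids) == 1L && file.exists(target_ids)) {
        l <- trimws(readLines(target_ids))
        l[nzchar(l) & !startsWith(l, "#")]
      } else as.character(target_ids)
      resample_enrichment(tids, lrt, lengths = lengths,
                          n_samples = n_samples, seed = seed)
    })
    emit(enrich, "enrichment.tsv")
    out$enrichment <- enrich
  }

  if (!is.null(edges)) {
    partners <- stage("partners", {
      ed <- if (is.data.frame(edges)) edges else read_edge_list(edges)
      rep_groups <- lrt |>
        dplyr::filter(.data$longest >= qualifying_length)
      groups <- split(rep_groups$protein_id, rep_groups$amino_acid)
      groups <- groups[vapply(groups, length, 0L) > 0]
      partner_summary(ed, groups, universe = records$id)
    })
    emit(partners, "partners.tsv")
    out$partners <- partners
  }

  out$paths <- written
  invisible(out)
}

read_labels_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(id = readr::col_character(),
                                          label = readr::col_integer()))
}

#' Read an interaction edge list TSV
#'
#' Two tab-separated id columns, '#' comment lines allowed, no header.
#'
#' @param path File path.
#' @return Tibble `from`, `to`.
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, comment = "#", col_names = c("from", "to"),
                  col_types = "cc", show_col_types = FALSE)
}

#' Load per-amino-acid contingency counts
#'
#' Turns a table of per-amino-acid totals (repeat-bearing proteins) and
#' annotated counts into validated contingency rows ready for
#' [association_z()]. Input columns: `amino_acid`, `N_b` (proteins with a
#' qualifying homo-repeat), `N_ab` (of those, annotated e.g. with a
#' disease).
#'
#' @param table A TSV path ('#' comments allowed) or data frame.
#' @param N Proteome size.
#' @param N_a Number of annotated proteins in the proteome.
#' @return Tibble `amino_acid`, `N`, `N_a`, `N_b`, `N_ab`.
#' @export
load_contingency <- function(table, N, N_a) {
  df <- if (is.data.frame(table)) {
    tibble::as_tibble(table)
  } else {
    readr::read_tsv(table, comment = "#", show_col_types = FALSE)
  }
  if (nrow(df) == 0L) {
    return(tibble::tibble(amino_acid = character(), N = integer(),
                          N_a = integer(), N_b = integer(),
                          N_ab = integer()))
  }
  if (!all(c("amino_acid", "N_b", "N_ab") %in% names(df))) {
    abort("contingency table needs columns `amino_acid`, `N_b`, `N_ab`")
  }
  if (nrow(df) > 20L) abort("at most one row per canonical amino acid")
  bad <- df$N_ab > df$N_b | df$N_b > N | df$N_ab > N_a |
    df$N_b < 0 | df$N_ab < 0
  if (any(bad)) {
    abort(paste0("invalid contingency row for amino acid ",
                 df$amino_acid[bad][1L],
                 ": need 0 <= N_ab <= min(N_a, N_b) and N_b <= N"))
  }
  tibble::tibble(amino_acid = df$amino_acid, N = as.integer(N),
                 N_a = as.integer(N_a), N_b = as.integer(df$N_b),
                 N_ab = as.integer(df$N_ab))
}

#' Human OMIM homo-repeat contingency counts
#'
#' The published per-amino-acid counts of human proteins carrying a
#' homo-repeat of length at least 5 (`N_b`) and, of those, proteins with an
#' OMIM disease annotation (`N_ab`), in a proteome of N = 59053 proteins of
#' which N_a = 2501 are disease-annotated. Shipped as a plain-text table so
#' the disease-association banding can be reproduced without any download.
#'
#' @return Tibble `amino_acid`, `N`, `N_a`, `N_b`, `N_ab` (20 rows), ready
#'   for [association_z()].
#' @examples
#' association_z(human_disease_counts())
#' @export
human_disease_counts <- function() {
  path <- system.file("extdata", "human_omim_repeat_counts.tsv",
                      package = "polyrun", mustWork = TRUE)
  load_contingency(path, N = 59053L, N_a = 2501L)
}
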