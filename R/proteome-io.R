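# FASTA input/output and proteome composition profiles.

#' Read protein sequences from a FASTA file
#'
#' Parses a protein FASTA file into a tibble with one row per record.
#' Sequences are uppercased and sanitized: stop codons (`*`) and gap
#' characters (`-`) are stripped from either end (a common artifact of
#' translated proteome files) and rejected when internal. Characters outside
#' the 20 canonical amino acids plus the tolerated ambiguity codes
#' (X, B, Z, U, O) are a parse error reported with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, possibly empty)
#'   and `sequence` (sanitized uppercase amino-acid string).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "QQQA"), f)
#' read_fasta(f)
#' @seealso [write_fasta()], [profile_proteome()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) abort(paste0("empty FASTA file: ", path))
  hdr <- startsWith(trimws(lines), ">")
  first <- nonblank[1L]
  if (!hdr[first]) {
    abort(paste0("not FASTA: expected '>' header at line ", first,
                 " of ", path))
  }
  hdr_idx <- which(hdr)
  rec_of_line <- cumsum(hdr)
  headers <- sub("^>", "", trimws(lines[hdr_idx]))
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S+", "", headers))
  if (any(!nzchar(ids))) {
    abort(paste0("empty record id at line ", hdr_idx[!nzchar(ids)][1L]))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record id: ", ids[duplicated(ids)][1L]))
  }

  seq_lines <- toupper(gsub("\\s", "", lines))
  seq_lines[hdr] <- ""
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYXBZUO*-]*$", seq_lines)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    abort(paste0("illegal sequence character at line ", bad, " of ", path))
  }
  seqs <- vapply(split(seq_lines, rec_of_line), paste, character(1),
                 collapse = "")
  seqs <- seqs[as.character(seq_along(ids))]
  out <- tibble::tibble(id = ids, description = desc,
                        sequence = unname(seqs))
  out$sequence <- sanitize_sequences(out$sequence, out$id)
  if (any(!nzchar(out$sequence))) {
    abort(paste0("record with empty sequence: ",
                 out$id[!nzchar(out$sequence)][1L]))
  }
  out
}

# strip terminal '*' / '-' and reject internal occurrences
sanitize_sequences <- function(seqs, ids) {
  s <- gsub("^[*-]+|[*-]+$", "", toupper(seqs))
  bad <- grepl("[*-]", s)
  if (any(bad)) {
    abort(paste0("internal stop/gap character in record: ", ids[bad][1L]))
  }
  s
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()] or [sample_null_proteome()].
#' @param path Output file path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  check_records(records)
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  chunks <- purrr::map2(records$sequence, hdr, function(s, h) {
    starts <- seq.int(1L, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

check_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence") %in% names(records))) {
    abort("`records` must be a data frame with columns `id` and `sequence`")
  }
  if (nrow(records) == 0L) abort("`records` is empty")
  if (anyDuplicated(records$id)) abort("duplicate ids in `records`")
  invisible(records)
}

#' Summarize a proteome into length counts and amino-acid frequencies
#'
#' Computes the two ingredients the null model needs: the protein length
#' distribution (counts per chain length) and the background frequency of
#' each of the 20 canonical amino acids. Under the default
#' `"drop_ambiguous"` policy the ambiguity codes X/B/Z/U/O are excluded
#' from both numerator and denominator of the frequencies (sequences are
#' kept); `"strict20"` refuses any non-canonical residue.
#'
#' @param records Tibble of protein records (see [read_fasta()]).
#' @param alphabet_policy `"drop_ambiguous"` (default) or `"strict20"`.
#' @return An object of class `proteome_profile`: a list with
#'   `length_counts` (tibble `length`, `count`), `aa_frequencies`
#'   (tibble `amino_acid`, `frequency`, all 20 canonical letters),
#'   `n_proteins` and `n_residues`.
#' @examples
#' recs <- tibble::tibble(id = c("a", "b"), sequence = c("QQ", "AA"))
#' profile_proteome(recs)
#' @export
profile_proteome <- function(records,
                             alphabet_policy = c("drop_ambiguous", "strict20")) {
  check_records(records)
  alphabet_policy <- match.arg(alphabet_policy)
  lens <- nchar(records$sequence)
  chars <- strsplit(paste(records$sequence, collapse = ""), "", fixed = TRUE)[[1]]
  if (alphabet_policy == "strict20" && any(chars %in% AA_AMBIG)) {
    abort("strict20 policy: non-canonical residue codes present (X/B/Z/U/O)")
  }
  counts <- table(factor(chars, levels = AA20))
  n_canon <- sum(counts)
  if (n_canon == 0L) abort("no canonical residues in input; cannot profile")
  lc <- dplyr::count(tibble::tibble(length = lens), .data$length,
                     name = "count")
  structure(
    list(
      length_counts = lc,
      aa_frequencies = tibble::tibble(amino_acid = AA20,
                                      frequency = as.numeric(counts) / n_canon),
      n_proteins = nrow(records),
      n_residues = sum(lens)
    ),
    class = "proteome_profile"
  )
}

#' @export
print.proteome_profile <- function(x, ...) {
  cat("<proteome_profile>\n")
  cat("  proteins:", x$n_proteins, "  residues:", x$n_residues, "\n")
  cat("  mean length:", round(mean_length(x), 1),
      " sd:", round(sd_length(x), 1), "\n")
  top <- dplyr::slice_max(x$aa_frequencies, .data$frequency, n = 3)
  cat("  top frequencies:",
      paste(sprintf("%s=%.3f", top$amino_acid, top$frequency), collapse = " "),
      "\n")
  invisible(x)
}

mean_length <- function(profile) {
  with(profile$length_counts, sum(length * count) / sum(count))
}

sd_length <- function(profile) {
  m <- mean_length(profile)
  with(profile$length_counts,
       sqrt(sum(count * (length - m)^2) / max(1, sum(count) - 1)))
}

#' @describeIn profile_proteome Tidy the profile into one long tibble
#'   (`statistic` is `"length_count"` or `"aa_frequency"`).
#' @param x A `proteome_profile`.
#' @param ... Unused.
#' @export
tidy.proteome_profile <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(statistic = "length_count",
                   key = as.character(x$length_counts$length),
                   value = as.numeric(x$length_counts$count)),
    tibble::tibble(statistic = "aa_frequency",
                   key = x$aa_frequencies$amino_acid,
                   value = x$aa_frequencies$frequency)
  )
}

#' @describeIn profile_proteome One-row summary of the profiled proteome.
#' @export
glance.proteome_profile <- function(x, ...) {
  tibble::tibble(
    n_proteins = x$n_proteins,
    n_residues = x$n_residues,
    mean_length = mean_length(x),
    sd_length = sd_length(x),
    max_frequency = max(x$aa_frequencies$frequency)
  )
}

#' @describeIn profile_proteome Plot the length distribution
#'   (`which = "lengths"`) or amino-acid frequencies (`which = "frequencies"`).
#' @param object A `proteome_profile`.
#' @param which Panel to draw.
#' @export
autoplot.proteome_profile <- function(object,
                                      which = c("lengths", "frequencies"),
                                      ...) {
  which <- match.arg(which)
  if (which == "lengths") {
    ggplot2::ggplot(object$length_counts,
                    ggplot2::aes(x = .data$length, y = .data$count)) +
      ggplot2::geom_col(width = 1, fill = "grey30") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "protein length (residues)", y = "proteins",
                    title = "Protein length distribution")
  } else {
    ggplot2::ggplot(object$aa_frequencies,
                    ggplot2::aes(x = .data$amino_acid, y = .data$frequency)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "amino acid", y = "background frequency",
                    title = "Amino-acid frequencies")
  }
}

#' Write / read a proteome profile as TSV
#'
#' The file has two '#'-tagged sections: `#lengths` (length, count) and
#' `#frequencies` (amino acid, frequency).
#'
#' @param profile A `proteome_profile`.
#' @param path File path.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a `proteome_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "proteome_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#lengths", con)
  writeLines(sprintf("%d\t%d", profile$length_counts$length,
                     profile$length_counts$count), con)
  writeLines("#frequencies", con)
  writeLines(sprintf("%s\t%.12g", profile$aa_frequencies$amino_acid,
                     profile$aa_frequencies$frequency), con)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  i_len <- match("#lengths", lines)
  i_frq <- match("#frequencies", lines)
  if (is.na(i_len) || is.na(i_frq) || i_frq <= i_len) {
    abort("malformed profile TSV: need '#lengths' then '#frequencies' sections")
  }
  parse2 <- function(chunk) {
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "#")]
    parts <- strsplit(chunk, "\t", fixed = TRUE)
    list(k = vapply(parts, `[`, character(1), 1L),
         v = as.numeric(vapply(parts, `[`, character(1), 2L)))
  }
  len <- parse2(lines[(i_len + 1):(i_frq - 1)])
  frq <- parse2(lines[(i_frq + 1):length(lines)])
  lc <- tibble::tibble(length = as.integer(len$k), count = as.integer(len$v))
  af <- tibble::tibble(amino_acid = frq$k, frequency = frq$v) |>
    dplyr::right_join(tibble::tibble(amino_acid = AA20), by = "amino_acid") |>
    tidyr::replace_na(list(frequency = 0))
  structure(
    list(length_counts = lc, aa_frequencies = af,
         n_proteins = sum(lc$count),
         n_residues = sum(lc$length * lc$count)),
    class = "proteome_profile"
  )
}

#' Construct a proteome profile from summary statistics
#'
#' Builds the same object as [profile_proteome()] directly from a length
#' distribution and an amino-acid frequency vector, for studying null
#' expectations at proteome scales without materializing sequences (e.g.
#' 59053 chains of mean length 395).
#'
#' @param length_counts Tibble or data frame with columns `length`, `count`.
#' @param aa_frequencies Named numeric vector over canonical amino acids
#'   summing to 1; default uniform 1/20.
#' @return A `proteome_profile`.
#' @examples
#' as_proteome_profile(tibble::tibble(length = 395, count = 59053))
#' @export
as_proteome_profile <- function(length_counts, aa_frequencies = NULL) {
  stopifnot(is.data.frame(length_counts),
            all(c("length", "count") %in% names(length_counts)))
  if (any(length_counts$length < 1) || any(length_counts$count < 0)) {
    abort("lengths must be >= 1 and counts >= 0")
  }
  fq <- check_aa_freq(aa_frequencies)
  af <- tibble::tibble(amino_acid = AA20,
                       frequency = unname(fq[AA20]))
  af$frequency[is.na(af$frequency)] <- 0
  lc <- tibble::tibble(length = as.integer(length_counts$length),
                       count = as.integer(length_counts$count))
  structure(
    list(length_counts = lc, aa_frequencies = af,
         n_proteins = sum(lc$count),
         n_residues = sum(as.numeric(lc$length) * lc$count)),
    class = "proteome_profile"
  )
}
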