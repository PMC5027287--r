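#' PAM-plus-seed query sequence
#'
#' A query over the alphabet `A`, `C`, `G`, `T`, `N`, e.g. eight
#' protospacer-proximal bases followed by the `NGG` PAM. `N` positions are
#' wildcards; `n_specified` counts the non-`N` positions and drives the
#' random-sequence expectation `(1/4)^n_specified`.
#'
#' @param sequence query string (case-insensitive).
#' @return A `seed_query` with fields `sequence` and `n_specified`.
#' @examples
#' seed_query("GTCACCTCNGG")$n_specified  # 8 seed bases + GG of the PAM
#' @export
seed_query <- function(sequence) {
  sequence <- toupper(as.character(sequence)[1])
  if (nchar(sequence) < 1) stop("query must have length >= 1")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid character(s) in query: ", paste(bad, collapse = ", "))
  structure(list(sequence = sequence,
                 n_specified = sum(chars != "N")),
            class = "seed_query")
}

#' Count query occurrences in a genome
#'
#' Sliding-window exact matching of the query against the forward strand
#' and (by default) the reverse complement of every FASTA record.
#' Overlapping matches are counted; matches never span record boundaries.
#' `N` in the query is a wildcard for any unambiguous base; an ambiguous
#' genome base (`N`) never matches a specified query base (it matches a
#' query `N` only, the subset-matching convention recorded in the result).
#'
#' @param genome path to a FASTA file (plain or gzip) or a
#'   [Biostrings::DNAStringSet].
#' @param query a [seed_query()] or query string.
#' @param both_strands count the reverse complement too (default `TRUE`).
#' @param double_strand_expectation multiply the single-strand random
#'   expectation by two for comparability with a two-strand actual count
#'   (default follows `both_strands`).
#' @param positions also return the forward-strand match coordinates
#'   (1-based, inclusive) per record.
#' @return A `genome_count_result`: `actual_count`, `probabilistic_count`,
#'   `genome_length_bp`, `query`, `strand_convention`, and optionally
#'   `match_positions`.
#' @examples
#' \dontrun{
#' count_matches("genome.fa", seed_query("GTCACCTCNGG"))
#' }
#' @export
count_matches <- function(genome, query, both_strands = TRUE,
                          double_strand_expectation = both_strands,
                          positions = FALSE) {
  if (!inherits(query, "seed_query")) query <- seed_query(query)
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(inherits(genome, "DNAStringSet"))
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
    stop("genome is empty")
  pat <- Biostrings::DNAString(query$sequence)
  L <- sum(Biostrings::width(genome))

  # fixed = "subject": IUPAC codes in the pattern are expanded, genome
  # letters are literal, so pattern N matches A/C/G/T/N and a genome N is
  # matched by nothing narrower than N.
  fwd <- sum(Biostrings::vcountPattern(pat, genome, fixed = "subject"))
  rev_n <- 0L
  if (both_strands) {
    rc <- Biostrings::reverseComplement(genome)
    rev_n <- sum(Biostrings::vcountPattern(pat, rc, fixed = "subject"))
  }
  expected <- probabilistic_count(query, L,
                                  double_strand = double_strand_expectation)

  out <- list(actual_count = fwd + rev_n,
              forward_count = fwd,
              reverse_count = rev_n,
              probabilistic_count = expected,
              genome_length_bp = L,
              query = query$sequence,
              n_specified = query$n_specified,
              strand_convention = if (both_strands) "both" else "forward",
              expectation_strands = if (double_strand_expectation) 2L else 1L)
  if (positions) {
    hits <- Biostrings::vmatchPattern(pat, genome, fixed = "subject")
    tabs <- lapply(seq_along(genome), function(i) {
      ir <- as.data.frame(hits[[i]])
      if (nrow(ir) == 0) return(NULL)
      rec <- if (is.null(names(genome))) as.character(i) else names(genome)[i]
      data.frame(record = rec, start = ir$start, end = ir$end,
                 strand = "+", stringsAsFactors = FALSE)
    })
    out$match_positions <- do.call(rbind, tabs)
  }
  structure(out, class = "genome_count_result")
}

#' @export
print.genome_count_result <- function(x, ...) {
  cat(sprintf(
    "Query %s (%d specified bases) in %s bp genome (%s strand%s):\n",
    x$query, x$n_specified, format(x$genome_length_bp, big.mark = ","),
    x$strand_convention, if (x$strand_convention == "both") "s" else ""))
  cat(sprintf("  actual count: %d   probabilistic count: %.4g\n",
              x$actual_count, x$probabilistic_count))
  invisible(x)
}

#' Random-sequence expectation of query occurrences
#'
#' `probabilistic_count = (1/4)^n * L`, where `n` is the number of
#' specified (non-`N`) query positions, each unambiguous base occurring
#' with probability 1/4, and `L` the genome length in bp. The formula is a
#' per-strand expectation; set `double_strand = TRUE` to compare with an
#' actual count taken over both strands.
#'
#' @param query a [seed_query()] or query string.
#' @param genome_length genome size in bp (> 0).
#' @param double_strand double the expectation (default `FALSE`).
#' @return expected number of occurrences.
#' @examples
#' probabilistic_count("NN", 100)       # 100: wildcards are free
#' probabilistic_count("AC", 16)        # 1
#' @export
probabilistic_count <- function(query, genome_length, double_strand = FALSE) {
  if (!inherits(query, "seed_query")) query <- seed_query(query)
  if (!is.finite(genome_length) || genome_length <= 0)
    stop("`genome_length` must be > 0")
  0.25^query$n_specified * genome_length * (if (double_strand) 2 else 1)
}

#' Write genome-count results
#'
#' JSON summary plus an optional BED file of forward-strand match
#' positions (BED is 0-based half-open).
#'
#' @param result a [count_matches()] result.
#' @param json_path output JSON path.
#' @param bed_path optional BED path (requires `positions = TRUE` in
#'   [count_matches()]).
#' @return `json_path`, invisibly.
#' @export
write_count_result <- function(result, json_path, bed_path = NULL) {
  stopifnot(inherits(result, "genome_count_result"))
  jsonlite::write_json(
    result[c("query", "n_specified", "actual_count", "forward_count",
             "reverse_count", "probabilistic_count", "genome_length_bp",
             "strand_convention", "expectation_strands")],
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(bed_path)) {
    mp <- result$match_positions
    if (is.null(mp)) stop("no match positions recorded; rerun with positions = TRUE")
    bed <- data.frame(mp$record, mp$start - 1L, mp$end, ".", 0L, mp$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(json_path)
}
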