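#' Count guides in amplicon reads by exact spacer matching
#'
#' Assigns each read to at most one guide by scanning for an exact 20-mer
#' spacer match inside a user-supplied search window of the read. Exact
#' matching keeps the assignment deterministic and auditable; there is no
#' mismatch tolerance. Reads matching spacers of two or more guides are
#' left unassigned, as are reads matching none, so that
#' `sum(assigned) + unassigned == n_reads` always holds. Amplicon
#' structure (stagger, vector handles) varies by protocol, so the window
#' is a required argument with no default.
#'
#' @param fastq_path path to a FASTQ file (gzip-transparent, 4-line
#'   records).
#' @param library a `guide_library` supplying the spacers.
#' @param search_window integer pair `c(start, end)`, 1-based positions in
#'   the read between which a spacer match may begin and end; e.g.
#'   `c(1, 30)` scans the first 30 bases.
#' @param revcomp also scan the reverse complement of each read
#'   (default `FALSE`; amplicon orientation is protocol-dependent).
#' @return List with `counts` (named integer vector per guide) and
#'   `n_unassigned`.
#' @examples
#' lib <- build_library(2, 2, 1, 0, seed = 1)
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", lib$spacer[1], "+", strrep("I", 20)), fq)
#' count_guides_from_fastq(fq, lib, search_window = c(1, 20))
#' @export
count_guides_from_fastq <- function(fastq_path, library, search_window,
                                    revcomp = FALSE) {
  stopifnot(inherits(library, "guide_library"))
  if (!file.exists(fastq_path)) {
    is_abort(paste0("file not found: ", fastq_path),
             "isletscreen_config_error")
  }
  if (!is.numeric(search_window) || length(search_window) != 2 ||
      search_window[1] < 1 || search_window[2] < search_window[1]) {
    is_abort("search_window must be c(start, end) with 1 <= start <= end",
             "isletscreen_config_error")
  }
  validate_fastq_structure(fastq_path)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq_path, format = "fastq"),
    error = function(e) {
      is_abort(paste0("malformed FASTQ ", fastq_path, ": ",
                      conditionMessage(e)),
               "isletscreen_data_error")
    }
  )
  counts <- stats::setNames(integer(nrow(library)), library$guide_id)
  if (length(reads) == 0) {
    return(list(counts = counts, n_unassigned = 0L))
  }

  # Clip each read to the search window, then count exact spacer hits with
  # a preprocessed dictionary; a read's assignment is the unique matching
  # spacer, if any.
  hits <- window_hits(reads, library$spacer, search_window)
  if (revcomp) {
    hits <- hits + window_hits(Biostrings::reverseComplement(reads),
                               library$spacer, search_window)
  }
  n_matched <- colSums(hits > 0)        # spacers matched per read
  unique_hit <- n_matched == 1L
  if (any(unique_hit)) {
    idx <- apply(hits[, unique_hit, drop = FALSE] > 0, 2, which.max)
    tab <- tabulate(idx, nbins = nrow(library))
    counts <- counts + stats::setNames(as.integer(tab), library$guide_id)
  }
  list(counts = counts,
       n_unassigned = as.integer(sum(!unique_hit)))
}

# Structural FASTQ validation (4-line records, '@' headers, '+'
# separators, sequence/quality length agreement), gzip-transparent.
# Biostrings tolerates some truncations silently, so malformed records are
# rejected here, with the failing record's index.
validate_fastq_structure <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    is_abort(sprintf("malformed FASTQ %s: %d lines, record %d truncated",
                     path, length(lines), length(lines) %/% 4 + 1),
             "isletscreen_data_error")
  }
  n_rec <- length(lines) %/% 4
  if (n_rec == 0) return(invisible(TRUE))
  heads <- lines[seq(1, length(lines), by = 4)]
  seps <- lines[seq(3, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad) > 0) {
    is_abort(sprintf("malformed FASTQ %s at record %d", path, bad[1]),
             "isletscreen_data_error")
  }
  invisible(TRUE)
}

# pattern x read indicator matrix of exact spacer occurrences within the
# window (window bounds clamped to read length; reads shorter than the
# spacer never match).
window_hits <- function(reads, spacers, search_window) {
  widths <- Biostrings::width(reads)
  start <- pmin(search_window[1], widths)
  end <- pmin(search_window[2], widths)
  windows <- Biostrings::subseq(reads, start = start, end = end)
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(spacers))
  m <- Biostrings::vcountPDict(pdict, windows)
  m
}
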