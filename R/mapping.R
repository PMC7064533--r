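#' Read mature miRNA reference sequences from FASTA
#'
#' Reads a miRBase-style FASTA of mature sequences. Identifiers are the
#' first whitespace-delimited token of each header. Sequences are
#' canonicalized to uppercase DNA alphabet (U -> T); any character outside
#' A/C/G/T/U is rejected.
#'
#' @param path FASTA file path.
#' @return Named character vector of canonicalized sequences.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- canonicalize_seq(as.character(set))
  names(seqs) <- ids
  if (anyDuplicated(ids))
    stop("duplicated sequence identifier(s) in ", path)
  seqs
}

# U/T and case canonicalization; validates the alphabet.
canonicalize_seq <- function(x) {
  up <- chartr("u", "U", toupper(x))
  up <- chartr("U", "T", up)
  bad <- grepl("[^ACGT]", up)
  if (any(bad))
    stop("sequence(s) contain characters outside A/C/G/T/U: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  up
}

#' Define a probe signature for cross-platform mapping
#'
#' @param name signature label (e.g. `"5-miRNA profile"`).
#' @param probes named character vector: probe id -> probe sequence.
#' @param intended_features optional miRNA identifiers the probes are meant
#'   to represent.
#' @return An object of class `signature_definition`.
#' @export
signature_definition <- function(name, probes, intended_features = character()) {
  if (is.null(names(probes)) || any(names(probes) == ""))
    stop("`probes` must be a named character vector (probe_id -> sequence)")
  seqs <- canonicalize_seq(probes)
  structure(list(name = name, probes = seqs, intended_features = intended_features),
            class = "signature_definition")
}

# Longest exact common substring of a (short) probe within a reference,
# returned as c(offset_in_reference_1based, length) or NULL if < k.
longest_exact_match <- function(probe, reference, k) {
  np <- nchar(probe)
  best <- NULL
  # scan probe substrings from longest to shortest; stop at first hit
  for (len in seq(np, k)) {
    for (start in seq_len(np - len + 1L)) {
      sub <- substr(probe, start, start + len - 1L)
      pos <- regexpr(sub, reference, fixed = TRUE)
      if (pos > 0L) return(c(offset = as.integer(pos), length = len))
    }
  }
  best
}

#' Map probe signatures onto reference sequences by exact k-mer homology
#'
#' A probe maps to a reference sequence iff some contiguous substring of
#' the probe of length >= `k` occurs exactly in the reference, after U/T
#' and case canonicalization. All matching references are reported; probes
#' matching more than one reference are flagged ambiguous rather than
#' resolved silently.
#'
#' @param sig a [signature_definition()].
#' @param references named character vector of reference sequences (see
#'   [read_mirna_fasta()]).
#' @param k minimum exact-match length in bases (default 18).
#' @return A data.frame with one row per (probe, matching reference):
#'   `probe_id`, `feature_id` (NA when unmatched), `offset` (1-based
#'   position of the match in the reference), `length` (bases matched,
#'   >= k), `ambiguous`.
#' @export
map_signature <- function(sig, references, k = 18) {
  if (!inherits(sig, "signature_definition")) stop("`sig` must be a signature_definition")
  if (!is.numeric(k) || k < 1) stop("`k` must be >= 1")
  k <- as.integer(k)
  short <- nchar(sig$probes) < k
  if (any(short))
    stop("probe(s) shorter than k=", k, ": ", paste(names(sig$probes)[short], collapse = ", "))
  refs <- canonicalize_seq(references)
  rows <- lapply(names(sig$probes), function(pid) {
    probe <- sig$probes[[pid]]
    hits <- lapply(names(refs), function(rid) {
      m <- longest_exact_match(probe, refs[[rid]], k)
      if (is.null(m)) NULL else data.frame(probe_id = pid, feature_id = rid,
                                           offset = m[["offset"]], length = m[["length"]])
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits))
      return(data.frame(probe_id = pid, feature_id = NA_character_,
                        offset = NA_integer_, length = NA_integer_, ambiguous = FALSE))
    hits$ambiguous <- nrow(hits) > 1L
    hits
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname map_signature
#' @param mapping a mapping result from `map_signature()`.
#' @param path output TSV path.
#' @export
write_mapping <- function(mapping, path) {
  utils::write.table(mapping, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
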