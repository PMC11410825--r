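#' Read protein sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a protein collection. Sequences are
#' uppercased and validated against the 20-letter canonical amino-acid
#' alphabet; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param on_invalid What to do with a record containing a non-canonical
#'   residue: `"error"` (default) aborts naming the offending position;
#'   `"skip"` drops the record with a warning.
#' @return A data.frame with columns `id` and `sequence`, one row per record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV", ">p2", "ACDEF"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop2("duplicate sequence id in FASTA: ", ids[duplicated(ids)][1])
  }
  sequences <- toupper(as.character(seqs))
  keep <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    if (nchar(sequences[i]) == 0L) {
      if (on_invalid == "skip") {
        warning("dropping empty record '", ids[i], "'", call. = FALSE)
        keep[i] <- FALSE
        next
      }
      stop2("record '", ids[i], "' has an empty sequence")
    }
    bad <- which(!strsplit(sequences[i], "")[[1]] %in% AA_ALPHABET)
    if (length(bad) > 0) {
      if (on_invalid == "skip") {
        warning("dropping record '", ids[i], "': non-canonical residue at position ",
                bad[1], call. = FALSE)
        keep[i] <- FALSE
      } else {
        stop2("record '", ids[i], "': non-canonical residue '",
              substr(sequences[i], bad[1], bad[1]), "' at position ", bad[1])
      }
    }
  }
  data.frame(id = unname(ids[keep]), sequence = unname(sequences[keep]),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for wrapping sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
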