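#' Read a labeled sequence collection from FASTA plus a label table
#'
#' Sequence identifiers are taken as the first whitespace-delimited word
#' of each FASTA header and matched against a two-column label table
#' (id, label; CSV or TSV with a header row). Labels travel in a
#' separate table rather than in FASTA headers because header
#' conventions drift across database releases.
#'
#' Records containing any of the ambiguity codes B, J, O, U, X, Z are
#' handled according to `policy`: `"drop"` (default) removes the whole
#' record, which is conservative for composition statistics; `"strip"`
#' deletes the offending residues and keeps the record. Either way the
#' number of affected records is reported via a warning.
#'
#' @param fasta_path path to a FASTA file of amino-acid sequences.
#' @param labels_path path to a 2-column CSV/TSV (`id`, `label`) with header.
#' @param policy `"drop"` or `"strip"`; treatment of ambiguous residues.
#' @param ignore optional character vector of ids to discard silently
#'   (e.g. orphan receptors excluded from subtype classification).
#' @param min_length minimum retained sequence length; see [seqset()].
#'
#' @return A [seqset()].
#' @export
read_labeled_fasta <- function(fasta_path, labels_path,
                               policy = c("drop", "strip"),
                               ignore = NULL, min_length = 15L) {
  policy <- match.arg(policy)
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  names(seqs) <- NULL

  labtab <- read_label_table(labels_path)

  if (!is.null(ignore)) {
    keep <- !(ids %in% ignore)
    ids <- ids[keep]; seqs <- seqs[keep]
  }

  missing <- setdiff(ids, labtab$id)
  if (length(missing))
    stop("no label for id(s): ", paste(utils::head(missing, 5), collapse = ", "))

  amb_re <- paste0("[", paste(.AMBIGUOUS, collapse = ""), "]")
  has_amb <- grepl(amb_re, seqs)
  if (any(has_amb)) {
    if (policy == "drop") {
      warning(sum(has_amb), " record(s) with ambiguous residues dropped")
      ids <- ids[!has_amb]; seqs <- seqs[!has_amb]
    } else {
      warning(sum(has_amb), " record(s) had ambiguous residues stripped")
      seqs <- gsub(amb_re, "", seqs)
    }
  }
  short <- nchar(seqs) < min_length
  if (any(short)) {
    warning(sum(short), " record(s) below minimum length ", min_length, " dropped")
    ids <- ids[!short]; seqs <- seqs[!short]
  }
  if (!length(ids)) stop("no records retained")
  lab <- labtab$label[match(ids, labtab$id)]
  seqset(ids, seqs, lab, min_length = min_length)
}

read_label_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) stop("label table must have two columns (id, label)")
  names(tab)[1:2] <- c("id", "label")
  tab[, 1:2]
}

#' Write a labeled sequence set to FASTA plus a label table
#'
#' Inverse of [read_labeled_fasta()]: emits an unwrapped FASTA file and
#' a 2-column CSV label table so that reading them back reproduces the
#' set exactly.
#'
#' @param x a [seqset()].
#' @param fasta_path,labels_path output paths.
#' @return `x`, invisibly.
#' @export
write_labeled_fasta <- function(x, fasta_path, labels_path) {
  stopifnot(inherits(x, "seqset"))
  aa <- Biostrings::AAStringSet(x$sequence)
  names(aa) <- x$id
  Biostrings::writeXStringSet(aa, fasta_path, width = 20000L)
  utils::write.csv(data.frame(id = x$id, label = x$label),
                   labels_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Write a misclassification shortlist report
#'
#' Serializes per-sequence consistency profiles (error rate, voting
#' ratio, cumulative decision value and threshold flags) as CSV, one
#' row per sequence, in the layout of a curation worksheet: id, true
#' class, modal predicted class, the three statistics and the flags.
#'
#' @param profiles a data frame of profiles as returned by
#'   [shortlist()] (possibly empty).
#' @param path output CSV path.
#' @return `profiles`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(profiles, path) {
  cols <- c("id", "true_class", "predicted_class", "er", "r", "cdv",
            "selected", "consistent", "large")
  if (is.null(profiles) || nrow(profiles) == 0) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(profiles))
  }
  stopifnot(all(cols %in% names(profiles)))
  utils::write.csv(profiles[, cols], path, row.names = FALSE)
  invisible(profiles)
}

#' Read back a shortlist report written by [write_report()]
#'
#' @param path CSV path.
#' @return A data frame with the report columns.
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
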