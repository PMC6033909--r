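#' The 20 standard amino-acid one-letter codes
#'
#' Alphabet used throughout the package, in the conventional alphabetical
#' one-letter order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AMBIGUOUS <- c("B", "J", "O", "U", "X", "Z")

#' Construct a labeled sequence set
#'
#' A `seqset` bundles unaligned amino-acid sequences with their class
#' labels. It is the unit of ingestion, synthesis and transformation.
#'
#' @param id character vector of unique sequence identifiers.
#' @param sequence character vector of amino-acid strings over the
#'   20-letter standard alphabet (see [aa_alphabet()]).
#' @param label character vector of class labels, parallel to `id`.
#' @param class_names optional ordered vector of distinct class names;
#'   defaults to the sorted unique labels. Every class must have at
#'   least one record.
#' @param min_length minimum admissible sequence length. The default 15
#'   guarantees every auto-cross covariance term up to the conventional
#'   maximum lag 13 has at least two summands.
#'
#' @return An object of class `seqset`: a list with elements `id`,
#'   `sequence`, `label` and `class_names`.
#' @seealso [read_labeled_fasta()], [generate_sequences()]
#' @export
seqset <- function(id, sequence, label, class_names = NULL, min_length = 15L) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  label <- as.character(label)
  stopifnot(length(id) == length(sequence), length(id) == length(label))
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  bad <- grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), sequence)
  if (any(bad))
    stop("non-standard residues in: ", paste(utils::head(id[bad], 5), collapse = ", "))
  short <- nchar(sequence) < min_length
  if (any(short))
    stop(sum(short), " sequence(s) shorter than the minimum length ", min_length)
  if (is.null(class_names)) class_names <- sort(unique(label))
  if (!all(label %in% class_names))
    stop("labels not in class_names: ", paste(setdiff(label, class_names), collapse = ", "))
  if (!all(class_names %in% label))
    stop("empty class(es): ", paste(setdiff(class_names, label), collapse = ", "))
  structure(
    list(id = id, sequence = sequence, label = label,
         class_names = as.character(class_names)),
    class = "seqset")
}

#' @export
length.seqset <- function(x) length(x$id)

#' @export
print.seqset <- function(x, ...) {
  cat("Labeled sequence set:", length(x), "sequences,",
      length(x$class_names), "classes\n")
  tab <- table(factor(x$label, levels = x$class_names))
  for (cl in x$class_names) cat(sprintf("  %-8s %d\n", cl, tab[[cl]]))
  rng <- range(nchar(x$sequence))
  cat("Lengths:", rng[1], "-", rng[2], "residues\n")
  invisible(x)
}

#' @export
as.data.frame.seqset <- function(x, ...) {
  data.frame(id = x$id, sequence = x$sequence, label = x$label,
             stringsAsFactors = FALSE)
}

#' @export
`[.seqset` <- function(x, i) {
  seqset(x$id[i], x$sequence[i], x$label[i], min_length = 1L)
}

labels_factor <- function(x) factor(x$label, levels = x$class_names)
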