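#' Construct a labeled protein sequence dataset
#'
#' The central data container: an ordered collection of identified,
#' validated amino-acid sequences with optional binary class labels
#' (`"CML"` = positive, `"Control"` = negative). Internally a data frame
#' with columns `id`, `residues`, `label`.
#'
#' @param id character vector of unique sequence identifiers.
#' @param residues character vector of amino-acid strings over the 20
#'   canonical one-letter codes (validated; see [validate_sequence()]).
#' @param label optional character vector of class labels (`NA` allowed).
#' @return An object of class `protein_dataset`.
#' @export
protein_dataset <- function(id, residues, label = NULL) {
  id <- as.character(id)
  residues <- as.character(residues)
  if (length(id) != length(residues)) {
    stop("`id` and `residues` must have the same length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (is.null(label)) label <- rep(NA_character_, length(id))
  label <- as.character(label)
  if (length(label) != length(id)) {
    stop("`label` must match the number of sequences")
  }
  bad <- !vapply(residues, is_canonical, logical(1))
  if (any(bad)) {
    stop("invalid residues in sequence(s): ",
         paste(utils::head(id[bad], 5), collapse = ", "))
  }
  structure(
    data.frame(id = id, residues = residues, label = label,
               stringsAsFactors = FALSE),
    class = c("protein_dataset", "data.frame")
  )
}

is_canonical <- function(x) {
  nchar(x) > 0L && !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
}

#' Class counts of a labeled dataset
#' @param ds a `protein_dataset`.
#' @return Named integer vector of per-class sequence counts.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "protein_dataset"))
  tab <- table(ds$label, useNA = "no")
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.protein_dataset <- function(x, ...) {
  cat(sprintf("<protein_dataset> %d sequences\n", nrow(x)))
  cc <- class_counts(x)
  if (length(cc)) {
    cat("  classes:", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "),
        "\n")
  }
  if (nrow(x)) {
    cat(sprintf("  lengths: %d..%d\n",
                min(nchar(x$residues)), max(nchar(x$residues))))
  }
  invisible(x)
}

#' Validate and clean a raw amino-acid string
#'
#' Uppercases and strips whitespace/digits, then rejects sequences that are
#' empty after cleaning or contain any non-canonical residue code
#' (`B J O U X Z *`) -- ambiguous or incomplete entries are excluded rather
#' than remapped.
#'
#' @param raw a single character string.
#' @return A list with elements `accepted` (logical), `residues` (cleaned
#'   string, or `NA` when rejected) and `reason` (`NA` when accepted).
#' @examples
#' validate_sequence("acdEF gh")   # accepted, "ACDEFGH"
#' validate_sequence("ACDXFG")     # rejected: non-canonical residue X
#' @export
validate_sequence <- function(raw) {
  if (is.null(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single non-missing string")
  }
  cleaned <- toupper(gsub("[[:space:][:digit:]]", "", raw))
  if (nchar(cleaned) == 0L) {
    return(list(accepted = FALSE, residues = NA_character_,
                reason = "empty after cleaning"))
  }
  chars <- strsplit(cleaned, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    return(list(accepted = FALSE, residues = NA_character_,
                reason = paste0("non-canonical residue(s): ",
                                paste(bad, collapse = ""))))
  }
  list(accepted = TRUE, residues = cleaned, reason = NA_character_)
}

#' Read a labeled FASTA file
#'
#' Labels come from a `|label=<class>` tag in the FASTA header or, with
#' priority, from a sidecar two-column tab-separated manifest
#' (`id<TAB>class`, no header). Records failing [validate_sequence()] are
#' skipped and reported in the `skipped` attribute.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param manifest optional path to a sidecar label manifest.
#' @return A `protein_dataset`; attribute `skipped` is a data frame of
#'   skipped ids and reasons.
#' @export
read_fasta <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no parseable FASTA records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- character(0); seqs <- character(0); labels <- character(0)
  skipped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (k in seq_along(hdr)) {
    header <- sub("^>", "", lines[hdr[k]])
    first <- strsplit(header, "[ \t]")[[1]][1]
    id <- strsplit(first, "|", fixed = TRUE)[[1]][1]
    lab <- NA_character_
    m <- regmatches(header, regexpr("\\|label=[^| \t]+", header))
    if (length(m)) lab <- sub("\\|label=", "", m)
    body <- if (hdr[k] + 1L > ends[k]) "" else
      paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    v <- validate_sequence(if (nchar(body)) body else " ")
    if (!v$accepted) {
      skipped <- rbind(skipped, data.frame(id = id, reason = v$reason,
                                           stringsAsFactors = FALSE))
      next
    }
    if (id %in% ids) stop("duplicate sequence id in FASTA: ", id)
    ids <- c(ids, id); seqs <- c(seqs, v$residues); labels <- c(labels, lab)
  }
  if (!length(ids)) stop("no valid records in ", path)
  if (!is.null(manifest)) {
    man <- utils::read.delim(manifest, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("id", "class"))
    idx <- match(ids, man$id)
    labels <- ifelse(is.na(idx), labels, man$class[idx])
  }
  ds <- protein_dataset(ids, seqs, labels)
  attr(ds, "skipped") <- skipped
  ds
}

#' Write a dataset as FASTA
#'
#' Labels (when present) are carried as `|label=<class>` header tags so that
#' `read_fasta(write_fasta(ds))` round-trips ids, residues and labels.
#'
#' @param ds a `protein_dataset`.
#' @param path output file path.
#' @param width line-wrap width for residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path, width = 60L) {
  stopifnot(inherits(ds, "protein_dataset"))
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(ds))) {
    tag <- if (is.na(ds$label[i])) "" else paste0("|label=", ds$label[i])
    writeLines(paste0(">", ds$id[i], tag), con, sep = "\n")
    s <- ds$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Specification of a train/validation/test split
#'
#' @param fractions numeric length-3 vector of (train, validation, test)
#'   proportions, each in (0,1), summing to 1 (tolerance 1e-9).
#' @param seed integer seed driving the (only) shuffling randomness.
#' @param stratified draw splits per class (default `TRUE`).
#' @return A `split_spec` list.
#' @export
split_spec <- function(fractions = c(train = 0.70, validation = 0.15,
                                     test = 0.15),
                       seed = 0L, stratified = TRUE) {
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1)) {
    stop("`fractions` must be three proportions in (0, 1)")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("`fractions` must sum to 1")
  names(fractions) <- c("train", "validation", "test")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' Deterministic rounding: within each class, each split receives
#' `floor(fraction * class_size)` sequences and any remainder goes to the
#' training split, so a balanced 1,600-sequence corpus at 70/15/15 yields
#' exactly 1,120/240/240 with 560 + 560 per class in training. Shuffling is
#' driven solely by `spec$seed`; the three outputs partition the input.
#'
#' @param ds a fully labeled `protein_dataset` (at least one sequence per
#'   class).
#' @param spec a [split_spec()].
#' @return Named list of three `protein_dataset`s: `train`, `validation`,
#'   `test`.
#' @export
stratified_split <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "protein_dataset"), inherits(spec, "split_spec"))
  if (anyNA(ds$label)) stop("all sequences must be labeled before splitting")
  classes <- unique(ds$label)
  sizes <- table(ds$label)
  if (any(sizes < 3L)) {
    stop("each class needs at least as many sequences as splits (3)")
  }
  take <- list(train = integer(0), validation = integer(0), test = integer(0))
  groups <- if (spec$stratified) classes else "all"
  for (cl in groups) {
    idx <- if (spec$stratified) which(ds$label == cl) else seq_len(nrow(ds))
    idx <- with_seed(spec$seed,
                     idx[sample.int(length(idx))])
    n <- length(idx)
    n_val <- floor(spec$fractions[["validation"]] * n)
    n_test <- floor(spec$fractions[["test"]] * n)
    n_train <- n - n_val - n_test  # floor(train * n) + remainder
    take$train <- c(take$train, idx[seq_len(n_train)])
    take$validation <- c(take$validation, idx[n_train + seq_len(n_val)])
    take$test <- c(take$test, idx[n_train + n_val + seq_len(n_test)])
  }
  out <- lapply(take, function(i) {
    i <- sort(i)
    protein_dataset(ds$id[i], ds$residues[i], ds$label[i])
  })
  out
}

#' Write a split to disk
#'
#' Three FASTA files (`<prefix>_train.fasta`, ...) plus a JSON manifest
#' mapping each split to its sequence ids.
#'
#' @param splits result of [stratified_split()].
#' @param prefix output path prefix.
#' @return Paths of the files written, invisibly.
#' @export
write_split <- function(splits, prefix) {
  paths <- character(0)
  for (nm in names(splits)) {
    p <- paste0(prefix, "_", nm, ".fasta")
    write_fasta(splits[[nm]], p)
    paths <- c(paths, p)
  }
  manifest <- lapply(splits, function(d) d$id)
  mp <- paste0(prefix, "_splits.json")
  jsonlite::write_json(manifest, mp, auto_unbox = FALSE, pretty = TRUE)
  invisible(c(paths, mp))
}
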