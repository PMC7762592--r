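# Readers and writers for genome-length inputs and classification outputs.

#' Read genome lengths from a FASTA file
#'
#' One record per sequence; the length is the residue count (ambiguity codes
#' included; dsDNA assumed, 1 residue = 1 bp) and the id is the header up to
#' the first whitespace. Plain and gzip-compressed FASTA are accepted.
#'
#' @param path FASTA or FASTA.gz path.
#' @param source Value for the `source` column (default `"isolate"`).
#' @return Data frame of genome records: `id`, `length_bp`, `source`.
#' @export
read_fasta_lengths <- function(path, source = "isolate") {
  if (!file.exists(path)) stop("no such file: ", path)
  widths <- tryCatch(
    Biostrings::fasta.seqlengths(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  data.frame(
    id = sub("\\s.*$", "", names(widths)),
    length_bp = as.integer(unname(widths)),
    source = source,
    stringsAsFactors = FALSE
  )
}

#' Read genome lengths from a tabular file
#'
#' Accepts TSV or CSV with an `id` and a `length_bp` (or `length`) column;
#' the delimiter and the presence of a header are auto-detected. Duplicate
#' ids and non-numeric lengths are rejected with row-level messages.
#'
#' @param path TSV/CSV path.
#' @param source Value for the `source` column (default `"isolate"`).
#' @return Data frame of genome records: `id`, `length_bp`, `source`.
#' @export
read_length_table <- function(path, source = "isolate") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    warning("empty genome-length table: ", path)
    return(data.frame(id = character(0), length_bp = integer(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(all(is.na(as.numeric(fields))))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (!has_header) {
    names(tab)[1:2] <- c("id", "length_bp")
  } else {
    names(tab) <- tolower(names(tab))
    if (!"length_bp" %in% names(tab) && "length" %in% names(tab)) {
      names(tab)[names(tab) == "length"] <- "length_bp"
    }
    if (!all(c("id", "length_bp") %in% names(tab))) {
      stop("table must have 'id' and 'length_bp' (or 'length') columns")
    }
  }
  len <- suppressWarnings(as.numeric(tab$length_bp))
  if (anyNA(len)) {
    bad <- which(is.na(len))
    stop("non-numeric genome length in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    dup <- unique(tab$id[duplicated(tab$id)])
    stop("duplicated genome id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(len <= 0)) stop("genome lengths must be positive")
  data.frame(id = as.character(tab$id), length_bp = as.integer(round(len)),
             source = source, stringsAsFactors = FALSE)
}

#' Write classification outputs
#'
#' Writes the per-genome assignment table and the T-number frequency table
#' as CSV, and the small-capsid candidate report as JSON.
#'
#' @param classification A `"t_classification"` from [classify_batch()].
#' @param dir Output directory (created if needed).
#' @param threshold_t Candidate threshold passed to [candidate_report()].
#' @return Named vector of the paths written, invisibly.
#' @export
write_classification <- function(classification, dir, threshold_t = 4) {
  stopifnot(inherits(classification, "t_classification"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    assignments = file.path(dir, "assignments.csv"),
    frequency = file.path(dir, "t_frequency.csv"),
    candidates = file.path(dir, "candidates.json")
  )
  utils::write.csv(classification$assignments, paths["assignments"],
                   row.names = FALSE)
  utils::write.csv(classification$frequency, paths["frequency"],
                   row.names = FALSE)
  rep <- candidate_report(classification, threshold_t)
  jsonlite::write_json(
    list(threshold_t = rep$threshold_t,
         n_candidates = nrow(rep$candidates),
         counts = rep$counts,
         candidates = rep$candidates),
    paths["candidates"], auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(paths)
}
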