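# Query input readers: FASTA + dot-bracket, Stockholm (with SS_cons),
# Clustal.

# normalize an SS_cons-style consensus line to plain dot-bracket
normalize_ss <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  open <- chars %in% c("(", "<", "[", "{")
  close <- chars %in% c(")", ">", "]", "}")
  out <- rep(".", length(chars))
  out[open] <- "("
  out[close] <- ")"
  paste(out, collapse = "")
}

#' Read a query from FASTA plus an optional dot-bracket file
#'
#' The structure file holds one dot-bracket line (comment lines with
#' `#` or `>` are ignored).
#'
#' @param fasta path to a FASTA file (one or more rows of an ungapped
#'   or aligned query)
#' @param structure_file optional path to the consensus dot-bracket
#' @return a [query_input()]
#' @export
read_query_fasta <- function(fasta, structure_file = NULL) {
  seqs <- read_fasta(fasta)
  structure <- NULL
  if (!is.null(structure_file)) {
    lines <- readLines(structure_file)
    lines <- trimws(lines[!grepl("^[#>]", lines) & nzchar(trimws(lines))])
    if (length(lines) == 0) stop("no structure line in ", structure_file,
                                 call. = FALSE)
    structure <- normalize_ss(lines[1])
  }
  query_input(unname(seqs), structure = structure,
              id = names(seqs)[1] %||% "query")
}

#' Read a query from a Stockholm alignment
#'
#' Parses the sequence rows and the `#=GC SS_cons` consensus structure
#' (wuss brackets are normalized to plain dot-bracket).
#'
#' @param path Stockholm file
#' @return a [query_input()]
#' @export
read_query_stockholm <- function(path) {
  lines <- readLines(path)
  seqs <- list()
  ss <- character(0)
  for (ln in lines) {
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (!grepl("^#", ln) && !grepl("^//", ln) && grepl("\\S\\s+\\S", ln)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) == 2) {
        seqs[[parts[1]]] <- paste0(seqs[[parts[1]]] %||% "", parts[2])
      }
    }
  }
  if (length(seqs) == 0) stop("no sequences in Stockholm file ", path,
                              call. = FALSE)
  structure <- if (length(ss) > 0) normalize_ss(paste(ss, collapse = "")) else
    NULL
  rows <- unlist(seqs, use.names = FALSE)
  rows <- gsub("[~_,:]", ".", rows)
  query_input(rows, structure = structure, id = names(seqs)[1])
}

#' Read a query from a Clustal alignment
#'
#' @param path Clustal file (structure must be supplied separately)
#' @param structure_file optional dot-bracket file
#' @return a [query_input()]
#' @export
read_query_clustal <- function(path, structure_file = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
    stop("not a Clustal file: ", path, call. = FALSE)
  }
  seqs <- list()
  for (ln in lines[-1]) {
    if (!grepl("^\\S+\\s+\\S+", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2 || grepl("^[*:. ]+$", parts[2])) next
    seqs[[parts[1]]] <- paste0(seqs[[parts[1]]] %||% "", parts[2])
  }
  if (length(seqs) == 0) stop("no sequences in Clustal file ", path,
                              call. = FALSE)
  structure <- NULL
  if (!is.null(structure_file)) {
    sl <- readLines(structure_file)
    sl <- trimws(sl[!grepl("^[#>]", sl) & nzchar(trimws(sl))])
    structure <- normalize_ss(sl[1])
  }
  query_input(unlist(seqs, use.names = FALSE), structure = structure,
              id = names(seqs)[1])
}
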