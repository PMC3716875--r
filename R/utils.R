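# Shared low-level helpers: residue coding, score discretization,
# dot-bracket parsing, plain FASTA I/O.

RNA_BASES <- c("A", "C", "G", "U")

# ordered canonical pairs (left, right)
CANONICAL_PAIRS <- matrix(c("A", "U",
                            "U", "A",
                            "C", "G",
                            "G", "C",
                            "G", "U",
                            "U", "G"), ncol = 2, byrow = TRUE)

#' Round to integer centi-units, half away from zero
#'
#' All score contributions are discretized to integer hundredths; this
#' is the single rounding rule used throughout the scoring model.
#'
#' @param x numeric
#' @return numeric holding integers
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Encode an RNA sequence as integer codes
#'
#' A=0, C=1, G=2, U=3, N=4; T is mapped to U, lower case accepted.
#' Any other character is rejected (parse time is the only place where
#' alphabet errors can arise).
#'
#' @param x a single character string
#' @return integer vector
#' @export
encode_residues <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  chars[chars == "T"] <- "U"
  code <- match(chars, c(RNA_BASES, "N")) - 1L
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop("invalid residue '", chars[bad], "' at position ", bad,
         " (alphabet is A,C,G,U,T,N)", call. = FALSE)
  }
  code
}

decode_residues <- function(code) {
  paste(c(RNA_BASES, "N")[code + 1L], collapse = "")
}

is_canonical_code <- function(a, b) {
  # a, b integer codes 0..3
  (a == 0L & b == 3L) | (a == 3L & b == 0L) |
    (a == 1L & b == 2L) | (a == 2L & b == 1L) |
    (a == 2L & b == 3L) | (a == 3L & b == 2L)
}

#' Parse a dot-bracket string into base pairs
#'
#' @param structure dot-bracket string using `(`, `)` and `.`
#' @return integer matrix with columns `i`, `j` (1-based, i < j),
#'   ordered by `i`
#' @examples
#' db_pairs("((...))")
#' @export
db_pairs <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  ok <- chars %in% c("(", ")", ".")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("invalid structure character '", chars[bad], "' at position ", bad,
         call. = FALSE)
  }
  stack <- integer(0)
  pi <- integer(0)
  pj <- integer(0)
  for (t in seq_along(chars)) {
    if (chars[t] == "(") {
      stack <- c(stack, t)
    } else if (chars[t] == ")") {
      if (length(stack) == 0) {
        stop("unbalanced structure: unmatched ')' at position ", t,
             call. = FALSE)
      }
      pi <- c(pi, stack[length(stack)])
      pj <- c(pj, t)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) {
    stop("unbalanced structure: unmatched '(' at position ", stack[1],
         call. = FALSE)
  }
  m <- cbind(i = pi, j = pj)
  m[order(m[, 1]), , drop = FALSE]
}

#' Render base pairs as a dot-bracket string
#' @param pairs matrix with columns i, j
#' @param len structure length
#' @return character string
#' @keywords internal
pairs_to_db <- function(pairs, len) {
  s <- rep(".", len)
  if (length(pairs) > 0 && nrow(pairs) > 0) {
    s[pairs[, 1]] <- "("
    s[pairs[, 2]] <- ")"
  }
  paste(s, collapse = "")
}

#' Read a (multi-record) FASTA file
#'
#' Uses Biostrings when available; otherwise a minimal reader.  T is not
#' converted here; sequence consumers encode and validate residues.
#'
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    return(setNames(as.character(x), names(x)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  setNames(unname(seqs), id)
}

#' Write sequences to a FASTA file
#' @param seqs named character vector
#' @param path file path
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
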