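# Sparse base pair probability matrices.
#
# A bpp_matrix holds the substochastic pair probabilities of one
# sequence as triplets (i, j, p) with i < j.  Target matrices are
# span-limited (j - i <= max_span); query matrices are not.

#' Construct a sparse base pair probability matrix
#'
#' @param length sequence length (positions are 1-based)
#' @param i,j integer vectors of pair ends, `i < j`
#' @param p probabilities in (0, 1]
#' @param max_span optional maximal span `j - i` (targets); `NULL` for
#'   unbounded (queries)
#' @param p_min probability cutoff associated with the matrix; entries
#'   below it are dropped
#' @return object of class `bpp_matrix`
#' @export
bpp_matrix <- function(length, i = integer(0), j = integer(0),
                       p = numeric(0), max_span = NULL, p_min = 0) {
  stopifnot(length >= 1)
  i <- as.integer(i); j <- as.integer(j); p <- as.numeric(p)
  if (!(base::length(i) == base::length(j) &&
        base::length(j) == base::length(p))) {
    stop("i, j, p must have equal length", call. = FALSE)
  }
  if (any(i < 1 | j > length | i >= j)) {
    stop("pair indices must satisfy 1 <= i < j <= length", call. = FALSE)
  }
  if (any(p <= 0 | p > 1)) {
    stop("probabilities must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(paste(i, j))) {
    stop("duplicate base pair entries", call. = FALSE)
  }
  keep <- p >= p_min
  i <- i[keep]; j <- j[keep]; p <- p[keep]
  if (!is.null(max_span) && base::length(i) > 0 && any(j - i > max_span)) {
    stop("pair span exceeds max_span", call. = FALSE)
  }
  # substochasticity: per position, total pairing probability <= 1 (+ slack)
  if (base::length(i) > 0) {
    tot <- rowsum(c(p, p), c(i, j))
    if (any(tot > 1 + 1e-6)) {
      bad <- rownames(tot)[which(tot > 1 + 1e-6)[1]]
      stop("pair probabilities at position ", bad, " sum to ",
           format(max(tot)), " > 1", call. = FALSE)
    }
  }
  ord <- order(i, j)
  structure(list(length = as.integer(length),
                 i = i[ord], j = j[ord], p = p[ord],
                 max_span = if (is.null(max_span)) NULL else as.integer(max_span),
                 p_min = p_min),
            class = "bpp_matrix")
}

#' @export
print.bpp_matrix <- function(x, ...) {
  cat("bpp_matrix: length", x$length, "with", length(x$i), "pairs",
      if (!is.null(x$max_span)) paste0("(max span ", x$max_span, ")"), "\n")
  invisible(x)
}

#' Read base pair probabilities from sparse triplet text
#'
#' Lines hold `i j p` (whitespace separated, 1-based, i < j,
#' p in (0, 1]); `#` starts a comment.  Entries below `p_min` are
#' dropped; the span limit is inferred as the maximal `j - i`.
#'
#' @param path file path
#' @param p_min probability cutoff (default 0: keep everything)
#' @param length sequence length; inferred as `max(j)` when `NULL`
#' @return a [bpp_matrix()]
#' @export
read_bpp <- function(path, p_min = 0, length = NULL) {
  lines <- readLines(path)
  if (is.null(length)) {
    hdr <- grep("^#\\s*length=", lines, value = TRUE)
    if (base::length(hdr) > 0) {
      length <- as.integer(sub("^#\\s*length=\\s*", "", hdr[1]))
    }
  }
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (base::length(lines) == 0) {
    return(bpp_matrix(length %||% 1L, p_min = p_min, max_span = NULL))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, base::length, 1L) != 3L)
  if (base::length(bad) > 0) {
    stop("malformed bpp line ", lineno[bad[1]], " in ", path, call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("malformed bpp line ", lineno[bad], " in ", path, call. = FALSE)
  }
  i <- m[, 1]; j <- m[, 2]; p <- m[, 3]
  if (any(i != round(i) | j != round(j) | i < 1 | i >= j)) {
    bad <- which(i != round(i) | j != round(j) | i < 1 | i >= j)[1]
    stop("invalid pair indices on bpp line ", lineno[bad], call. = FALSE)
  }
  if (any(p <= 0 | p > 1)) {
    bad <- which(p <= 0 | p > 1)[1]
    stop("invalid probability on bpp line ", lineno[bad], call. = FALSE)
  }
  if (anyDuplicated(paste(i, j))) {
    stop("duplicate base pair entries in ", path, call. = FALSE)
  }
  len <- length %||% as.integer(max(j))
  keepp <- p >= p_min
  ms <- if (any(keepp)) as.integer(max(j[keepp] - i[keepp])) else NULL
  bpp_matrix(len, i[keepp], j[keepp], p[keepp], max_span = ms, p_min = p_min)
}

#' Write a bpp_matrix as sparse triplet text
#' @param bpp a [bpp_matrix()]
#' @param path file path
#' @param digits probability precision
#' @export
write_bpp <- function(bpp, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# length=", bpp$length), con)
  if (length(bpp$i) > 0) {
    writeLines(paste(bpp$i, bpp$j, formatC(bpp$p, digits = digits,
                                           format = "g"), sep = "\t"), con)
  }
  invisible(path)
}
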