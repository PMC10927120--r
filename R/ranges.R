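#' Residue ranges
#'
#' A residue range is an ordered set of 1-based inclusive `(start, end)`
#' segments, the unit in which domain boundaries are expressed (possibly
#' discontinuous, as in ECOD-style range strings such as `"1-120,190-240"`).
#'
#' @param segments A two-column integer matrix (or coercible object) with one
#'   row per segment, columns `start` and `end`.
#' @return An object of class `residue_range`: a two-column integer matrix
#'   with rows sorted by start.
#' @examples
#' r <- residue_range(rbind(c(7, 9), c(1, 3)))
#' format_range(r)
#' @export
residue_range <- function(segments) {
  m <- matrix(as.integer(segments), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(m) == 0L) stop("residue range must be nonempty")
  if (any(!is.finite(m))) stop("non-finite segment bound")
  if (any(m[, "start"] > m[, "end"])) stop("inverted segment")
  m <- m[order(m[, "start"]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-nrow(m), "end"] >= m[-1L, "start"]))
    stop("overlap between segments")
  structure(m, class = "residue_range")
}

#' Parse an ECOD-style range string
#'
#' @param text A string of comma-separated `"start-end"` tokens, e.g.
#'   `"1-3,7-9"`. Segments are validated (no inversion, no overlap) but
#'   touching segments are kept as written, not merged.
#' @return A [residue_range()].
#' @examples
#' parse_range("5-10")
#' parse_range("1-3,7-9")
#' @export
parse_range <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), ",", fixed = TRUE)[[1L]]
  if (length(toks) == 0L) stop("empty range string")
  parts <- regmatches(toks, regexec("^\\s*(\\d+)-(\\d+)\\s*$", toks))
  if (any(lengths(parts) != 3L)) stop("malformed range token in: ", text)
  m <- t(vapply(parts, function(p) as.integer(p[2:3]), integer(2)))
  residue_range(m)
}

#' Format a residue range as an ECOD-style string
#'
#' Inverse of [parse_range()]: `parse_range(format_range(r))` reproduces `r`.
#'
#' @param r A [residue_range()].
#' @return A string such as `"1-3,7-9"`.
#' @export
format_range <- function(r) {
  stopifnot(inherits(r, "residue_range"))
  paste(paste0(r[, "start"], "-", r[, "end"]), collapse = ",")
}

#' Residues covered by a range
#'
#' @param r A [residue_range()].
#' @return Integer vector of all residue indices in the range, ascending.
#' @export
range_residues <- function(r) {
  stopifnot(inherits(r, "residue_range"))
  unlist(lapply(seq_len(nrow(r)), function(i) seq.int(r[i, 1L], r[i, 2L])),
         use.names = FALSE)
}

#' Total number of residues in a range
#' @param r A [residue_range()].
#' @return Integer count.
#' @export
range_length <- function(r) {
  stopifnot(inherits(r, "residue_range"))
  sum(r[, "end"] - r[, "start"] + 1L)
}

# Build a residue_range from a sorted set of residue indices, merging
# consecutive runs into contiguous segments.
range_from_residues <- function(res) {
  res <- sort(unique(as.integer(res)))
  if (length(res) == 0L) stop("residue range must be nonempty")
  brk <- c(0L, which(diff(res) > 1L), length(res))
  segs <- t(vapply(seq_len(length(brk) - 1L), function(k) {
    c(res[brk[k] + 1L], res[brk[k + 1L]])
  }, integer(2)))
  residue_range(segs)
}

#' Jaccard index between two residue ranges
#'
#' Used to score how well a predicted domain recovers a true one.
#'
#' @param a,b [residue_range()] objects.
#' @return Intersection-over-union of the two residue sets, in \[0, 1\].
#' @export
range_jaccard <- function(a, b) {
  ra <- range_residues(a)
  rb <- range_residues(b)
  length(intersect(ra, rb)) / length(union(ra, rb))
}
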