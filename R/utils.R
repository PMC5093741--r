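# Shared helpers: sequence accessors, reverse complement, interval algebra.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input. Only `A`, `C`, `G`, `T`, `N` (any case) are
#' accepted; other IUPAC ambiguity codes are rejected because downstream
#' alignment scoring is defined over the five-letter alphabet.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements, uppercase.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  x <- toupper(x)
  check_dna(x)
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGTN]", "", x[bad][1]), "")))
    abort(sprintf(
      "%s contains characters outside {A,C,G,T,N}: %s (ambiguity codes other than N are not supported)",
      what, paste(utils::head(ch, 5), collapse = ", ")))
  }
  invisible(x)
}

# Accept a character scalar, a single-row sequence tibble, or a named list
# with a `residues` field; return the residue string.
get_residues <- function(x, what = "sequence") {
  if (is.character(x) && length(x) == 1L) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L)
      abort(sprintf("expected a single %s, got %d rows", what, nrow(x)))
    return(x$residues)
  }
  if (is.list(x) && !is.null(x$residues)) return(x$residues)
  abort(sprintf("cannot extract residues for %s", what))
}

get_seq_id <- function(x, default = "seq") {
  if (is.data.frame(x)) {
    if (nrow(x) == 1L && "id" %in% names(x)) return(x$id)
    return(default)
  }
  if (is.list(x) && "id" %in% names(x) && !is.null(x$id)) return(x$id)
  default
}

# Union size of a set of 0-based half-open intervals.
interval_union_bp <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::IRanges(start = start + 1L, end = end)
  sum(IRanges::width(IRanges::reduce(ir)))
}

# Merge 0-based half-open intervals separated by a gap <= max_gap.
merge_intervals <- function(start, end, max_gap = 0L) {
  if (length(start) == 0L)
    return(tibble(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end),
                        min.gapwidth = max_gap + 1L)
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Round half away from zero to `digits` decimals (printed-percent convention).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Longest run of a single base containing 0-based position `pos`.
homopolymer_run_at <- function(residues, pos) {
  n <- nchar(residues)
  if (pos < 0 || pos >= n) return(0L)
  base <- substr(residues, pos + 1L, pos + 1L)
  left <- pos
  while (left > 0 && substr(residues, left, left) == base) left <- left - 1L
  right <- pos + 1L
  while (right < n && substr(residues, right + 1L, right + 1L) == base)
    right <- right + 1L
  as.integer(right - left)
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(salt)) %% 2147483) + 1L
}
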